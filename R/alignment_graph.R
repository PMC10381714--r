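# Alignment-graph construction. Nodes are cross-species protein pairs
# selected from seed similarities; edges carry weights from the
# seven-parameter homogeneous/heterogeneous match/mismatch/gap scheme with
# shortest-path cutoff delta.

#' Edge-weighting parameters for the alignment graph
#'
#' The seven parameters of the weighting scheme: the path-length cutoff
#' `delta` and one weight per (topology, color) category. Topological
#' categories compare the two composite endpoints' proteins within each
#' input network: *match* = direct edge in both networks; *mismatch* =
#' direct edge in one, shortest path of length 2..`delta` in the other;
#' *gap* = direct edge in one, distance beyond `delta` (or disconnected)
#' in the other. The color class is *homogeneous* when all four proteins
#' carry the same color, *heterogeneous* otherwise.
#'
#' Defaults are the published operating point: delta 2 and weights
#' 1 / 0.9 / 0.5 / 0.4 / 0.2 / 0.1 for homogeneous/heterogeneous
#' match, mismatch and gap respectively. The conventional ordering
#' `hom_match >= het_match >= hom_mismatch >= het_mismatch >= hom_gap >=
#' het_gap >= 0` is checked with a warning, not an error.
#'
#' @param delta integer >= 1, shortest-path cutoff separating mismatch
#'   from gap.
#' @param hom_match,het_match,hom_mismatch,het_mismatch,hom_gap,het_gap
#'   finite edge weights per category.
#' @return object of class `weight_params` with elements `delta` and
#'   `weights` (named numeric of length 6).
#' @export
weight_params <- function(delta = 2L, hom_match = 1, het_match = 0.9,
                          hom_mismatch = 0.5, het_mismatch = 0.4,
                          hom_gap = 0.2, het_gap = 0.1) {
  delta <- as.integer(delta)
  stopifnot(length(delta) == 1L, !is.na(delta), delta >= 1L)
  w <- c(hom_match = hom_match, het_match = het_match,
         hom_mismatch = hom_mismatch, het_mismatch = het_mismatch,
         hom_gap = hom_gap, het_gap = het_gap)
  if (any(!is.finite(w))) stop("all weights must be finite")
  if (any(diff(unname(w)) > 1e-12) || any(w < 0))
    warning(paste("weights violate the conventional ordering",
                  "hom_match >= het_match >= hom_mismatch >= het_mismatch",
                  ">= hom_gap >= het_gap >= 0"))
  structure(list(delta = delta, weights = w), class = "weight_params")
}

#' @export
print.weight_params <- function(x, ...) {
  cat(sprintf("weight_params: delta = %d; %s\n", x$delta,
              paste(names(x$weights), x$weights, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Select alignment-graph composite nodes from seed pairs
#'
#' Each composite node represents a pair of similar proteins, one from each
#' network. Under `best_match`, for every protein of network 1 the pair(s)
#' with maximal similarity are kept, symmetrically for network 2, and the
#' union returned (ties keep all tied pairs, so the mapping stays
#' many-to-many). Under `all_pairs`, every valid seed pair is kept. Seeds
#' referencing proteins absent from their network are dropped with a
#' warning.
#'
#' @param net1,net2 the two [ppi_network()]s.
#' @param seeds a [seed_pair_map()].
#' @param strategy `"best_match"` (default) or `"all_pairs"`.
#' @return data.frame of class `composite_nodes` with columns `a`, `b`,
#'   `similarity`, sorted lexicographically by `(a, b)`.
#' @export
select_composite_nodes <- function(net1, net2, seeds,
                                   strategy = c("best_match", "all_pairs")) {
  strategy <- match.arg(strategy)
  s <- as.data.frame(seeds, stringsAsFactors = FALSE)
  if (!nrow(s)) stop("empty alignment-graph node set: no seed pairs supplied")
  known <- s$a %in% net1$nodes & s$b %in% net2$nodes
  if (any(!known))
    warning(sprintf("%d seed pair(s) reference proteins absent from the networks; dropped",
                    sum(!known)))
  s <- s[known, , drop = FALSE]
  if (!nrow(s)) stop("empty alignment-graph node set: no seed pair survives")
  if (strategy == "best_match") {
    pick <- function(group) {
      unlist(lapply(split(seq_len(nrow(s)), group), function(i)
        i[s$similarity[i] >= max(s$similarity[i])]), use.names = FALSE)
    }
    s <- s[sort(unique(c(pick(s$a), pick(s$b)))), , drop = FALSE]
  }
  s <- s[order(s$a, s$b), , drop = FALSE]
  rownames(s) <- NULL
  class(s) <- c("composite_nodes", "data.frame")
  s
}

#' Unweighted shortest-path distance between two proteins
#'
#' @param net a [ppi_network()].
#' @param p,q distinct protein ids in `net`.
#' @return integer path length, or `Inf` when disconnected.
#' @export
pair_distance <- function(net, p, q) {
  if (identical(p, q))
    stop("pair_distance is undefined for identical proteins (composite endpoints never share a protein within one network)")
  if (!(p %in% net$nodes) || !(q %in% net$nodes))
    stop("both proteins must be present in the network")
  g <- as_igraph(net)
  igraph::distances(g, v = p, to = q)[1, 1]
}

# Vectorized topological classification from precomputed distances.
classify_topology <- function(d1, d2, delta) {
  out <- rep("none", length(d1))
  out[d1 == 1 & d2 == 1] <- "match"
  out[(d1 == 1 & d2 > 1 & d2 <= delta) | (d2 == 1 & d1 > 1 & d1 <= delta)] <- "mismatch"
  out[(d1 == 1 & d2 > delta) | (d2 == 1 & d1 > delta)] <- "gap"
  out
}

#' Classify a candidate alignment-graph edge
#'
#' Applies the topological and color rules to one pair of composite nodes.
#' Composite nodes sharing a protein in either coordinate get no edge
#' (`NULL`), as do pairs with no direct interaction on either side.
#'
#' @param u,v composite nodes: lists or named vectors with elements `a`
#'   (protein in `net1`) and `b` (protein in `net2`).
#' @param net1,net2 the input [ppi_network()]s.
#' @param delta path-length cutoff (see [weight_params()]).
#' @return `NULL` when no edge arises, else a list with elements
#'   `topology` (`"match"`, `"mismatch"` or `"gap"`), `color_class`
#'   (`"homogeneous"` or `"heterogeneous"`) and `category` (e.g.
#'   `"hom_match"`, naming the weight to apply).
#' @export
classify_edge <- function(u, v, net1, net2, delta = 2L) {
  ua <- as.character(u[["a"]]); ub <- as.character(u[["b"]])
  va <- as.character(v[["a"]]); vb <- as.character(v[["b"]])
  if (ua == va && ub == vb) stop("classify_edge requires two distinct composite nodes")
  if (ua == va || ub == vb) return(NULL)
  d1 <- pair_distance(net1, ua, va)
  d2 <- pair_distance(net2, ub, vb)
  topo <- classify_topology(d1, d2, delta)
  if (topo == "none") return(NULL)
  hom <- net1$colors[[ua]] == net1$colors[[va]] &&
    net2$colors[[ub]] == net2$colors[[vb]] &&
    net1$colors[[ua]] == net2$colors[[ub]]
  cls <- if (hom) "homogeneous" else "heterogeneous"
  list(topology = topo, color_class = cls,
       category = paste0(substr(cls, 1, 3), "_", topo))
}

#' Build the alignment graph of two PPI networks
#'
#' Selects composite nodes from the seeds, then classifies every unordered
#' node pair with the match/mismatch/gap rules and attaches the configured
#' weight. Per-category edge counts are reported via `message()`.
#'
#' @param net1,net2 the input [ppi_network()]s.
#' @param seeds a [seed_pair_map()].
#' @param params a [weight_params()].
#' @param strategy composite-node selection strategy, see
#'   [select_composite_nodes()].
#' @return object of class `alignment_graph`: list with `nodes` (the
#'   composite-node data.frame), `edges` (data.frame `i`, `j`, `weight`,
#'   `category` indexing into `nodes`), `params`, and `networks` (the two
#'   input names).
#' @export
build_alignment_graph <- function(net1, net2, seeds, params = weight_params(),
                                  strategy = "best_match") {
  stopifnot(inherits(params, "weight_params"))
  if (!n_edges(net1) || !n_edges(net2)) stop("input networks must be non-empty")
  nodes <- select_composite_nodes(net1, net2, seeds, strategy)
  m <- nrow(nodes)
  edges <- data.frame(i = integer(0), j = integer(0), weight = numeric(0),
                      category = character(0), stringsAsFactors = FALSE)
  if (m >= 2L) {
    ua <- unique(nodes$a); ub <- unique(nodes$b)
    D1 <- igraph::distances(as_igraph(net1), v = ua, to = ua)
    D2 <- igraph::distances(as_igraph(net2), v = ub, to = ub)
    pr <- which(upper.tri(matrix(NA_integer_, m, m)), arr.ind = TRUE)
    i <- pr[, 1]; j <- pr[, 2]
    ai <- nodes$a[i]; aj <- nodes$a[j]
    bi <- nodes$b[i]; bj <- nodes$b[j]
    d1 <- D1[cbind(match(ai, ua), match(aj, ua))]
    d2 <- D2[cbind(match(bi, ub), match(bj, ub))]
    topo <- classify_topology(d1, d2, params$delta)
    topo[ai == aj | bi == bj] <- "none"  # shared-protein pairs: no edge
    keep <- topo != "none"
    if (any(keep)) {
      c1 <- net1$colors; c2 <- net2$colors
      hom <- c1[ai] == c1[aj] & c2[bi] == c2[bj] & c1[ai] == c2[bi]
      category <- paste0(ifelse(hom[keep], "hom", "het"), "_", topo[keep])
      edges <- data.frame(i = i[keep], j = j[keep],
                          weight = unname(params$weights[category]),
                          category = category, stringsAsFactors = FALSE)
    }
  }
  counts <- table(factor(edges$category, levels = names(params$weights)))
  message(sprintf("alignment graph: %d composite nodes, %d edges (%s)",
                  m, nrow(edges),
                  paste(names(counts), counts, sep = "=", collapse = ", ")))
  structure(list(nodes = nodes, edges = edges, params = params,
                 networks = c(net1$name, net2$name)),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(sprintf("alignment_graph (%s ~ %s): %d composite nodes, %d edges\n",
              x$networks[1], x$networks[2], nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Composite-node labels of an alignment graph
#' @param ag an [build_alignment_graph()] result.
#' @return character vector `"a|b"` per composite node.
#' @export
node_labels <- function(ag) paste(ag$nodes$a, ag$nodes$b, sep = "|")

#' Weighted adjacency matrix of an alignment graph
#' @param ag an `alignment_graph`.
#' @return symmetric numeric matrix with composite-node labels as dimnames.
#' @export
adjacency_matrix <- function(ag) {
  m <- nrow(ag$nodes)
  lab <- node_labels(ag)
  A <- matrix(0, m, m, dimnames = list(lab, lab))
  if (nrow(ag$edges)) {
    A[cbind(ag$edges$i, ag$edges$j)] <- ag$edges$weight
    A[cbind(ag$edges$j, ag$edges$i)] <- ag$edges$weight
  }
  A
}

#' Export an alignment graph as TSV plus JSON parameter sidecar
#'
#' TSV columns: `node1` (`a|b`), `node2`, `weight`, `category`. The sidecar
#' (same path, `.json`) records delta and the seven weights for provenance.
#'
#' @param ag an `alignment_graph`.
#' @param path output TSV path.
#' @export
write_alignment_graph <- function(ag, path) {
  lab <- node_labels(ag)
  df <- data.frame(node1 = lab[ag$edges$i], node2 = lab[ag$edges$j],
                   weight = ag$edges$weight, category = ag$edges$category,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(networks = ag$networks, n_nodes = nrow(ag$nodes),
         n_edges = nrow(ag$edges), delta = ag$params$delta,
         weights = as.list(ag$params$weights)),
    paste0(sub("\\.tsv$", "", path), ".json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
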