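# Readers and writers for the plain-text formats the pipeline touches:
# tab-separated edge lists (plain or STRING-flavoured), seed-pair tables,
# and module reports.

#' Construct a protein-protein interaction network
#'
#' A `ppi_network` is an undirected graph over opaque, case-sensitive
#' protein identifiers. Each node carries a categorical `color` (all nodes
#' share one color unless declared otherwise) and each edge an optional
#' confidence in \[0, 1\]. Self-loops are rejected; duplicate records of the
#' same unordered edge are collapsed keeping the highest confidence.
#'
#' @param edges data.frame with columns `a`, `b` and optionally
#'   `confidence` (defaults to 1).
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers beyond the edge endpoints.
#' @param colors optional named character vector mapping node id to color;
#'   nodes not named get `default_color`.
#' @param name label for the network.
#' @param default_color color assigned where none is declared.
#' @return An object of class `ppi_network` with elements `name`, `nodes`,
#'   `colors` (named by node) and `edges` (canonical `a < b` order).
#' @export
ppi_network <- function(edges, nodes = NULL, colors = NULL, name = "network",
                        default_color = "protein") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) == 2L) edges$confidence <- 1
  names(edges)[1:3] <- c("a", "b", "confidence")
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$confidence <- as.numeric(edges$confidence)
  if (any(edges$a == edges$b)) stop("self-loops are not allowed in a ppi_network")
  if (any(!is.finite(edges$confidence) | edges$confidence < 0 | edges$confidence > 1))
    stop("edge confidence must be a real number in [0, 1]")
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]
  edges$a[swap] <- edges$b[swap]
  edges$b[swap] <- tmp
  key <- paste(edges$a, edges$b, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -edges$confidence)
    edges <- edges[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  }
  node_ids <- sort(unique(c(edges$a, edges$b, as.character(nodes))))
  col <- stats::setNames(rep(default_color, length(node_ids)), node_ids)
  if (!is.null(colors)) {
    known <- intersect(names(colors), node_ids)
    col[known] <- colors[known]
  }
  edges <- edges[order(edges$a, edges$b), c("a", "b", "confidence"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(name = name, nodes = node_ids, colors = col, edges = edges),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network '%s': %d nodes, %d edges, %d color(s)\n",
              x$name, length(x$nodes), nrow(x$edges),
              length(unique(x$colors))))
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param net a [ppi_network()].
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Convert a ppi_network to an igraph object
#'
#' @param net a [ppi_network()].
#' @return an undirected `igraph` graph with vertex attribute `color`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = net$nodes,
                          color = unname(net$colors[net$nodes]),
                          stringsAsFactors = FALSE))
}

split_fields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

#' Read a PPI network from an edge-list or STRING-style TSV file
#'
#' Two dialects are supported. `edgelist`: `idA<TAB>idB[<TAB>confidence]`
#' with `#` comment lines, plus optional `!node<TAB>id[<TAB>color]` lines
#' declaring colored and/or isolated nodes. `string_tsv`: a STRING export
#' with columns `protein1 protein2 combined_score` and a tolerated header
#' line; scores are auto-detected as either reals in \[0, 1\] or integers
#' 0-999 (values above 1 are divided by 1000).
#'
#' Edges with confidence below `min_confidence` are discarded, emulating a
#' score cut on a STRING export (the conventional high-confidence cut is
#' 0.7). Isolated nodes survive filtering only when declared via `!node`.
#'
#' @param path file to read.
#' @param format `"edgelist"` or `"string_tsv"`.
#' @param min_confidence minimum confidence for an edge to be kept.
#' @param name network label; defaults to the file name.
#' @return a [ppi_network()].
#' @export
read_network <- function(path, format = c("edgelist", "string_tsv"),
                         min_confidence = 0, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  stopifnot(length(min_confidence) == 1L, min_confidence >= 0, min_confidence <= 1)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*(#|$)", lines))

  a <- character(0); b <- character(0); conf <- numeric(0)
  decl_id <- character(0); decl_color <- character(0)

  if (format == "edgelist") {
    for (i in idx) {
      f <- split_fields(lines[i])
      if (length(f) >= 1L && f[1] == "!node") {
        if (length(f) < 2L || !nzchar(f[2]))
          stop(sprintf("%s: malformed !node line %d", path, i))
        decl_id <- c(decl_id, f[2])
        decl_color <- c(decl_color, if (length(f) >= 3L) f[3] else "protein")
      } else {
        if (length(f) < 2L || length(f) > 3L || !nzchar(f[1]) || !nzchar(f[2]))
          stop(sprintf("%s: malformed edge line %d (expected idA<TAB>idB[<TAB>confidence])",
                       path, i))
        ci <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3])) else 1
        if (is.na(ci))
          stop(sprintf("%s: malformed confidence value on line %d", path, i))
        a <- c(a, f[1]); b <- c(b, f[2]); conf <- c(conf, ci)
      }
    }
  } else {
    if (length(idx)) {
      f1 <- split_fields(lines[idx[1]])
      third <- if (length(f1) >= 3L) suppressWarnings(as.numeric(f1[3])) else NA
      if (grepl("protein", f1[1], ignore.case = TRUE) ||
          (length(f1) >= 3L && is.na(third)))
        idx <- idx[-1]  # header line
    }
    for (i in idx) {
      f <- split_fields(lines[i])
      if (length(f) < 3L)
        stop(sprintf("%s: malformed STRING line %d (expected protein1 protein2 combined_score)",
                     path, i))
      ci <- suppressWarnings(as.numeric(f[3]))
      if (is.na(ci))
        stop(sprintf("%s: malformed combined_score on line %d", path, i))
      a <- c(a, f[1]); b <- c(b, f[2]); conf <- c(conf, ci)
    }
    if (length(conf) && any(conf > 1)) conf <- conf / 1000
  }

  loops <- a == b
  if (any(loops)) {
    warning(sprintf("%s: dropping %d self-loop edge(s)", path, sum(loops)))
    a <- a[!loops]; b <- b[!loops]; conf <- conf[!loops]
  }
  keep <- conf >= min_confidence
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  if (!length(a)) stop(sprintf("%s: no edges survive filter (min_confidence = %g)",
                               path, min_confidence))
  colors <- if (length(decl_id)) stats::setNames(decl_color, decl_id) else NULL
  ppi_network(data.frame(a = a, b = b, confidence = conf,
                         stringsAsFactors = FALSE),
              nodes = decl_id, colors = colors, name = name)
}

#' Write a network as an edge-list TSV
#'
#' Emits one `!node` declaration per node (so isolated nodes and colors
#' round-trip) followed by the edges with confidences.
#'
#' @param net a [ppi_network()].
#' @param path output file.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# network: %s", net$name), con)
  writeLines(sprintf("!node\t%s\t%s", net$nodes, unname(net$colors[net$nodes])), con)
  e <- net$edges
  writeLines(sprintf("%s\t%s\t%s", e$a, e$b,
                     formatC(e$confidence, format = "g", digits = 15)), con)
  invisible(path)
}

#' Construct a seed-pair map
#'
#' Seed pairs are scored cross-species protein pairs (typically orthologs,
#' e.g. apl-1/APP) that instantiate candidate alignment-graph nodes.
#'
#' @param a,b protein ids in network 1 / network 2 namespaces.
#' @param similarity non-negative finite similarity scores (default 1).
#' @return data.frame of class `seed_pair_map` with columns `a`, `b`,
#'   `similarity`, exact duplicates removed, input order preserved.
#' @export
seed_pair_map <- function(a, b, similarity = 1) {
  df <- data.frame(a = as.character(a), b = as.character(b),
                   similarity = as.numeric(similarity),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$similarity) | df$similarity < 0))
    stop("seed similarities must be finite and non-negative")
  key <- paste(df$a, df$b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- vapply(unique(key[dup]), function(k) {
      length(unique(df$similarity[key == k])) > 1L
    }, logical(1))
    if (any(conflict))
      stop("duplicate seed pair(s) with conflicting similarity values")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("seed_pair_map", "data.frame")
  df
}

#' Read seed pairs from a TSV file
#'
#' Format: `idA<TAB>idB[<TAB>similarity]`, `#` comments allowed; a missing
#' similarity column defaults to 1. Exact duplicate rows are dropped;
#' duplicate pairs with conflicting similarities are an error.
#'
#' @param path file to read.
#' @return a [seed_pair_map()].
#' @export
read_seed_pairs <- function(path) {
  if (!file.exists(path)) stop(sprintf("seed file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  a <- character(0); b <- character(0); s <- numeric(0)
  for (i in idx) {
    f <- split_fields(lines[i])
    if (length(f) < 2L || length(f) > 3L || !nzchar(f[1]) || !nzchar(f[2]))
      stop(sprintf("%s: malformed seed line %d (expected idA<TAB>idB[<TAB>similarity])",
                   path, i))
    si <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3])) else 1
    if (is.na(si))
      stop(sprintf("%s: malformed similarity value on line %d", path, i))
    a <- c(a, f[1]); b <- c(b, f[2]); s <- c(s, si)
  }
  if (!length(a)) {
    df <- data.frame(a = character(0), b = character(0),
                     similarity = numeric(0), stringsAsFactors = FALSE)
    class(df) <- c("seed_pair_map", "data.frame")
    return(df)
  }
  seed_pair_map(a, b, s)
}

#' Write seed pairs as TSV
#' @param seeds a [seed_pair_map()].
#' @param path output file.
#' @export
write_seed_pairs <- function(seeds, path) {
  writeLines(sprintf("%s\t%s\t%s", seeds$a, seeds$b,
                     formatC(seeds$similarity, format = "g", digits = 15)),
             path)
  invisible(path)
}

#' Write a module report (TSV plus JSON provenance sidecar)
#'
#' One row per module: index, composite-pair count, protein counts
#' (pooled and per species), member composite pairs, per-species member
#' lists, and one column per similarity measure when `scores` is given.
#' A JSON sidecar (same path with `.json` extension) records provenance.
#'
#' @param modules non-empty list of [alignment_module()] objects.
#' @param scores optional data.frame from [score_modules()] (column
#'   `module` plus one column per measure).
#' @param path output TSV path.
#' @param provenance named list echoed into the JSON sidecar (parameters,
#'   seeds, input hashes, ...).
#' @return invisibly, the TSV path.
#' @export
write_module_report <- function(modules, scores = NULL, path,
                                provenance = list()) {
  if (!length(modules)) stop("modules must be non-empty")
  join <- function(x) paste(x, collapse = ",")
  df <- data.frame(
    module = vapply(modules, function(m) m$index, integer(1)),
    n_pairs = vapply(modules, function(m)
      if (is.null(m$members)) NA_integer_ else nrow(m$members), integer(1)),
    size = vapply(modules, function(m) m$size, integer(1)),
    size_species1 = vapply(modules, function(m) length(m$projection_1), integer(1)),
    size_species2 = vapply(modules, function(m) length(m$projection_2), integer(1)),
    members = vapply(modules, function(m)
      if (is.null(m$members)) "" else join(paste(m$members$a, m$members$b, sep = "|")),
      character(1)),
    proteins_1 = vapply(modules, function(m) join(m$projection_1), character(1)),
    proteins_2 = vapply(modules, function(m) join(m$projection_2), character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    df <- merge(df, scores[, setdiff(names(scores), "size"), drop = FALSE],
                by = "module", all.x = TRUE, sort = FALSE)
    df <- df[order(df$module), , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop(sprintf("cannot write module report to %s: %s",
                                      path, conditionMessage(e))))
  sidecar <- paste0(sub("\\.tsv$", "", path), ".json")
  prov <- c(list(generated_by = paste0("localign ",
                                       as.character(utils::packageVersion("localign"))),
                 n_modules = length(modules)),
            provenance)
  jsonlite::write_json(prov, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a module report back into alignment modules
#'
#' @param path TSV written by [write_module_report()].
#' @return list of [alignment_module()] objects (score columns, if present,
#'   attached as attribute `"scores"`).
#' @export
read_module_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(members = "character",
                                            proteins_1 = "character",
                                            proteins_2 = "character"))
  splitc <- function(x) if (is.na(x) || !nzchar(x)) character(0)
                        else strsplit(x, ",", fixed = TRUE)[[1]]
  mods <- lapply(seq_len(nrow(df)), function(k) {
    mem <- splitc(df$members[k])
    members <- if (length(mem)) {
      ab <- do.call(rbind, strsplit(mem, "|", fixed = TRUE))
      data.frame(a = ab[, 1], b = ab[, 2], stringsAsFactors = FALSE)
    } else NULL
    alignment_module(df$module[k], members = members,
                     projection_1 = splitc(df$proteins_1[k]),
                     projection_2 = splitc(df$proteins_2[k]))
  })
  extra <- setdiff(names(df), c("module", "n_pairs", "size", "size_species1",
                                "size_species2", "members", "proteins_1",
                                "proteins_2"))
  if (length(extra)) attr(mods, "scores") <- df[, c("module", extra), drop = FALSE]
  mods
}
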