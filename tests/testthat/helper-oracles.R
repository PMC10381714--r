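# Independent oracles and programmatic fixtures. Everything here is
# deliberately written without reusing the package's internals: plain
# queue-based BFS, transitive-closure ancestor enumeration, and a naive
# loop-based Markov clustering, so package results can be checked against
# genuinely separate computations.

# ---- plain BFS shortest-path oracle (no igraph) -------------------------

bfs_oracle <- function(edges, nodes, from, to) {
  adj <- lapply(stats::setNames(nm = nodes), function(x) character(0))
  for (k in seq_len(nrow(edges))) {
    a <- edges$a[k]; b <- edges$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  unname(dist[to])
}

# Literal restatement of the edge rules, driven by the BFS oracle.
classify_oracle <- function(d1, d2, delta) {
  if (d1 == 1 && d2 == 1) return("match")
  if (d1 == 1 && d2 > 1 && d2 <= delta) return("mismatch")
  if (d2 == 1 && d1 > 1 && d1 <= delta) return("mismatch")
  if (d1 == 1 && d2 > delta) return("gap")
  if (d2 == 1 && d1 > delta) return("gap")
  "none"
}

# ---- random graphs and seed tables --------------------------------------

random_ppi <- function(n, p, seed, prefix = "n") {
  set.seed(seed)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(length(keep), 2)] <- TRUE
  ppi_network(data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                         stringsAsFactors = FALSE),
              nodes = ids, name = sprintf("random_%s", prefix))
}

random_seeds <- function(net1, net2, k, seed) {
  set.seed(seed)
  seed_pair_map(sample(net1$nodes, k, replace = FALSE),
                sample(net2$nodes, k, replace = FALSE))
}

# ---- naive reference MCL (dense loops, no pruning) ----------------------

mcl_reference <- function(A, inflation = 2, expansion = 2, iters = 200) {
  n <- nrow(A)
  for (i in 1:n) {
    mx <- max(A[, i])
    A[i, i] <- if (mx > 0) mx else 1
  }
  for (j in 1:n) A[, j] <- A[, j] / sum(A[, j])
  for (it in 1:iters) {
    B <- A
    for (e in seq_len(expansion - 1)) B <- B %*% A
    B <- B^inflation
    for (j in 1:n) B[, j] <- B[, j] / sum(B[, j])
    if (max(abs(B - A)) < 1e-10) { A <- B; break }
    A <- B
  }
  # read clusters: nodes supported by the same attractor rows belong together
  attractors <- which(diag(A) > 1e-8)
  assign <- integer(n)
  for (j in 1:n) assign[j] <- attractors[which.max(A[attractors, j])]
  split(seq_len(n), assign)
}

# canonical form of a partition for comparisons up to relabelling
partition_canon <- function(clusters) {
  canon <- lapply(clusters, function(x) sort(x))
  canon[order(vapply(canon, function(x) x[1], numeric(1)))]
}

# ---- ontology fixtures --------------------------------------------------

# Two-level tree with two clades of two leaves each; eight genes, four of
# them on distinct leaves and four on the root, so leaf IC = log(8),
# clade-parent IC = log(4), root IC = 0.
make_ic_fixture <- function() {
  terms <- c(root = "TO:0000001", ta = "TO:0000002", tb = "TO:0000003",
             ta1 = "TO:0000004", ta2 = "TO:0000005",
             tb1 = "TO:0000006", tb2 = "TO:0000007")
  parents <- data.frame(
    child = terms[c("ta", "tb", "ta1", "ta2", "tb1", "tb2")],
    parent = terms[c("root", "root", "ta", "ta", "tb", "tb")],
    type = "is_a", stringsAsFactors = FALSE)
  onto <- ontology_store(terms, parents)
  corpus <- list(g1 = terms[["ta1"]], g2 = terms[["ta2"]],
                 g3 = terms[["tb1"]], g4 = terms[["tb2"]],
                 g5 = terms[["root"]], g6 = terms[["root"]],
                 g7 = terms[["root"]], g8 = terms[["root"]])
  list(terms = terms, onto = onto, corpus = corpus,
       ic = compute_ic(onto, corpus))
}

# Five-term DAG with one part_of edge, for hand-checked Wang values.
make_wang_fixture <- function() {
  terms <- c(r = "W:1", a = "W:2", b = "W:3", a1 = "W:4", a2 = "W:5")
  parents <- data.frame(
    child = terms[c("a", "b", "a1", "a2")],
    parent = terms[c("r", "r", "a", "a")],
    type = c("is_a", "is_a", "is_a", "part_of"), stringsAsFactors = FALSE)
  list(terms = terms, onto = ontology_store(terms, parents))
}

# Random rooted DAG over n terms (term 1 is the single root); each later
# term gets one or two parents among the earlier ones.
random_dag <- function(n, seed) {
  set.seed(seed)
  terms <- sprintf("D:%04d", seq_len(n))
  child <- character(0); parent <- character(0); type <- character(0)
  for (i in 2:n) {
    np <- sample(1:2, 1)
    ps <- sample(seq_len(i - 1), min(np, i - 1))
    for (p in ps) {
      child <- c(child, terms[i]); parent <- c(parent, terms[p])
      type <- c(type, sample(c("is_a", "part_of"), 1))
    }
  }
  edges <- data.frame(child = child, parent = parent, type = type,
                      stringsAsFactors = FALSE)
  list(terms = terms, edges = edges,
       onto = ontology_store(terms, edges))
}

# Transitive-closure ancestor enumeration straight off the edge table.
ancestors_oracle <- function(edges, term) {
  anc <- term
  repeat {
    more <- unique(edges$parent[edges$child %in% anc])
    new <- setdiff(more, anc)
    if (!length(new)) return(anc)
    anc <- c(anc, new)
  }
}

mica_oracle <- function(edges, ic, t1, t2) {
  common <- intersect(ancestors_oracle(edges, t1), ancestors_oracle(edges, t2))
  common <- common[!is.na(ic[common])]
  if (!length(common)) return(NA_character_)
  sort(common[ic[common] == max(ic[common])])[1]
}

# ---- misc ---------------------------------------------------------------

make_module <- function(index, n_pairs, prefix = "m") {
  alignment_module(index, members = data.frame(
    a = sprintf("%s%d_a%02d", prefix, index, seq_len(n_pairs)),
    b = sprintf("%s%d_b%02d", prefix, index, seq_len(n_pairs)),
    stringsAsFactors = FALSE))
}

# adjacency matrix of disjoint cliques (optionally bridged)
clique_matrix <- function(sizes, bridge = NULL) {
  n <- sum(sizes)
  A <- matrix(0, n, n)
  off <- 0
  for (s in sizes) {
    idx <- off + seq_len(s)
    A[idx, idx] <- 1
    off <- off + s
  }
  diag(A) <- 0
  if (!is.null(bridge)) A[bridge[1], bridge[2]] <- A[bridge[2], bridge[1]] <- 1
  A
}
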