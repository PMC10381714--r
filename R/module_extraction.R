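# Conserved-module mining: a from-scratch Markov clustering (MCL)
# implementation over the alignment graph, and projection of clusters back
# to per-species protein sets.

#' Markov clustering parameters
#'
#' Canonical MCL defaults: inflation 2, expansion 2, pruning threshold
#' 1e-5, at most 100 iterations, convergence tolerance 1e-8. Self-loops
#' default to each node's maximum incident edge weight (`NULL`), the
#' standard regularization preventing period-2 oscillation on bipartite-ish
#' structure; a scalar overrides this for all nodes.
#'
#' @param inflation entrywise (Hadamard) power applied each iteration; > 1.
#' @param expansion matrix-power applied each iteration; integer >= 2.
#' @param prune_threshold entries below this are zeroed after inflation
#'   (a column's largest entry is never pruned).
#' @param max_iterations iteration cap.
#' @param convergence_tol maximum absolute entry change between successive
#'   iterations below which iteration stops.
#' @param self_loop_weight `NULL` (per-node max incident weight) or a
#'   non-negative scalar.
#' @return object of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 2, expansion = 2L, prune_threshold = 1e-5,
                       max_iterations = 100L, convergence_tol = 1e-8,
                       self_loop_weight = NULL) {
  expansion <- as.integer(expansion)
  max_iterations <- as.integer(max_iterations)
  stopifnot(inflation > 1, expansion >= 2L, prune_threshold >= 0,
            max_iterations >= 1L, convergence_tol > 0,
            is.null(self_loop_weight) || self_loop_weight >= 0)
  structure(list(inflation = inflation, expansion = expansion,
                 prune_threshold = prune_threshold,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 self_loop_weight = self_loop_weight),
            class = "mcl_params")
}

#' Markov clustering of a weighted graph
#'
#' Builds the weighted adjacency matrix with self-loops, column-normalizes
#' it to a stochastic matrix, then alternates expansion (matrix power) and
#' inflation (entrywise power followed by column renormalization) with
#' pruning of small entries, until the matrix change falls below
#' `convergence_tol` or `max_iterations` is reached (the latter with a
#' warning). Clusters are read off the limit matrix: attractor rows
#' (positive diagonal) define clusters; every node joins the attractor
#' with the largest value in its column (ties resolved to the lowest
#' cluster index, for determinism); empty clusters are dropped.
#'
#' @param graph an [build_alignment_graph()] result, or a symmetric
#'   non-negative weighted adjacency matrix.
#' @param params an [mcl_params()].
#' @return object of class `mcl_result`: `membership` (integer per node),
#'   `clusters` (list of integer node-index vectors), `labels`,
#'   `iterations`, `converged`, and `colsum_dev` (max abs deviation of
#'   column sums from 1 observed after each normalization, a numerical
#'   diagnostic).
#' @export
mcl_cluster <- function(graph, params = mcl_params()) {
  A <- if (inherits(graph, "alignment_graph")) adjacency_matrix(graph)
       else as.matrix(graph)
  n <- nrow(A)
  stopifnot(n >= 1L, ncol(A) == n, all(A >= 0))
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency matrix must be symmetric")
  labels <- colnames(A) %||% as.character(seq_len(n))

  loops <- if (is.null(params$self_loop_weight)) apply(A, 2, max)
           else rep(params$self_loop_weight, n)
  loops[loops == 0] <- 1  # isolated nodes still need a positive column
  diag(A) <- loops
  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  colsum_dev <- max(abs(colSums(M) - 1))

  iterations <- 0L
  converged <- FALSE
  while (iterations < params$max_iterations) {
    iterations <- iterations + 1L
    Mx <- M
    for (k in seq_len(params$expansion - 1L)) Mx <- Mx %*% M
    Mx <- Mx^params$inflation
    keep <- Mx >= params$prune_threshold
    keep[cbind(max.col(t(Mx), ties.method = "first"), seq_len(n))] <- TRUE
    Mx[!keep] <- 0
    Mx <- normalize(Mx)
    colsum_dev <- c(colsum_dev, max(abs(colSums(Mx) - 1)))
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("MCL did not converge within %d iterations; clusters read from the final matrix",
                    params$max_iterations))

  attractors <- which(diag(M) > 0)
  if (!length(attractors))
    attractors <- sort(unique(max.col(t(M), ties.method = "first")))
  S <- M[attractors, , drop = FALSE]
  assign_to <- integer(n)
  for (j in seq_len(n)) {
    col <- S[, j]
    assign_to[j] <- if (any(col > 0)) which.max(col) else NA_integer_
  }
  # nodes with no attractor mass (pathological) become their own clusters
  if (anyNA(assign_to)) {
    extra <- seq.int(length(attractors) + 1L,
                     length.out = sum(is.na(assign_to)))
    assign_to[is.na(assign_to)] <- extra
  }
  membership <- match(assign_to, sort(unique(assign_to)))
  clusters <- unname(split(seq_len(n), membership))
  structure(list(membership = membership, clusters = clusters,
                 labels = labels, iterations = iterations,
                 converged = converged, colsum_dev = colsum_dev),
            class = "mcl_result")
}

#' @export
print.mcl_result <- function(x, ...) {
  cat(sprintf("mcl_result: %d nodes in %d cluster(s) after %d iteration(s)%s\n",
              length(x$membership), length(x$clusters), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Construct an alignment module
#'
#' A module is one cluster of composite nodes together with its
#' projections into each species. `size` counts distinct proteins
#' namespaced by species (a composite node contributes up to two), which is
#' how published module protein counts are tallied.
#'
#' @param index positive integer module index.
#' @param members data.frame with columns `a`, `b` (composite pairs), or
#'   `NULL` for modules defined directly by projections (e.g. random
#'   modules).
#' @param projection_1,projection_2 used only when `members` is `NULL`.
#' @return object of class `alignment_module` with elements `index`,
#'   `members`, `projection_1`, `projection_2` (distinct, sorted) and
#'   `size`.
#' @export
alignment_module <- function(index, members = NULL, projection_1 = NULL,
                             projection_2 = NULL) {
  if (!is.null(members)) {
    stopifnot(nrow(members) >= 1L, all(c("a", "b") %in% names(members)))
    projection_1 <- sort(unique(members$a))
    projection_2 <- sort(unique(members$b))
  } else {
    projection_1 <- sort(unique(as.character(projection_1 %||% character(0))))
    projection_2 <- sort(unique(as.character(projection_2 %||% character(0))))
    if (!length(projection_1) && !length(projection_2))
      stop("an alignment module must have at least one member protein")
  }
  structure(list(index = as.integer(index), members = members,
                 projection_1 = projection_1, projection_2 = projection_2,
                 size = length(projection_1) + length(projection_2)),
            class = "alignment_module")
}

#' @export
print.alignment_module <- function(x, ...) {
  cat(sprintf("alignment_module %d: %d proteins (%d + %d)%s\n", x$index,
              x$size, length(x$projection_1), length(x$projection_2),
              if (is.null(x$members)) "" else
                sprintf(", %d composite pairs", nrow(x$members))))
  invisible(x)
}

#' Extract conserved modules from an alignment graph
#'
#' Runs [mcl_cluster()] and turns every cluster with at least `min_size`
#' composite nodes into an [alignment_module()], sorted by descending
#' protein count (ties by descending composite count, then first member)
#' and indexed from 1.
#'
#' @param graph an `alignment_graph`.
#' @param params an [mcl_params()].
#' @param min_size minimum number of composite nodes for a cluster to
#'   become a module (default 2; published alignments report modules down
#'   to two proteins, i.e. one composite pair per species side).
#' @return list of [alignment_module()] (empty, with a warning, when no
#'   cluster reaches `min_size`).
#' @export
extract_modules <- function(graph, params = mcl_params(), min_size = 2L) {
  stopifnot(inherits(graph, "alignment_graph"), min_size >= 1L)
  res <- mcl_cluster(graph, params)
  clusters <- res$clusters[lengths(res$clusters) >= min_size]
  if (!length(clusters)) {
    warning(sprintf("no cluster reaches min_size = %d; returning empty module list",
                    min_size))
    return(list())
  }
  mods <- lapply(clusters, function(ix)
    alignment_module(0L, members = graph$nodes[ix, c("a", "b", "similarity"),
                                               drop = FALSE]))
  sizes <- vapply(mods, function(m) m$size, integer(1))
  npairs <- vapply(mods, function(m) nrow(m$members), integer(1))
  first <- vapply(mods, function(m) paste(m$members$a[1], m$members$b[1]),
                  character(1))
  ord <- order(-sizes, -npairs, first)
  mods <- mods[ord]
  for (k in seq_along(mods)) mods[[k]]$index <- k
  mods
}

#' Project a module into one species
#'
#' @param m an [alignment_module()].
#' @param species 1 or 2.
#' @return sorted distinct protein ids of that species.
#' @export
project_module <- function(m, species) {
  stopifnot(inherits(m, "alignment_module"), species %in% c(1L, 2L))
  if (species == 1L) m$projection_1 else m$projection_2
}
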