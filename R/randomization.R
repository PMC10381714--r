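# Size-matched random alignments and the real-vs-random comparison: the
# null model is uniform sampling of proteins (without replacement, within
# a module) from the pooled node set of both input networks, the minimal
# null under which a module's semantic-similarity score can be referenced
# against chance.

#' Generate size-matched random alignment modules
#'
#' For each requested size `s`, draws `s` distinct proteins uniformly
#' without replacement from the pooled node set of both networks (species
#' membership is recorded in the projections). Modules are drawn
#' independently of each other and the whole list is reproducible from
#' `rng_seed`.
#'
#' @param net1,net2 the input [ppi_network()]s.
#' @param sizes integer vector of module protein counts (each >= 1 and at
#'   most the pooled node count).
#' @param rng_seed integer seed; mandatory for reproducibility.
#' @return list of [alignment_module()] with `members = NULL`.
#' @export
random_alignment <- function(net1, net2, sizes, rng_seed) {
  sizes <- as.integer(sizes)
  if (!length(sizes) || any(is.na(sizes) | sizes < 1L))
    stop("module sizes must be positive integers")
  pool_species <- rep(1:2, c(length(net1$nodes), length(net2$nodes)))
  pool_id <- c(net1$nodes, net2$nodes)
  if (any(sizes > length(pool_id)))
    stop("requested module size exceeds the pooled protein set")
  with_seed(rng_seed, lapply(seq_along(sizes), function(k) {
    draw <- sample.int(length(pool_id), sizes[k])
    alignment_module(k, members = NULL,
                     projection_1 = pool_id[draw[pool_species[draw] == 1L]],
                     projection_2 = pool_id[draw[pool_species[draw] == 2L]])
  }))
}

#' Compare real module scores against size-matched random alignments
#'
#' Scores every real module under each measure, draws `replicates`
#' independent size-matched random alignments, scores those identically,
#' and reports per module the empirical exceedance fraction
#' `#(random >= real) / replicates`. An exceedance of 0 at the default 9
#' replicates is the qualitative "real beats random" outcome; no formal
#' p-value is claimed beyond this fraction. Modules without at least two
#' annotated proteins are excluded with a warning.
#'
#' @param real list of [alignment_module()] (the observed alignment).
#' @param net1,net2 the input [ppi_network()]s (the sampling pool).
#' @param onto an [ontology_store()].
#' @param corpus annotation corpus.
#' @param measures measure names, see [term_similarity()].
#' @param replicates number of random alignments (default 9).
#' @param rng_seed integer seed.
#' @param ic optional precomputed [compute_ic()] table.
#' @return object of class `null_comparison`: `summary` (data.frame
#'   `measure`, `module`, `size`, `real_score`, `exceedance`),
#'   `replicate_scores` (long data.frame with one row per measure x module
#'   x replicate), `replicates`, `rng_seed`.
#' @export
compare_real_vs_random <- function(real, net1, net2, onto, corpus,
                                   measures = c("resnik_bma", "lin", "wang"),
                                   replicates = 9L, rng_seed = 1L, ic = NULL) {
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L, length(real) >= 1L)
  if (is.null(ic)) ic <- compute_ic(onto, corpus)
  sizes <- vapply(real, function(m) m$size, integer(1))
  sub_seeds <- derive_seeds(rng_seed, replicates)
  rand <- lapply(seq_len(replicates), function(r)
    random_alignment(net1, net2, sizes, sub_seeds[r]))

  pool_genes <- unique(c(net1$nodes, net2$nodes,
                         unlist(lapply(real, function(m)
                           c(m$projection_1, m$projection_2)))))
  cache <- similarity_cache()
  summ <- list()
  reps <- list()
  for (ms in measures) {
    gsim <- gene_similarity_matrix(pool_genes, onto, corpus, ms,
                                   ic = ic, cache = cache)
    real_scores <- vapply(real, function(m)
      module_score(m, measure = ms, gene_sim = gsim), numeric(1))
    scorable <- !is.na(real_scores)
    if (any(!scorable))
      warning(sprintf("%d module(s) not scorable under %s; excluded",
                      sum(!scorable), ms))
    rep_scores <- vapply(rand, function(modlist)
      vapply(seq_along(modlist), function(k)
        suppressWarnings(module_score(modlist[[k]], measure = ms,
                                      gene_sim = gsim)),
        numeric(1)),
      numeric(length(real)))
    rep_scores <- matrix(rep_scores, nrow = length(real))
    exceed <- vapply(seq_along(real), function(k) {
      if (!scorable[k]) return(NA_real_)
      mean(rep_scores[k, ] >= real_scores[k], na.rm = TRUE)
    }, numeric(1))
    summ[[ms]] <- data.frame(
      measure = ms,
      module = vapply(real, function(m) m$index, integer(1)),
      size = sizes, real_score = real_scores, exceedance = exceed,
      stringsAsFactors = FALSE)
    reps[[ms]] <- data.frame(
      measure = ms,
      module = rep(vapply(real, function(m) m$index, integer(1)), replicates),
      replicate = rep(seq_len(replicates), each = length(real)),
      score = as.vector(rep_scores), stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, c(summ, make.row.names = FALSE)),
                 replicate_scores = do.call(rbind, c(reps, make.row.names = FALSE)),
                 replicates = replicates, rng_seed = rng_seed),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("null_comparison: %d replicate(s), seed %d\n",
              x$replicates, x$rng_seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a null-comparison report as TSV
#'
#' One row per measure x module: real score, each replicate's score and
#' the exceedance fraction.
#'
#' @param nc a [compare_real_vs_random()] result.
#' @param path output TSV.
#' @export
write_null_report <- function(nc, path) {
  wide <- nc$summary
  for (r in seq_len(nc$replicates)) {
    col <- nc$replicate_scores[nc$replicate_scores$replicate == r, ]
    key <- paste(wide$measure, wide$module)
    wide[[sprintf("random_%d", r)]] <-
      col$score[match(key, paste(col$measure, col$module))]
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dot plot of real vs random module scores
#'
#' One panel per measure: modules on the x axis, the real score as a
#' filled black marker and each random replicate as an open colored
#' marker.
#'
#' @param nc a [compare_real_vs_random()] result.
#' @param measure which measure to plot (default: first present).
#' @export
plot_null_comparison <- function(nc, measure = NULL) {
  measure <- measure %||% nc$summary$measure[1]
  s <- nc$summary[nc$summary$measure == measure, ]
  r <- nc$replicate_scores[nc$replicate_scores$measure == measure, ]
  ylim <- range(c(s$real_score, r$score), na.rm = TRUE)
  graphics::plot(s$module, s$real_score, pch = 16, cex = 1.4,
                 xlim = c(0.5, max(s$module) + 0.5), ylim = ylim,
                 xlab = "module", ylab = sprintf("semantic similarity (%s)", measure),
                 main = sprintf("real vs random alignments (%s)", measure),
                 xaxt = "n")
  graphics::axis(1, at = s$module)
  cols <- grDevices::rainbow(nc$replicates)
  for (rep_i in seq_len(nc$replicates)) {
    ri <- r[r$replicate == rep_i, ]
    graphics::points(ri$module, ri$score, pch = 1, col = cols[rep_i])
  }
  graphics::legend("bottomleft", legend = c("real", "random"),
                   pch = c(16, 1), bty = "n")
  invisible(nc)
}
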