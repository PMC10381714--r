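# Pipeline orchestration: align -> extract -> score -> null-compare, with
# config, stderr logging and provenance capture. Each stage writes its
# report files under the configured output directory; a provenance JSON
# (config echo, input hashes, package version, seed) makes every run
# reproducible bit-for-bit.

#' Pipeline configuration
#'
#' Inputs may be file paths (loaded through the package readers) or
#' already-constructed objects; the provenance record captures whichever
#' was used.
#'
#' @param net1,net2 [ppi_network()] objects or edge-list/STRING TSV paths.
#' @param seeds [seed_pair_map()] or TSV path.
#' @param obo [ontology_store()] or OBO path (needed for scoring stages).
#' @param annotations annotation corpus (named list) or GAF/TSV path.
#' @param net_format,min_confidence passed to [read_network()] for path
#'   inputs.
#' @param weights a [weight_params()].
#' @param mcl an [mcl_params()].
#' @param strategy composite-node selection strategy.
#' @param measures semantic-similarity measures to report.
#' @param min_module_size minimum composite nodes per module.
#' @param replicates random alignments for the null comparison.
#' @param rng_seed integer seed, mandatory for any stochastic stage.
#' @param out_dir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(net1, net2, seeds, obo = NULL, annotations = NULL,
                            net_format = "edgelist", min_confidence = 0,
                            weights = weight_params(), mcl = mcl_params(),
                            strategy = "best_match",
                            measures = c("resnik_bma", "lin", "wang"),
                            min_module_size = 2L, replicates = 9L,
                            rng_seed = 1L, out_dir = ".") {
  for (p in list(net1, net2, seeds, obo, annotations))
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stop(sprintf("input file not found: %s", p))
  structure(list(net1 = net1, net2 = net2, seeds = seeds, obo = obo,
                 annotations = annotations, net_format = net_format,
                 min_confidence = min_confidence, weights = weights,
                 mcl = mcl, strategy = strategy, measures = measures,
                 min_module_size = as.integer(min_module_size),
                 replicates = as.integer(replicates),
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "pipeline_config")
}

log_info <- function(fmt, ...) message(sprintf(paste0("[localign] ", fmt), ...))

load_input <- function(x, loader, ...) {
  if (is.character(x) && length(x) == 1L) loader(x, ...) else x
}

input_hash <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    unname(tools::md5sum(x))
  else sprintf("in-memory:%s", class(x)[1])
}

config_provenance <- function(config, extra = list()) {
  c(list(
    package_version = as.character(utils::packageVersion("localign")),
    rng_seed = config$rng_seed,
    inputs = list(net1 = input_hash(config$net1),
                  net2 = input_hash(config$net2),
                  seeds = input_hash(config$seeds),
                  obo = if (is.null(config$obo)) NULL else input_hash(config$obo),
                  annotations = if (is.null(config$annotations)) NULL
                                else input_hash(config$annotations)),
    weights = c(list(delta = config$weights$delta),
                as.list(config$weights$weights)),
    mcl = unclass(config$mcl),
    strategy = config$strategy,
    measures = config$measures,
    min_module_size = config$min_module_size,
    replicates = config$replicates),
    extra)
}

#' Run the alignment stage
#'
#' Loads the networks and seeds, builds the alignment graph, extracts
#' modules by Markov clustering, and writes `alignment_graph.tsv`,
#' `modules.tsv` (with JSON provenance sidecars) under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, list with `net1`, `net2`, `seeds`, `graph`,
#'   `modules` and `files`.
#' @export
run_align <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  net1 <- load_input(config$net1, read_network, format = config$net_format,
                     min_confidence = config$min_confidence)
  net2 <- load_input(config$net2, read_network, format = config$net_format,
                     min_confidence = config$min_confidence)
  seeds <- load_input(config$seeds, read_seed_pairs)
  log_info("networks: %s (%d nodes, %d edges) vs %s (%d nodes, %d edges); %d seed pairs",
           net1$name, n_nodes(net1), n_edges(net1),
           net2$name, n_nodes(net2), n_edges(net2), nrow(seeds))
  graph <- build_alignment_graph(net1, net2, seeds, config$weights,
                                 config$strategy)
  modules <- extract_modules(graph, config$mcl, config$min_module_size)
  log_info("extracted %d module(s) of sizes: %s", length(modules),
           paste(vapply(modules, function(m) m$size, integer(1)),
                 collapse = ", "))
  gfile <- file.path(config$out_dir, "alignment_graph.tsv")
  write_alignment_graph(graph, gfile)
  mfile <- file.path(config$out_dir, "modules.tsv")
  if (length(modules))
    write_module_report(modules, NULL, mfile,
                        provenance = config_provenance(config,
                          list(stage = "align",
                               elapsed_s = proc.time()[["elapsed"]] - t0)))
  log_info("align stage done in %.2f s", proc.time()[["elapsed"]] - t0)
  invisible(list(net1 = net1, net2 = net2, seeds = seeds, graph = graph,
                 modules = modules,
                 files = c(graph = gfile, modules = mfile)))
}

#' Run the scoring stage
#'
#' Computes per-module, per-measure semantic-similarity scores and
#' rewrites the module report with the score columns appended.
#'
#' @param config a [pipeline_config()] (with `obo` and `annotations`).
#' @param modules list of [alignment_module()]; when `NULL`,
#'   [run_align()] is executed first.
#' @return invisibly, list with `modules`, `scores`, `onto`, `corpus`,
#'   `ic`, and the stage context.
#' @export
run_score <- function(config, modules = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$obo) || is.null(config$annotations))
    stop("scoring requires an ontology (obo) and annotations in the config")
  ctx <- NULL
  if (is.null(modules)) {
    ctx <- run_align(config)
    modules <- ctx$modules
  }
  if (!length(modules)) stop("no modules to score")
  t0 <- proc.time()[["elapsed"]]
  onto <- load_input(config$obo, load_ontology)
  corpus <- if (is.character(config$annotations))
    read_annotations(config$annotations, onto = onto)
  else config$annotations
  ic <- compute_ic(onto, corpus)
  scores <- score_modules(modules, onto, corpus, config$measures, ic = ic)
  log_info("scored %d module(s) under %s", nrow(scores),
           paste(config$measures, collapse = ", "))
  mfile <- file.path(config$out_dir, "modules.tsv")
  write_module_report(modules, scores, mfile,
                      provenance = config_provenance(config,
                        list(stage = "score",
                             elapsed_s = proc.time()[["elapsed"]] - t0)))
  log_info("score stage done in %.2f s", proc.time()[["elapsed"]] - t0)
  invisible(c(list(modules = modules, scores = scores, onto = onto,
                   corpus = corpus, ic = ic), ctx))
}

#' Run the null-comparison stage
#'
#' Compares module scores against size-matched random alignments and
#' writes `null_comparison.tsv`; optionally a dot-plot PDF per measure.
#'
#' @param config a [pipeline_config()].
#' @param scored result of [run_score()]; computed when `NULL`.
#' @param plot also write `null_<measure>.pdf` figures.
#' @return invisibly, the [compare_real_vs_random()] report plus context.
#' @export
run_null <- function(config, scored = NULL, plot = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(scored)) scored <- run_score(config)
  if (is.null(scored$net1)) {
    scored$net1 <- load_input(config$net1, read_network,
                              format = config$net_format,
                              min_confidence = config$min_confidence)
    scored$net2 <- load_input(config$net2, read_network,
                              format = config$net_format,
                              min_confidence = config$min_confidence)
  }
  t0 <- proc.time()[["elapsed"]]
  nc <- compare_real_vs_random(scored$modules, scored$net1, scored$net2,
                               scored$onto, scored$corpus,
                               measures = config$measures,
                               replicates = config$replicates,
                               rng_seed = config$rng_seed, ic = scored$ic)
  nfile <- file.path(config$out_dir, "null_comparison.tsv")
  write_null_report(nc, nfile)
  jsonlite::write_json(config_provenance(config,
                         list(stage = "null",
                              elapsed_s = proc.time()[["elapsed"]] - t0)),
                       file.path(config$out_dir, "null_comparison.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (plot) {
    for (ms in config$measures) {
      grDevices::pdf(file.path(config$out_dir, sprintf("null_%s.pdf", ms)),
                     width = 6, height = 4)
      plot_null_comparison(nc, ms)
      grDevices::dev.off()
    }
  }
  log_info("null stage done in %.2f s (%d replicates)",
           proc.time()[["elapsed"]] - t0, config$replicates)
  invisible(c(list(null = nc), scored))
}

#' Generate and write a synthetic fixture (simulate stage)
#'
#' Thin wrapper over [generate_coherence_fixture()] and
#' [write_synthetic_fixture()].
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir fixture directory.
#' @param with_ontology also generate the toy ontology and annotations.
#' @return invisibly, the generated fixture.
#' @export
run_simulate <- function(spec, out_dir, with_ontology = TRUE) {
  fix <- if (with_ontology) generate_coherence_fixture(spec)
         else generate_paired_networks(spec)
  write_synthetic_fixture(fix, out_dir)
  log_info("simulated fixture written to %s (%d+%d nodes, %d+%d edges)",
           out_dir, n_nodes(fix$net1), n_nodes(fix$net2),
           n_edges(fix$net1), n_edges(fix$net2))
  invisible(fix)
}

#' Run the full pipeline: align, score, null-compare
#'
#' @param config a [pipeline_config()].
#' @param plot write null-comparison figures.
#' @return invisibly, the accumulated stage results.
#' @export
run_pipeline <- function(config, plot = FALSE) {
  run_null(config, scored = run_score(config), plot = plot)
}
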