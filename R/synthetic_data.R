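# Synthetic study-condition generators: paired PPI networks with planted
# conserved modules mirrored across species, ortholog-like seed pairs
# (plus decoys), and a toy ontology/annotation corpus with controlled
# functional coherence. Everything the pipeline consumes can be produced
# here, at the published network scales, without external databases.

#' Specification of a synthetic paired-network study
#'
#' `preset = "ad"` uses the scale of the Alzheimer-related pair of input
#' networks (33 nodes / 82 edges vs 41 nodes / 157 edges) and plants two
#' conserved modules of 12 and 8 proteins per species, mirroring the
#' published AD module-size profile. `preset = "pd"` uses the
#' Parkinson-related pair (51/438 vs 51/651) and plants one large module
#' of 20 proteins per species: at that background density (about half of
#' all node pairs interact) the published modules span most of the
#' network, and small disjoint planted modules would not be
#' distinguishable from the dense background by any topology-driven
#' miner. Explicitly supplied `planted_sizes` override the preset.
#' Other defaults: full seed coverage, no edge noise, 10% decoy seeds,
#' annotation coherence 0.9.
#'
#' @param n1,e1,n2,e2 node and edge counts of the two networks.
#' @param planted_sizes integer vector: per-species node count of each
#'   planted conserved module (their sum must not exceed `min(n1, n2)`).
#' @param seed_coverage fraction of planted cross-species node pairs
#'   emitted as seed pairs.
#' @param edge_noise fraction of planted-module edges removed (and
#'   replaced by random background edges) independently per network.
#' @param decoy_fraction decoy (false ortholog) seeds among background
#'   nodes, as a fraction of the true seeds.
#' @param module_density edge probability inside a planted module
#'   (connected Erdos-Renyi; default 0.8).
#' @param coherence annotation coherence used when a toy ontology is
#'   attached (see [generate_toy_ontology()]).
#' @param rng_seed integer seed.
#' @param preset `"custom"`, `"ad"` or `"pd"`.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n1 = 33L, e1 = 82L, n2 = 41L, e2 = 157L,
                           planted_sizes = c(12L, 8L), seed_coverage = 1,
                           edge_noise = 0, decoy_fraction = 0.1,
                           module_density = 0.8, coherence = 0.9,
                           rng_seed = 1L,
                           preset = c("custom", "ad", "pd")) {
  preset <- match.arg(preset)
  sizes_given <- !missing(planted_sizes)
  if (preset == "ad") {
    n1 <- 33L; e1 <- 82L; n2 <- 41L; e2 <- 157L
    if (!sizes_given) planted_sizes <- c(12L, 8L)
  }
  if (preset == "pd") {
    n1 <- 51L; e1 <- 438L; n2 <- 51L; e2 <- 651L
    if (!sizes_given) planted_sizes <- c(20L)
  }
  n1 <- as.integer(n1); e1 <- as.integer(e1)
  n2 <- as.integer(n2); e2 <- as.integer(e2)
  planted_sizes <- as.integer(planted_sizes)
  stopifnot(n1 >= 2L, n2 >= 2L, e1 >= 1L, e2 >= 1L,
            all(planted_sizes >= 2L),
            sum(planted_sizes) <= min(n1, n2),
            e1 <= n1 * (n1 - 1) / 2, e2 <= n2 * (n2 - 1) / 2,
            seed_coverage >= 0, seed_coverage <= 1,
            edge_noise >= 0, edge_noise <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1,
            module_density > 0, module_density <= 1)
  structure(list(n1 = n1, e1 = e1, n2 = n2, e2 = e2,
                 n_planted = length(planted_sizes),
                 planted_sizes = planted_sizes,
                 seed_coverage = seed_coverage, edge_noise = edge_noise,
                 decoy_fraction = decoy_fraction,
                 module_density = module_density, coherence = coherence,
                 rng_seed = as.integer(rng_seed), preset = preset),
            class = "synthetic_spec")
}

# Connected Erdos-Renyi topology on s labelled nodes (edge indices into
# 1..s); resamples until connected.
rgraph_connected <- function(s, p) {
  if (s < 2L) return(matrix(integer(0), ncol = 2))
  pairs <- t(utils::combn(s, 2))
  repeat {
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) next
    g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, s - igraph::vcount(g)))
    if (igraph::is_connected(g)) return(pairs[keep, , drop = FALSE])
  }
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Generate a pair of networks with planted conserved modules
#'
#' Each planted module is a connected dense subgraph (connected
#' Erdos-Renyi with probability `module_density`) whose topology is
#' mirrored in both networks through the true node-pair map. When a dense
#' draw overshoots the published edge budgets, the shared topology is
#' trimmed at random — never below a spanning tree, so modules stay
#' connected and mirrored — until it fits both networks. Background
#' edges are then added uniformly at random until the exact requested edge
#' counts are reached; `edge_noise` removes a fraction of planted edges
#' (independently per network) before the fill, so noisy modules lose
#' mirrored structure. Seed pairs cover `seed_coverage` of the planted
#' pairs (similarity 1) plus decoy pairs among background nodes (lower
#' similarity).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `net1`, `net2` ([ppi_network()]s of exactly the
#'   requested sizes), `seeds` ([seed_pair_map()]), and `truth`
#'   (ground-truth list: per-module memberships per species, the full true
#'   pair map, decoys, background nodes).
#' @export
generate_paired_networks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$rng_seed, {
    id1 <- sprintf("ce%03d", seq_len(spec$n1))
    id2 <- sprintf("hs%03d", seq_len(spec$n2))
    tot <- sum(spec$planted_sizes)
    sel1 <- sample(id1, tot)
    sel2 <- sample(id2, tot)
    mod_of <- rep(seq_len(spec$n_planted), spec$planted_sizes)

    planted1 <- character(0); planted2 <- character(0)
    modules <- vector("list", spec$n_planted)
    topos <- vector("list", spec$n_planted)
    for (k in seq_len(spec$n_planted)) {
      s <- spec$planted_sizes[k]
      v1 <- sel1[mod_of == k]; v2 <- sel2[mod_of == k]
      topos[[k]] <- rgraph_connected(s, spec$module_density)
      modules[[k]] <- list(species1 = sort(v1), species2 = sort(v2),
                           pairs = data.frame(a = v1, b = v2,
                                              stringsAsFactors = FALSE))
      planted1 <- c(planted1, v1); planted2 <- c(planted2, v2)
    }
    # A dense draw can overshoot the published edge budgets; trim the
    # shared topology (never below a spanning tree, so modules stay
    # connected and mirrored) until it fits both networks.
    budget <- min(spec$e1, spec$e2)
    total <- sum(vapply(topos, nrow, integer(1)))
    if (total > budget) {
      removable <- list()
      for (k in seq_along(topos)) {
        g <- igraph::graph_from_edgelist(topos[[k]], directed = FALSE)
        in_tree <- igraph::as_edgelist(igraph::mst(g))
        key <- edge_key(topos[[k]][, 1], topos[[k]][, 2])
        removable[[k]] <- cbind(k, which(!(key %in%
          edge_key(in_tree[, 1], in_tree[, 2]))))
      }
      removable <- do.call(rbind, removable)
      excess <- total - budget
      if (excess > nrow(removable))
        stop("infeasible spec: planted modules alone exceed the requested edge count")
      drop <- removable[sample.int(nrow(removable), excess), , drop = FALSE]
      for (k in unique(drop[, 1]))
        topos[[k]] <- topos[[k]][-drop[drop[, 1] == k, 2], , drop = FALSE]
    }
    pe1 <- do.call(rbind, lapply(seq_len(spec$n_planted), function(k) {
      v1 <- modules[[k]]$pairs$a
      cbind(v1[topos[[k]][, 1]], v1[topos[[k]][, 2]])
    }))
    pe2 <- do.call(rbind, lapply(seq_len(spec$n_planted), function(k) {
      v2 <- modules[[k]]$pairs$b
      cbind(v2[topos[[k]][, 1]], v2[topos[[k]][, 2]])
    }))

    drop_frac <- function(e, frac) {
      if (frac <= 0 || !nrow(e)) return(e)
      k <- round(frac * nrow(e))
      if (k >= nrow(e)) return(e[0, , drop = FALSE])
      if (k == 0L) return(e)
      e[-sample.int(nrow(e), k), , drop = FALSE]
    }
    pe1 <- drop_frac(pe1, spec$edge_noise)
    pe2 <- drop_frac(pe2, spec$edge_noise)

    fill_background <- function(ids, planted_edges, e_target) {
      if (nrow(planted_edges) > e_target)
        stop("infeasible spec: planted modules alone exceed the requested edge count")
      all_pairs <- t(utils::combn(ids, 2))
      used <- edge_key(planted_edges[, 1], planted_edges[, 2])
      cand <- all_pairs[!(edge_key(all_pairs[, 1], all_pairs[, 2]) %in% used),
                        , drop = FALSE]
      need <- e_target - nrow(planted_edges)
      if (need > nrow(cand))
        stop("infeasible spec: not enough node pairs for the requested edge count")
      rbind(planted_edges,
            cand[sample.int(nrow(cand), need), , drop = FALSE])
    }
    ee1 <- fill_background(id1, pe1, spec$e1)
    ee2 <- fill_background(id2, pe2, spec$e2)
    conf1 <- round(stats::runif(nrow(ee1), 0.701, 0.999), 3)
    conf2 <- round(stats::runif(nrow(ee2), 0.701, 0.999), 3)
    net1 <- ppi_network(data.frame(a = ee1[, 1], b = ee1[, 2],
                                   confidence = conf1, stringsAsFactors = FALSE),
                        nodes = id1, name = "synthetic_species1")
    net2 <- ppi_network(data.frame(a = ee2[, 1], b = ee2[, 2],
                                   confidence = conf2, stringsAsFactors = FALSE),
                        nodes = id2, name = "synthetic_species2")

    true_pairs <- do.call(rbind, lapply(modules, function(m) m$pairs))
    covered <- if (spec$seed_coverage >= 1) seq_len(nrow(true_pairs))
               else sort(sample.int(nrow(true_pairs),
                                    round(spec$seed_coverage * nrow(true_pairs))))
    bg1 <- setdiff(id1, planted1); bg2 <- setdiff(id2, planted2)
    n_decoy <- ceiling(spec$decoy_fraction * length(covered))
    n_decoy <- min(n_decoy, length(bg1), length(bg2))
    decoys <- if (n_decoy > 0L)
      data.frame(a = sample(bg1, n_decoy), b = sample(bg2, n_decoy),
                 similarity = round(stats::runif(n_decoy, 0.4, 0.8), 3),
                 stringsAsFactors = FALSE)
    else data.frame(a = character(0), b = character(0),
                    similarity = numeric(0), stringsAsFactors = FALSE)
    seeds <- seed_pair_map(c(true_pairs$a[covered], decoys$a),
                           c(true_pairs$b[covered], decoys$b),
                           c(rep(1, length(covered)), decoys$similarity))

    list(net1 = net1, net2 = net2, seeds = seeds,
         truth = list(modules = modules, true_pairs = true_pairs,
                      covered_pairs = true_pairs[covered, , drop = FALSE],
                      decoys = decoys,
                      background = list(species1 = sort(bg1),
                                        species2 = sort(bg2)),
                      spec = unclass(spec)))
  })
}

#' Generate a toy ontology and annotation corpus with controlled coherence
#'
#' Builds a rooted tree-shaped DAG: one root plus `n_clades` disjoint
#' complete binary sub-branches of `depth` levels each (a clade of depth
#' `d` has `2^d - 1` terms). Each gene belongs to one clade and draws
#' `annotations_per_gene` annotations: with probability `coherence` a
#' uniform leaf of its own clade, otherwise a uniform leaf of the whole
#' ontology, so `coherence = 0` collapses to fully uniform annotation
#' and the same-clade / cross-clade similarity contrast vanishes on
#' average. Background genes (no clade) annotate uniformly across all
#' leaves. High coherence therefore makes same-clade gene pairs
#' semantically close and background pairs incoherent.
#'
#' @param n_clades number of disjoint clades (>= 2).
#' @param depth levels per clade (>= 2).
#' @param genes_per_clade genes per clade when `genes` is not supplied.
#' @param coherence probability in \[0, 1\] of an in-clade annotation.
#' @param rng_seed integer seed.
#' @param genes optional list of character vectors, one per clade,
#'   naming the genes of each clade (overrides `genes_per_clade`).
#' @param background_genes optional character vector of incoherently
#'   annotated genes.
#' @param annotations_per_gene direct annotations drawn per gene.
#' @return list with `onto` ([ontology_store()]), `corpus` (named list)
#'   and `truth` (`clade_of_gene`, `clade_leaves`).
#' @export
generate_toy_ontology <- function(n_clades = 2L, depth = 2L,
                                  genes_per_clade = 4L, coherence = 1,
                                  rng_seed = 1L, genes = NULL,
                                  background_genes = NULL,
                                  annotations_per_gene = 3L) {
  n_clades <- as.integer(n_clades); depth <- as.integer(depth)
  stopifnot(n_clades >= 2L, depth >= 2L, coherence >= 0, coherence <= 1,
            annotations_per_gene >= 1L)
  root <- "TOY:0000000"
  terms <- root
  edges <- list()
  clade_leaves <- vector("list", n_clades)
  counter <- 0L
  for (k in seq_len(n_clades)) {
    prev <- root
    level_terms <- root
    for (d in seq_len(depth)) {
      n_level <- 2L^(d - 1L)
      new_terms <- sprintf("TOY:%07d", counter + seq_len(n_level))
      counter <- counter + n_level
      parent_idx <- if (d == 1L) rep(1L, n_level)
                    else rep(seq_along(level_terms), each = 2L)
      for (i in seq_len(n_level))
        edges[[length(edges) + 1L]] <-
          c(new_terms[i], level_terms[parent_idx[i]], "is_a")
      terms <- c(terms, new_terms)
      level_terms <- new_terms
    }
    clade_leaves[[k]] <- level_terms
  }
  em <- do.call(rbind, edges)
  onto <- ontology_store(terms,
                         data.frame(child = em[, 1], parent = em[, 2],
                                    type = em[, 3], stringsAsFactors = FALSE),
                         namespace = stats::setNames(
                           rep("toy_process", length(terms)), terms))

  if (is.null(genes))
    genes <- lapply(seq_len(n_clades), function(k)
      sprintf("gene_c%d_%02d", k, seq_len(genes_per_clade)))
  stopifnot(length(genes) == n_clades)
  all_leaves <- unlist(clade_leaves)
  corpus <- list()
  clade_of <- character(0)
  with_seed(rng_seed, {
    for (k in seq_len(n_clades)) {
      for (g in genes[[k]]) {
        coh <- stats::runif(annotations_per_gene) < coherence
        draw <- character(annotations_per_gene)
        draw[coh] <- sample(clade_leaves[[k]], sum(coh), replace = TRUE)
        draw[!coh] <- sample(all_leaves, sum(!coh), replace = TRUE)
        corpus[[g]] <- unique(draw)
        clade_of[g] <- as.character(k)
      }
    }
    for (g in background_genes %||% character(0)) {
      corpus[[g]] <- unique(sample(all_leaves, annotations_per_gene,
                                   replace = TRUE))
      clade_of[g] <- "0"
    }
  })
  list(onto = onto, corpus = corpus,
       truth = list(clade_of_gene = clade_of, clade_leaves = clade_leaves))
}

#' Generate a complete coherence fixture
#'
#' Combines [generate_paired_networks()] with a toy ontology in which the
#' proteins of planted module `k` (both species) form clade `k` with the
#' spec's `coherence`, and all background proteins are annotated
#' incoherently. This is the canonical input for real-vs-random
#' comparisons: planted modules are both topologically conserved and
#' functionally coherent.
#'
#' @param spec a [synthetic_spec()].
#' @param depth clade depth of the toy ontology.
#' @param annotations_per_gene direct annotations per gene.
#' @return list with `net1`, `net2`, `seeds`, `truth`, `onto`, `corpus`,
#'   `onto_truth`.
#' @export
generate_coherence_fixture <- function(spec, depth = 3L,
                                       annotations_per_gene = 3L) {
  nets <- generate_paired_networks(spec)
  genes <- lapply(nets$truth$modules, function(m)
    c(m$species1, m$species2))
  bg <- c(nets$truth$background$species1, nets$truth$background$species2)
  onto_seed <- derive_seeds(spec$rng_seed, 1)
  toy <- generate_toy_ontology(
    n_clades = max(2L, spec$n_planted), depth = depth,
    coherence = spec$coherence, rng_seed = onto_seed,
    genes = c(genes, rep(list(character(0)),
                         max(0L, 2L - spec$n_planted))),
    background_genes = bg,
    annotations_per_gene = annotations_per_gene)
  c(nets, list(onto = toy$onto, corpus = toy$corpus,
               onto_truth = toy$truth))
}

#' Recovery of planted modules by an extracted alignment
#'
#' For every planted module, the best Jaccard index between its
#' species-namespaced protein set and any extracted module's.
#'
#' @param modules list of [alignment_module()] (extracted).
#' @param truth ground truth from [generate_paired_networks()].
#' @return numeric vector, one best-Jaccard per planted module (0 when no
#'   module was extracted).
#' @export
module_recovery <- function(modules, truth) {
  namespaced <- function(s1, s2) c(paste0("1:", s1), paste0("2:", s2))
  vapply(truth$modules, function(tm) {
    planted <- namespaced(tm$species1, tm$species2)
    if (!length(modules)) return(0)
    max(vapply(modules, function(m)
      jaccard(planted, namespaced(m$projection_1, m$projection_2)),
      numeric(1)))
  }, numeric(1))
}

#' Write a synthetic fixture to a directory
#'
#' Emits the same formats the pipeline consumes: `net1.tsv`, `net2.tsv`
#' (edge lists with node declarations), `seeds.tsv`, and when the fixture
#' carries an ontology, `ontology.obo`, `annotations.gaf`, plus a
#' `ground_truth.json` provenance file.
#'
#' @param fix result of [generate_paired_networks()] or
#'   [generate_coherence_fixture()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_synthetic_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(fix$net1, file.path(dir, "net1.tsv"))
  write_network(fix$net2, file.path(dir, "net2.tsv"))
  write_seed_pairs(fix$seeds, file.path(dir, "seeds.tsv"))
  if (!is.null(fix$onto)) {
    write_obo(fix$onto, file.path(dir, "ontology.obo"))
    write_gaf(fix$corpus, file.path(dir, "annotations.gaf"), fix$onto)
  }
  truth <- fix$truth
  truth$modules <- lapply(truth$modules, function(m)
    list(species1 = m$species1, species2 = m$species2))
  truth$true_pairs <- NULL
  truth$covered_pairs <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
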