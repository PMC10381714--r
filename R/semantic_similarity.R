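# Ontology handling and semantic-similarity scoring: OBO/GAF parsing,
# information content over an annotation corpus, the IC-based measures
# (Resnik, Lin, Jiang) via the most informative common ancestor, the
# hybrid Wang S-value measure, best-match-average aggregation to gene
# pairs, and module-level scores.

#' Construct an ontology store
#'
#' A validated DAG of terms with typed child-to-parent edges (`is_a`,
#' `part_of`). Ancestor sets (each term included in its own) and a
#' children index are precomputed. Cycles and dangling parents are errors.
#'
#' @param terms character vector of term ids.
#' @param parents data.frame with columns `child`, `parent`, `type`
#'   (each type one of `"is_a"`, `"part_of"`).
#' @param namespace optional named character vector (per-term namespace
#'   label); unnamed terms get `"default"`.
#' @param names optional named character vector of human-readable term
#'   names.
#' @return object of class `ontology_store` with elements `terms`,
#'   `parents` (per-term data.frames), `children`, `edges`, `roots`,
#'   `namespace`, `ancestors`, `term_names`, `alt_ids`.
#' @export
ontology_store <- function(terms, parents, namespace = NULL, names = NULL) {
  terms <- unique(as.character(terms))
  parents <- as.data.frame(parents, stringsAsFactors = FALSE)
  if (!nrow(parents))
    parents <- data.frame(child = character(0), parent = character(0),
                          type = character(0), stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "type") %in% colnames(parents)))
  if (!all(parents$type %in% c("is_a", "part_of")))
    stop("edge types must be 'is_a' or 'part_of'")
  dangling <- setdiff(c(parents$child, parents$parent), terms)
  if (length(dangling))
    stop(sprintf("dangling term reference(s) in ontology edges: %s",
                 paste(utils::head(dangling, 5), collapse = ", ")))

  # Kahn topological sort (parents before children); leftover => cycle
  parent_of <- split(parents$parent, factor(parents$child, levels = terms))
  child_of <- split(parents$child, factor(parents$parent, levels = terms))
  indeg <- lengths(parent_of)
  queue <- terms[indeg == 0L]
  topo <- character(0)
  indeg_now <- indeg
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (c in child_of[[t]]) {
      indeg_now[c] <- indeg_now[c] - 1L
      if (indeg_now[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(topo) < length(terms)) {
    bad <- setdiff(terms, topo)
    # walk parent links among the residual nodes until one repeats
    cyc <- bad[1]
    seen <- character(0)
    cur <- cyc
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      cur <- intersect(parent_of[[cur]], bad)[1]
    }
    cycle <- c(seen[which(seen == cur):length(seen)], cur)
    stop(sprintf("ontology contains a cycle: %s", paste(cycle, collapse = " -> ")))
  }

  ns <- stats::setNames(rep("default", length(terms)), terms)
  if (!is.null(namespace)) {
    known <- intersect(base::names(namespace), terms)
    ns[known] <- namespace[known]
  }
  anc <- stats::setNames(vector("list", length(terms)), terms)
  for (t in topo)  # parents appear before children
    anc[[t]] <- unique(c(t, unlist(anc[parent_of[[t]]], use.names = FALSE)))
  structure(list(
    terms = terms,
    parents = split(parents[, c("parent", "type"), drop = FALSE],
                    factor(parents$child, levels = terms)),
    children = child_of,
    edges = parents,
    roots = terms[indeg == 0L],
    namespace = ns,
    ancestors = anc,
    term_names = names %||% stats::setNames(terms, terms),
    alt_ids = character(0)
  ), class = "ontology_store")
}

#' @export
print.ontology_store <- function(x, ...) {
  cat(sprintf("ontology_store: %d terms, %d edges, %d root(s), namespaces: %s\n",
              length(x$terms), nrow(x$edges), length(x$roots),
              paste(unique(x$namespace), collapse = ", ")))
  invisible(x)
}

#' Ancestor set of a term
#' @param onto an [ontology_store()].
#' @param term a term id (alt ids are resolved).
#' @return character vector of ancestors, the term itself included.
#' @export
term_ancestors <- function(onto, term) {
  term <- resolve_term(onto, term)
  onto$ancestors[[term]]
}

resolve_term <- function(onto, term) {
  if (term %in% onto$terms) return(term)
  if (term %in% names(onto$alt_ids)) return(onto$alt_ids[[term]])
  stop(sprintf("unknown term: %s", term))
}

#' Load an ontology from an OBO file
#'
#' Parses OBO 1.2/1.4 `[Term]` stanzas: `id`, `name`, `namespace`,
#' `alt_id`, `is_a`, `relationship: part_of`, `is_obsolete`. Obsolete
#' terms are skipped; alt ids map to their canonical term. The resulting
#' graph is validated as a DAG (see [ontology_store()]).
#'
#' @param path OBO file.
#' @return an [ontology_store()].
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop(sprintf("OBO file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  stanza_at <- grepl("^\\[", lines)
  block_id <- cumsum(stanza_at)
  term_blocks <- split(lines, block_id)
  term_blocks <- Filter(function(b) length(b) && b[1] == "[Term]", term_blocks)

  ids <- character(0); nms <- character(0); nss <- character(0)
  alt <- list()
  edges <- list()
  for (b in term_blocks) {
    kv <- regmatches(b, regexec("^([A-Za-z_]+): *(.*)$", b))
    keys <- vapply(kv, function(m) if (length(m)) m[2] else NA_character_,
                   character(1))
    vals <- vapply(kv, function(m) if (length(m)) m[3] else NA_character_,
                   character(1))
    id <- vals[match("id", keys)]
    if (is.na(id)) next
    if (isTRUE(vals[match("is_obsolete", keys)] == "true")) next
    ids <- c(ids, id)
    nm <- vals[match("name", keys)]
    nms <- c(nms, if (is.na(nm)) id else nm)
    ns <- vals[match("namespace", keys)]
    nss <- c(nss, if (is.na(ns)) "default" else ns)
    for (v in vals[which(keys == "alt_id")]) alt[[v]] <- id
    for (v in vals[which(keys == "is_a")]) {
      parent <- sub(" *!.*$", "", v)
      edges[[length(edges) + 1L]] <- c(id, parent, "is_a")
    }
    for (v in vals[which(keys == "relationship")]) {
      f <- strsplit(sub(" *!.*$", "", v), " +")[[1]]
      if (length(f) >= 2L && f[1] == "part_of")
        edges[[length(edges) + 1L]] <- c(id, f[2], "part_of")
    }
  }
  if (!length(ids)) stop(sprintf("%s: no usable [Term] stanzas", path))
  pe <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(child = m[, 1], parent = m[, 2], type = m[, 3],
               stringsAsFactors = FALSE)
  } else data.frame(child = character(0), parent = character(0),
                    type = character(0), stringsAsFactors = FALSE)
  # edges may reference an obsolete term's alt id
  pe$parent <- vapply(pe$parent, function(p) alt[[p]] %||% p, character(1))
  onto <- ontology_store(ids, pe,
                         namespace = stats::setNames(nss, ids),
                         names = stats::setNames(nms, ids))
  onto$alt_ids <- unlist(alt) %||% character(0)
  onto
}

#' Write an ontology as an OBO file
#' @param onto an [ontology_store()].
#' @param path output file.
#' @export
write_obo <- function(onto, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in onto$terms) {
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", onto$term_names[[t]]),
                 paste0("namespace: ", onto$namespace[[t]])), con)
    p <- onto$parents[[t]]
    if (!is.null(p) && nrow(p)) {
      for (k in seq_len(nrow(p))) {
        if (p$type[k] == "is_a")
          writeLines(paste0("is_a: ", p$parent[k]), con)
        else
          writeLines(paste0("relationship: part_of ", p$parent[k]), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read gene annotations (GAF 2.x or two-column TSV)
#'
#' GAF lines use column 2 (object id), 5 (term), 7 (evidence code) and 9
#' (aspect); header/comment lines start with `!`. The plain dialect is
#' `gene<TAB>term` with `#` comments. Evidence codes are not filtered
#' unless `exclude_evidence` is given. Terms unknown to `onto` (after alt
#' id resolution) are dropped with a warning.
#'
#' @param path annotation file.
#' @param onto optional [ontology_store()] used to validate terms.
#' @param format `"auto"` (sniff), `"gaf"` or `"tsv"`.
#' @param aspect optional GAF aspect letter(s) (`"P"`, `"F"`, `"C"`) to
#'   retain; ignored for TSV input.
#' @param exclude_evidence optional character vector of evidence codes to
#'   drop (GAF only).
#' @return named list: gene id -> character vector of directly annotated
#'   terms (the annotation corpus).
#' @export
read_annotations <- function(path, onto = NULL, format = c("auto", "gaf", "tsv"),
                             aspect = NULL, exclude_evidence = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    body <- lines[!grepl("^\\s*[!#]", lines) & nzchar(lines)]
    ncol1 <- if (length(body)) length(split_fields(body[1])) else 2L
    format <- if (any(grepl("^!gaf", lines)) || ncol1 >= 15L) "gaf" else "tsv"
  }
  gene <- character(0); term <- character(0)
  if (format == "gaf") {
    body <- lines[!grepl("^!", lines) & nzchar(lines)]
    for (ln in body) {
      f <- split_fields(ln)
      if (length(f) < 9L) stop(sprintf("%s: GAF line with fewer than 9 columns", path))
      if (!is.null(exclude_evidence) && f[7] %in% exclude_evidence) next
      if (!is.null(aspect) && !(f[9] %in% aspect)) next
      gene <- c(gene, f[2]); term <- c(term, f[5])
    }
  } else {
    body <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
    for (i in seq_along(body)) {
      f <- split_fields(body[i])
      if (length(f) < 2L)
        stop(sprintf("%s: malformed annotation line (expected gene<TAB>term)", path))
      gene <- c(gene, f[1]); term <- c(term, f[2])
    }
  }
  if (!is.null(onto)) {
    mapped <- ifelse(term %in% onto$terms, term,
                     ifelse(term %in% names(onto$alt_ids),
                            onto$alt_ids[term], NA))
    if (anyNA(mapped))
      warning(sprintf("%s: dropped %d annotation(s) to unknown terms",
                      path, sum(is.na(mapped))))
    keep <- !is.na(mapped)
    gene <- gene[keep]; term <- mapped[keep]
  }
  lapply(split(term, gene), unique)
}

#' Write an annotation corpus as GAF 2.2
#' @param corpus named list gene -> terms.
#' @param path output file.
#' @param onto optional [ontology_store()] used to fill the aspect column.
#' @export
write_gaf <- function(corpus, path, onto = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (g in names(corpus)) {
    for (t in corpus[[g]]) {
      asp <- if (!is.null(onto)) substr(toupper(onto$namespace[[t]]), 1, 1) else "P"
      writeLines(paste(c("LOCALIGN", g, g, "", t, "LOCALIGN:0", "IEA", "",
                         asp, g, "", "protein", "taxon:0", "20260101",
                         "LOCALIGN", "", ""), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Information content of every term under an annotation corpus
#'
#' Direct annotations are propagated to all ancestors; a term's frequency
#' is the number of genes annotated to it or any descendant, and
#' `IC = -log(frequency / total annotated genes)` (natural log by default,
#' so a root covering the whole corpus has IC 0 and IC is non-decreasing
#' from parent to child). Terms with zero frequency get `NA` and are
#' excluded from MICA searches.
#'
#' @param onto an [ontology_store()].
#' @param corpus named list gene -> terms; genes annotated only to unknown
#'   terms are dropped with a warning.
#' @param base logarithm base (default `exp(1)`).
#' @return named numeric vector of class `ic_table` over `onto$terms`,
#'   with attribute `total_genes`.
#' @export
compute_ic <- function(onto, corpus, base = exp(1)) {
  if (!length(corpus)) stop("annotation corpus is empty")
  anc_sets <- lapply(corpus, function(ts) {
    ts <- ts[ts %in% onto$terms | ts %in% names(onto$alt_ids)]
    if (!length(ts)) return(NULL)
    unique(unlist(lapply(ts, function(t) term_ancestors(onto, t)),
                  use.names = FALSE))
  })
  bad <- vapply(anc_sets, is.null, logical(1))
  if (any(bad))
    warning(sprintf("%d gene(s) have no annotation to known terms and were dropped",
                    sum(bad)))
  anc_sets <- anc_sets[!bad]
  if (!length(anc_sets)) stop("no gene carries a usable annotation")
  total <- length(anc_sets)
  tab <- table(unlist(anc_sets, use.names = FALSE))
  freq <- stats::setNames(rep(0L, length(onto$terms)), onto$terms)
  freq[names(tab)] <- as.integer(tab)
  ic <- -log(freq / total, base = base)
  ic[freq == 0L] <- NA_real_
  structure(ic, total_genes = total, class = c("ic_table", "numeric"))
}

#' Most informative common ancestor of two terms
#'
#' The common ancestor (ancestor sets include the terms themselves) with
#' maximal information content; ties resolve to the lexicographically
#' smallest term id. Terms with undefined IC never qualify.
#'
#' @param onto an [ontology_store()].
#' @param ic an [compute_ic()] table.
#' @param t1,t2 term ids.
#' @return the MICA term id.
#' @export
mica <- function(onto, ic, t1, t2) {
  common <- intersect(term_ancestors(onto, t1), term_ancestors(onto, t2))
  common <- common[!is.na(ic[common])]
  if (!length(common))
    stop(sprintf("no common ancestor with defined IC for %s and %s", t1, t2))
  sort(common[ic[common] == max(ic[common])])[1]
}

#' Resnik similarity of two terms
#'
#' `IC(MICA(t1, t2))`: the information content of the most informative
#' common ancestor. Unbounded above by the maximum corpus IC; 0 when the
#' only shared ancestor is a root covering the whole corpus.
#'
#' @inheritParams mica
#' @return non-negative real.
#' @export
sim_resnik <- function(onto, ic, t1, t2) {
  unname(ic[mica(onto, ic, t1, t2)])
}

#' Lin similarity of two terms
#'
#' `2 * IC(MICA) / (IC(t1) + IC(t2))`, in \[0, 1\], with the convention
#' that two zero-IC terms (roots) score 0. `paper_literal = TRUE` drops
#' the factor 2 (a printed variant under which self-similarity is 0.5).
#'
#' @inheritParams mica
#' @param paper_literal use the unnormalized printed form (no factor 2).
#' @return real in \[0, 1\] (\[0, 0.5\] under `paper_literal`).
#' @export
sim_lin <- function(onto, ic, t1, t2, paper_literal = FALSE) {
  i1 <- unname(ic[resolve_term(onto, t1)])
  i2 <- unname(ic[resolve_term(onto, t2)])
  if (is.na(i1) || is.na(i2))
    stop("Lin similarity requires both terms to have defined IC")
  if (i1 + i2 == 0) return(0)
  fac <- if (paper_literal) 1 else 2
  fac * sim_resnik(onto, ic, t1, t2) / (i1 + i2)
}

#' Jiang-Conrath similarity of two terms
#'
#' `1 - (IC(t1) + IC(t2) - 2 * IC(MICA))`: one minus the IC distance.
#' The raw value is unbounded below (ICs are in nats); reported values are
#' clamped to \[0, 1\] so score columns stay comparable across measures,
#' with `clamp = FALSE` returning the raw value.
#'
#' @inheritParams mica
#' @param clamp clamp the result to \[0, 1\] (default).
#' @return real (in \[0, 1\] when clamped).
#' @export
sim_jiang <- function(onto, ic, t1, t2, clamp = TRUE) {
  i1 <- unname(ic[resolve_term(onto, t1)])
  i2 <- unname(ic[resolve_term(onto, t2)])
  if (is.na(i1) || is.na(i2))
    stop("Jiang similarity requires both terms to have defined IC")
  raw <- 1 - (i1 + i2 - 2 * sim_resnik(onto, ic, t1, t2))
  if (clamp) min(max(raw, 0), 1) else raw
}

# S-values of a term's ancestor sub-DAG: S(t) = 1 at the term itself and
# S(parent) = max over child edges of w_edge * S(child), propagated upward.
wang_svalues <- function(onto, term, w_is_a = 0.8, w_part_of = 0.6) {
  term <- resolve_term(onto, term)
  wts <- c(is_a = w_is_a, part_of = w_part_of)
  S <- stats::setNames(1, term)
  queue <- term
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    p <- onto$parents[[u]]
    if (is.null(p) || !nrow(p)) next
    for (k in seq_len(nrow(p))) {
      cand <- unname(wts[p$type[k]]) * S[[u]]
      tgt <- p$parent[k]
      if (is.na(S[tgt]) || cand > S[[tgt]]) {
        S[tgt] <- cand
        queue <- c(queue, tgt)
      }
    }
  }
  S
}

#' Wang hybrid similarity of two terms
#'
#' The S-value method: each term's ancestor sub-DAG carries semantic
#' contributions `S(t) = 1` at the term and `S(u) = max over child edges
#' (w_edge * S(child))` above it, with edge weights by relationship type.
#' The similarity is the sum of `S1 + S2` over shared ancestors divided by
#' the two terms' total semantic values. Self-similarity is 1; terms with
#' no shared ancestor score 0.
#'
#' @param onto an [ontology_store()].
#' @param t1,t2 term ids.
#' @param w_is_a,w_part_of semantic contribution factors per edge type,
#'   in (0, 1); defaults 0.8 and 0.6.
#' @return real in \[0, 1\].
#' @export
sim_wang <- function(onto, t1, t2, w_is_a = 0.8, w_part_of = 0.6) {
  stopifnot(w_is_a > 0, w_is_a < 1, w_part_of > 0, w_part_of < 1)
  S1 <- wang_svalues(onto, t1, w_is_a, w_part_of)
  S2 <- wang_svalues(onto, t2, w_is_a, w_part_of)
  common <- intersect(names(S1), names(S2))
  if (!length(common)) return(0)
  sum(S1[common] + S2[common]) / (sum(S1) + sum(S2))
}

normalize_measure <- function(measure) {
  m <- sub("_bma$", "", tolower(measure))
  if (!m %in% c("resnik", "lin", "jiang", "wang"))
    stop(sprintf("unknown measure: %s", measure))
  m
}

#' Pairwise similarity of two terms under a named measure
#'
#' @param onto an [ontology_store()].
#' @param ic an [compute_ic()] table (ignored by `wang`).
#' @param t1,t2 term ids.
#' @param measure one of `"resnik"` (alias `"resnik_bma"`), `"lin"`,
#'   `"jiang"`, `"wang"`.
#' @param ... passed to the specific measure.
#' @return the similarity value.
#' @export
term_similarity <- function(onto, ic, t1, t2, measure, ...) {
  switch(normalize_measure(measure),
         resnik = sim_resnik(onto, ic, t1, t2),
         lin = sim_lin(onto, ic, t1, t2, ...),
         jiang = sim_jiang(onto, ic, t1, t2, ...),
         wang = sim_wang(onto, t1, t2, ...))
}

#' A memoising cache for term- and gene-pair similarities
#' @return an environment usable as the `cache` argument of the scoring
#'   functions; share one across calls to avoid recomputation.
#' @export
similarity_cache <- function() new.env(parent = emptyenv())

cached <- function(cache, key, compute) {
  if (is.null(cache)) return(compute())
  if (!is.null(cache[[key]])) return(cache[[key]])
  cache[[key]] <- compute()
  cache[[key]]
}

#' Best-match-average similarity of two genes
#'
#' Builds the term-pair similarity matrix `M[i, j] = measure(ti, tj)` over
#' the two genes' direct annotations and aggregates by best-match average:
#' `(mean of row maxima + mean of column maxima) / 2`. Symmetric by
#' construction. An unannotated gene yields `NA` with a warning.
#'
#' @param onto an [ontology_store()].
#' @param corpus annotation corpus (named list gene -> terms).
#' @param g1,g2 gene ids.
#' @param measure see [term_similarity()].
#' @param ic an [compute_ic()] table; computed on the fly when `NULL`
#'   (pass one explicitly in loops).
#' @param cache optional [similarity_cache()].
#' @param ... passed to the term measure.
#' @return the BMA similarity, or `NA` for an unannotated gene.
#' @export
gene_similarity_bma <- function(onto, corpus, g1, g2, measure = "lin",
                                ic = NULL, cache = NULL, ...) {
  t1 <- corpus[[g1]]; t2 <- corpus[[g2]]
  if (is.null(t1) || !length(t1) || is.null(t2) || !length(t2)) {
    warning(sprintf("gene(s) without annotations: %s",
                    paste(c(g1, g2)[c(!length(t1 %||% character(0)),
                                      !length(t2 %||% character(0)))],
                          collapse = ", ")))
    return(NA_real_)
  }
  meas <- normalize_measure(measure)
  if (is.null(ic) && meas != "wang") ic <- compute_ic(onto, corpus)
  key <- paste("g", meas, paste(sort(c(g1, g2)), collapse = "\r"), sep = "\r")
  cached(cache, key, function() {
    M <- matrix(NA_real_, length(t1), length(t2))
    for (i in seq_along(t1)) {
      for (j in seq_along(t2)) {
        tk <- paste("t", meas, paste(sort(c(t1[i], t2[j])), collapse = "\r"),
                    sep = "\r")
        M[i, j] <- cached(cache, tk, function()
          term_similarity(onto, ic, t1[i], t2[j], meas, ...))
      }
    }
    (mean(apply(M, 1, max)) + mean(apply(M, 2, max))) / 2
  })
}

#' Pairwise gene-similarity matrix
#'
#' @param genes character vector of gene ids.
#' @inheritParams gene_similarity_bma
#' @return symmetric matrix of BMA similarities (`NA` rows/columns for
#'   unannotated genes; diagonal left `NA`).
#' @export
gene_similarity_matrix <- function(genes, onto, corpus, measure = "lin",
                                   ic = NULL, cache = NULL, ...) {
  genes <- unique(genes)
  meas <- normalize_measure(measure)
  if (is.null(ic) && meas != "wang") ic <- compute_ic(onto, corpus)
  if (is.null(cache)) cache <- similarity_cache()
  n <- length(genes)
  M <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  annotated <- vapply(genes, function(g) length(corpus[[g]] %||% character(0)) > 0,
                      logical(1))
  for (i in seq_len(n - 1)) {
    if (!annotated[i]) next
    for (j in seq.int(i + 1, n)) {
      if (!annotated[j]) next
      M[i, j] <- M[j, i] <-
        gene_similarity_bma(onto, corpus, genes[i], genes[j], meas,
                            ic = ic, cache = cache, ...)
    }
  }
  M
}

#' Functional-coherence score of an alignment module
#'
#' The mean best-match-average similarity over all unordered pairs of
#' distinct annotated proteins in the module's pooled (both-species)
#' protein set. Scores depend only on the shared ontology, so
#' cross-species pairs contribute like within-species ones. Modules with
#' fewer than two annotated proteins score `NA` with a warning.
#'
#' @param m an [alignment_module()].
#' @inheritParams gene_similarity_bma
#' @param gene_sim optional precomputed [gene_similarity_matrix()]; when
#'   given, the score is read from it and no similarity is recomputed.
#' @return the module score, or `NA`.
#' @export
module_score <- function(m, onto = NULL, corpus = NULL, measure = "lin",
                         ic = NULL, cache = NULL, gene_sim = NULL, ...) {
  pooled <- unique(c(m$projection_1, m$projection_2))
  if (!is.null(gene_sim)) {
    pooled <- intersect(pooled, rownames(gene_sim))
    sub <- gene_sim[pooled, pooled, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      warning(sprintf("module %d has fewer than 2 annotated proteins; score undefined",
                      m$index))
      return(NA_real_)
    }
    return(mean(vals))
  }
  annotated <- pooled[vapply(pooled, function(g)
    length(corpus[[g]] %||% character(0)) > 0, logical(1))]
  if (length(annotated) < 2L) {
    warning(sprintf("module %d has fewer than 2 annotated proteins; score undefined",
                    m$index))
    return(NA_real_)
  }
  meas <- normalize_measure(measure)
  if (is.null(ic) && meas != "wang") ic <- compute_ic(onto, corpus)
  if (is.null(cache)) cache <- similarity_cache()
  pairs <- utils::combn(annotated, 2)
  mean(vapply(seq_len(ncol(pairs)), function(k)
    gene_similarity_bma(onto, corpus, pairs[1, k], pairs[2, k], meas,
                        ic = ic, cache = cache, ...), numeric(1)))
}

#' Score a list of modules under several measures
#'
#' @param modules list of [alignment_module()].
#' @param onto an [ontology_store()].
#' @param corpus annotation corpus.
#' @param measures character vector of measure names (see
#'   [term_similarity()]); the conventional trio is
#'   `c("resnik_bma", "lin", "wang")`.
#' @param ic optional precomputed [compute_ic()] table.
#' @param cache optional shared [similarity_cache()].
#' @return data.frame (the score table): `module`, `size`, one column per
#'   measure.
#' @export
score_modules <- function(modules, onto, corpus,
                          measures = c("resnik_bma", "lin", "wang"),
                          ic = NULL, cache = NULL) {
  if (is.null(ic)) ic <- compute_ic(onto, corpus)
  if (is.null(cache)) cache <- similarity_cache()
  out <- data.frame(module = vapply(modules, function(m) m$index, integer(1)),
                    size = vapply(modules, function(m) m$size, integer(1)))
  for (ms in measures) {
    out[[ms]] <- vapply(modules, function(m)
      module_score(m, onto, corpus, ms, ic = ic, cache = cache), numeric(1))
  }
  out
}
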