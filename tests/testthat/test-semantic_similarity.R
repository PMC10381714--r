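# Ontology parsing, information content, MICA, the four similarity
# measures, BMA aggregation and module scoring.

toy_obo_lines <- c(
  "format-version: 1.2", "",
  "[Term]", "id: T:1", "name: root", "namespace: demo", "",
  "[Term]", "id: T:2", "name: left", "namespace: demo", "is_a: T:1 ! root", "",
  "[Term]", "id: T:3", "name: right", "namespace: demo", "is_a: T:1", "",
  "[Term]", "id: T:4", "name: leafL", "namespace: demo",
  "alt_id: T:44", "is_a: T:2", "",
  "[Term]", "id: T:5", "name: leafR", "namespace: demo",
  "relationship: part_of T:3", "",
  "[Term]", "id: T:9", "name: gone", "is_obsolete: true", "is_a: T:1", "")

test_that("OBO parsing builds a validated DAG, skips obsoletes, maps alt ids", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(toy_obo_lines, f)
  onto <- load_ontology(f)
  expect_equal(length(onto$terms), 5L)  # root + 2 children + 2 grandchildren
  expect_equal(nrow(onto$edges), 4L)
  expect_false("T:9" %in% onto$terms)   # obsolete excluded
  expect_equal(onto$roots, "T:1")
  expect_identical(term_ancestors(onto, "T:44"), term_ancestors(onto, "T:4"))
  expect_equal(onto$edges$type[onto$edges$child == "T:5"], "part_of")

  # term count equals a stanza-count oracle on the same file
  stanzas <- sum(readLines(f) == "[Term]") -
    sum(grepl("is_obsolete: true", readLines(f)))
  expect_equal(length(onto$terms), stanzas)
})

test_that("cyclic or dangling ontologies are rejected with located messages", {
  expect_error(
    ontology_store(c("A", "B"),
                   data.frame(child = c("A", "B"), parent = c("B", "A"),
                              type = "is_a")),
    "cycle")
  expect_error(
    ontology_store("A", data.frame(child = "A", parent = "Z", type = "is_a")),
    "dangling")
})

test_that("ontologies and annotation corpora round-trip through OBO and GAF", {
  fx <- make_ic_fixture()
  fo <- withr::local_tempfile(fileext = ".obo")
  write_obo(fx$onto, fo)
  back <- load_ontology(fo)
  expect_setequal(back$terms, fx$onto$terms)
  expect_equal(nrow(back$edges), nrow(fx$onto$edges))
  for (t in back$terms)
    expect_setequal(term_ancestors(back, t), term_ancestors(fx$onto, t))

  fg <- withr::local_tempfile(fileext = ".gaf")
  write_gaf(fx$corpus, fg, fx$onto)
  corpus2 <- read_annotations(fg, onto = back)
  expect_identical(corpus2[order(names(corpus2))],
                   fx$corpus[order(names(fx$corpus))])

  # two-column dialect and unknown-term dropping
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tTO:0000004", "g1\tNOPE:1", "g2\tTO:0000005"), ft)
  expect_warning(c2 <- read_annotations(ft, onto = fx$onto), "unknown")
  expect_equal(c2$g1, "TO:0000004")
})

test_that("information content matches hand computation and is monotone down the DAG", {
  fx <- make_ic_fixture()
  ic <- fx$ic
  expect_equal(attr(ic, "total_genes"), 8L)
  expect_equal(unname(ic[fx$terms[["root"]]]), 0)            # -ln(1)
  expect_equal(unname(ic[fx$terms[["ta1"]]]), log(8), tolerance = 1e-12)
  expect_equal(unname(ic[fx$terms[["ta"]]]), log(4), tolerance = 1e-12)
  for (k in seq_len(nrow(fx$onto$edges)))
    expect_gte(ic[[fx$onto$edges$child[k]]], ic[[fx$onto$edges$parent[k]]])
})

test_that("MICA agrees with the brute-force ancestor-set oracle and handles ties/self", {
  fx <- make_ic_fixture()
  expect_equal(mica(fx$onto, fx$ic, fx$terms[["ta1"]], fx$terms[["ta1"]]),
               fx$terms[["ta1"]])
  expect_equal(mica(fx$onto, fx$ic, fx$terms[["ta1"]], fx$terms[["ta2"]]),
               fx$terms[["ta"]])

  dag <- random_dag(30, seed = 77)
  genes <- stats::setNames(
    lapply(1:20, function(i) sample(dag$terms, 2)), sprintf("g%02d", 1:20))
  ic <- compute_ic(dag$onto, genes)
  set.seed(78)
  for (k in 1:50) {
    ts <- sample(dag$terms, 2)
    expect_equal(mica(dag$onto, ic, ts[1], ts[2]),
                 mica_oracle(dag$edges, ic, ts[1], ts[2]))
  }

  # disjoint roots: no common ancestor
  two <- ontology_store(c("R1", "R2", "C1", "C2"),
                        data.frame(child = c("C1", "C2"),
                                   parent = c("R1", "R2"), type = "is_a"))
  ic2 <- compute_ic(two, list(a = "C1", b = "C2"))
  expect_error(mica(two, ic2, "C1", "C2"), "no common ancestor")
})

test_that("Resnik, Lin and Jiang reproduce the hand-checked fixture values", {
  fx <- make_ic_fixture()
  t <- fx$terms
  o <- fx$onto; ic <- fx$ic

  # Resnik: IC of the MICA
  expect_equal(sim_resnik(o, ic, t[["ta1"]], t[["tb1"]]), 0)        # root MICA
  expect_equal(sim_resnik(o, ic, t[["ta1"]], t[["ta1"]]), log(8),
               tolerance = 1e-9)
  expect_equal(sim_resnik(o, ic, t[["ta1"]], t[["ta2"]]), log(4),
               tolerance = 1e-9)

  # Lin: identity 1, disjoint branches 0, siblings ln4/ln8 = 2/3
  expect_equal(sim_lin(o, ic, t[["ta1"]], t[["ta1"]]), 1)
  expect_equal(sim_lin(o, ic, t[["ta1"]], t[["tb1"]]), 0)
  expect_equal(sim_lin(o, ic, t[["ta1"]], t[["ta2"]]), 2 / 3,
               tolerance = 1e-9)
  expect_equal(sim_lin(o, ic, t[["root"]], t[["root"]]), 0)  # two-roots convention
  expect_equal(sim_lin(o, ic, t[["ta1"]], t[["ta1"]], paper_literal = TRUE),
               0.5)

  # Jiang: identity 1; siblings raw 1 - 2*(ln8 - ln4) = 1 - ln4, clamped to 0
  expect_equal(sim_jiang(o, ic, t[["ta1"]], t[["ta1"]]), 1)
  expect_equal(sim_jiang(o, ic, t[["ta1"]], t[["ta2"]], clamp = FALSE),
               1 - log(4), tolerance = 1e-9)
  expect_equal(sim_jiang(o, ic, t[["ta1"]], t[["ta2"]]), 0)
  # raw value is exactly 1 iff IC(t1) + IC(t2) = 2 IC(MICA)
  expect_equal(sim_jiang(o, ic, t[["ta"]], t[["ta"]], clamp = FALSE), 1)
})

test_that("Wang S-values reproduce the hand-propagated fixture", {
  wf <- make_wang_fixture()
  t <- wf$terms; o <- wf$onto
  expect_equal(sim_wang(o, t[["a1"]], t[["a1"]]), 1)
  # S(a1): {a1:1, a:0.8, r:0.64}; S(a2): {a2:1, a:0.6, r:0.48}
  expect_equal(sim_wang(o, t[["a1"]], t[["a2"]]), 2.52 / 4.52,
               tolerance = 1e-9)
  # S(b): {b:1, r:0.8}; shared ancestor r only
  expect_equal(sim_wang(o, t[["a1"]], t[["b"]]), 1.44 / 4.24,
               tolerance = 1e-9)

  # disjoint roots share no ancestor at all -> 0
  two <- ontology_store(c("R1", "R2", "C1", "C2"),
                        data.frame(child = c("C1", "C2"),
                                   parent = c("R1", "R2"), type = "is_a"))
  expect_equal(sim_wang(two, "C1", "C2"), 0)
})

test_that("similarity measures are symmetric and bounded", {
  dag <- random_dag(25, seed = 41)
  genes <- stats::setNames(
    lapply(1:15, function(i) sample(dag$terms, 3)), sprintf("g%02d", 1:15))
  ic <- compute_ic(dag$onto, genes)
  max_ic <- max(ic, na.rm = TRUE)
  defined <- dag$terms[!is.na(ic[dag$terms])]
  set.seed(42)
  for (k in 1:25) {
    ts <- sample(defined, 2)
    for (ms in c("resnik", "lin", "jiang", "wang")) {
      s12 <- term_similarity(dag$onto, ic, ts[1], ts[2], ms)
      s21 <- term_similarity(dag$onto, ic, ts[2], ts[1], ms)
      expect_equal(s12, s21)
      if (ms %in% c("lin", "wang", "jiang")) {
        expect_gte(s12, 0); expect_lte(s12, 1)
      } else {
        expect_gte(s12, 0); expect_lte(s12, max_ic + 1e-12)
      }
    }
  }
})

test_that("Resnik grows as a term approaches its partner along a root path", {
  fx <- make_ic_fixture()
  t <- fx$terms
  path <- c(t[["root"]], t[["ta"]], t[["ta1"]])
  vals <- sapply(path, function(x) sim_resnik(fx$onto, fx$ic, x, t[["ta1"]]))
  expect_true(all(diff(vals) >= 0))
})

test_that("gene BMA matches hand computation, is symmetric, flags unannotated genes", {
  fx <- make_ic_fixture()
  t <- fx$terms
  corpus <- list(gA = c(t[["ta1"]], t[["ta2"]]), gB = t[["ta1"]],
                 gC = t[["ta1"]], gD = character(0))
  # IC comes from the reference 8-gene corpus, so leaf terms stay informative
  ic <- fx$ic

  # identical single annotations: measure(t, t) = 1 under Lin and Wang
  expect_equal(gene_similarity_bma(fx$onto, corpus, "gB", "gC", "lin", ic), 1)
  expect_equal(gene_similarity_bma(fx$onto, corpus, "gB", "gC", "wang"), 1)

  # 2x1 term matrix: rows max (1, lin(ta2,ta1)), col max 1
  lin_sib <- sim_lin(fx$onto, ic, t[["ta2"]], t[["ta1"]])
  expect_equal(gene_similarity_bma(fx$onto, corpus, "gA", "gB", "lin", ic),
               (mean(c(1, lin_sib)) + 1) / 2, tolerance = 1e-9)
  expect_equal(gene_similarity_bma(fx$onto, corpus, "gA", "gB", "lin", ic),
               gene_similarity_bma(fx$onto, corpus, "gB", "gA", "lin", ic))

  expect_warning(na <- gene_similarity_bma(fx$onto, corpus, "gA", "gD", "lin", ic),
                 "without annotations")
  expect_true(is.na(na))
})

test_that("module scores average pairwise BMA and separate coherent from incoherent sets", {
  fx <- make_ic_fixture()
  t <- fx$terms
  corpus <- list(p1 = t[["ta1"]], p2 = t[["ta1"]], p3 = c(t[["ta1"]], t[["ta2"]]),
                 q1 = t[["ta1"]], q2 = t[["tb1"]], q3 = t[["tb2"]])
  ic <- compute_ic(fx$onto, corpus)

  m2 <- alignment_module(1, members = data.frame(a = "p1", b = "p2"))
  expect_equal(module_score(m2, fx$onto, corpus, "lin", ic), 1)

  # three proteins: mean of the three pairwise BMA values
  m3 <- alignment_module(2, members = data.frame(a = c("p1", "p3"),
                                                 b = c("p2", "p2")))
  b12 <- gene_similarity_bma(fx$onto, corpus, "p1", "p2", "lin", ic)
  b13 <- gene_similarity_bma(fx$onto, corpus, "p1", "p3", "lin", ic)
  b23 <- gene_similarity_bma(fx$onto, corpus, "p2", "p3", "lin", ic)
  expect_equal(module_score(m3, fx$onto, corpus, "lin", ic),
               mean(c(b12, b13, b23)), tolerance = 1e-9)

  # same-branch module scores above a mixed-branch module
  coher <- alignment_module(3, members = data.frame(a = c("p1", "p3"),
                                                    b = c("p2", "p1")))
  mixed <- alignment_module(4, members = data.frame(a = c("q1", "q3"),
                                                    b = c("q2", "q1")))
  expect_gt(module_score(coher, fx$onto, corpus, "lin", ic),
            module_score(mixed, fx$onto, corpus, "lin", ic))

  # fewer than two annotated proteins: undefined with a warning
  m1 <- alignment_module(5, members = data.frame(a = "p1", b = "p1"))
  expect_warning(s <- module_score(m1, fx$onto, corpus, "lin", ic),
                 "fewer than 2")
  expect_true(is.na(s))

  # precomputed gene-similarity matrix gives the same answer
  gs <- gene_similarity_matrix(names(corpus), fx$onto, corpus, "lin", ic)
  expect_equal(module_score(m3, gene_sim = gs),
               mean(c(b12, b13, b23)), tolerance = 1e-9)
})

test_that("score_modules reports one column per measure over pooled cross-species sets", {
  fx <- make_ic_fixture()
  t <- fx$terms
  corpus <- list(x1 = t[["ta1"]], y1 = t[["ta2"]], x2 = t[["tb1"]],
                 y2 = t[["tb2"]])
  mods <- list(alignment_module(1, members = data.frame(a = "x1", b = "y1")),
               alignment_module(2, members = data.frame(a = "x2", b = "y2")))
  st <- score_modules(mods, fx$onto, corpus,
                      measures = c("resnik_bma", "lin", "wang"))
  expect_equal(names(st), c("module", "size", "resnik_bma", "lin", "wang"))
  expect_equal(nrow(st), 2L)
  expect_true(all(st$lin >= 0 & st$lin <= 1))
  # cross-species scoring works purely through the shared ontology
  ic <- compute_ic(fx$onto, corpus)
  expect_equal(st$resnik_bma[1],
               gene_similarity_bma(fx$onto, corpus, "x1", "y1", "resnik", ic))
})
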