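# Composite-node selection, distances, edge classification and graph
# construction.

triangle <- function(ids, name = "tri") {
  ppi_network(data.frame(a = ids[c(1, 2, 3)], b = ids[c(2, 3, 1)],
                         stringsAsFactors = FALSE), name = name)
}

test_that("composite-node selection implements best-match with ties kept", {
  net1 <- ppi_network(data.frame(a = c("x", "x"), b = c("y", "z")))
  net2 <- ppi_network(data.frame(a = c("u", "u"), b = c("v", "w")))

  one <- select_composite_nodes(net1, net2, seed_pair_map("x", "u", 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$a, "x")

  # x's best is u; v's best is y (checked against brute-force argmax)
  s <- seed_pair_map(c("x", "x", "y"), c("u", "v", "v"), c(0.9, 0.5, 0.7))
  sel <- select_composite_nodes(net1, net2, s, "best_match")
  expect_equal(paste(sel$a, sel$b), c("x u", "y v"))
  brute <- unique(c(
    unlist(lapply(unique(s$a), function(p) {
      rows <- which(s$a == p)
      rows[s$similarity[rows] == max(s$similarity[rows])]
    })),
    unlist(lapply(unique(s$b), function(p) {
      rows <- which(s$b == p)
      rows[s$similarity[rows] == max(s$similarity[rows])]
    }))))
  expect_setequal(paste(sel$a, sel$b), paste(s$a, s$b)[brute])

  # ties keep all tied pairs (many-to-many mapping preserved)
  tie <- select_composite_nodes(net1, net2,
                                seed_pair_map(c("x", "x"), c("u", "v"),
                                              c(0.8, 0.8)))
  expect_equal(nrow(tie), 2L)

  # all_pairs keeps every valid seed
  all3 <- select_composite_nodes(net1, net2, s, "all_pairs")
  expect_equal(nrow(all3), 3L)

  expect_warning(
    sel2 <- select_composite_nodes(net1, net2,
                                   seed_pair_map(c("x", "GHOST"), c("u", "v"))),
    "absent")
  expect_equal(nrow(sel2), 1L)
  expect_error(
    suppressWarnings(select_composite_nodes(net1, net2,
                                            seed_pair_map("GHOST", "u"))),
    "empty alignment-graph node set")
})

test_that("pair_distance is BFS shortest-path length with Inf across components", {
  path <- ppi_network(data.frame(a = c("x", "y"), b = c("y", "z")))
  expect_equal(pair_distance(path, "x", "z"), 2)
  two <- ppi_network(data.frame(a = c("x", "u"), b = c("y", "v")))
  expect_equal(pair_distance(two, "x", "u"), Inf)
  expect_error(pair_distance(path, "x", "x"), "identical")

  net <- random_ppi(20, 0.12, seed = 11)
  pairs <- utils::combn(net$nodes, 2)
  for (k in seq_len(ncol(pairs))) {
    expect_equal(pair_distance(net, pairs[1, k], pairs[2, k]),
                 bfs_oracle(net$edges, net$nodes, pairs[1, k], pairs[2, k]))
  }
})

test_that("edge classification follows the match/mismatch/gap rules and the configured weights", {
  # net1: x-y edge (d1 = 1); net2 topologies give d2 = 1, 2, Inf
  net1 <- ppi_network(data.frame(a = "x", b = "y"))
  w <- weight_params()  # published defaults

  n2_match <- ppi_network(data.frame(a = "u", b = "v"))
  e <- classify_edge(list(a = "x", b = "u"), list(a = "y", b = "v"),
                     net1, n2_match, delta = 2)
  expect_equal(e$category, "hom_match")
  expect_equal(unname(w$weights[e$category]), 1)

  n2_mm <- ppi_network(data.frame(a = c("u", "m"), b = c("m", "v")))
  e <- classify_edge(list(a = "x", b = "u"), list(a = "y", b = "v"),
                     net1, n2_mm, delta = 2)
  expect_equal(e$category, "hom_mismatch")
  expect_equal(unname(w$weights[e$category]), 0.5)

  n2_gap <- ppi_network(data.frame(a = c("u", "v"), b = c("p", "q")))
  e <- classify_edge(list(a = "x", b = "u"), list(a = "y", b = "v"),
                     net1, n2_gap, delta = 2)
  expect_equal(e$category, "hom_gap")
  expect_equal(unname(w$weights[e$category]), 0.2)

  # no direct edge on either side -> no edge at all
  chain1 <- ppi_network(data.frame(a = c("x", "m1", "m2"),
                                   b = c("m1", "m2", "y")))
  chain2 <- ppi_network(data.frame(a = c("u", "k1", "k2"),
                                   b = c("k1", "k2", "v")))
  expect_null(classify_edge(list(a = "x", b = "u"), list(a = "y", b = "v"),
                            chain1, chain2, delta = 2))

  # composite nodes sharing a protein get no edge
  n2 <- ppi_network(data.frame(a = "u", b = "v"))
  expect_null(classify_edge(list(a = "x", b = "u"), list(a = "x", b = "v"),
                            net1, n2, delta = 2))
  expect_error(classify_edge(list(a = "x", b = "u"), list(a = "x", b = "u"),
                             net1, n2), "distinct")

  # heterogeneous when any endpoint color differs
  net1c <- ppi_network(data.frame(a = "x", b = "y"), colors = c(x = "red"))
  e <- classify_edge(list(a = "x", b = "u"), list(a = "y", b = "v"),
                     net1c, n2_match, delta = 2)
  expect_equal(e$color_class, "heterogeneous")
})

test_that("classification is symmetric in the two composite nodes", {
  set.seed(5)
  net1 <- random_ppi(10, 0.3, 1, "a")
  net2 <- random_ppi(10, 0.3, 2, "b")
  for (k in 1:25) {
    u <- list(a = sample(net1$nodes, 1), b = sample(net2$nodes, 1))
    v <- list(a = sample(net1$nodes, 1), b = sample(net2$nodes, 1))
    if (u$a == v$a && u$b == v$b) next
    expect_identical(classify_edge(u, v, net1, net2, 2),
                     classify_edge(v, u, net1, net2, 2))
  }
})

test_that("two isomorphic networks with identity seeds give an all-match copy of the input", {
  net1 <- triangle(c("x", "y", "z"), "t1")
  net2 <- triangle(c("u", "v", "w"), "t2")
  seeds <- seed_pair_map(c("x", "y", "z"), c("u", "v", "w"))
  ag <- suppressMessages(build_alignment_graph(net1, net2, seeds))
  expect_equal(nrow(ag$nodes), 3L)
  expect_equal(nrow(ag$edges), 3L)
  expect_true(all(ag$edges$category == "hom_match"))
  expect_true(all(ag$edges$weight == 1))
})

test_that("edge weights come from the configured set and hom_match rescales only its own class", {
  net1 <- random_ppi(15, 0.25, 3, "a")
  net2 <- random_ppi(15, 0.25, 4, "b")
  seeds <- random_seeds(net1, net2, 10, 5)
  ag <- suppressMessages(build_alignment_graph(net1, net2, seeds))
  expect_true(all(ag$edges$weight %in% ag$params$weights))

  w2 <- weight_params(hom_match = 5)
  ag2 <- suppressMessages(build_alignment_graph(net1, net2, seeds, w2))
  expect_identical(ag2$edges$category, ag$edges$category)
  is_hm <- ag$edges$category == "hom_match"
  expect_equal(ag2$edges$weight[is_hm], rep(5, sum(is_hm)))
  expect_equal(ag2$edges$weight[!is_hm], ag$edges$weight[!is_hm])

  # single shared color: heterogeneous categories never appear
  expect_false(any(grepl("^het_", ag$edges$category)))
})

test_that("raising delta reclassifies gaps to mismatches monotonically", {
  for (s in 1:3) {
    net1 <- random_ppi(18, 0.15, s, "a")
    net2 <- random_ppi(18, 0.15, s + 50, "b")
    seeds <- random_seeds(net1, net2, 12, s)
    counts <- sapply(1:4, function(d) {
      ag <- suppressMessages(
        build_alignment_graph(net1, net2, seeds, weight_params(delta = d)))
      c(mismatch = sum(grepl("mismatch", ag$edges$category)),
        gap = sum(grepl("gap", ag$edges$category)))
    })
    expect_true(all(diff(counts["mismatch", ]) >= 0))
    expect_true(all(diff(counts["gap", ]) <= 0))
  }
})

test_that("weight parameters validate delta and warn on ordering violations", {
  expect_error(weight_params(delta = 0))
  expect_warning(weight_params(hom_gap = 2), "ordering")
  expect_silent(weight_params())
  f <- withr::local_tempfile(fileext = ".tsv")
  net1 <- triangle(c("x", "y", "z"))
  net2 <- triangle(c("u", "v", "w"))
  ag <- suppressMessages(
    build_alignment_graph(net1, net2,
                          seed_pair_map(c("x", "y", "z"), c("u", "v", "w"))))
  write_alignment_graph(ag, f)
  df <- read.delim(f)
  expect_equal(nrow(df), 3L)
  prov <- jsonlite::read_json(sub("\\.tsv$", ".json", f))
  expect_equal(prov$delta, 2L)
  expect_equal(prov$weights$hom_match, 1)
})
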