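# Network assembly and the topological statistics with permutation nulls.

test_that("build_network merges ceRNA and PPI edges with deduplication", {
  pairs <- data.frame(
    lnc_id = c("L1", "L2", "L1"), tf_id = c("T1", "T1", "T1"),
    r_shared = 3, hyper_p = 0.01, pcc = 0.8, pcc_p = 1e-4, bh_q = 0.05,
    significant = c(TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  ppi <- data.frame(a = "T1", b = "T2", stringsAsFactors = FALSE)
  net <- build_network(pairs, ppi)
  expect_equal(igraph::vcount(net), 4)   # L1 L2 T1 T2
  expect_equal(igraph::ecount(net), 3)   # duplicate L1-T1 collapsed
  nt <- setNames(igraph::V(net)$node_type, igraph::V(net)$name)
  expect_identical(unname(nt[c("L1", "T2")]), c("lncRNA", "TF"))
  # PPI edge touching a lncRNA id is rejected
  expect_error(build_network(pairs, data.frame(a = "L1", b = "T2")),
               "non-TF")
  # non-significant pairs are not admitted
  pairs$significant <- FALSE
  empty <- build_network(pairs, NULL)
  expect_equal(igraph::vcount(empty), 0)
})

test_that("a ceRNA+PPI parallel pair collapses to one dual-typed edge", {
  pairs <- data.frame(lnc_id = "L1", tf_id = "T1", r_shared = 3,
                      hyper_p = 0.01, pcc = 0.8, pcc_p = 1e-4, bh_q = 0.05,
                      significant = TRUE, stringsAsFactors = FALSE)
  # same unordered pair supplied twice with different types
  net <- gene_network(
    data.frame(source = c("L1", "T1"), target = c("T1", "L1"),
               edge_type = c("ceRNA", "PPI"), stringsAsFactors = FALSE),
    c(L1 = "lncRNA", T1 = "TF"))
  expect_equal(igraph::ecount(net), 1)
  expect_identical(igraph::E(net)$edge_type, "PPI+ceRNA")
})

test_that("clustering coefficient and ASPL match closed forms", {
  # edges {AB, AC, BC, CD}: (1 + 1 + 1/3 + 0) / 4 = 7/12
  g <- toy_network(rbind(c("A", "B"), c("A", "C"), c("B", "C"), c("C", "D")))
  expect_equal(clustering_coefficient(g), 7 / 12, tolerance = 1e-12)
  expect_equal(clustering_coefficient(toy_clique(c("A", "B", "C"))), 1)
  path <- toy_network(rbind(c("A", "B"), c("B", "C")))
  expect_equal(clustering_coefficient(path), 0)
  expect_equal(average_shortest_path(path), 4 / 3, tolerance = 1e-12)
  for (n in c(2, 4, 7))
    expect_equal(average_shortest_path(toy_clique(LETTERS[1:n])), 1)
  # disconnected: computed on the largest component
  two <- toy_network(rbind(c("A", "B"), c("A", "C"), c("B", "C"),
                           c("X", "Y"), c("X", "Z"), c("Y", "Z")))
  expect_equal(average_shortest_path(two), 1)
  expect_error(average_shortest_path(toy_network(matrix(character(0), 0, 2))),
               class = "lncnet_insufficient_data")
})

test_that("power-law fit recovers an exact power-law histogram", {
  # degree histogram exactly proportional to k^-2.5 (see helper): the
  # log-log regression must be perfectly linear with slope -2.5
  g <- powerlaw_fixture()
  fit <- fit_power_law(g)
  expect_equal(fit$alpha, 2.5, tolerance = 1e-10)
  expect_gte(fit$r2, 0.999)
  # a realistic sparse graph still gives alpha > 0 and r2 in (0, 1]
  mk_star <- function(centre, k)
    cbind(centre, paste0(centre, "_leaf", seq_len(k)))
  edges <- do.call(rbind, c(
    lapply(1:6, function(i) mk_star(paste0("s4_", i), 4)),
    lapply(1:12, function(i) mk_star(paste0("s3_", i), 3)),
    lapply(1:33, function(i) mk_star(paste0("s2_", i), 2))))
  rough <- fit_power_law(toy_network(edges))
  expect_gt(rough$alpha, 0)
  expect_true(rough$r2 > 0 && rough$r2 <= 1)
  # a single distinct degree cannot be fit
  expect_error(fit_power_law(toy_clique(LETTERS[1:5])),
               class = "lncnet_insufficient_data")
})

test_that("permutation p-values follow the add-one estimator exactly", {
  # 30 disjoint triangles maximize the clustering coefficient; every gnm
  # null at this density is below 1, so p attains its minimum 1/(n+1)
  tri <- do.call(rbind, lapply(1:30, function(i) {
    ids <- paste0("t", i, "_", 1:3)
    rbind(ids[c(1, 2)], ids[c(1, 3)], ids[c(2, 3)])
  }))
  g <- toy_network(tri)
  res <- permutation_test(g, "cc", n_perm = 199, scheme = "gnm",
                          alternative = "greater", seed = 5)
  expect_equal(res$p, 1 / 200, tolerance = 1e-12)
  res999 <- permutation_test(g, "cc", n_perm = 999, scheme = "gnm",
                             alternative = "greater", seed = 5)
  expect_equal(res999$p, 1 / 1000, tolerance = 1e-12)
  # identical nulls equal to the observed value give p = 1: a clique's cc
  # and any rewiring-preserved statistic on a complete graph are constant
  k5 <- toy_clique(LETTERS[1:5])
  resk <- permutation_test(k5, "cc", n_perm = 50,
                           scheme = "degree_preserving",
                           alternative = "greater", seed = 1)
  expect_equal(resk$p, 1)
  # reproducibility under a fixed seed
  expect_identical(
    permutation_test(g, "cc", 50, "gnm", "greater", seed = 9)$nulls,
    permutation_test(g, "cc", 50, "gnm", "greater", seed = 9)$nulls)
})

test_that("null schemes preserve their invariants in every draw", {
  sm <- simulate_modular_graph(60, 0.05, c(5), seed = 3)
  g <- sm$network
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  with_seed_checked <- function(scheme, check) {
    set.seed(stream_seed(11, paste0("check_", scheme)))
    for (i in 1:50) {
      null_g <- if (scheme == "gnm") igraph::sample_gnm(n, m) else
        igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
      check(null_g)
    }
  }
  with_seed_checked("gnm", function(ng) {
    expect_identical(igraph::vcount(ng), n)
    expect_identical(igraph::ecount(ng), m)
  })
  with_seed_checked("degree_preserving", function(ng) {
    expect_identical(sort(igraph::degree(ng)), sort(igraph::degree(g)))
  })
})

test_that("hub extraction follows the ceiling rule with lexicographic ties", {
  # 20 nodes -> exactly 2 hubs
  edges <- cbind(paste0("N", sprintf("%02d", 1:19)), "N20")
  star <- toy_network(edges)  # N20 degree 19, rest degree 1
  hubs <- extract_hubs(star, 0.10)
  expect_identical(length(hubs), 2L)
  expect_identical(hubs[1], "N20")
  expect_identical(hubs[2], "N01")  # tie among leaves -> lexicographic
  expect_error(extract_hubs(gene_network(
    data.frame(source = character(0), target = character(0),
               edge_type = character(0)),
    setNames(character(0), character(0)))), "empty")
})
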