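# Construction guarantees, moment checks and seed determinism of the
# synthetic-data generators.

test_that("planted interaction overlaps are constructed exactly", {
  planted <- data.frame(lnc = "LNC0001", tf = "TF001",
                        stringsAsFactors = FALSE)
  si <- simulate_interactions(n_mirna = 50, n_lnc = 5, n_tf = 5,
                              base_rate = 0, overlap_boost = 5,
                              planted = planted, seed = 1)
  tg <- si$interactions$targets_of
  expect_length(intersect(tg$LNC0001, tg$TF001), 5)
  others <- setdiff(names(tg), c("LNC0001", "TF001"))
  expect_true(all(lengths(tg[others]) == 0))
  expect_error(
    simulate_interactions(10, 2, 2, 0.1, 2,
                          data.frame(lnc = "LNC9999", tf = "TF001")),
    "outside the universe")
})

test_that("null shared-target counts match the binomial moment", {
  # with no planting, E[shared] = n_mirna * base_rate^2 per pair
  n_mirna <- 200; rate <- 0.1
  si <- simulate_interactions(n_mirna, 100, 10, rate, 0, NULL, seed = 5)
  tg <- si$interactions$targets_of
  lncs <- sprintf("LNC%04d", 1:100)
  tfs <- sprintf("TF%03d", 1:10)
  shared <- vapply(lncs, function(l) vapply(tfs, function(t)
    length(intersect(tg[[l]], tg[[t]])), numeric(1)), numeric(10))
  n_pairs <- length(shared)
  expect_gte(n_pairs, 1000)
  mu <- n_mirna * rate^2
  se <- sqrt(n_mirna * rate^2 * (1 - rate^2) / n_pairs)
  expect_lt(abs(mean(shared) - mu), 3 * se)
})

test_that("planted co-expression hits its target correlation", {
  pl <- data.frame(a = "G1", b = "G2", rho = 0.99, stringsAsFactors = FALSE)
  ex <- simulate_expression(c("G1", "G2", "G3"), pl, n_samples = 10000,
                            seed = 3)
  expect_lt(abs(cor(ex["G1", ], ex["G2", ]) - 0.99), 0.02)
  # negative targets flip through the latent factor sign
  pln <- data.frame(a = "G1", b = "G2", rho = -0.8)
  exn <- simulate_expression(c("G1", "G2"), pln, n_samples = 10000, seed = 3)
  expect_lt(abs(cor(exn["G1", ], exn["G2", ]) + 0.8), 0.03)
  expect_error(simulate_expression(c("G1", "G2"),
                                   data.frame(a = "G1", b = "G2", rho = 1),
                                   100), "\\(-1, 1\\)")
  expect_error(simulate_expression("G1", NULL, n_samples = 2), ">= 3")
})

test_that("independent genes almost never cross the PCC threshold", {
  ids <- sprintf("G%05d", 1:2000)
  ex <- simulate_expression(ids, NULL, n_samples = 300, seed = 11)
  a <- ex[1:1000, ]; b <- ex[1001:2000, ]
  cc <- vapply(1:1000, function(i) cor(a[i, ], b[i, ]), numeric(1))
  # 10,000 spurious-pair checks via a second pairing
  cc2 <- vapply(1:1000, function(i) cor(a[i, ], b[1001 - i, ]), numeric(1))
  expect_lte(mean(abs(c(cc, cc2)) > 0.6), 1e-3)
})

test_that("survival times follow the planted exponential model", {
  ids <- "G1"
  ex <- simulate_expression(ids, NULL, n_samples = 5000, seed = 2)
  cl <- simulate_survival(ex, setNames(numeric(0), character(0)),
                          baseline_rate = 0.5, censor_rate = 1e-9, seed = 2)
  expect_gte(mean(cl$event), 0.999)
  se <- (1 / 0.5) / sqrt(5000)
  expect_lt(abs(mean(cl$time) - 2), 3 * se)
  # heavy censoring: nearly all censored
  cl2 <- simulate_survival(ex, setNames(numeric(0), character(0)),
                           baseline_rate = 0.01, censor_rate = 100, seed = 2)
  expect_gt(mean(cl2$event == 0), 0.99)
  expect_error(simulate_survival(ex, c(G1 = 1), baseline_rate = -1),
               "positive")
})

test_that("modular graphs contain the planted cliques plus one bridge each", {
  sm <- simulate_modular_graph(20, 0, clique_sizes = 5, seed = 1)
  expect_equal(igraph::ecount(sm$network), choose(5, 2) + 1)
  ids <- sm$truth$planted_modules[[1]]
  sub <- igraph::induced_subgraph(sm$network, ids)
  expect_equal(igraph::ecount(sub), choose(5, 2))  # density 1
  expect_error(simulate_modular_graph(10, 0.1, clique_sizes = 2), ">= 3")
})

test_that("sequence backgrounds match the stated base frequencies", {
  pwm <- sharp_pwm(6)
  sq <- simulate_sequences(pwm, n_seq = 40, seq_len = 1000,
                           planted_sites = 0, seed = 4)
  comp <- table(strsplit(paste(sq$sequences, collapse = ""), "")[[1]])
  n <- sum(comp)
  se <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(comp - n * 0.25) < 3 * se))
  # a deterministic PWM plants its exact word at the recorded offset
  cts <- matrix(0, 5, 4); cts[cbind(1:5, c(1, 2, 3, 4, 1))] <- 100
  det <- pwm_from_counts(cts, "DET", pseudocount = 1e-6)
  sqd <- simulate_sequences(det, n_seq = 6, seq_len = 50,
                            planted_sites = 1, seed = 9)
  for (i in seq_len(nrow(sqd$truth))) {
    s <- sqd$sequences[[sqd$truth$seq_id[i]]]
    word <- substr(s, sqd$truth$offset[i] + 1, sqd$truth$offset[i] + 5)
    expected <- if (sqd$truth$strand[i] == "+") "ACGTA" else "TACGT"
    expect_identical(word, expected)
  }
})

test_that("every generator is deterministic under a fixed seed", {
  expect_identical(simulate_interactions(50, 10, 5, 0.1, 3, NULL, seed = 7),
                   simulate_interactions(50, 10, 5, 0.1, 3, NULL, seed = 7))
  expect_identical(simulate_expression(c("A", "B"), NULL, 50, seed = 7),
                   simulate_expression(c("A", "B"), NULL, 50, seed = 7))
  ex <- simulate_expression(c("A", "B"), NULL, 50, seed = 7)
  expect_identical(simulate_survival(ex, c(A = 0.5), seed = 7),
                   simulate_survival(ex, c(A = 0.5), seed = 7))
  g1 <- simulate_modular_graph(30, 0.05, c(4), seed = 7)
  g2 <- simulate_modular_graph(30, 0.05, c(4), seed = 7)
  expect_identical(igraph::as_edgelist(g1$network),
                   igraph::as_edgelist(g2$network))
  pwm <- sharp_pwm(5)
  expect_identical(simulate_sequences(pwm, 3, 100, 1, seed = 7)$sequences,
                   simulate_sequences(pwm, 3, 100, 1, seed = 7)$sequences)
  # named sub-streams: different generators do not share draws
  expect_false(identical(
    simulate_expression(c("A", "B"), NULL, 50, seed = 7)["A", 1:5],
    simulate_expression(c("A", "B"), NULL, 50, seed = 8)["A", 1:5]))
})
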