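# PWM construction, exact DP p-values, region scanning, promoter/enhancer
# definition and feedback-loop calling.

test_that("PWM frequencies and log-odds satisfy their invariants", {
  set.seed(1)
  cts <- matrix(rpois(24, 8), 6, 4)
  pwm <- pwm_from_counts(cts, "T1", pseudocount = 0.1)
  expect_equal(unname(rowSums(pwm$freq)), rep(1, 6), tolerance = 1e-9)
  expect_equal(pwm$log_odds,
               log2(sweep(pwm$freq, 2, pwm$background, "/")),
               tolerance = 1e-12)
  expect_error(pwm_from_counts(matrix(-1, 4, 4)), "non-negative")
  expect_error(pwm_from_counts(cts, pseudocount = 0), "positive")
})

test_that("score_pvalue matches exhaustive word enumeration", {
  # oracle: enumerate all 4^w words with the PWM's discretized integer
  # column scores and sum the background probabilities of words at or
  # above each threshold
  set.seed(7)
  for (rep in 1:10) {
    w <- sample(3:5, 1)
    cts <- matrix(stats::rgamma(w * 4, 1, 0.2), w, 4)
    bg <- stats::rgamma(4, 5, 1); bg <- bg / sum(bg)
    pwm <- pwm_from_counts(cts, "x", background = bg)
    grid <- as.matrix(expand.grid(rep(list(1:4), w)))
    K <- rowSums(matrix(pwm$kmat[cbind(rep(seq_len(w), each = nrow(grid)),
                                       as.vector(grid))], nrow(grid), w))
    prob <- apply(grid, 1, function(g) prod(pwm$background[g]))
    for (kq in unique(c(0, 1, sort(sample(0:pwm$kmax, 20))))) {
      oracle <- sum(prob[K >= kq])
      expect_equal(pwm$tail_p[kq + 1], oracle, tolerance = 1e-12)
    }
  }
})

test_that("score_pvalue boundary behaviour and monotonicity", {
  pwm <- sharp_pwm(6)
  expect_equal(score_pvalue(pwm, pwm$min_total - 1), 1)
  # single best word per column, uniform background -> (1/4)^w at the max
  expect_equal(score_pvalue(pwm, pwm$max_total), 0.25^6, tolerance = 1e-12)
  scores <- seq(pwm$min_total, pwm$max_total, length.out = 50)
  p <- score_pvalue(pwm, scores)
  expect_true(all(diff(p) <= 1e-14))
  expect_true(all(p > 0 & p <= 1))
  # an information-free PWM gives p = 1 everywhere
  flat <- pwm_from_counts(matrix(5, 4, 4), "flat")
  expect_equal(score_pvalue(flat, 0), 1)
})

test_that("scanning finds a deterministic word at the right offset and p", {
  cts <- matrix(0, 8, 4); cts[cbind(1:8, rep(1:4, 2))] <- 100
  pwm <- pwm_from_counts(cts, "DET", pseudocount = 0.1)
  word <- "ACGTACGT"
  seqs <- setNames(paste0(strrep("A", 10), word, strrep("C", 10)), "s1")
  reg <- data.frame(chrom = "s1", start = 0L, end = 28L, role = "promoter",
                    owner_gene = "L1", name = "r1", stringsAsFactors = FALSE)
  hits <- scan_regions(pwm, seqs, reg, p_cutoff = 1e-4)
  plus <- hits[hits$strand == "+", ]
  expect_identical(plus$offset, 10L)
  expect_equal(plus$p, 0.25^8, tolerance = 1e-12)   # 1.5e-5 < 1e-4
  # information-free PWM yields no hits anywhere
  flat <- pwm_from_counts(matrix(5, 4, 4), "flat")
  expect_identical(nrow(scan_regions(flat, seqs, reg)), 0L)
})

test_that("minus-strand planting is recovered with the correct offset", {
  pwm <- sharp_pwm(9, dom_count = 1000)
  sq <- simulate_sequences(pwm, n_seq = 30, seq_len = 300,
                           planted_sites = 1, seed = 6)
  minus <- sq$truth[sq$truth$strand == "-", ]
  expect_gt(nrow(minus), 0)
  hits <- scan_regions(pwm, sq$sequences, sq$regions)
  hk <- paste(hits$chrom, hits$offset, hits$strand)
  found <- paste(minus$seq_id, minus$offset, minus$strand) %in% hk
  expect_gte(mean(found), 0.9)
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  pwm <- sharp_pwm(7, dom_count = 500, seed = 5)
  sq <- simulate_sequences(pwm, n_seq = 10, seq_len = 200,
                           planted_sites = 1, seed = 13)
  s <- sq$sequences[1]
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s[[1]])))
  reg <- function(id, len) data.frame(
    chrom = id, start = 0L, end = len, role = "promoter",
    owner_gene = "L1", name = id, stringsAsFactors = FALSE)
  h_f <- scan_regions(pwm, s, reg(names(s), nchar(s)))
  h_r <- scan_regions(pwm, setNames(rc, "rc"), reg("rc", nchar(rc)))
  # mirrored: offset' = len - offset - w, strand flipped
  len <- nchar(s[[1]]); w <- pwm$width
  key_f <- sort(paste(h_f$offset, h_f$strand))
  key_r <- sort(paste(len - h_r$offset - w,
                      ifelse(h_r$strand == "+", "-", "+")))
  expect_identical(key_f, key_r)
})

test_that("planted-site recovery is sensitive with calibrated false hits", {
  # near-deterministic width-9 motif planted in 50 of 200 promoters
  pwm <- sharp_pwm(9, dom_count = 5000)
  planted <- simulate_sequences(pwm, n_seq = 50, seq_len = 500,
                                planted_sites = 1, seed = 31)
  bg <- simulate_sequences(pwm, n_seq = 150, seq_len = 500,
                           planted_sites = 0, seed = 32)
  bg$regions$chrom <- sub("seq", "bgseq", bg$regions$chrom)
  bg$regions$name <- sub("seq", "bgseq", bg$regions$name)
  names(bg$sequences) <- sub("seq", "bgseq", names(bg$sequences))
  seqs <- c(planted$sequences, bg$sequences)
  regions <- rbind(planted$regions, bg$regions)
  hits <- scan_regions(pwm, seqs, regions, p_cutoff = 1e-4)
  tk <- paste(planted$truth$seq_id, planted$truth$offset,
              planted$truth$strand)
  hk <- paste(hits$chrom, hits$offset, hits$strand)
  expect_gte(mean(tk %in% hk), 0.95)
  # false hits on pure background stay within the p-value calibration:
  # expected count = 2 strands x windows x effective tail probability
  n_bg_hits <- sum(grepl("^bgseq", hits$chrom) )
  p_eff <- max(pwm$tail_p[pwm$tail_p < 1e-4])
  expected <- 2 * (500 - 9 + 1) * 150 * p_eff
  expect_lte(n_bg_hits, expected + 3 * sqrt(expected) + 1)
  # and per 1e5 background bp the expected false-hit count is at most 1
  expect_lte(expected / (150 * 500) * 1e5, 1)
})

test_that("promoter and enhancer region arithmetic follows the flank rules", {
  tss <- data.frame(chrom = c("chr1", "chr1"), tss = c(5000L, 1000L),
                    lnc_id = c("L1", "L2"), stringsAsFactors = FALSE)
  prom <- define_promoters(tss, 2000)
  expect_identical(prom$start, c(3000L, 0L))  # second clipped at 0
  expect_identical(prom$end, c(7000L, 3000L))
  expect_identical(prom$role, c("promoter", "promoter"))
  expect_error(define_promoters(transform(tss, tss = c(-5L, 10L))),
               "negative TSS")
  # two lncRNAs sharing a TSS get distinct regions
  shared <- data.frame(chrom = "chr2", tss = 100L,
                       lnc_id = c("La", "Lb"), stringsAsFactors = FALSE)
  expect_identical(define_promoters(shared)$owner_gene, c("La", "Lb"))

  enh <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    start = c(6400L, 15000L, 1000L),
                    end = c(6600L, 15200L, 1200L),
                    name = c("e1", "e2", "e3"), stringsAsFactors = FALSE)
  asn <- assign_enhancers(enh, tss[1, , drop = FALSE], 2000, 100000)
  # e1 is 1,400-1,600 bp away (inside promoter window): excluded;
  # e2 is ~10 kb away: assigned; e3 is on another chromosome: excluded
  expect_identical(asn$name, "e2_L1")
  expect_error(assign_enhancers(enh, tss, 2000, 1000), "max_dist")
})

test_that("feedback loops require both ceRNA significance and binding", {
  pairs <- data.frame(
    lnc_id = c("L1", "L2", "L3"), tf_id = c("T1", "T1", "T2"),
    r_shared = 5, hyper_p = c(1e-4, 1e-4, 1e-4), pcc = 0.8, pcc_p = 1e-5,
    bh_q = 0.01, significant = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  hits <- data.frame(
    tf_id = c("T1", "T1", "T2", "T2"),
    region_id = c("r1", "r2", "r3", "r4"),
    chrom = "c", region_start = 0L, region_end = 100L,
    role = c("promoter", "promoter", "promoter", "enhancer"),
    owner_gene = c("L1", "L2", "L3", "L3"),
    offset = 1L, strand = "+", score = 10, p = 1e-5,
    stringsAsFactors = FALSE)
  loops <- find_feedback_loops(pairs, hits)
  expect_identical(nrow(loops), 2L)
  # L2-T1 has binding but no significant pair -> no loop
  expect_false(any(loops$lnc_id == "L2"))
  l3 <- loops[loops$lnc_id == "L3", ]
  expect_identical(l3$region_roles, "enhancer+promoter")
  expect_identical(l3$n_promoter_hits, 1L)
  expect_identical(l3$n_enhancer_hits, 1L)
  # loop set is a subset of the significant pair set
  sig_keys <- paste(pairs$tf_id[pairs$significant],
                    pairs$lnc_id[pairs$significant])
  expect_true(all(paste(loops$tf_id, loops$lnc_id) %in% sig_keys))
})
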