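test_that("gamma fit recovers sampling parameters and agrees with moments", {
  set.seed(31)
  x <- rgamma(10000, shape = 2, scale = 100)
  fit <- fit_fragment_gamma(x)
  expect_equal(fit$shape, 2, tolerance = 0.10)
  expect_equal(fit$scale, 100, tolerance = 0.10)
  expect_true(fit$mean >= min(x) && fit$mean <= max(x))
  # method-of-moments cross-check
  mom_shape <- mean(x)^2 / var(x)
  expect_equal(fit$shape, mom_shape, tolerance = 0.15)
})

test_that("degenerate or invalid fragment lengths are rejected", {
  expect_error(fit_fragment_gamma(rep(100, 1000)), "variance 0")
  expect_error(fit_fragment_gamma(c(rep(100.5, 100), 0, -3)),
               "2 zero/negative")
  expect_error(fit_fragment_gamma(rgamma(20, 2, scale = 10)), "at least 50")
})

test_that("PCR estimator reproduces 1/n_bar exactly", {
  expect_equal(estimate_pcr_p(c("1" = 100)), 1.0)
  expect_equal(estimate_pcr_p(c("1" = 50, "2" = 25, "3" = 25)), 1 / 1.75)
  expect_equal(estimate_pcr_p(c("2" = 10)), 0.5)
  # p = 1 iff no fragment has any duplicate, for any count
  for (n in c(1, 7, 1000))
    expect_equal(estimate_pcr_p(stats::setNames(n, "1")), 1.0)
  expect_error(estimate_pcr_p(data.frame(i = integer(0), n = integer(0))),
               "empty")
})

test_that("duplicate histogram groups by position, strand and template", {
  rec <- data.frame(
    chrom = c("c1", "c1", "c1", "c1", "c1"),
    pos = c(10L, 10L, 10L, 10L, 500L),
    is_reverse = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    is_duplicate = FALSE, is_proper_pair = FALSE,
    template_len = 0L, mapq = 60L, qwidth = 36L)
  h <- build_duplicate_histogram(rec, paired = FALSE)
  # 3 forward at the same 5', 1 reverse there (different 5'), 1 elsewhere
  expect_equal(h$n[h$i == 3], 1L)
  expect_equal(h$n[h$i == 1], 2L)
  # all-unique records: every class has multiplicity 1
  rec2 <- rec; rec2$pos <- c(1L, 2L, 3L, 4L, 5L)
  h2 <- build_duplicate_histogram(rec2, paired = FALSE)
  expect_equal(h2, structure(data.frame(i = 1L, n = 5L),
                             class = class(h2)), ignore_attr = TRUE)
  # paired grouping counts once per pair via the leftmost mate
  recp <- data.frame(
    chrom = "c1", pos = c(10L, 110L, 10L, 110L),
    is_reverse = c(FALSE, TRUE, FALSE, TRUE), is_duplicate = FALSE,
    is_proper_pair = TRUE, template_len = c(136L, -136L, 136L, -136L),
    mapq = 60L, qwidth = 36L)
  hp <- build_duplicate_histogram(recp, paired = TRUE)
  expect_equal(hp$i, 2L)
  expect_equal(hp$n, 1L)
})

test_that("f is the score-weighted covered fraction", {
  pk <- data.frame(chrom = "chrT", start = 1000L, end = 2000L, score = 1)
  expect_equal(estimate_f(pk, 10000), 0.1)
  pk$score <- 0.5
  expect_equal(estimate_f(pk, 10000), 0.05)
  # full coverage clips just below 1
  full <- data.frame(chrom = "chrT", start = 0L, end = 10000L, score = 1)
  expect_equal(estimate_f(full, 10000), 1 - 1e-6)
  expect_error(estimate_f(pk[0, ], 10000), "empty")
})

test_that("s is the fraction of 5' positions in peaks", {
  pk <- data.frame(chrom = "chrT", start = 0L, end = 1000L, score = 1)
  rec <- data.frame(chrom = "chrT",
                    pos = c(rep(500L, 300), rep(5000L, 700)),
                    is_reverse = FALSE, is_duplicate = FALSE,
                    is_proper_pair = FALSE, template_len = 0L,
                    mapq = 60L, qwidth = 36L)
  expect_equal(estimate_s(rec, pk), 0.30)
  # order invariance
  perm <- sample(nrow(rec))
  expect_equal(estimate_s(rec[perm, ], pk), 0.30)
  # all reads in peaks clips just below 1
  rec_in <- rec; rec_in$pos <- rep(10L, nrow(rec))
  expect_equal(estimate_s(rec_in, pk), 1 - 1e-6)
  # uniform reads on a genome 10% covered by peaks: binomial oracle
  set.seed(32)
  n <- 20000
  rec_u <- rec[rep(1, n), ]
  rec_u$pos <- sample.int(100000L, n, replace = TRUE) - 1L
  pk10 <- data.frame(chrom = "chrT", start = 0L, end = 10000L, score = 1)
  expect_lt(abs(estimate_s(rec_u, pk10) - 0.10),
            3 * sqrt(0.1 * 0.9 / n))
  # duplicates and low-MAPQ records are excluded
  rec_dup <- rec
  rec_dup$is_duplicate <- c(rep(TRUE, 300), rep(FALSE, 700))
  expect_warning(s_dup <- estimate_s(rec_dup, pk), "noisy")
  expect_equal(s_dup, 1e-6)  # all in-peak reads were flagged duplicate
})

test_that("cross-correlation recovers a constructed strand shift exactly", {
  set.seed(33)
  n <- 3000
  x <- sort(sample.int(800000L, n))
  rec <- data.frame(
    chrom = "chrT",
    pos = c(x, x + 150L - 36L + 1L),  # reverse 5' = pos + qwidth - 1
    is_reverse = rep(c(FALSE, TRUE), each = n),
    is_duplicate = FALSE, is_proper_pair = FALSE, template_len = 0L,
    mapq = 60L, qwidth = 36L)
  est <- estimate_fraglen_single_end(rec, c(chrT = 1000000L),
                                     smooth_k = 1)
  expect_equal(est$mean, 150)
  expect_equal(est$scale * est$shape, 150)
})

test_that("cross-correlation estimate is self-consistent with the simulator", {
  L <- 1000000L
  ref <- toy_genome(L, seed = 34)
  pks <- toy_peaks(L, n = 300, len = c(20, 60), seed = 35)
  m <- chip_model(10, 20, f = estimate_f(pks, L), s = 0.7, pcr_p = 1)
  p <- experiment_params(numreads = 50000, readlen = 36,
                         numcopies = 800, seed = 36)
  sim <- suppressWarnings(simreads(ref, pks, m, p))
  est <- estimate_fraglen_single_end(sim_to_records(sim), c(chrT = L))
  expect_equal(est$mean, 200, tolerance = 25 / 200)
})

test_that("single-strand or sparse input is rejected by the heuristic", {
  rec <- data.frame(chrom = "chrT", pos = 1:2000, is_reverse = FALSE,
                    is_duplicate = FALSE, is_proper_pair = FALSE,
                    template_len = 0L, mapq = 60L, qwidth = 36L)
  expect_error(estimate_fraglen_single_end(rec, c(chrT = 10000L)),
               "one strand")
  expect_error(estimate_fraglen_single_end(rec[1:100, ],
                                           c(chrT = 10000L)),
               "too few")
})

test_that("learn_all composes the estimators into a validated model", {
  ts <- toy_sim(numreads = 30000, s = 0.5, pcr_p = 0.8, paired = TRUE,
                L = 500000L, n_peaks = 8, peak_len = c(4000, 6000),
                seed = 37)
  rec <- sim_to_records(ts$sim)
  m <- learn_all(rec, ts$peaks, chrom_lengths(ts$ref), paired = TRUE)
  expect_s3_class(m, "chip_model")
  expect_equal(m$f, ts$model$f)  # f depends on the peaks alone
  expect_equal(m$s, 0.5, tolerance = 0.05 / 0.5)
  expect_equal(m$pcr_p, 0.8, tolerance = 0.05 / 0.8)
  expect_equal(m$frag_shape * m$frag_scale, 200, tolerance = 0.10)
  info <- attr(m, "learn_info")
  expect_match(info$fragment_method, "paired")
})

test_that("learn_all warns and falls back without proper pairs", {
  ts <- toy_sim(numreads = 30000, s = 0.6, paired = FALSE, L = 500000L,
                n_peaks = 60, peak_len = c(100, 300), seed = 38)
  rec <- sim_to_records(ts$sim)
  expect_warning(m <- learn_all(rec, ts$peaks, chrom_lengths(ts$ref),
                                paired = TRUE),
                 "single-end")
  expect_match(attr(m, "learn_info")$fragment_method, "cross-correlation")
  # peaks on a chromosome absent from the alignments are dropped loudly
  pk2 <- rbind(ts$peaks, data.frame(chrom = "chrZ", start = 0L,
                                    end = 100L, score = 1))
  expect_warning(learn_all(rec, pk2, c(chrom_lengths(ts$ref), chrZ = 1000L),
                           paired = FALSE),
                 "absent")
})
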