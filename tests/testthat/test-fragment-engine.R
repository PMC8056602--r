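test_that("sheared fragments tile the chromosome without gaps", {
  set.seed(1)
  fr <- shear_copy(c(chrT = 50000L), 2, 100, copy = 3L)
  expect_true(all(fr$end > fr$start))
  expect_true(all(diff(fr$start) > 0))
  # tiling: each fragment ends where the next begins
  expect_equal(fr$end[-nrow(fr)], fr$start[-1])
  expect_equal(fr$end[nrow(fr)], 50000L)
  expect_true(fr$start[1] < 200)  # offset u < mean fragment length
  expect_true(all(fr$copy == 3L))
})

test_that("empirical fragment-length mean matches the gamma model", {
  set.seed(2)
  lens <- vector("list", 2000)
  for (i in 1:2000) {
    fr <- shear_copy(c(chrT = 100000L), 2, 100)
    lens[[i]] <- fr$end - fr$start
  }
  expect_equal(mean(unlist(lens)), 200, tolerance = 0.02)
})

test_that("a fragment mean above the chromosome length yields one fragment", {
  set.seed(3)
  for (i in 1:10) {
    fr <- shear_copy(c(chrT = 1000L), 2, 5000)
    expect_equal(nrow(fr), 1L)
    expect_equal(fr$end, 1000L)
  }
})

test_that("chromosomes shorter than the minimum length are skipped", {
  set.seed(4)
  expect_warning(fr <- shear_copy(c(tiny = 10L, chrT = 5000L), 2, 100,
                                  min_len = 36L), "skipped")
  expect_true(all(fr$chrom == "chrT"))
})

test_that("binding follows peak scores as probabilities", {
  pk <- data.frame(chrom = "chrT", start = 1000L, end = 9000L, score = 0.3)
  fr <- data.frame(chrom = "chrT", start = rep(2000L, 10000),
                   end = rep(2400L, 10000), copy = 1L)
  set.seed(5)
  b <- assign_binding(fr, pk)
  expect_equal(mean(b$bound), 0.3, tolerance = 3 * sqrt(0.3 * 0.7 / 1e4) / 0.3)
  # no overlap -> never bound; full overlap with score 1 -> always bound
  fr_out <- data.frame(chrom = "chrT", start = 20000L, end = 20400L)
  expect_false(assign_binding(fr_out, pk)$bound)
  pk1 <- data.frame(chrom = "chrT", start = 0L, end = 9000L, score = 1)
  expect_true(all(assign_binding(fr[1:100, ], pk1)$bound))
  # 1 bp overlap counts
  fr_edge <- data.frame(chrom = "chrT", start = 8999L, end = 9400L)
  expect_true(assign_binding(fr_edge, pk1)$bound)
  fr_miss <- data.frame(chrom = "chrT", start = 9000L, end = 9400L)
  expect_false(assign_binding(fr_miss, pk1)$bound)
})

test_that("neutral pulldown (alpha = 1) is uniform", {
  set.seed(6)
  pool <- data.frame(chrom = "chrT", start = 1:50000, end = 2:50001,
                     bound = runif(50000) < 0.2)
  sel <- pulldown_sample(pool, alpha = 1, n_target = 20000)
  expect_equal(nrow(sel), 20000L)
  expect_equal(mean(sel$bound), mean(pool$bound), tolerance = 0.05)
})

test_that("pulldown matches the weighted-selection closed form", {
  set.seed(7)
  f_pool <- 0.1; alpha <- 5
  pool <- data.frame(chrom = "chrT", start = 1:400000, end = 2:400001,
                     bound = runif(400000) < f_pool)
  fb <- mean(pool$bound)
  sel <- pulldown_sample(pool, alpha = alpha, n_target = 100000)
  expect_equal(nrow(sel), 100000L)
  expected <- alpha * fb / (alpha * fb + (1 - fb))
  expect_equal(mean(sel$bound), expected, tolerance = 0.02)
  # selection is a subset of the pool
  expect_true(all(sel$start %in% pool$start))
})

test_that("pulldown returns everything with a warning when the pool is short", {
  set.seed(8)
  pool <- data.frame(chrom = "chrT", start = 1:100, end = 2:101,
                     bound = rep(TRUE, 100))
  expect_warning(sel <- pulldown_sample(pool, alpha = 2, n_target = 500),
                 "numcopies")
  expect_equal(nrow(sel), 100L)
  expect_error(pulldown_sample(pool[0, ], 2, 10), "empty")
})

test_that("PCR multiplicities are geometric with mean 1/p", {
  fr <- data.frame(chrom = "chrT", start = 1:100000, end = 2:100001)
  # p = 1: no duplicates ever
  out1 <- pcr_amplify(fr, 1)
  expect_equal(nrow(out1), nrow(fr))
  expect_true(all(out1$dup_index == 1L))
  set.seed(9)
  out <- pcr_amplify(fr, 0.5)
  expect_equal(nrow(out) / nrow(fr), 2, tolerance = 0.02)
  # round trip through the histogram estimator
  mult <- table(table(out$start))
  p_hat <- estimate_pcr_p(stats::setNames(as.numeric(mult), names(mult)))
  expect_equal(p_hat, 0.5, tolerance = 0.02 / 0.5)
})

test_that("identical seeds replay the simulation bit-identically", {
  a <- toy_sim(numreads = 2000, numcopies = 30, seed = 77)$sim
  b <- toy_sim(numreads = 2000, numcopies = 30, seed = 77)$sim
  expect_identical(a$reads, b$reads)
  c <- toy_sim(numreads = 2000, numcopies = 30, seed = 78)$sim
  expect_false(identical(a$reads$seq1, c$reads$seq1))
})
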