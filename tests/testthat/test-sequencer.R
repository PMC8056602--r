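test_that("error-free reads reproduce the reference exactly", {
  ref <- toy_genome(20000L, seed = 21)
  set.seed(22)
  n <- 500
  start <- sample.int(19000L, n) - 1L
  fr <- data.frame(chrom = "chrT", start = start, end = start + 300L)
  reads <- sequence_fragments(fr, ref, readlen = 50, paired = FALSE)
  expect_true(all(nchar(reads$seq1) == 50))
  fwd <- reads$strand == "+"
  expect_identical(reads$seq1[fwd],
                   substring(ref[["chrT"]], reads$start[fwd] + 1,
                             reads$start[fwd] + 50))
  # reverse-strand reads are the reverse complement of the fragment 3' end
  rc <- chipsim:::revcomp(substring(ref[["chrT"]], reads$end[!fwd] - 49,
                                    reads$end[!fwd]))
  expect_identical(reads$seq1[!fwd], rc)
  # both strands occur
  expect_true(any(fwd) && any(!fwd))
})

test_that("paired mates have the expected geometry", {
  ref <- toy_genome(20000L, seed = 23)
  fr <- data.frame(chrom = "chrT", start = c(100L, 5000L),
                   end = c(400L, 5300L))
  set.seed(24)
  reads <- sequence_fragments(fr, ref, readlen = 40, paired = TRUE)
  expect_identical(reads$seq1,
                   substring(ref[["chrT"]], fr$start + 1, fr$start + 40))
  expect_identical(chipsim:::revcomp(reads$seq2),
                   substring(ref[["chrT"]], fr$end - 39, fr$end))
})

test_that("substitution rate converges to the model rate", {
  ref <- toy_genome(50000L, seed = 25)
  set.seed(26)
  n <- 2000; rl <- 50  # 100k sequenced bases
  start <- sample.int(49000L, n, replace = TRUE) - 1L
  fr <- data.frame(chrom = "chrT", start = start, end = start + 200L)
  reads <- sequence_fragments(fr, ref, readlen = rl, paired = FALSE,
                              sub_rate = 0.02)
  truth <- ifelse(reads$strand == "+",
                  substring(ref[["chrT"]], reads$start + 1,
                            reads$start + rl),
                  chipsim:::revcomp(substring(ref[["chrT"]],
                                              reads$end - rl + 1,
                                              reads$end)))
  mism <- sum(mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                     reads$seq1, truth))
  expect_equal(sum(reads$n_sub), mism)  # logged edits match observation
  total <- n * rl
  expect_lt(abs(mism / total - 0.02), 3 * sqrt(0.02 * 0.98 / total))
})

test_that("indels shift the template and pad with N when exhausted", {
  ref <- c(chrT = strrep("ACGT", 100))
  # deletion-only, deterministic template: read longer than what remains
  fr <- data.frame(chrom = "chrT", start = 0L, end = 30L)
  set.seed(27)
  reads <- sequence_fragments(fr, ref, readlen = 30, paired = FALSE,
                              del_rate = 0.3)
  expect_equal(nchar(reads$seq1), 30L)
  # deletions exhaust the 30 bp template before 30 bases are emitted, so
  # the read must end in N padding (the reference itself contains no N)
  n_pad <- nchar(sub("^.*[^N]", "", reads$seq1))
  expect_gt(reads$n_del, 0)
  expect_gt(n_pad, 0)
  expect_lte(n_pad, reads$n_del)
  # insertion-only reads keep length but contain inserted bases
  set.seed(28)
  r2 <- sequence_fragments(data.frame(chrom = "chrT", start = 0L,
                                      end = 400L),
                           ref, readlen = 50, ins_rate = 0.1)
  expect_equal(nchar(r2$seq1), 50L)
  expect_gt(r2$n_ins, 0)
})

test_that("template N bases pass through the error model untouched", {
  ref <- c(chrT = strrep("N", 200))
  fr <- data.frame(chrom = "chrT", start = 0L, end = 200L)
  set.seed(29)
  reads <- sequence_fragments(fr, ref, readlen = 50, sub_rate = 0.5)
  expect_identical(reads$seq1, strrep("N", 50))
  expect_equal(reads$n_sub, 0L)
})

test_that("fragments shorter than the read length cannot be sequenced", {
  ref <- toy_genome(1000L, seed = 30)
  fr <- data.frame(chrom = "chrT", start = 0L, end = 20L)
  expect_error(sequence_fragments(fr, ref, readlen = 36), "shorter")
})
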