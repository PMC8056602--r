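# Deterministic toy-data generation: random references and structured peak
# sets, so every example and test runs with no download.

#' Generate a random toy reference genome
#'
#' I.i.d. bases at a given GC fraction. Deterministic under `seed`
#' (generation uses a private RNG stream and does not disturb the caller's
#' RNG state). Real repeat structure is deliberately absent: the simulator
#' never maps reads, so mappability does not matter at toy scale.
#'
#' @param chrom_lens Named integer vector of chromosome lengths, e.g.
#'   `c(chrT = 1e6)`.
#' @param gc_fraction Expected fraction of G+C bases, in [0, 1].
#' @param seed Integer seed.
#' @param path Optional FASTA output path.
#' @return Named character vector of sequences (invisibly if written).
#' @export
make_reference <- function(chrom_lens, gc_fraction = 0.5, seed = 1,
                           path = NULL) {
  stopifnot(gc_fraction >= 0, gc_fraction <= 1, all(chrom_lens >= 1))
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- withr::with_seed(as.integer(seed), {
    vapply(chrom_lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- names(chrom_lens)
  if (!is.null(path)) {
    write_fasta(seqs, path)
    return(invisible(seqs))
  }
  seqs
}

#' Generate a structured toy peak set
#'
#' Places non-overlapping, sorted peaks with at least `min_gap` bp between
#' them, uniformly at random along each chromosome. Two presets mirror the
#' two broad classes of ChIP-seq targets: `"tf"` (transcription-factor-like,
#' narrow ~200 bp sites) and `"hm"` (histone-modification-like, broad ~2 kb
#' domains). Deterministic under `seed`.
#'
#' @param chrom_lens Named chromosome lengths.
#' @param n_peaks Total number of peaks (split across chromosomes
#'   proportionally to length).
#' @param len_range Two-element numeric: min and max peak length (bp),
#'   drawn uniformly. Ignored when `preset` is given.
#' @param scores `"constant"` (all 1), `"uniform"` (Uniform(0.5, 1)), or a
#'   numeric vector/scalar of probabilities in [0, 1].
#' @param preset `"tf"` or `"hm"`, or NULL to use `len_range`.
#' @param min_gap Minimum gap between adjacent peaks (bp, >= 1).
#' @param seed Integer seed.
#' @param path Optional BED output path (written via [write_peaks()]).
#' @return Peak data frame (`chrom`, `start`, `end`, `score`).
#' @export
make_peaks <- function(chrom_lens, n_peaks = 20, len_range = c(500, 1500),
                       scores = "constant", preset = NULL, min_gap = 1,
                       seed = 1, path = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("tf", "hm"))
    len_range <- if (preset == "tf") c(150, 250) else c(1000, 3000)
  }
  stopifnot(length(len_range) == 2, len_range[1] >= 1,
            len_range[2] >= len_range[1], n_peaks >= 1, min_gap >= 1)
  total_len <- sum(as.numeric(chrom_lens))
  n_per <- pmax(1L, round(n_peaks * chrom_lens / total_len))
  # adjust rounding so the total matches
  while (sum(n_per) > n_peaks) n_per[which.max(n_per)] <-
      n_per[which.max(n_per)] - 1L
  while (sum(n_per) < n_peaks) n_per[which.max(chrom_lens)] <-
      n_per[which.max(chrom_lens)] + 1L
  out <- withr::with_seed(as.integer(seed), {
    res <- list()
    for (ci in seq_along(chrom_lens)) {
      n <- n_per[ci]
      if (n == 0) next
      L <- chrom_lens[[ci]]
      len <- floor(stats::runif(n, len_range[1], len_range[2] + 1))
      avail <- L - sum(len) - (n + 1) * min_gap
      if (avail < 0)
        stop("cannot pack ", n, " peaks totalling ", sum(len),
             " bp into chromosome of length ", L, call. = FALSE)
      u <- sort(stats::runif(n, 0, avail))
      starts <- floor(u) + c(0, cumsum(len[-n])) +
        min_gap * seq_len(n)
      sc <- if (is.numeric(scores)) rep(scores, length.out = n)
            else if (scores == "constant") rep(1, n)
            else stats::runif(n, 0.5, 1)
      res[[ci]] <- data.frame(chrom = names(chrom_lens)[ci],
                              start = as.integer(starts),
                              end = as.integer(starts + len),
                              score = sc, stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  })
  rownames(out) <- NULL
  if (!is.null(path)) {
    write_peaks(out, path)
    return(invisible(out))
  }
  out
}

#' Write a complete toy fixture set to a directory
#'
#' Emits `ref.fa`, `peaks.bed` and a default `model.json` for a TF-like or
#' HM-like experiment, ready for [simreads()] or the command-line
#' interface.
#'
#' @param dir Output directory (created if needed).
#' @param preset `"tf"` or `"hm"`.
#' @param chrom_lens Named chromosome lengths (default one 1 Mb
#'   chromosome).
#' @param n_peaks Number of peaks.
#' @param seed Integer seed.
#' @return Named list of the file paths written.
#' @export
make_fixture <- function(dir, preset = c("tf", "hm"),
                         chrom_lens = c(chrT = 1000000L), n_peaks = 50,
                         seed = 1) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_path <- file.path(dir, "ref.fa")
  bed_path <- file.path(dir, "peaks.bed")
  model_path <- file.path(dir, "model.json")
  make_reference(chrom_lens, seed = seed, path = ref_path)
  peaks <- make_peaks(chrom_lens, n_peaks = n_peaks, preset = preset,
                      seed = seed + 1, path = bed_path)
  f <- estimate_f(peaks, sum(as.numeric(chrom_lens)))
  model <- chip_model(frag_shape = 4, frag_scale = 50, f = f,
                      s = if (preset == "tf") 0.3 else 0.5, pcr_p = 0.9)
  write_model(model, model_path)
  list(ref = ref_path, peaks = bed_path, model = model_path)
}
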