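# Parameter inference from an existing aligned ChIP-seq experiment.
#
# Alignment records are plain data frames ("AlnRecord") with columns:
#   chrom, pos (0-based leftmost), is_reverse, is_duplicate,
#   is_proper_pair, template_len (signed, SAM convention; 0 when absent),
#   mapq, and optionally qwidth (read length).
# read_alignments() builds this table from BAM/SAM via Rsamtools; every
# estimator also accepts a table constructed directly (e.g. from
# sim_to_records()).

.EPS_FRAC <- 1e-6

# Shared record filter: drop low-MAPQ and (optionally) duplicate records.
filter_records <- function(records, min_mapq = 10, dedup = TRUE) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(records$mapq)) keep <- keep & (records$mapq >= min_mapq)
  if (dedup && !is.null(records$is_duplicate))
    keep <- keep & !records$is_duplicate
  records[keep, , drop = FALSE]
}

# 5' position of each record: leftmost base for forward reads, rightmost
# for reverse reads (requires qwidth; falls back to pos without it).
record_five_prime <- function(records) {
  p <- records$pos
  if (!is.null(records$qwidth) && !is.null(records$is_reverse)) {
    rev <- records$is_reverse
    p[rev] <- p[rev] + records$qwidth[rev] - 1L
  }
  p
}

#' Fit a gamma distribution to fragment lengths
#'
#' Maximum-likelihood gamma fit to fragment lengths observed as absolute
#' template lengths of properly paired reads (counted once per pair).
#' Parameterized as (shape, scale); the fitted mean is `shape * scale`.
#'
#' @param lengths Numeric vector of fragment lengths (bp, > 0).
#' @param min_obs Minimum number of observations required (default 50).
#' @return List with `shape`, `scale`, `mean`, `n`.
#' @export
fit_fragment_gamma <- function(lengths, min_obs = 50) {
  lengths <- lengths[!is.na(lengths)]
  n_bad <- sum(lengths <= 0)
  if (n_bad > 0)
    stop(n_bad, " zero/negative fragment length(s) rejected; ",
         "fragment lengths must be positive", call. = FALSE)
  if (length(lengths) < min_obs)
    stop("need at least ", min_obs, " fragment lengths, got ",
         length(lengths), call. = FALSE)
  if (stats::var(lengths) == 0)
    stop("degenerate input: all fragment lengths identical (variance 0)",
         call. = FALSE)
  # method-of-moments start for the MLE
  m <- mean(lengths); v <- stats::var(lengths)
  start <- list(shape = m^2 / v, rate = m / v)
  fit <- fitdistrplus::fitdist(as.numeric(lengths), "gamma",
                               method = "mle", start = start,
                               lower = c(1e-8, 1e-12))
  shape <- unname(fit$estimate["shape"])
  scale <- 1 / unname(fit$estimate["rate"])
  list(shape = shape, scale = scale, mean = shape * scale,
       n = length(lengths))
}

#' Estimate mean fragment length from single-end data
#'
#' Strand cross-correlation heuristic: counts forward-read and reverse-read
#' 5' ends per base, and finds the shift `d` maximizing the cross-correlation
#' between the two profiles, searched over
#' `d` in `[readlen + 1, max_shift]` — shifts at or below the read length
#' are excluded as the "phantom peak" of read-length self-correlation. The
#' cross-correlation is computed by FFT and smoothed with a short moving
#' average before taking the argmax.
#'
#' The gamma fragment-length model is then set with mean `d` and a fixed
#' default shape (`scale = d / shape`), flagged as an approximation: the
#' shape is not identifiable from the correlation peak alone.
#'
#' @param records Alignment-record data frame (single-end).
#' @param chrom_lens Named chromosome lengths.
#' @param readlen Read length in bp; taken from `records$qwidth` if absent.
#' @param max_shift Largest shift searched (default 1500 bp).
#' @param shape Gamma shape assumed for the returned model (default 5).
#' @param min_mapq MAPQ filter applied before counting.
#' @param smooth_k Moving-average window (odd, bp) applied to the
#'   correlation profile.
#' @return List with `mean` (the estimated shift), `shape`, `scale`,
#'   `method = "cross-correlation"`, and the searched profile.
#' @export
estimate_fraglen_single_end <- function(records, chrom_lens, readlen = NULL,
                                        max_shift = 1500, shape = 5,
                                        min_mapq = 10, smooth_k = 15) {
  records <- filter_records(records, min_mapq, dedup = TRUE)
  if (is.null(readlen)) {
    if (is.null(records$qwidth))
      stop("readlen not given and records lack qwidth", call. = FALSE)
    readlen <- as.integer(stats::median(records$qwidth))
  }
  if (nrow(records) < 1000)
    stop("too few reads (", nrow(records),
         ") for cross-correlation; need >= 1000", call. = FALSE)
  if (all(records$is_reverse) || all(!records$is_reverse))
    stop("all reads on one strand; cannot cross-correlate", call. = FALSE)
  p5 <- record_five_prime(records)
  cc <- numeric(max_shift + 1)
  for (ch in intersect(unique(records$chrom), names(chrom_lens))) {
    sel <- records$chrom == ch
    L <- chrom_lens[[ch]]
    fwd <- tabulate(p5[sel & !records$is_reverse] + 1L, L)
    rev <- tabulate(pmin(p5[sel & records$is_reverse], L - 1L) + 1L, L)
    n2 <- stats::nextn(L + max_shift + 1)
    F <- stats::fft(c(fwd, numeric(n2 - L)))
    R <- stats::fft(c(rev, numeric(n2 - L)))
    # cc[d + 1] = sum_i fwd[i] * rev[i + d]
    x <- Re(stats::fft(R * Conj(F), inverse = TRUE)) / n2
    cc <- cc + x[seq_len(max_shift + 1)]
  }
  sm <- stats::filter(cc, rep(1 / smooth_k, smooth_k), sides = 2)
  search <- seq.int(readlen + 2L, max_shift + 1L)  # shifts > readlen
  d <- search[which.max(sm[search])] - 1L
  if (d <= readlen)
    stop("no correlation peak above the phantom-peak shift; ",
         "use paired-end input to estimate fragment lengths", call. = FALSE)
  list(mean = d, shape = shape, scale = d / shape,
       method = "cross-correlation",
       profile = data.frame(shift = seq.int(0L, max_shift),
                            crosscorr = cc))
}

#' Duplicate-multiplicity histogram
#'
#' Groups records into original-fragment equivalence classes and tabulates
#' how many classes were observed `i` times (`i` includes the original
#' fragment, so a fragment with no PCR duplicates contributes to `i = 1`).
#' Grouping keys follow duplicate-marker convention: `(chrom, 5' position,
#' strand)` for single-end records, `(chrom, leftmost position, template
#' length)` for paired records (counted once per pair, on the leftmost
#' mate, `template_len > 0`).
#'
#' @param records Alignment-record data frame.
#' @param paired Treat records as paired-end.
#' @param min_mapq MAPQ filter.
#' @return Data frame of class `duplicate_histogram` with columns `i`
#'   (multiplicity) and `n` (number of fragment classes observed `i`
#'   times).
#' @export
build_duplicate_histogram <- function(records, paired = FALSE,
                                      min_mapq = 10) {
  records <- filter_records(records, min_mapq, dedup = FALSE)
  if (nrow(records) == 0) {
    h <- data.frame(i = integer(0), n = integer(0))
    class(h) <- c("duplicate_histogram", "data.frame")
    return(h)
  }
  if (paired) {
    recs <- records[records$template_len > 0, , drop = FALSE]
    key <- paste(recs$chrom, recs$pos, recs$template_len, sep = ":")
  } else {
    key <- paste(records$chrom, record_five_prime(records),
                 records$is_reverse, sep = ":")
  }
  sizes <- table(table(key))
  h <- data.frame(i = as.integer(names(sizes)), n = as.integer(sizes))
  class(h) <- c("duplicate_histogram", "data.frame")
  h
}

#' Estimate the PCR parameter p
#'
#' The geometric PCR model's parameter `p` (probability a fragment has no
#' PCR duplicates) is estimated as `1 / n_bar`, where
#' `n_bar = sum(i * n_i) / sum(n_i)` is the mean multiplicity over the
#' duplicate histogram (`n_i` = number of fragments observed `i` times,
#' including the original). `p = 1` exactly when no fragment has any
#' duplicate.
#'
#' @param hist A histogram from [build_duplicate_histogram()], or any data
#'   frame/list with elements `i` and `n`, or a named vector
#'   (`c("1" = 50, "2" = 25)`).
#' @return `p` in (0, 1].
#' @examples
#' estimate_pcr_p(c("1" = 100))             # 1
#' estimate_pcr_p(c("1" = 50, "2" = 25, "3" = 25))  # 1/1.75
#' @export
estimate_pcr_p <- function(hist) {
  if (!is.null(names(hist)) && is.numeric(hist))
    hist <- data.frame(i = as.integer(names(hist)), n = as.numeric(hist))
  i <- as.numeric(hist$i); n <- as.numeric(hist$n)
  if (length(i) == 0 || sum(n) <= 0)
    stop("empty duplicate histogram", call. = FALSE)
  if (any(i < 1) || any(n < 0))
    stop("invalid duplicate histogram (need i >= 1, n >= 0)", call. = FALSE)
  n_bar <- sum(i * n) / sum(n)
  1 / n_bar
}

#' Estimate f, the bound fraction of the genome
#'
#' Score-weighted fraction of the genome covered by peaks:
#' `f = sum(peak length * score) / genome length` over merged peaks, clipped
#' away from {0, 1} by 1e-6 so the enrichment ratio stays finite.
#'
#' @param peaks Peak data frame.
#' @param genome_length Total genome length in bp.
#' @return `f` in (0, 1).
#' @export
estimate_f <- function(peaks, genome_length) {
  stopifnot(genome_length > 0)
  if (is.null(peaks) || nrow(peaks) == 0)
    stop("empty peak set: f = 0 leaves the enrichment ratio undefined",
         call. = FALSE)
  peaks <- merge_peaks(peaks)
  f <- sum(as.numeric(peaks$end - peaks$start) * peaks$score) / genome_length
  min(max(f, .EPS_FRAC), 1 - .EPS_FRAC)
}

#' Estimate s, the fraction of reads in peaks (FRIP/SPOT)
#'
#' Fraction of non-duplicate records whose 5' position lies inside a peak,
#' clipped away from {0, 1} by 1e-6. This is the FRIP (fraction of reads in
#' peaks) convention: read membership is decided by the 5' end alone, which
#' is order-invariant and cheap. No correction for reads expected in peaks
#' by chance is applied.
#'
#' @param records Alignment-record data frame.
#' @param peaks Peak data frame.
#' @param min_mapq MAPQ filter.
#' @return `s` in (0, 1).
#' @export
estimate_s <- function(records, peaks, min_mapq = 10) {
  if (is.null(peaks) || nrow(peaks) == 0)
    stop("empty peak set", call. = FALSE)
  records <- filter_records(records, min_mapq, dedup = TRUE)
  if (nrow(records) == 0) stop("no usable records", call. = FALSE)
  if (nrow(records) < 1000)
    warning("only ", nrow(records),
            " non-duplicate records; s estimate will be noisy")
  index <- peak_index(peaks)
  s <- mean(point_in_peak(records$chrom, record_five_prime(records), index))
  min(max(s, .EPS_FRAC), 1 - .EPS_FRAC)
}

#' Learn all model parameters from an experiment
#'
#' Composes the individual estimators into a validated [chip_model()]:
#' gamma fragment-length parameters from paired-end template lengths (or
#' the single-end cross-correlation heuristic), `f` from the peaks, `s`
#' from the fraction of reads in peaks, and `p` from the duplicate
#' histogram. Sequencing error rates are not estimable from these inputs
#' and default to 0 unless supplied.
#'
#' @param records Alignment-record data frame (see [read_alignments()],
#'   [sim_to_records()]).
#' @param peaks Peak data frame or BED path.
#' @param chrom_lens Named chromosome lengths (or a FASTA/.fai path).
#' @param paired Records are paired-end; with `paired = TRUE` but no proper
#'   pairs present the single-end heuristic is used with a warning.
#' @param min_mapq MAPQ filter applied by every estimator (default 10).
#' @param sub_rate,ins_rate,del_rate Sequencing error rates to record in
#'   the model (not estimated).
#' @param single_end_shape Gamma shape assumed by the single-end heuristic.
#' @return A validated `chip_model`; attribute `learn_info` carries each
#'   estimate's input counts and method.
#' @export
learn_all <- function(records, peaks, chrom_lens, paired = TRUE,
                      min_mapq = 10, sub_rate = 0, ins_rate = 0,
                      del_rate = 0, single_end_shape = 5) {
  if (is.character(peaks)) peaks <- read_peaks(peaks)
  if (is.character(chrom_lens) || !is.null(dim(chrom_lens)))
    chrom_lens <- chrom_lengths(chrom_lens)
  peaks <- merge_peaks(peaks)
  off <- !(peaks$chrom %in% unique(records$chrom))
  if (any(off)) {
    warning(sum(off), " peak(s) on chromosome(s) absent from the ",
            "alignments were ignored")
    peaks <- peaks[!off, , drop = FALSE]
  }
  frag_method <- "paired-end template lengths"
  pairs_ok <- paired && !is.null(records$is_proper_pair) &&
    any(records$is_proper_pair & records$template_len > 0)
  if (paired && !pairs_ok) {
    warning("paired = TRUE but no proper pairs present; ",
            "falling back to the single-end heuristic")
  }
  if (pairs_ok) {
    pr <- filter_records(records, min_mapq, dedup = TRUE)
    lens <- abs(pr$template_len[pr$is_proper_pair & pr$template_len > 0])
    fit <- fit_fragment_gamma(lens)
    frag_shape <- fit$shape; frag_scale <- fit$scale
    frag_n <- fit$n
  } else {
    fit <- estimate_fraglen_single_end(records, chrom_lens,
                                       shape = single_end_shape,
                                       min_mapq = min_mapq)
    frag_shape <- fit$shape; frag_scale <- fit$scale
    frag_n <- sum(!records$is_duplicate)
    frag_method <- paste0("single-end cross-correlation (approximate; ",
                          "shape fixed at ", single_end_shape, ")")
  }
  f <- estimate_f(peaks, sum(as.numeric(chrom_lens)))
  s <- estimate_s(records, peaks, min_mapq = min_mapq)
  hist <- build_duplicate_histogram(records, paired = pairs_ok,
                                    min_mapq = min_mapq)
  p <- estimate_pcr_p(hist)
  model <- chip_model(frag_shape, frag_scale, f = f, s = s, pcr_p = p,
                      sub_rate = sub_rate, ins_rate = ins_rate,
                      del_rate = del_rate)
  attr(model, "learn_info") <- list(
    fragment_method = frag_method, fragment_n = frag_n,
    n_records = nrow(records), n_peaks = nrow(peaks),
    duplicate_histogram = hist)
  model
}

#' Read alignment records from BAM or SAM
#'
#' Thin wrapper over Rsamtools producing the alignment-record table used by
#' the learning component. SAM input is converted with
#' `Rsamtools::asBam()` first. Unmapped and secondary/supplementary records
#' are excluded.
#'
#' @param path Path to a coordinate-sorted BAM (or SAM) file.
#' @return Alignment-record data frame (`chrom`, `pos` 0-based,
#'   `is_reverse`, `is_duplicate`, `is_proper_pair`, `template_len`,
#'   `mapq`, `qwidth`).
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_alignments() requires the Rsamtools package", call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "flag", "isize", "mapq", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  isize <- b$isize
  isize[is.na(isize)] <- 0L
  data.frame(chrom = as.character(b$rname), pos = b$pos - 1L,
             is_reverse = as.character(b$strand) == "-",
             is_duplicate = bitwAnd(b$flag, 1024L) > 0L,
             is_proper_pair = bitwAnd(b$flag, 2L) > 0L,
             template_len = isize, mapq = b$mapq, qwidth = b$qwidth,
             stringsAsFactors = FALSE)
}
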