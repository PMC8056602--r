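# Evaluation utilities: binned read-count tracks, track correlation,
# peak-set precision/recall, enrichment ratio.

#' Count reads in fixed-width genomic bins
#'
#' Divides every chromosome into consecutive non-overlapping bins of
#' `bin_size` bp (the last, partial bin included) and counts the reads whose
#' 5' position falls in each bin. Bins overlapping at least one peak by
#' >= 1 bp are labelled `"peak"`, the rest `"background"`.
#'
#' @param positions Data frame with columns `chrom` and `pos` (0-based read
#'   5' positions), or a `chip_sim` object (read-1 5' positions are used).
#' @param chrom_lens Named chromosome lengths.
#' @param bin_size Bin width in bp (>= 1).
#' @param peaks Peak data frame used for labelling (optional; without it
#'   all bins are background).
#' @return A `bin_track` data frame: `chrom`, `bin_start`, `bin_end`,
#'   `count`, `label`; attribute `bin_size`.
#' @export
bin_counts <- function(positions, chrom_lens, bin_size, peaks = NULL) {
  stopifnot(bin_size >= 1)
  positions <- as_positions(positions)
  index <- if (!is.null(peaks)) peak_index(peaks) else NULL
  out <- lapply(names(chrom_lens), function(ch) {
    L <- chrom_lens[[ch]]
    nb <- ceiling(L / bin_size)
    p <- positions$pos[positions$chrom == ch]
    cnt <- tabulate(p %/% bin_size + 1L, nb)
    bs <- (seq_len(nb) - 1L) * bin_size
    be <- pmin(bs + bin_size, L)
    lab <- rep("background", nb)
    if (!is.null(index)) {
      sc <- peak_range_scores(rep(ch, nb), bs, be, index)
      lab[!is.na(sc)] <- "peak"
    }
    data.frame(chrom = ch, bin_start = as.integer(bs),
               bin_end = as.integer(be), count = cnt, label = lab,
               stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  attr(track, "bin_size") <- as.integer(bin_size)
  class(track) <- c("bin_track", "data.frame")
  track
}

as_positions <- function(x) {
  if (inherits(x, "chip_sim")) {
    r <- x$reads
    p5 <- ifelse(r$strand == "+", r$start, r$end - 1L)
    return(data.frame(chrom = r$chrom, pos = as.integer(p5),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("chrom", "pos") %in% names(x)))
  x
}

#' Pearson correlation between two binned tracks
#'
#' Correlates the per-bin read counts of two tracks with identical binning,
#' optionally restricted to peak-overlapping or background bins (as in
#' replicate-concordance analyses where the signal of interest is the
#' read-count profile over peaks).
#'
#' @param a,b `bin_track` objects from [bin_counts()] on the same
#'   chromosomes and bin size.
#' @param subset `"all"`, `"peak"`, or `"background"` (labels from `a`).
#' @return List with `r` (Pearson correlation) and `n_bins`.
#' @export
track_correlation <- function(a, b, subset = c("all", "peak",
                                               "background")) {
  subset <- match.arg(subset)
  if (!identical(a$chrom, b$chrom) ||
      !identical(a$bin_start, b$bin_start))
    stop("tracks have mismatched binning", call. = FALSE)
  sel <- if (subset == "all") rep(TRUE, nrow(a)) else a$label == subset
  x <- a$count[sel]; y <- b$count[sel]
  if (length(x) < 3)
    stop("fewer than 3 bins in subset '", subset, "'", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant track: correlation undefined", call. = FALSE)
  list(r = stats::cor(x, y), n_bins = length(x))
}

#' Precision, recall and F1 of a called peak set against truth
#'
#' A truth peak counts as recovered if at least one called peak overlaps it
#' by >= 1 bp; a called peak counts as correct if it overlaps at least one
#' truth peak. Recall = recovered / |truth|, precision = correct /
#' |called|, F1 = their harmonic mean (0 when both are 0). Both sets are
#' merged within themselves before scoring.
#'
#' @param truth,called Peak data frames.
#' @return List with `precision`, `recall`, `f1`, `n_truth`, `n_called`.
#' @export
score_peak_recovery <- function(truth, called) {
  if (is.null(truth) || nrow(truth) == 0)
    stop("empty truth peak set", call. = FALSE)
  truth <- merge_peaks(truth)
  called <- if (is.null(called)) truth[0, ] else merge_peaks(called)
  if (nrow(called) == 0) {
    return(list(precision = 0, recall = 0, f1 = 0,
                n_truth = nrow(truth), n_called = 0L))
  }
  cidx <- peak_index(called)
  tidx <- peak_index(truth)
  recovered <- !is.na(peak_range_scores(truth$chrom, truth$start,
                                        truth$end, cidx))
  correct <- !is.na(peak_range_scores(called$chrom, called$start,
                                      called$end, tidx))
  recall <- mean(recovered)
  precision <- mean(correct)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_truth = nrow(truth), n_called = nrow(called))
}

#' Read-start enrichment ratio in peaks versus background
#'
#' Per-base density of read 5' positions inside peaks divided by the
#' density in background. Background excludes a flank of `flank` bp around
#' every peak, because fragments overlapping a peak edge spill read starts
#' into the immediately adjacent background; with the flank excluded the
#' expected ratio for score-1 peaks (at zero sequencing error and no PCR)
#' equals the pulldown enrichment ratio `alpha`.
#'
#' @param positions Read-position data frame (`chrom`, `pos`) or a
#'   `chip_sim` object.
#' @param peaks Peak data frame.
#' @param chrom_lens Named chromosome lengths.
#' @param flank Exclusion margin around peaks in bp (use a few fragment
#'   lengths).
#' @return List with `ratio`, peak/background densities and counts.
#' @export
enrichment_ratio <- function(positions, peaks, chrom_lens, flank = 1000) {
  positions <- as_positions(positions)
  peaks <- merge_peaks(peaks)
  expanded <- peaks
  expanded$start <- pmax(0L, peaks$start - as.integer(flank))
  expanded$end <- peaks$end + as.integer(flank)
  for (ch in unique(expanded$chrom))
    expanded$end[expanded$chrom == ch] <-
      pmin(expanded$end[expanded$chrom == ch], chrom_lens[[ch]])
  expanded <- merge_peaks(expanded)
  pidx <- peak_index(peaks)
  eidx <- peak_index(expanded)
  in_peak <- point_in_peak(positions$chrom, positions$pos, pidx)
  in_exp <- point_in_peak(positions$chrom, positions$pos, eidx)
  peak_len <- peak_total_length(peaks)
  bg_len <- sum(as.numeric(chrom_lens)) - peak_total_length(expanded)
  n_peak <- sum(in_peak)
  n_bg <- sum(!in_exp)
  stopifnot(peak_len > 0, bg_len > 0)
  d_peak <- n_peak / peak_len
  d_bg <- n_bg / bg_len
  list(ratio = d_peak / d_bg, peak_density = d_peak, bg_density = d_bg,
       n_peak = n_peak, n_background = n_bg)
}

#' Export a binned track as bedGraph
#'
#' @param track A `bin_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%d", track$chrom, track$bin_start,
                     track$bin_end, track$count), path)
  invisible(path)
}
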