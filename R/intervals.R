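# Interval utilities over merged, sorted, non-overlapping peak sets.
#
# All coordinates package-wide are 0-based half-open [start, end), the BED
# convention. Peaks are plain data frames with columns chrom, start, end,
# score. After merge_peaks() the set is sorted and non-overlapping per
# chromosome, which lets overlap queries run as two findInterval() calls —
# this sits in the per-copy simulation hot loop, so it stays O(log n) per
# query with no object construction. Correctness is cross-checked against
# IRanges in the test suite.

#' Merge overlapping peaks
#'
#' Sorts peaks and merges overlapping intervals per chromosome, assigning the
#' merged interval the maximum score of its members. Book-ended intervals
#' (end of one equal to start of the next) are not merged.
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end`, `score`
#'   (0-based half-open).
#' @return A sorted, non-overlapping peak data frame.
#' @export
merge_peaks <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (is.null(peaks$score)) peaks$score <- 1
  if (nrow(peaks) == 0) return(peaks)
  dt <- data.table::as.data.table(peaks)
  data.table::setorder(dt, chrom, start, end)
  merged <- dt[, {
    n <- .N
    grp <- cumsum(c(1L, as.integer(start[-1] >= cummax(end[-n]))))
    .(start = tapply(start, grp, min),
      end = tapply(end, grp, max),
      score = tapply(score, grp, max))
  }, by = chrom]
  out <- as.data.frame(merged)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$score <- as.numeric(out$score)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Pre-split a merged peak set by chromosome for repeated queries.
peak_index <- function(peaks) {
  peaks <- merge_peaks(peaks)
  idx <- split(peaks[c("start", "end", "score")], peaks$chrom)
  lapply(idx, function(p) list(start = p$start, end = p$end, score = p$score))
}

# Max peak score over each query interval [start, end), or NA when the query
# overlaps no peak (>= 1 bp overlap required). Vectorized; chrom, start, end
# same length. `index` from peak_index().
peak_range_scores <- function(chrom, start, end, index) {
  out <- rep(NA_real_, length(start))
  for (ch in unique(chrom)) {
    p <- index[[ch]]
    sel <- which(chrom == ch)
    if (is.null(p)) next
    # first peak ending after query start; last peak starting before query end
    j_min <- findInterval(start[sel], p$end) + 1L
    j_max <- findInterval(end[sel] - 1L, p$start)
    hit <- j_min <= j_max
    one <- hit & (j_min == j_max)
    out[sel[one]] <- p$score[j_min[one]]
    multi <- which(hit & !one)
    for (k in multi) {
      j <- sel[k]
      out[j] <- max(p$score[j_min[k]:j_max[k]])
    }
  }
  out
}

# TRUE where point position pos (0-based) lies inside a peak.
point_in_peak <- function(chrom, pos, index) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    p <- index[[ch]]
    sel <- which(chrom == ch)
    if (is.null(p)) next
    j <- findInterval(pos[sel], p$start)
    out[sel] <- j >= 1L & pos[sel] < p$end[pmax(j, 1L)]
  }
  out
}

# Total length covered by a merged peak set.
peak_total_length <- function(peaks) {
  peaks <- merge_peaks(peaks)
  sum(as.numeric(peaks$end - peaks$start))
}
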