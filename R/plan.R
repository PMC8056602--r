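#' Suggest the number of simulation rounds
#'
#' Estimates how many genome copies are needed so that pulldown thinning
#' retains at least `margin` times the fragments the run must pull down
#' (`numreads * pcr_p`). The retention rate per fragment is
#' `fb + (1 - fb) / alpha` for `alpha >= 1` (or `fb * alpha + 1 - fb`
#' otherwise), where `fb` is the expected bound fraction of the sheared
#' pool, approximated from the score-weighted peak lengths widened by one
#' mean fragment length (a fragment overlaps a peak if it starts up to one
#' fragment length before it).
#'
#' High enrichment ratios discard almost all background fragments, which is
#' why transcription-factor-like settings need many more rounds than broad
#' histone-modification-like settings.
#'
#' @param model A [chip_model()].
#' @param peaks Peak data frame.
#' @param chrom_lens Named chromosome lengths.
#' @param numreads Reads (or read pairs) to be emitted.
#' @param margin Safety factor on the retained pool (default 1.4).
#' @return Integer number of copies.
#' @export
suggest_numcopies <- function(model, peaks, chrom_lens, numreads,
                              margin = 1.4) {
  model <- validate_chip_model(model)
  peaks <- merge_peaks(peaks)
  G <- sum(as.numeric(chrom_lens))
  mean_frag <- model$frag_shape * model$frag_scale
  frags_per_copy <- G / mean_frag
  fb <- sum((peaks$end - peaks$start + mean_frag) * peaks$score) / G
  fb <- min(fb, 1)
  alpha <- compute_alpha(model$f, model$s)
  rate <- if (alpha >= 1) fb + (1 - fb) / alpha else fb * alpha + (1 - fb)
  n_pull <- max(1, round(numreads * model$pcr_p))
  max(1L, as.integer(ceiling(margin * n_pull / (frags_per_copy * rate))))
}
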