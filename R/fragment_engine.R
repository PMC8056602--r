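# Generative core: shearing, binding assignment, pulldown, PCR.
#
# Fragments are data frames with columns chrom, start, end (0-based
# half-open), bound (logical), copy (simulation round index). They exist
# only in memory; the simulation pipeline thins them copy-by-copy so the
# full pool is never materialized.

#' Shear one genome copy into gamma-length fragments
#'
#' Simulates random shearing of one copy of the genome. Per chromosome the
#' first cut is placed at an offset u ~ Uniform[0, mean fragment length) —
#' decorrelating cut sites across copies — and consecutive fragments with
#' i.i.d. Gamma(shape, scale) lengths (rounded half-up, minimum 1 bp) tile
#' the chromosome without gaps or overlaps until its end. The final partial
#' fragment is cropped at the chromosome end and kept only if it is at least
#' `min_len` bp.
#'
#' @param chrom_lens Named integer vector of chromosome lengths.
#' @param frag_shape,frag_scale Gamma parameters of the fragment length
#'   distribution (mean `frag_shape * frag_scale` bp).
#' @param copy Simulation round index recorded on each fragment.
#' @param min_len Minimum fragment length kept (set this to the read length
#'   when simulating reads; shorter fragments cannot be sequenced).
#' @return Data frame of fragments (`chrom`, `start`, `end`, `copy`).
#' @export
shear_copy <- function(chrom_lens, frag_shape, frag_scale, copy = 1L,
                       min_len = 1L) {
  stopifnot(frag_shape > 0, frag_scale > 0)
  mean_len <- frag_shape * frag_scale
  res <- vector("list", length(chrom_lens))
  for (ci in seq_along(chrom_lens)) {
    L <- chrom_lens[[ci]]
    if (L < min_len) {
      warning("chromosome ", names(chrom_lens)[ci], " (", L,
              " bp) shorter than ", min_len, " bp; skipped")
      next
    }
    u <- floor(stats::runif(1, 0, min(mean_len, L)))
    need <- L - u
    n_est <- ceiling(need / mean_len * 1.2) + 8
    len <- floor(stats::rgamma(n_est, shape = frag_shape,
                               scale = frag_scale) + 0.5)
    len <- pmax(len, 1)
    while (sum(len) < need) {
      extra <- floor(stats::rgamma(n_est, shape = frag_shape,
                                   scale = frag_scale) + 0.5)
      len <- c(len, pmax(extra, 1))
    }
    ends <- u + cumsum(len)
    k <- which(ends >= need + u)[1]
    starts <- u + c(0, cumsum(len))[seq_len(k)]
    ends <- pmin(ends[seq_len(k)], L)
    keep <- (ends - starts) >= min_len
    res[[ci]] <- data.frame(chrom = names(chrom_lens)[ci],
                            start = as.integer(starts[keep]),
                            end = as.integer(ends[keep]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  out$copy <- as.integer(copy)
  out
}

#' Assign bound status to fragments from peak scores
#'
#' A fragment overlapping at least one peak by >= 1 bp is bound with
#' probability equal to the maximum score of the peaks it overlaps
#' (scores are binding probabilities in [0, 1]); fragments overlapping no
#' peak are never bound.
#'
#' @param frags Fragment data frame from [shear_copy()].
#' @param peaks Peak data frame, or a prebuilt index from
#'   `chipsim:::peak_index()`.
#' @return `frags` with a logical `bound` column added.
#' @export
assign_binding <- function(frags, peaks) {
  index <- if (is.data.frame(peaks)) peak_index(peaks) else peaks
  n <- nrow(frags)
  if (n == 0) { frags$bound <- logical(0); return(frags) }
  sc <- peak_range_scores(frags$chrom, frags$start, frags$end, index)
  bound <- !is.na(sc)
  hit <- which(bound)
  if (length(hit) > 0)
    bound[hit] <- stats::runif(length(hit)) < sc[hit]
  frags$bound <- bound
  frags
}

#' Pulldown: enrichment-weighted sampling of fragments
#'
#' Models immunoprecipitation as sampling without replacement where a bound
#' fragment's probability of selection is `alpha` times an unbound
#' fragment's ([compute_alpha()]). Implemented as
#' inclusion-probability-proportional-to-weight sampling: fragments are
#' independently retained with probability `w / max(w)` (bound weight
#' `alpha`, unbound weight 1) and the retained set is uniformly subsampled
#' to `n_target`. Each fragment is selected at most once, and the expected
#' bound fraction among selected fragments is exactly
#' `alpha * f_pool / (alpha * f_pool + 1 - f_pool)` where `f_pool` is the
#' bound fraction of the pool.
#'
#' If fewer than `n_target` fragments survive thinning, all survivors are
#' returned with a warning — raise `numcopies` to enlarge the pool.
#'
#' @param frags Fragment data frame with a `bound` column.
#' @param alpha Positive enrichment ratio.
#' @param n_target Number of fragments to select.
#' @return Selected fragment data frame.
#' @export
pulldown_sample <- function(frags, alpha, n_target) {
  stopifnot(alpha > 0, n_target >= 1)
  if (nrow(frags) == 0) stop("empty fragment pool", call. = FALSE)
  kept <- frags[pulldown_retain(frags$bound, alpha), , drop = FALSE]
  if (nrow(kept) <= n_target) {
    if (nrow(kept) < n_target)
      warning("fragment pool yielded only ", nrow(kept), " of ", n_target,
              " requested fragments; increase numcopies")
    return(kept)
  }
  kept[sample.int(nrow(kept), n_target), , drop = FALSE]
}

# Bernoulli thinning step of the pulldown: keep each fragment with
# probability proportional to its weight (alpha for bound, 1 for unbound),
# scaled so the larger class is kept with probability 1.
pulldown_retain <- function(bound, alpha) {
  q <- if (alpha >= 1) ifelse(bound, 1, 1 / alpha)
       else ifelse(bound, alpha, 1)
  stats::runif(length(bound)) < q
}

#' PCR amplification with geometric duplicate counts
#'
#' Each fragment is emitted `i` times where `i ~ Geometric(p)` on support
#' {1, 2, ...}, i.e. `P(i) = p (1 - p)^(i - 1)`: `p` is the probability a
#' fragment has no PCR duplicates and the expected multiplicity is `1/p`.
#' With `p = 1` the output equals the input.
#'
#' @param frags Fragment data frame.
#' @param pcr_p Probability of no duplicates, in (0, 1].
#' @return Fragment data frame with duplicated rows; a `dup_index` column
#'   numbers the emissions of each source fragment (1 = original).
#' @export
pcr_amplify <- function(frags, pcr_p) {
  stopifnot(pcr_p > 0, pcr_p <= 1)
  n <- nrow(frags)
  if (n == 0) { frags$dup_index <- integer(0); return(frags) }
  mult <- if (pcr_p == 1) rep(1L, n) else stats::rgeom(n, pcr_p) + 1L
  out <- frags[rep(seq_len(n), mult), , drop = FALSE]
  out$dup_index <- sequence(mult)
  rownames(out) <- NULL
  out
}
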