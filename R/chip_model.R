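#' Construct a ChIP-seq model parameter set
#'
#' A `chip_model` bundles every parameter of the generative ChIP-seq model:
#' the gamma fragment-length distribution from shearing, the pulldown
#' parameters `f` (fraction of the genome bound by the factor) and `s`
#' (fraction of pulled-down reads originating from true binding sites,
#' empirically the FRIP/SPOT score), the PCR parameter `p` (probability that
#' a fragment has no PCR duplicates), and per-base sequencing error rates.
#'
#' The pulldown enrichment ratio `alpha` is never stored; it is always
#' derived from `(f, s)` via [compute_alpha()] so there is a single source
#' of truth.
#'
#' @param frag_shape Gamma shape parameter k of the fragment-length
#'   distribution (dimensionless, > 0). The mean fragment length is
#'   `frag_shape * frag_scale` bp.
#' @param frag_scale Gamma scale parameter theta in bp (> 0).
#' @param f Fraction of the genome bound, in (0, 1).
#' @param s Fraction of pulled-down reads from true binding sites, in (0, 1).
#' @param pcr_p Probability a fragment has no PCR duplicates, in (0, 1].
#'   `pcr_p = 1` means duplicates never occur.
#' @param sub_rate,ins_rate,del_rate Per-base substitution / insertion /
#'   deletion rates during sequencing, each in [0, 1) and summing to < 1.
#' @return An object of class `chip_model` (a validated named list).
#' @examples
#' m <- chip_model(frag_shape = 5, frag_scale = 40, f = 0.02, s = 0.5)
#' compute_alpha(m$f, m$s)
#' @export
chip_model <- function(frag_shape, frag_scale, f, s, pcr_p = 1,
                       sub_rate = 0, ins_rate = 0, del_rate = 0) {
  m <- structure(
    list(frag_shape = as.numeric(frag_shape),
         frag_scale = as.numeric(frag_scale),
         f = as.numeric(f), s = as.numeric(s),
         pcr_p = as.numeric(pcr_p),
         sub_rate = as.numeric(sub_rate),
         ins_rate = as.numeric(ins_rate),
         del_rate = as.numeric(del_rate)),
    class = "chip_model")
  validate_chip_model(m)
}

#' Validate a chip_model
#'
#' Checks every model invariant and fails with an error naming the first
#' offending field.
#'
#' @param m A `chip_model` or a named list with the same fields.
#' @return The validated `chip_model`, invisibly usable in pipelines.
#' @export
validate_chip_model <- function(m) {
  fields <- c("frag_shape", "frag_scale", "f", "s", "pcr_p",
              "sub_rate", "ins_rate", "del_rate")
  missing <- setdiff(fields, names(m))
  if (length(missing) > 0)
    stop("model is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  chk <- function(field, ok, what) {
    v <- m[[field]]
    if (length(v) != 1 || !is.numeric(v) || is.na(v) || !ok(v))
      stop("invalid model field '", field, "': must be ", what,
           " (got ", deparse(m[[field]]), ")", call. = FALSE)
  }
  chk("frag_shape", function(v) v > 0, "> 0")
  chk("frag_scale", function(v) v > 0, "> 0")
  chk("f", function(v) v > 0 && v < 1, "in (0, 1)")
  chk("s", function(v) v > 0 && v < 1, "in (0, 1)")
  chk("pcr_p", function(v) v > 0 && v <= 1, "in (0, 1]")
  chk("sub_rate", function(v) v >= 0 && v < 1, "in [0, 1)")
  chk("ins_rate", function(v) v >= 0 && v < 1, "in [0, 1)")
  chk("del_rate", function(v) v >= 0 && v < 1, "in [0, 1)")
  if (m$sub_rate + m$ins_rate + m$del_rate >= 1)
    stop("invalid model: sub_rate + ins_rate + del_rate must be < 1",
         call. = FALSE)
  if (!inherits(m, "chip_model")) class(m) <- "chip_model"
  m
}

#' @export
print.chip_model <- function(x, ...) {
  cat("ChIP-seq model parameters\n")
  cat(sprintf("  fragment lengths : Gamma(shape = %g, scale = %g), mean %.1f bp\n",
              x$frag_shape, x$frag_scale, x$frag_shape * x$frag_scale))
  cat(sprintf("  pulldown         : f = %g, s = %g  (alpha = %.4g)\n",
              x$f, x$s, compute_alpha(x$f, x$s)))
  cat(sprintf("  PCR              : p = %g (expected duplicates per fragment: %.3g)\n",
              x$pcr_p, 1 / x$pcr_p - 1))
  cat(sprintf("  sequencing error : sub = %g, ins = %g, del = %g\n",
              x$sub_rate, x$ins_rate, x$del_rate))
  invisible(x)
}

#' Pulldown enrichment ratio alpha
#'
#' Computes the ratio of the probability of pulling down a bound versus an
#' unbound fragment,
#' \deqn{\alpha = \frac{s (1 - f)}{(1 - s) f}}
#' where `f` is the fraction of the genome bound by the factor and `s` is the
#' fraction of pulled-down reads that originate from true binding sites.
#' `alpha` is strictly increasing in `s` and strictly decreasing in `f`;
#' `alpha = 1` whenever `f == s` (pulldown is then no better than chance).
#'
#' @param f Fraction of the genome bound, in (0, 1). Vectorized.
#' @param s Fraction of pulled-down reads from binding sites, in (0, 1).
#' @return The enrichment ratio (positive numeric).
#' @examples
#' compute_alpha(0.5, 0.5)   # 1
#' compute_alpha(0.1, 0.9)   # 81
#' @export
compute_alpha <- function(f, s) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("f must be in (0, 1): a value of 0 or 1 means nothing or everything ",
         "is bound and the enrichment ratio is undefined", call. = FALSE)
  if (any(!is.finite(s)) || any(s <= 0) || any(s >= 1))
    stop("s must be in (0, 1)", call. = FALSE)
  s * (1 - f) / ((1 - s) * f)
}

#' Experimental (sequencing-run) parameters
#'
#' Parameters of the simulated sequencing experiment, as opposed to the
#' biochemical model held in [chip_model()].
#'
#' @param numreads Total reads (single-end) or read pairs (paired-end) to
#'   emit.
#' @param readlen Read length in bp.
#' @param paired Paired-end (`TRUE`) or single-end (`FALSE`) sequencing.
#' @param numcopies Number of simulation rounds, i.e. how many times the
#'   reference genome is sheared. Loosely analogous to (but not equal to)
#'   the number of cells in the experiment. As a rule of thumb 25--100
#'   rounds work well for broad histone-modification data and ~1000 for
#'   transcription factors; raise it if the fragment pool warning fires.
#' @param seed Integer RNG seed; every stage of the simulation derives an
#'   independent stream from it.
#' @return An object of class `experiment_params`.
#' @export
experiment_params <- function(numreads = 100000L, readlen = 36L,
                              paired = FALSE, numcopies = 100L, seed = 1L) {
  numreads <- as.integer(numreads); readlen <- as.integer(readlen)
  numcopies <- as.integer(numcopies)
  if (is.na(numreads) || numreads < 1) stop("numreads must be >= 1")
  if (is.na(readlen) || readlen < 1) stop("readlen must be >= 1")
  if (is.na(numcopies) || numcopies < 1) stop("numcopies must be >= 1")
  structure(list(numreads = numreads, readlen = readlen,
                 paired = isTRUE(paired), numcopies = numcopies,
                 seed = as.integer(seed)),
            class = "experiment_params")
}

# Model file schema: nested JSON, explicit keys, unknown keys rejected.
.model_schema <- list(
  frag = c("shape", "scale"),
  pulldown = c("f", "s"),
  pcr = "p",
  seq_error = c("sub", "ins", "del"))

#' Write a model to a JSON file
#'
#' Serializes a [chip_model()] to a small JSON document with explicit nested
#' keys (`frag`, `pulldown`, `pcr`, `seq_error`). The gamma distribution is
#' stored as (shape, scale) — mean = shape * scale — and a `_comment` field in
#' the file says so, to avoid shape/rate confusion. Full double precision is
#' preserved so that write-then-read is an exact identity.
#'
#' @param model A validated `chip_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  model <- validate_chip_model(model)
  doc <- list(
    "_comment" = "gamma fragment-length model parameterized as (shape, scale); mean = shape*scale bp",
    frag = list(shape = model$frag_shape, scale = model$frag_scale),
    pulldown = list(f = model$f, s = model$s),
    pcr = list(p = model$pcr_p),
    seq_error = list(sub = model$sub_rate, ins = model$ins_rate,
                     del = model$del_rate))
  # digits = I(17): shortest representation that round-trips a double
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a model from a JSON file
#'
#' Parses and validates a model file written by [write_model()] (or by hand).
#' Unknown keys are rejected so that typos (`"scale "` , `"shapes"`) fail
#' loudly instead of silently falling back to defaults; missing fields and
#' out-of-range values raise an error naming the field.
#'
#' @param path Path to a model JSON file.
#' @return A validated `chip_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc[["_comment"]] <- NULL
  unknown_top <- setdiff(names(doc), names(.model_schema))
  if (length(unknown_top) > 0)
    stop("unknown key(s) in model file: ",
         paste(unknown_top, collapse = ", "), call. = FALSE)
  for (section in names(.model_schema)) {
    if (is.null(doc[[section]]))
      stop("model file missing section '", section, "'", call. = FALSE)
    unknown <- setdiff(names(doc[[section]]), .model_schema[[section]])
    if (length(unknown) > 0)
      stop("unknown key(s) in model file section '", section, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    miss <- setdiff(.model_schema[[section]], names(doc[[section]]))
    if (length(miss) > 0)
      stop("model file missing field '",
           paste0(section, ".", miss[1]), "'", call. = FALSE)
  }
  validate_chip_model(structure(list(
    frag_shape = doc$frag$shape, frag_scale = doc$frag$scale,
    f = doc$pulldown$f, s = doc$pulldown$s,
    pcr_p = doc$pcr$p,
    sub_rate = doc$seq_error$sub, ins_rate = doc$seq_error$ins,
    del_rate = doc$seq_error$del), class = "chip_model"))
}

# Derive an independent, reproducible seed for a named simulation stage from
# the user seed. Keeps results < 2^31 so set.seed() accepts them.
stage_seed <- function(seed, stage, batch = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + batch) %% 2147483647)
}
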