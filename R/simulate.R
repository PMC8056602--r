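#' Simulate a ChIP-seq experiment
#'
#' Runs the full generative pipeline — shearing, binding assignment,
#' pulldown, PCR amplification, sequencing — and returns (and optionally
#' writes to FASTQ) exactly `numreads` reads or read pairs.
#'
#' Each simulation round (genome copy) is sheared into gamma-length
#' fragments, fragments overlapping peaks become bound with probability
#' equal to the peak score, and pulldown retains fragments with relative
#' probability `alpha : 1` (bound : unbound), where `alpha` is derived from
#' the model's `(f, s)` by [compute_alpha()]. Copies are processed one at a
#' time and thinned immediately, so the full fragment pool is never held in
#' memory. The retained pool is downsampled to `numreads * pcr_p` fragments
#' (so that the expected read count after PCR equals `numreads`), amplified
#' with geometric duplicate counts, topped up or truncated to exactly
#' `numreads`, and sequenced.
#'
#' Every stage draws from an independent RNG stream derived from
#' `params$seed`, so runs are bit-reproducible and a change to one stage's
#' internals does not perturb the draws of the others.
#'
#' @param reference Named character vector of chromosome sequences, or a
#'   FASTA path.
#' @param peaks Peak data frame (`chrom`, `start`, `end`, `score` in [0,1])
#'   or a BED path (read with [read_peaks()] defaults: all scores 1).
#' @param model A [chip_model()] or a model JSON path.
#' @param params An [experiment_params()].
#' @param out_prefix If non-NULL, write FASTQ (`<prefix>.fastq` or
#'   `<prefix>_1/2.fastq`), a provenance JSON (`<prefix>.run.json`), and —
#'   with `ground_truth = TRUE` — a per-read ground-truth TSV.
#' @param ground_truth Write the ground-truth table alongside the FASTQ.
#' @param max_n_frac Fragments with more than this fraction of N bases are
#'   excluded at pulldown (assembly gaps would otherwise dominate).
#' @param name_prefix Read-name prefix.
#' @return (Invisibly) a list of class `chip_sim` with elements `reads`
#'   (data frame: name, seq1, seq2, chrom, start, end, strand, bound,
#'   frag_id, dup_index, error-operation counts), `summary` (fragment
#'   accounting and achieved FRIP), `model`, `params`.
#' @examples
#' ref <- make_reference(c(chrT = 50000L), seed = 1)
#' pks <- make_peaks(chrom_lens = c(chrT = 50000L), n_peaks = 5,
#'                   len_range = c(500, 1000), seed = 2)
#' m <- chip_model(frag_shape = 4, frag_scale = 50, f = 0.05, s = 0.4)
#' sim <- simreads(ref, pks, m,
#'                 experiment_params(numreads = 2000, readlen = 36,
#'                                   numcopies = 50, seed = 7))
#' sim$summary$frip
#' @export
simreads <- function(reference, peaks, model, params,
                     out_prefix = NULL, ground_truth = FALSE,
                     max_n_frac = 0.5, name_prefix = "sim") {
  if (is.character(reference) && is.null(names(reference)))
    reference <- read_reference(reference)
  if (is.character(peaks)) peaks <- read_peaks(peaks)
  if (is.character(model)) model <- read_model(model)
  model <- validate_chip_model(model)
  stopifnot(inherits(params, "experiment_params"))
  peaks <- merge_peaks(peaks)
  clens <- chrom_lengths(reference)
  bad <- !(peaks$chrom %in% names(clens))
  if (any(bad)) {
    warning(sum(bad), " peak(s) on chromosome(s) absent from the reference",
            " were ignored")
    peaks <- peaks[!bad, , drop = FALSE]
  }
  index <- peak_index(peaks)
  alpha <- compute_alpha(model$f, model$s)
  readlen <- params$readlen
  numreads <- params$numreads
  n_pull <- max(1L, as.integer(round(numreads * model$pcr_p)))
  seed <- params$seed

  # cumulative N counts per chromosome, for the N-fraction filter
  ncum <- NULL
  if (max_n_frac < 1 && any(grepl("N", reference, fixed = TRUE))) {
    ncum <- lapply(reference, function(s)
      cumsum(utf8ToInt(s) == 78L))
  }

  retained <- vector("list", params$numcopies)
  n_generated <- 0; n_short <- 0; n_ncut <- 0
  for (copy in seq_len(params$numcopies)) {
    set.seed(stage_seed(seed, "shear", copy))
    fr <- shear_copy(clens, model$frag_shape, model$frag_scale,
                     copy = copy, min_len = 1L)
    n_generated <- n_generated + nrow(fr)
    short <- (fr$end - fr$start) < readlen
    n_short <- n_short + sum(short)
    fr <- fr[!short, , drop = FALSE]
    if (!is.null(ncum) && nrow(fr) > 0) {
      nfr <- numeric(nrow(fr))
      for (ch in unique(fr$chrom)) {
        sel <- fr$chrom == ch
        cn <- ncum[[ch]]
        nn <- cn[fr$end[sel]] -
          ifelse(fr$start[sel] > 0, cn[fr$start[sel]], 0)
        nfr[sel] <- nn / (fr$end[sel] - fr$start[sel])
      }
      drop_n <- nfr > max_n_frac
      n_ncut <- n_ncut + sum(drop_n)
      fr <- fr[!drop_n, , drop = FALSE]
    }
    if (nrow(fr) == 0) next
    set.seed(stage_seed(seed, "bind", copy))
    fr <- assign_binding(fr, index)
    set.seed(stage_seed(seed, "pulldown", copy))
    keep <- pulldown_retain(fr$bound, alpha)
    retained[[copy]] <- fr[keep, , drop = FALSE]
  }
  pool <- as.data.frame(data.table::rbindlist(
    retained[!vapply(retained, is.null, TRUE)]))
  if (nrow(pool) == 0) stop("no fragments survived pulldown; ",
                            "check the model and raise numcopies")
  pool$frag_id <- seq_len(nrow(pool))

  set.seed(stage_seed(seed, "downsample"))
  if (nrow(pool) <= n_pull) {
    if (nrow(pool) < n_pull)
      warning("fragment pool (", nrow(pool), ") smaller than the ",
              n_pull, " fragments needed; increase numcopies")
    perm <- sample.int(nrow(pool))
  } else {
    perm <- sample.int(nrow(pool))
  }
  sel_idx <- perm[seq_len(min(n_pull, nrow(pool)))]
  spare <- perm[-seq_len(min(n_pull, nrow(pool)))]

  set.seed(stage_seed(seed, "pcr"))
  amp <- pcr_amplify(pool[sel_idx, , drop = FALSE], model$pcr_p)
  while (nrow(amp) < numreads && length(spare) > 0) {
    k <- min(length(spare),
             max(1L, ceiling((numreads - nrow(amp)) * model$pcr_p)))
    extra <- pcr_amplify(pool[spare[seq_len(k)], , drop = FALSE],
                         model$pcr_p)
    spare <- spare[-seq_len(k)]
    amp <- rbind(amp, extra)
  }
  if (nrow(amp) > numreads) {
    amp <- amp[sort(sample.int(nrow(amp), numreads)), , drop = FALSE]
  } else if (nrow(amp) < numreads) {
    warning("emitted only ", nrow(amp), " of ", numreads,
            " requested reads; increase numcopies")
  }

  set.seed(stage_seed(seed, "sequence"))
  reads <- sequence_fragments(amp, reference, readlen,
                              paired = params$paired,
                              sub_rate = model$sub_rate,
                              ins_rate = model$ins_rate,
                              del_rate = model$del_rate,
                              name_prefix = name_prefix)

  five_prime <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  frip <- if (nrow(reads) > 0)
    mean(point_in_peak(reads$chrom, five_prime, index)) else NA_real_
  summary <- list(
    numreads = nrow(reads), paired = params$paired,
    fragments_generated = n_generated, dropped_short = n_short,
    dropped_n_rich = n_ncut, pool_retained = nrow(pool),
    pulled_down = length(sel_idx), alpha = alpha, frip = frip)

  out <- structure(list(reads = reads, summary = summary, model = model,
                        params = params), class = "chip_sim")
  if (!is.null(out_prefix)) {
    files <- write_fastq(reads, out_prefix, paired = params$paired)
    prov <- list(tool = "chipsim",
                 version = as.character(utils::packageVersion("chipsim")),
                 model = unclass(model), params = unclass(params),
                 summary = summary, fastq = files)
    jsonlite::write_json(prov, paste0(out_prefix, ".run.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (ground_truth) {
      gt <- reads[c("name", "chrom", "start", "end", "strand", "bound",
                    "frag_id", "dup_index", "n_sub", "n_ins", "n_del")]
      utils::write.table(gt, paste0(out_prefix, "_ground_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(out)
}

#' @export
print.chip_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("ChIP-seq simulation: %d %s reads\n", s$numreads,
              if (s$paired) "paired-end" else "single-end"))
  cat(sprintf("  fragments generated %d | dropped short %d | N-rich %d\n",
              s$fragments_generated, s$dropped_short, s$dropped_n_rich))
  cat(sprintf("  retained after pulldown thinning %d | pulled down %d\n",
              s$pool_retained, s$pulled_down))
  cat(sprintf("  alpha = %.4g | achieved FRIP = %.4f\n", s$alpha, s$frip))
  invisible(x)
}

#' Convert simulated reads to alignment records
#'
#' Produces the alignment-record table that a perfect aligner plus a
#' duplicate marker would emit for the simulated reads, for feeding the
#' learning component without running an external aligner. Coordinates come
#' from the ground-truth origin of each read; duplicates (all emissions of a
#' pulled-down fragment beyond the first, per strand) are flagged the way a
#' duplicate marker keyed on position would flag them.
#'
#' @param sim A `chip_sim` object from [simreads()].
#' @return Data frame of alignment records: `chrom`, `pos` (0-based
#'   leftmost), `is_reverse`, `is_duplicate`, `is_proper_pair`,
#'   `template_len` (signed, SAM convention; 0 for single-end), `mapq`,
#'   `qwidth`. Paired-end yields two records per pair.
#' @export
sim_to_records <- function(sim) {
  stopifnot(inherits(sim, "chip_sim"))
  r <- sim$reads
  readlen <- sim$params$readlen
  len <- r$end - r$start
  if (sim$params$paired) {
    dup <- duplicated(r$frag_id)
    left <- data.frame(chrom = r$chrom, pos = r$start, is_reverse = FALSE,
                       is_duplicate = dup, is_proper_pair = TRUE,
                       template_len = len, mapq = 60L, qwidth = readlen,
                       stringsAsFactors = FALSE)
    right <- data.frame(chrom = r$chrom, pos = r$end - readlen,
                        is_reverse = TRUE, is_duplicate = dup,
                        is_proper_pair = TRUE, template_len = -len,
                        mapq = 60L, qwidth = readlen,
                        stringsAsFactors = FALSE)
    out <- rbind(left, right)
  } else {
    dup <- duplicated(paste0(r$frag_id, r$strand))
    pos <- ifelse(r$strand == "+", r$start, r$end - readlen)
    out <- data.frame(chrom = r$chrom, pos = as.integer(pos),
                      is_reverse = r$strand == "-", is_duplicate = dup,
                      is_proper_pair = FALSE, template_len = 0L,
                      mapq = 60L, qwidth = readlen,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
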