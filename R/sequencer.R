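# Sequencing: turn amplified fragments into reads with per-base errors.

.BASES <- c("A", "C", "G", "T")

#' Sequence fragments into reads
#'
#' Generates single- or paired-end reads of length `readlen` from fragment
#' coordinates on the reference. Single-end: the sequenced end of the
#' fragment is chosen uniformly at random (both ends of a real library
#' molecule are sequenceable); reverse-strand reads are
#' reverse-complemented. Paired-end: mate 1 reads the 5' end forward, mate 2
#' reads the 3' end reverse-complemented, so the insert size equals the
#' fragment length.
#'
#' Per-base sequencing errors are applied with the rates in effect:
#' substitutions replace a base with a uniformly chosen different base,
#' deletions skip a template base, insertions add a uniformly chosen base;
#' template consumption continues until `readlen` bases are emitted, clipped
#' at the fragment end and padded with N if the template is exhausted.
#' Template N bases are emitted as N and never altered.
#'
#' Fragments shorter than `readlen` must be dropped upstream (the simulation
#' pipeline does this and counts them).
#'
#' @param frags Fragment data frame (`chrom`, `start`, `end`; optionally
#'   `bound`, `copy`, `dup_index`).
#' @param reference Named character vector of chromosome sequences.
#' @param readlen Read length in bp.
#' @param paired Logical.
#' @param sub_rate,ins_rate,del_rate Per-base error rates.
#' @param name_prefix Prefix for read names
#'   (`prefix:chrom:start-end:serial`).
#' @return Data frame of reads: `name`, `seq1`, `seq2` (NA if single-end),
#'   `chrom`, `start`, `end`, `strand`, plus pass-through columns `bound`
#'   and `frag_id` when present, and error-operation counts `n_sub`,
#'   `n_ins`, `n_del`.
#' @export
sequence_fragments <- function(frags, reference, readlen, paired = FALSE,
                               sub_rate = 0, ins_rate = 0, del_rate = 0,
                               name_prefix = "sim") {
  n <- nrow(frags)
  if (any(frags$end - frags$start < readlen))
    stop("internal error: fragment shorter than readlen reached sequencing")
  chrom <- frags$chrom; start <- frags$start; end <- frags$end
  seq2 <- rep(NA_character_, n)
  if (paired) {
    strand <- rep("+", n)
    seq1 <- extract_subseq(reference, chrom, start, start + readlen)
    seq2 <- revcomp(extract_subseq(reference, chrom, end - readlen, end))
  } else {
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    fwd <- strand == "+"
    seq1 <- character(n)
    seq1[fwd] <- extract_subseq(reference, chrom[fwd], start[fwd],
                                start[fwd] + readlen)
    seq1[!fwd] <- revcomp(extract_subseq(reference, chrom[!fwd],
                                         end[!fwd] - readlen, end[!fwd]))
  }
  n_sub <- n_ins <- n_del <- integer(n)
  if (sub_rate + ins_rate + del_rate > 0 && n > 0) {
    # template runs from the read start to the fragment end so deletions can
    # consume further into the fragment; pad with N beyond that.
    buf <- readlen + max(20L, ceiling(4 * readlen * del_rate /
                                        max(1 - del_rate, 0.5)) + 20L)
    t1 <- character(n)
    if (paired) {
      t1 <- extract_subseq(reference, chrom, start, pmin(start + buf, end))
      t2 <- revcomp(extract_subseq(reference, chrom, pmax(end - buf, start),
                                   end))
    } else {
      t1[fwd] <- extract_subseq(reference, chrom[fwd], start[fwd],
                                pmin(start[fwd] + buf, end[fwd]))
      t1[!fwd] <- revcomp(extract_subseq(reference, chrom[!fwd],
                                         pmax(end[!fwd] - buf, start[!fwd]),
                                         end[!fwd]))
    }
    e1 <- apply_seq_errors(t1, readlen, sub_rate, ins_rate, del_rate)
    seq1 <- e1$seqs
    n_sub <- e1$n_sub; n_ins <- e1$n_ins; n_del <- e1$n_del
    if (paired) {
      e2 <- apply_seq_errors(t2, readlen, sub_rate, ins_rate, del_rate)
      seq2 <- e2$seqs
      n_sub <- n_sub + e2$n_sub; n_ins <- n_ins + e2$n_ins
      n_del <- n_del + e2$n_del
    }
  }
  name <- sprintf("%s:%s:%d-%d:%d", name_prefix, chrom, start, end,
                  seq_len(n))
  out <- data.frame(name = name, seq1 = seq1, seq2 = seq2, chrom = chrom,
                    start = start, end = end, strand = strand,
                    n_sub = n_sub, n_ins = n_ins, n_del = n_del,
                    stringsAsFactors = FALSE)
  for (col in c("bound", "frag_id", "dup_index", "copy"))
    if (!is.null(frags[[col]])) out[[col]] <- frags[[col]]
  rownames(out) <- NULL
  out
}

# Vectorized substring extraction across chromosomes (0-based half-open in,
# 1-based closed for substring()).
extract_subseq <- function(reference, chrom, start, end) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- substring(reference[[ch]], start[sel] + 1L, end[sel])
  }
  out
}

# Apply the per-base error process to each template string, emitting exactly
# readlen bases per read. Per emitted position the events
# {deletion, insertion, substitution, faithful copy} are mutually exclusive:
# one uniform draw u per step selects deletion (u < del: skip a template
# base, emit nothing, draw again), insertion (emit a random base, template
# untouched), substitution (emit a uniformly chosen base different from the
# template base), or a faithful copy. Template N bases are passed through
# unchanged. When the template is exhausted, N is emitted (substitution/
# insertion draws still apply to pad positions for rate consistency, but an
# N pad is never "corrected").
apply_seq_errors <- function(templates, readlen, sub_rate, ins_rate,
                             del_rate) {
  n <- length(templates)
  seqs <- character(n)
  n_sub <- n_ins <- n_del <- integer(n)
  p_del <- del_rate
  p_ins <- del_rate + ins_rate
  p_sub <- del_rate + ins_rate + sub_rate
  for (i in seq_len(n)) {
    tmpl <- strsplit(templates[i], "", fixed = TRUE)[[1]]
    tl <- length(tmpl)
    out <- character(readlen)
    u <- stats::runif(readlen + 8L)
    ui <- 0L; ti <- 1L; oi <- 1L
    ns <- 0L; ni <- 0L; nd <- 0L
    while (oi <= readlen) {
      ui <- ui + 1L
      if (ui > length(u)) { u <- stats::runif(readlen); ui <- 1L }
      uu <- u[ui]
      if (uu < p_del) {
        ti <- ti + 1L; nd <- nd + 1L
        next
      }
      if (uu < p_ins) {
        out[oi] <- .BASES[floor(stats::runif(1) * 4) + 1]
        oi <- oi + 1L; ni <- ni + 1L
        next
      }
      base <- if (ti <= tl) tmpl[ti] else "N"
      ti <- ti + 1L
      if (uu < p_sub && base != "N") {
        out[oi] <- sample(setdiff(.BASES, base), 1L)
        ns <- ns + 1L
      } else {
        out[oi] <- base
      }
      oi <- oi + 1L
    }
    seqs[i] <- paste(out, collapse = "")
    n_sub[i] <- ns; n_ins[i] <- ni; n_del[i] <- nd
  }
  list(seqs = seqs, n_sub = n_sub, n_ins = n_ins, n_del = n_del)
}
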