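#' Read a FASTA reference genome
#'
#' Loads a FASTA file into a named character vector (one uppercase sequence
#' per chromosome). Record names are taken as the first whitespace-delimited
#' token of the header. Lowercase (soft-masked) bases are uppercased and any
#' character outside {A, C, G, T, N} — e.g. IUPAC ambiguity codes — is mapped
#' to N.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("duplicate record name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  out <- toupper(as.character(seqs))
  out <- gsub("[^ACGTN]", "N", out)
  names(out) <- nm
  out
}

#' Chromosome lengths of a reference
#'
#' Accepts a named character vector (from [read_reference()]), a FASTA path,
#' or a `.fai`-style two-plus-column index file, and returns named lengths.
#'
#' @param reference Named character vector, FASTA path, or `.fai` path.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference) && is.null(names(reference))) {
    if (grepl("\\.fai$", reference)) {
      fai <- utils::read.table(reference, sep = "\t",
                               stringsAsFactors = FALSE)
      return(stats::setNames(as.integer(fai[[2]]), fai[[1]]))
    }
    reference <- read_reference(reference)
  }
  stopifnot(!is.null(names(reference)))
  stats::setNames(nchar(reference), names(reference))
}

#' Read scored peaks from a BED file
#'
#' Reads a tab-delimited BED 3+ file of peak intervals (0-based half-open)
#' and normalizes the score column to a binding probability in [0, 1]:
#' raw scores are divided by `score_max` and clipped to [0, 1]. Peak scores
#' from common callers (e.g. narrowPeak) are not probabilities, hence the
#' explicit normalization contract. Overlapping peaks are merged, the merged
#' interval taking the maximum score.
#'
#' @param path Path to a BED-like file (>= 3 tab-delimited columns; `track`
#'   and `#` comment lines are skipped).
#' @param score_column 1-based column index of the raw score, or `NULL`
#'   (default) for no score column, in which case every peak gets
#'   probability 1.
#' @param score_max Raw score that maps to probability 1. Default 1 (scores
#'   used as-is). Values above `score_max` are clipped to 1.
#' @return Data frame with columns `chrom`, `start`, `end`, `score`, sorted
#'   and non-overlapping.
#' @export
read_peaks <- function(path, score_column = NULL, score_max = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("no peak records in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3) stop("BED file needs >= 3 tab-delimited columns",
                         call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinates in BED file", call. = FALSE)
  if (any(start < 0)) stop("negative coordinates in BED file", call. = FALSE)
  if (any(end <= start))
    stop("invalid interval(s) with start >= end in BED file", call. = FALSE)
  if (is.null(score_column)) {
    score <- rep(1, length(chrom))
  } else {
    if (ncol_min < score_column)
      stop("score_column = ", score_column, " but file has only ",
           ncol_min, " columns", call. = FALSE)
    raw <- suppressWarnings(as.numeric(vapply(fields, `[[`, "",
                                              as.integer(score_column))))
    if (anyNA(raw)) stop("non-numeric score(s) in column ", score_column,
                         call. = FALSE)
    if (is.null(score_max)) score_max <- 1
    score <- pmin(pmax(raw / score_max, 0), 1)
  }
  merge_peaks(data.frame(chrom = chrom, start = start, end = end,
                         score = score, stringsAsFactors = FALSE))
}

#' Write peaks to a BED file
#'
#' Writes normalized peaks as BED5 (`chrom start end name score`) with the
#' probability score in column 5, so that
#' `read_peaks(path, score_column = 5, score_max = 1)` round-trips.
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  nm <- sprintf("peak%d", seq_len(nrow(peaks)))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom,
                     as.integer(peaks$start), as.integer(peaks$end),
                     nm, format(peaks$score, digits = 15, trim = TRUE,
                                scientific = FALSE)),
             path)
  invisible(path)
}

# Constant quality string: Phred 30 in Phred+33 encoding ('?'). The model
# has a base-error process but no quality-score process.
qual_string <- function(readlen, n = 1) {
  strrep(rawToChar(as.raw(33L + 30L)), rep(readlen, length.out = n))
}

#' Write simulated reads to FASTQ
#'
#' Single-end reads go to `<prefix>.fastq`; paired-end reads go to
#' `<prefix>_1.fastq` and `<prefix>_2.fastq` with matching record order and
#' identical read names. Read names encode the origin fragment
#' (`prefix:chrom:start-end:serial`) so ground truth is recoverable without
#' auxiliary files. Qualities are a constant Phred-30 string.
#'
#' @param reads Data frame with columns `name`, `seq1` and, for paired-end,
#'   `seq2` (as produced by [simreads()]).
#' @param path_prefix Output path prefix.
#' @param paired Logical; write one or two FASTQ files.
#' @return Character vector of the file path(s) written, invisibly.
#' @export
write_fastq <- function(reads, path_prefix, paired = FALSE) {
  fq_lines <- function(name, seq) {
    if (length(seq) == 0) return(character(0))
    as.vector(rbind(paste0("@", name), seq, "+",
                    qual_string(nchar(seq), length(seq))))
  }
  if (!paired) {
    f <- paste0(path_prefix, ".fastq")
    writeLines(fq_lines(reads$name, reads$seq1), f)
    return(invisible(f))
  }
  if (is.null(reads$seq2) || (nrow(reads) > 0 && anyNA(reads$seq2)))
    stop("paired output requested but mate sequences are missing",
         call. = FALSE)
  f1 <- paste0(path_prefix, "_1.fastq")
  f2 <- paste0(path_prefix, "_2.fastq")
  writeLines(fq_lines(reads$name, reads$seq1), f1)
  writeLines(fq_lines(reads$name, reads$seq2), f2)
  invisible(c(f1, f2))
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Vectorized reverse complement on plain character strings.
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}
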