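# Read QC: 3' adaptor trimming with error tolerance and the retention
# rules (adaptor found, 15-45 nt insert, >=80% of bases with Q > 20).

#' QC configuration
#'
#' @param adaptor 3' adaptor sequence; the default is the standard
#'   Illumina small-RNA adaptor.
#' @param min_overlap minimum read/adaptor overlap considered (bases).
#' @param error_rate allowed mismatch fraction of the overlap;
#'   mismatches allowed = `floor(error_rate * overlap)`.
#' @param min_len,max_len retained insert length bounds (inclusive).
#' @param q_threshold Phred score that a base must strictly exceed to
#'   count as high quality.
#' @param min_q_fraction minimum fraction of high-quality bases.
#' @param phred_offset 33 (Sanger/Illumina 1.8+) or 64 (legacy).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(adaptor = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                      min_overlap = 3L, error_rate = 0.1,
                      min_len = 15L, max_len = 45L,
                      q_threshold = 20L, min_q_fraction = 0.8,
                      phred_offset = 33L) {
  stopifnot(error_rate >= 0, error_rate < 0.5, min_len <= max_len,
            min_overlap >= 1L, phred_offset %in% c(33L, 64L))
  structure(list(adaptor = normalize_seq(adaptor), min_overlap = as.integer(min_overlap),
                 error_rate = error_rate, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), q_threshold = as.integer(q_threshold),
                 min_q_fraction = min_q_fraction, phred_offset = as.integer(phred_offset)),
            class = "qc_config")
}

#' Trim the 3' adaptor from reads
#'
#' Finds, per read, the leftmost position where a prefix of the adaptor
#' occurs with overlap >= `min_overlap` and at most
#' `floor(error_rate * overlap)` mismatches, and removes it and
#' everything after it. A read whose adaptor starts at position 1 keeps
#' an empty insert (discarded later as too short); a read with no
#' acceptable occurrence is flagged `adaptor_found = FALSE` and left
#' untrimmed.
#'
#' @param sequences,qualities character vectors of equal length.
#' @param cfg [qc_config()].
#' @return list with `sequence`, `qualities` (trimmed) and
#'   `adaptor_found`.
#' @export
trim_adaptor <- function(sequences, qualities = NULL, cfg = qc_config()) {
  stopifnot(is.null(qualities) || length(qualities) == length(sequences))
  pos <- adaptor_positions_cpp(sequences, cfg$adaptor, cfg$min_overlap, cfg$error_rate)
  found <- pos >= 0L
  out_seq <- ifelse(found, substr(sequences, 1L, pos), sequences)
  out_qual <- qualities
  if (!is.null(qualities)) {
    out_qual <- ifelse(found, substr(qualities, 1L, pos), qualities)
  }
  list(sequence = out_seq, qualities = out_qual, adaptor_found = found)
}

#' Apply the read retention rules
#'
#' A read passes iff the adaptor was found, the trimmed insert is
#' between `min_len` and `max_len` nucleotides (inclusive), and at
#' least `min_q_fraction` of its bases have Phred quality strictly
#' above `q_threshold` (Q equal to the threshold does not count).
#'
#' @param trimmed result of [trim_adaptor()].
#' @param cfg [qc_config()].
#' @return character vector of statuses: `pass`, `no_adaptor`,
#'   `too_short`, `too_long` or `low_quality`.
#' @export
filter_reads <- function(trimmed, cfg = qc_config()) {
  len <- nchar(trimmed$sequence)
  status <- rep("pass", length(len))
  qfrac <- qual_frac_above_cpp(trimmed$qualities, cfg$phred_offset, cfg$q_threshold)
  status[!is.nan(qfrac) & qfrac < cfg$min_q_fraction] <- "low_quality"
  status[len > cfg$max_len] <- "too_long"
  status[len < cfg$min_len] <- "too_short"
  status[!trimmed$adaptor_found] <- "no_adaptor"
  status
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame `read_id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(ss),
             sequence = as.character(ss),
             qualities = as.character(S4Vectors::mcols(ss)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write retained reads to FASTQ
#'
#' @param reads data.frame `read_id`, `sequence`, `qualities`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qualities))
  invisible(path)
}

#' Run QC on one sample
#'
#' Trims adaptors, applies the retention rules and reports per-sample
#' statistics. The retained fraction of an empty file is `NA`.
#'
#' @param input FASTQ path or a data.frame as from [read_fastq()].
#' @param cfg [qc_config()].
#' @param sample_id sample label attached to the output.
#' @return list with `reads` (retained, trimmed) and `stats` (raw
#'   count, retained count, retained fraction, per-reason failure
#'   counts).
#' @export
run_qc <- function(input, cfg = qc_config(), sample_id = NA_character_) {
  reads <- if (is.character(input)) read_fastq(input) else input
  trimmed <- trim_adaptor(reads$sequence, reads$qualities, cfg)
  status <- filter_reads(trimmed, cfg)
  keep <- status == "pass"
  out <- data.frame(read_id = reads$read_id[keep],
                    sequence = as.character(trimmed$sequence[keep]),
                    qualities = as.character(trimmed$qualities[keep]),
                    sample_id = rep(sample_id, sum(keep)),
                    stringsAsFactors = FALSE)
  raw <- nrow(reads)
  retained <- sum(keep)
  reasons <- table(factor(status, levels = c("pass", "no_adaptor", "too_short",
                                             "too_long", "low_quality")))
  list(reads = out,
       stats = list(sample_id = sample_id, raw = raw, retained = retained,
                    retained_fraction = if (raw > 0L) retained / raw else NA_real_,
                    reasons = reasons))
}
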