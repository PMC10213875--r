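# Reference database construction: sequence normalization, tRNA
# preprocessing (intron removal, CCA tail, His G), and the per-biotype
# annotation index searched by the cascade.

#' Svedberg classes in size order
#'
#' Fixed small-to-large ordering of rRNA Svedberg classes used for
#' rsRNA parent precedence: when a fragment maps to several rRNA
#' species it is assigned to the smallest one (e.g. 18S rather than the
#' 45S precursor that contains it).
#' @export
SVEDBERG_ORDER <- c("4.5S", "5S", "5.8S", "12S", "16S", "18S", "28S", "45S")

#' Default biotype search order of the annotation cascade
#' @export
BIOTYPE_ORDER <- c("miRNA", "rRNA", "tRNA", "piRNA", "other_ncRNA")

#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases and maps U to T so that RNA- and DNA-alphabet reference
#' databases can be mixed. Any character outside `{A,C,G,T,N}` is an
#' error.
#'
#' @param x character vector of sequences.
#' @return character vector over `{A,C,G,T,N}`.
#' @export
normalize_seq <- function(x) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid characters in sequence(s): ", paste(head(which(bad), 5L), collapse = ", "))
  }
  x
}

#' Build a reference set
#'
#' Assembles a reference table (one row per reference sequence) of the
#' form consumed by [build_annotation_index()]. Sequences are
#' normalized with [normalize_seq()].
#'
#' @param ref_id unique identifiers.
#' @param sequence sequences (DNA or RNA alphabet).
#' @param biotype one of `miRNA`, `rRNA`, `tRNA`, `piRNA`,
#'   `other_ncRNA` (scalar or vector).
#' @param svedberg_class rRNA Svedberg class (`NA` for other biotypes).
#' @param amino_acid tRNA isoacceptor label, e.g. `"Glu"`, `"His"`,
#'   `"mt-Val"` (`NA` for other biotypes).
#' @param processed logical; `TRUE` once tRNA preprocessing has run.
#' @return data.frame with columns `ref_id`, `biotype`, `sequence`,
#'   `svedberg_class`, `amino_acid`, `processed`.
#' @export
reference_set <- function(ref_id, sequence, biotype,
                          svedberg_class = NA_character_,
                          amino_acid = NA_character_,
                          processed = FALSE) {
  sequence <- normalize_seq(sequence)
  refs <- data.frame(
    ref_id = as.character(ref_id),
    biotype = rep_len(as.character(biotype), length(ref_id)),
    sequence = sequence,
    svedberg_class = rep_len(as.character(svedberg_class), length(ref_id)),
    amino_acid = rep_len(as.character(amino_acid), length(ref_id)),
    processed = rep_len(processed, length(ref_id)),
    stringsAsFactors = FALSE
  )
  validate_reference_set(refs)
  refs
}

validate_reference_set <- function(refs) {
  stopifnot(is.data.frame(refs))
  known <- c(BIOTYPE_ORDER, "genome")
  bad_bt <- setdiff(unique(refs$biotype), known)
  if (length(bad_bt)) stop("unknown biotype(s): ", paste(bad_bt, collapse = ", "))
  if (any(nchar(refs$sequence) < 15L)) {
    stop("reference sequences must be at least 15 nt: ",
         paste(refs$ref_id[nchar(refs$sequence) < 15L], collapse = ", "))
  }
  is_rrna <- refs$biotype == "rRNA"
  if (any(is_rrna & is.na(refs$svedberg_class))) {
    stop("rRNA records need a svedberg_class: ",
         paste(refs$ref_id[is_rrna & is.na(refs$svedberg_class)], collapse = ", "))
  }
  if (any(!is_rrna & !is.na(refs$svedberg_class))) {
    stop("svedberg_class only applies to rRNA records")
  }
  bad_sv <- is_rrna & !refs$svedberg_class %in% SVEDBERG_ORDER
  if (any(bad_sv)) stop("unknown Svedberg class for: ",
                        paste(refs$ref_id[bad_sv], collapse = ", "))
  is_trna <- refs$biotype == "tRNA"
  if (any(is_trna & is.na(refs$amino_acid))) {
    stop("tRNA records need an amino_acid label: ",
         paste(refs$ref_id[is_trna & is.na(refs$amino_acid)], collapse = ", "))
  }
  if (any(!is_trna & !is.na(refs$amino_acid))) {
    stop("amino_acid only applies to tRNA records")
  }
  dup <- duplicated(refs[c("biotype", "ref_id")])
  if (any(dup)) stop("duplicate ref_id within a biotype: ",
                     paste(unique(refs$ref_id[dup]), collapse = ", "))
  invisible(refs)
}

#' Preprocess raw tRNA genes into mature matchable sequences
#'
#' Applies the three edits that turn a genomic tRNA gene into the
#' sequence that tRNA-derived fragments are actually matched against:
#' predicted introns are spliced out, the 3' `CCA` tail is appended,
#' and histidine tRNAs receive the post-transcriptional `G` at the 5'
#' end. Records already marked processed are rejected.
#'
#' @param refs reference set rows with `biotype == "tRNA"`.
#' @param introns optional data.frame `ref_id`, `start`, `end` with
#'   1-based inclusive intron intervals on the raw gene sequence.
#' @return `refs` with spliced/tailed sequences and `processed = TRUE`.
#' @export
preprocess_trna <- function(refs, introns = NULL) {
  stopifnot(all(refs$biotype == "tRNA"))
  if (any(refs$processed)) {
    stop("record(s) already processed: ",
         paste(refs$ref_id[refs$processed], collapse = ", "))
  }
  out <- refs
  for (i in seq_len(nrow(out))) {
    seq <- out$sequence[i]
    id <- out$ref_id[i]
    if (!is.null(introns)) {
      iv <- introns[introns$ref_id == id, , drop = FALSE]
      if (nrow(iv)) {
        iv <- iv[order(iv$start), , drop = FALSE]
        if (any(iv$start < 1L) || any(iv$end > nchar(seq)) || any(iv$start > iv$end)) {
          stop("intron interval out of range for record ", id)
        }
        if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)])) {
          stop("overlapping intron intervals for record ", id)
        }
        keep <- setdiff(seq_len(nchar(seq)),
                        unlist(mapply(function(a, b) a:b, iv$start, iv$end,
                                      SIMPLIFY = FALSE)))
        seq <- paste(strsplit(seq, "")[[1]][keep], collapse = "")
      }
    }
    seq <- paste0(seq, "CCA")
    # His-G: single G prepended to the intron-spliced histidine gene
    aa <- sub("^mt-", "", out$amino_acid[i])
    if (!is.na(aa) && toupper(aa) == "HIS") seq <- paste0("G", seq)
    out$sequence[i] <- seq
  }
  out$processed <- TRUE
  out
}

#' Read a reference FASTA
#'
#' Headers may carry `key=value` tokens after the identifier
#' (`svedberg=18S`, `aa=His`, `processed=1`), the convention used by
#' [write_reference_fasta()].
#'
#' @param path FASTA file.
#' @param biotype biotype assigned to all records in the file.
#' @return reference set data.frame.
#' @export
read_reference_fasta <- function(path, biotype) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  toks <- strsplit(headers, "\\s+")
  ids <- vapply(toks, `[`, character(1), 1L)
  get_tok <- function(key) {
    vapply(toks, function(tt) {
      hit <- grep(paste0("^", key, "="), tt, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA_character_
    }, character(1))
  }
  reference_set(
    ref_id = ids,
    sequence = as.character(ss),
    biotype = biotype,
    svedberg_class = get_tok("svedberg"),
    amino_acid = get_tok("aa"),
    processed = !is.na(get_tok("processed")) & get_tok("processed") == "1"
  )
}

#' Write a reference set to FASTA
#'
#' @param refs reference set data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  hdr <- refs$ref_id
  hdr <- ifelse(is.na(refs$svedberg_class), hdr,
                paste0(hdr, " svedberg=", refs$svedberg_class))
  hdr <- ifelse(is.na(refs$amino_acid), hdr,
                paste0(hdr, " aa=", refs$amino_acid))
  hdr <- ifelse(refs$processed, paste0(hdr, " processed=1"), hdr)
  ss <- Biostrings::DNAStringSet(refs$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Build the annotation index
#'
#' Packs a reference set into per-biotype `DNAStringSet`s (sense strand
#' only) plus an optional both-strand genome presence index, ready for
#' the sequential annotation cascade.
#'
#' @param refs reference set; tRNA records must be processed.
#' @param biotype_order search order; must be a permutation of the
#'   biotypes present in `refs`.
#' @param genome optional character vector of genome contig sequences
#'   (used only for the 0-mismatch presence check during rescue).
#' @return object of class `annotation_index`.
#' @export
build_annotation_index <- function(refs, biotype_order = BIOTYPE_ORDER,
                                   genome = NULL) {
  validate_reference_set(refs)
  if (any(refs$biotype == "tRNA" & !refs$processed)) {
    stop("unprocessed tRNA record(s): ",
         paste(refs$ref_id[refs$biotype == "tRNA" & !refs$processed], collapse = ", "))
  }
  present <- intersect(BIOTYPE_ORDER, unique(refs$biotype))
  if (!all(present %in% biotype_order)) {
    stop("biotype_order must contain every biotype present in refs")
  }
  sets <- lapply(stats::setNames(nm = biotype_order), function(bt) {
    rows <- refs[refs$biotype == bt, , drop = FALSE]
    ss <- Biostrings::DNAStringSet(rows$sequence)
    names(ss) <- rows$ref_id
    ss
  })
  genome_fwd <- NULL
  genome_rev <- NULL
  if (!is.null(genome)) {
    genome_fwd <- Biostrings::DNAStringSet(normalize_seq(genome))
    genome_rev <- Biostrings::reverseComplement(genome_fwd)
  }
  structure(
    list(
      sets = sets,
      refs = refs,
      biotype_order = biotype_order,
      genome_fwd = genome_fwd,
      genome_rev = genome_rev
    ),
    class = "annotation_index"
  )
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("annotation_index:",
      paste(sprintf("%s=%d", x$biotype_order,
                    vapply(x$sets[x$biotype_order], length, integer(1))),
            collapse = ", "),
      if (!is.null(x$genome_fwd)) sprintf("; genome contigs=%d", length(x$genome_fwd)) else "; no genome",
      "\n", sep = "")
  invisible(x)
}
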