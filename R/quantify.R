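# Quantification: identical-sequence clustering, miRNA-ID aggregation,
# RPM normalization and composition summaries.

#' Tally the distinct sequences of one sample
#'
#' @param seqs character vector of retained insert sequences.
#' @return named integer vector (sequence -> multiplicity).
#' @export
tally_sequences <- function(seqs) {
  tab <- table(seqs)
  stats::setNames(as.integer(tab), names(tab))
}

#' Collapse retained reads into identical-sequence clusters
#'
#' One cluster per distinct insert sequence; member reads are exactly
#' identical to the representative (no similarity radius). The cluster
#' identifier is the sequence itself, which makes cluster identity
#' stable across samples, generations and species.
#'
#' @param tallies named list `sample_id -> ` output of
#'   [tally_sequences()] (or a data.frame with `sample_id` and
#'   `sequence` columns, one row per read).
#' @return integer matrix of counts, rows = distinct sequences,
#'   columns = samples.
#' @export
cluster_identical <- function(tallies) {
  if (is.data.frame(tallies)) {
    tallies <- lapply(split(tallies$sequence, tallies$sample_id), tally_sequences)
  }
  all_seqs <- sort(unique(unlist(lapply(tallies, names), use.names = FALSE)))
  counts <- matrix(0L, nrow = length(all_seqs), ncol = length(tallies),
                   dimnames = list(all_seqs, names(tallies)))
  for (s in names(tallies)) {
    tl <- tallies[[s]]
    counts[names(tl), s] <- tl
  }
  counts
}

#' Aggregate miRNA clusters by mature miRNA identifier
#'
#' Clusters annotated as miRNA are summed per parent miRNA ID (isomiR
#' variants of the same mature miRNA collapse to one feature);
#' all other clusters keep their sequence as feature identity.
#'
#' @param counts cluster count matrix from [cluster_identical()]
#'   (rownames are sequences).
#' @param annotations annotation table from [annotate_sequences()]
#'   covering every row of `counts`.
#' @return list with `counts` (feature x sample integer matrix) and
#'   `features` (data.frame `feature_id`, `biotype`, `subtype`,
#'   `parent_class`, `primary_parent`, `sequence`; the sequence of an
#'   aggregated miRNA feature is the representative of its most
#'   abundant cluster).
#' @export
aggregate_mirna <- function(counts, annotations) {
  idx <- match(rownames(counts), annotations$sequence)
  if (anyNA(idx)) stop("unannotated sequence(s) in count matrix")
  ann <- annotations[idx, , drop = FALSE]
  is_mir <- ann$biotype == "miRNA"
  if (any(is_mir & (is.na(ann$primary_parent) | ann$primary_parent == ""))) {
    stop("miRNA cluster without parent miRNA ID")
  }
  key <- ifelse(is_mir, ann$primary_parent, ann$sequence)
  agg <- rowsum(counts, group = key, reorder = TRUE)
  storage.mode(agg) <- "integer"
  # feature metadata: take the most abundant member cluster as representative
  total <- rowSums(counts)
  ord <- order(key, -total)
  first <- !duplicated(key[ord])
  feats <- data.frame(feature_id = key[ord][first],
                      biotype = ann$biotype[ord][first],
                      subtype = ann$subtype[ord][first],
                      parent_class = ann$parent_class[ord][first],
                      primary_parent = ann$primary_parent[ord][first],
                      sequence = ann$sequence[ord][first],
                      stringsAsFactors = FALSE)
  feats <- feats[match(rownames(agg), feats$feature_id), , drop = FALSE]
  rownames(feats) <- NULL
  list(counts = agg, features = feats)
}

#' Reads-per-million normalization
#'
#' `RPM[f, s] = counts[f, s] * 1e6 / library_sizes[s]`. The library
#' size is the total number of retained (QC-passed) reads of the
#' sample, not only the annotated ones.
#'
#' @param counts feature x sample count matrix.
#' @param library_sizes named vector covering every column.
#' @return numeric RPM matrix.
#' @export
rpm_normalize <- function(counts, library_sizes) {
  libs <- library_sizes[colnames(counts)]
  if (anyNA(libs)) stop("missing library size for sample(s): ",
                        paste(colnames(counts)[is.na(libs)], collapse = ", "))
  if (any(libs <= 0)) stop("non-positive library size for sample(s): ",
                           paste(colnames(counts)[libs <= 0], collapse = ", "))
  sweep(counts, 2L, libs, function(x, l) x * 1e6 / l)
}

#' Composition summary: category percentages
#'
#' Returns the raw fractions and banker's-rounded (half-even)
#' two-decimal percentages of a named count vector.
#'
#' @param counts named non-negative counts with a positive total.
#' @return data.frame `category`, `count`, `fraction`, `percent`.
#' @export
composition_summary <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("all-zero composition")
  frac <- counts / total
  data.frame(category = names(counts),
             count = as.numeric(counts),
             fraction = as.numeric(frac),
             percent = round(100 * as.numeric(frac), 2L),
             stringsAsFactors = FALSE)
}
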