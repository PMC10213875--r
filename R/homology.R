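# Cross-species homology: seed-anchored identity matching between DE
# sncRNA sequences of two species.

#' Seed-anchored homology match between two sequences
#'
#' Argonaute-loaded small RNAs bind targets through the seed that
#' starts at the second 5' base, so the first base is ignored
#' entirely. Let `m` be the length of the longest identical block
#' anchored at base 2 of both sequences; the pair is accepted iff `m`
#' covers strictly more than `min_coverage` of the length of *each*
#' sequence.
#'
#' @param query,subject sequences (>= 15 nt).
#' @param min_coverage required coverage fraction (default 0.9,
#'   strict `>`).
#' @return `NULL` when rejected, otherwise a list with
#'   `matched_length`, `coverage_query`, `coverage_subject`.
#' @export
seed_anchored_match <- function(query, subject, min_coverage = 0.9) {
  lq <- nchar(query); ls <- nchar(subject)
  stopifnot(lq >= 15L, ls >= 15L)
  q <- utf8ToInt(substr(query, 2L, lq))
  s <- utf8ToInt(substr(subject, 2L, ls))
  n <- min(length(q), length(s))
  neq <- which(q[seq_len(n)] != s[seq_len(n)])
  m <- if (length(neq)) neq[1L] - 1L else n
  cq <- m / lq; cs <- m / ls
  if (cq > min_coverage && cs > min_coverage) {
    list(matched_length = m, coverage_query = cq, coverage_subject = cs)
  } else {
    NULL
  }
}

#' All-vs-all cross-species homolog pairs within biotype
#'
#' Runs [seed_anchored_match()] between every query and subject
#' feature of the same biotype (many-to-many pairs allowed).
#'
#' @param query_set,subject_set data.frames with `feature_id`,
#'   `sequence`, `biotype` and optionally `direction` columns (e.g.
#'   the human serum DE set and one lineage's mouse transgenerational
#'   set).
#' @param min_coverage passed to [seed_anchored_match()].
#' @return data.frame of accepted pairs: `query_id`, `subject_id`,
#'   `biotype`, `matched_length`, `coverage_query`,
#'   `coverage_subject`, `direction_query`, `direction_subject`.
#' @export
cross_species_pairs <- function(query_set, subject_set, min_coverage = 0.9) {
  out <- list()
  dirq <- query_set$direction %||% rep(NA_character_, nrow(query_set))
  dirs <- subject_set$direction %||% rep(NA_character_, nrow(subject_set))
  for (i in seq_len(nrow(query_set))) {
    same_bt <- which(subject_set$biotype == query_set$biotype[i])
    for (j in same_bt) {
      hit <- seed_anchored_match(query_set$sequence[i], subject_set$sequence[j],
                                 min_coverage = min_coverage)
      if (!is.null(hit)) {
        row <- data.frame(
          query_id = query_set$feature_id[i],
          subject_id = subject_set$feature_id[j],
          biotype = query_set$biotype[i],
          matched_length = hit$matched_length,
          coverage_query = hit$coverage_query,
          coverage_subject = hit$coverage_subject,
          direction_query = dirq[i],
          direction_subject = dirs[j],
          stringsAsFactors = FALSE)
        # tsRNA pairs also report the parent isoacceptor and fragment
        # origin when the subject set carries them
        row$subject_parent <- subject_set$primary_parent[j] %||% NA_character_
        row$subject_subtype <- subject_set$subtype[j] %||% NA_character_
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      biotype = character(), matched_length = integer(),
                      coverage_query = numeric(), coverage_subject = numeric(),
                      direction_query = character(), direction_subject = character(),
                      subject_parent = character(), subject_subtype = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
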