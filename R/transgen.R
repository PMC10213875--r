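# Transgenerational overlap calling: direction-consistent intersection
# of per-generation DE sets.

#' Intersect DE calls across F1, F2 and F3
#'
#' A feature is transgenerationally up-regulated iff it is in the up
#' set of all three generations, and down-regulated iff in all three
#' down sets; features with mixed directions are excluded. The
#' intergenerational (F1 and F2) sets are reported alongside.
#'
#' @param de_f1,de_f2,de_f3 DE tables from [run_exact_de()] for the
#'   same lineage-vs-control comparison in each generation; all three
#'   must use the same feature-identity scheme.
#' @param lineage optional lineage label carried through.
#' @return object of class `generational_call`: per-generation up/down
#'   sets, `transgenerational_up`, `transgenerational_down`,
#'   `intergenerational_up`, `intergenerational_down`, and the
#'   per-feature log2 fold-change triples of the transgenerational
#'   features.
#' @export
transgenerational_overlap <- function(de_f1, de_f2, de_f3, lineage = NA_character_) {
  des <- list(F1 = de_f1, F2 = de_f2, F3 = de_f3)
  keys <- lapply(des, function(d) sort(d$feature_id))
  if (!all(vapply(des, function(d) !anyDuplicated(d$feature_id), logical(1)))) {
    stop("duplicate feature ids within a generation's DE table")
  }
  if (!identical(keys$F1, keys$F2) || !identical(keys$F1, keys$F3)) {
    stop("inconsistent feature keying across generations")
  }
  up <- lapply(des, function(d) d$feature_id[d$de_status == "up"])
  down <- lapply(des, function(d) d$feature_id[d$de_status == "down"])
  tg_up <- sort(Reduce(intersect, up))
  tg_down <- sort(Reduce(intersect, down))
  tg <- c(tg_up, tg_down)
  fc <- if (length(tg)) {
    do.call(rbind, lapply(names(des), function(g) {
      d <- des[[g]]
      i <- match(tg, d$feature_id)
      data.frame(feature_id = tg, generation = g, log2fc = d$log2fc[i],
                 direction = rep(c("up", "down"),
                                 c(length(tg_up), length(tg_down))),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(feature_id = character(), generation = character(),
               log2fc = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(lineage = lineage,
                 up = up, down = down,
                 transgenerational_up = tg_up,
                 transgenerational_down = tg_down,
                 intergenerational_up = sort(intersect(up$F1, up$F2)),
                 intergenerational_down = sort(intersect(down$F1, down$F2)),
                 fc_table = fc),
            class = "generational_call")
}

#' @export
print.generational_call <- function(x, ...) {
  cat(sprintf("generational_call [%s]: transgenerational up=%d down=%d; intergenerational up=%d down=%d\n",
              x$lineage, length(x$transgenerational_up), length(x$transgenerational_down),
              length(x$intergenerational_up), length(x$intergenerational_down)))
  invisible(x)
}

#' Long-format fold-change table for heatmap plotting
#'
#' One row per transgenerational feature and generation, with the
#' feature's biotype when a feature table is supplied.
#'
#' @param call `generational_call`.
#' @param features optional feature table (`feature_id`, `biotype`).
#' @return data.frame `feature_id`, `biotype`, `generation`, `log2fc`,
#'   `direction`.
#' @export
export_fc_heatmap_table <- function(call, features = NULL) {
  fc <- call$fc_table
  fc$biotype <- rep(NA_character_, nrow(fc))
  if (!is.null(features)) {
    fc$biotype <- features$biotype[match(fc$feature_id, features$feature_id)]
  }
  fc[, c("feature_id", "biotype", "generation", "log2fc", "direction")]
}
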