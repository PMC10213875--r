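# Pipeline orchestration: config validation and the fixed stage order
# qc -> annotate -> quantify -> diffexpr -> transgen (-> homology),
# with a content-hashed output manifest.

#' Assemble a pipeline configuration
#'
#' @param fastq named character vector: `sample_id -> FASTQ path`.
#' @param samples sample sheet data.frame with `sample_id`, `lineage`,
#'   `generation` covering every FASTQ.
#' @param refs processed reference set (see [build_annotation_index()]).
#' @param genome optional genome contig sequence(s) for the rescue
#'   presence check.
#' @param comparisons data.frame `lineage`, `control`
#'   (default [default_comparisons()]).
#' @param qc [qc_config()].
#' @param lfc,alpha,min_log2_mean DE thresholds.
#' @param out_dir output directory for stage tables.
#' @param serum_de optional serum DE feature set (`feature_id`,
#'   `sequence`, `biotype`, `direction`) to pair against the
#'   transgenerational sets.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fastq, samples, refs, genome = NULL,
                            comparisons = default_comparisons(),
                            qc = qc_config(), lfc = 1, alpha = 0.05,
                            min_log2_mean = 1, out_dir = NULL,
                            serum_de = NULL) {
  structure(list(fastq = fastq, samples = samples, refs = refs, genome = genome,
                 comparisons = comparisons, qc = qc, lfc = lfc, alpha = alpha,
                 min_log2_mean = min_log2_mean, out_dir = out_dir,
                 serum_de = serum_de),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param cfg [pipeline_config()].
#' @return `character(0)` when valid, otherwise the violations, each
#'   naming the offending field.
#' @export
validate_config <- function(cfg) {
  v <- character()
  if (is.null(names(cfg$fastq)) || any(names(cfg$fastq) == "")) {
    v <- c(v, "fastq: paths must be named by sample_id")
  }
  missing_files <- cfg$fastq[!file.exists(cfg$fastq)]
  if (length(missing_files)) {
    v <- c(v, paste0("fastq: file not found: ", missing_files))
  }
  need_cols <- c("sample_id", "lineage", "generation")
  if (!all(need_cols %in% names(cfg$samples))) {
    v <- c(v, paste0("samples: missing column(s) ",
                     paste(setdiff(need_cols, names(cfg$samples)), collapse = ", ")))
  } else {
    unknown <- setdiff(names(cfg$fastq), cfg$samples$sample_id)
    if (length(unknown)) v <- c(v, paste0("samples: no metadata for sample ", unknown))
    comp_lin <- unique(c(cfg$comparisons$lineage, cfg$comparisons$control))
    absent <- setdiff(comp_lin, cfg$samples$lineage)
    if (length(absent)) {
      v <- c(v, paste0("comparisons: lineage not in sample sheet: ", absent))
    }
  }
  refs_ok <- tryCatch({ validate_reference_set(cfg$refs); TRUE },
                      error = function(e) { v <<- c(v, paste0("refs: ", conditionMessage(e))); FALSE })
  if (refs_ok && any(cfg$refs$biotype == "tRNA" & !cfg$refs$processed)) {
    v <- c(v, "refs: unprocessed tRNA records")
  }
  if (!inherits(cfg$qc, "qc_config")) v <- c(v, "qc: not a qc_config")
  v
}

#' Run the full pipeline
#'
#' Fixed stage order: per-sample QC, identical-sequence clustering,
#' cascade + rescue annotation of the distinct sequences, miRNA-ID
#' aggregation, RPM normalization, exact-test DE for every comparison
#' and generation, transgenerational overlap per lineage, and (when a
#' serum DE set is configured) cross-species homology. Stage outputs
#' are written as TSV under `out_dir` and content-hashed into the
#' returned manifest.
#'
#' @param cfg [pipeline_config()].
#' @return list with `qc_stats`, `library_sizes`, `annotations`,
#'   `features`, `counts`, `rpm`, `de` (nested comparison ->
#'   generation), `transgen` (per lineage), `homology` (or `NULL`),
#'   and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  v <- validate_config(cfg)
  if (length(v)) stop("invalid pipeline config:\n", paste("-", v, collapse = "\n"))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- qc: per-sample trimming/filtering and sequence tallies
  tallies <- list()
  qc_stats <- list()
  lib_sizes <- numeric()
  for (s in names(cfg$fastq)) {
    res <- tryCatch(run_qc(cfg$fastq[[s]], cfg$qc, sample_id = s),
                    error = function(e) stop("stage qc failed for sample ", s, ": ",
                                             conditionMessage(e)))
    tallies[[s]] <- tally_sequences(res$reads$sequence)
    lib_sizes[s] <- res$stats$retained
    qc_stats[[s]] <- data.frame(sample_id = s, raw = res$stats$raw,
                                retained = res$stats$retained,
                                retained_fraction = res$stats$retained_fraction)
  }
  qc_stats <- do.call(rbind, qc_stats)

  # --- quantify (clusters) + annotate (distinct sequences only)
  clusters <- cluster_identical(tallies)
  index <- build_annotation_index(cfg$refs, genome = cfg$genome)
  annotations <- annotate_sequences(rownames(clusters), index)
  agg <- aggregate_mirna(clusters, annotations)
  rpm <- rpm_normalize(agg$counts, lib_sizes)

  # --- diffexpr per comparison x generation
  de <- list()
  for (j in seq_len(nrow(cfg$comparisons))) {
    lin <- cfg$comparisons$lineage[j]
    ctl <- cfg$comparisons$control[j]
    de[[lin]] <- list()
    for (g in unique(cfg$samples$generation)) {
      ga <- cfg$samples$sample_id[cfg$samples$lineage == lin &
                                    cfg$samples$generation == g]
      gb <- cfg$samples$sample_id[cfg$samples$lineage == ctl &
                                    cfg$samples$generation == g]
      de[[lin]][[g]] <- run_exact_de(agg$counts, lib_sizes,
                                     group_a = ga, group_b = gb,
                                     lfc = cfg$lfc, alpha = cfg$alpha,
                                     min_log2_mean = cfg$min_log2_mean)
    }
  }

  # --- transgen per lineage
  transgen <- lapply(names(de), function(lin) {
    transgenerational_overlap(de[[lin]]$F1, de[[lin]]$F2, de[[lin]]$F3,
                              lineage = lin)
  })
  names(transgen) <- names(de)

  # --- homology (optional)
  homology <- NULL
  if (!is.null(cfg$serum_de)) {
    homology <- list()
    for (lin in names(transgen)) {
      tgc <- transgen[[lin]]
      ids <- c(tgc$transgenerational_up, tgc$transgenerational_down)
      subj <- agg$features[match(ids, agg$features$feature_id), , drop = FALSE]
      subj$direction <- rep(c("up", "down"),
                            c(length(tgc$transgenerational_up),
                              length(tgc$transgenerational_down)))
      homology[[lin]] <- cross_species_pairs(cfg$serum_de, subj)
    }
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    write_tsv <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    paths <- c(
      write_tsv(qc_stats, "qc_stats.tsv"),
      write_tsv(annotations, "annotations.tsv"),
      write_tsv(data.frame(feature_id = rownames(agg$counts), agg$counts,
                           check.names = FALSE), "counts.tsv"),
      write_tsv(agg$features, "features.tsv"),
      unlist(lapply(names(de), function(lin) {
        lapply(names(de[[lin]]), function(g) {
          write_tsv(de[[lin]][[g]], sprintf("de_%s_%s.tsv", lin, g))
        })
      })),
      unlist(lapply(names(transgen), function(lin) {
        write_tsv(export_fc_heatmap_table(transgen[[lin]], agg$features),
                  sprintf("transgen_%s.tsv", lin))
      })),
      if (!is.null(homology)) {
        unlist(lapply(names(homology), function(lin) {
          write_tsv(homology[[lin]], sprintf("homology_%s.tsv", lin))
        }))
      }
    )
    manifest <- data.frame(path = paths, md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE)
  }

  list(qc_stats = qc_stats, library_sizes = lib_sizes,
       annotations = annotations, features = agg$features,
       counts = agg$counts, rpm = rpm, de = de, transgen = transgen,
       homology = homology, manifest = manifest)
}
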