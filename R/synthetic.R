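# Synthetic-data generation with known truth: reference databases, a
# mini-genome, a feature panel of small-RNA sequences with planted
# lineage x generation effects, NB counts, and FASTQ reads.

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: four
#' maternal-exposure lineages (control, androgenized, obese, obese and
#' androgenized) followed over three generations with 4 sperm samples
#' per lineage and generation, plus a 9-vs-9 serum comparison in a
#' second species. Counts are negative binomial with common dispersion
#' `phi`; planted effects are direction-consistent multiplicative fold
#' changes.
#'
#' @param seed integer seed; one pseudo-random stream per run.
#' @param lineages lineage labels; the first is the unexposed control.
#' @param generations generation labels.
#' @param n_per_group samples per lineage x generation.
#' @param depth nominal clean-read depth per sample.
#' @param phi NB dispersion of the counts (variance `mu + phi mu^2`).
#' @param n_mirna,n_trna,n_pirna,n_other,n_tsrna,n_rsrna panel sizes
#'   per biotype (references / fragment features).
#' @param n_rescue_decoys off-genome 1-mismatch decoys that exercise
#'   the rescue pass.
#' @param fold_change planted effect size (>1).
#' @param n_transgen named vector: planted direction-consistent
#'   (F1-F3) DE features per exposed lineage.
#' @param n_intergen planted F1+F2-only DE features per exposed
#'   lineage.
#' @param n_f1only planted F1-only DE features per exposed lineage.
#' @param error_rate per-base substitution error rate of the reads.
#' @param adaptor_fraction fraction of reads carrying the 3' adaptor
#'   (adaptor-free reads are discarded by QC).
#' @param lowq_fraction fraction of reads given low base qualities.
#' @param isomir_fraction fraction of miRNA reads emitted as the
#'   3'-trimmed isomiR of the mature sequence.
#' @param lib_jitter library-size jitter half-width (fraction).
#' @param adaptor adaptor sequence appended to reads.
#' @param n_serum_per_group serum samples per group in the
#'   cross-species comparison.
#' @param n_homologs named vector: planted cross-species homolog pairs
#'   per exposed lineage.
#' @param n_homolog_decoys internally mutated copies planted DE in the
#'   serum set that must be rejected by the homology matcher.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       lineages = c("CD_Veh", "CD_DHT", "HFHS_Veh", "HFHS_DHT"),
                       generations = c("F1", "F2", "F3"),
                       n_per_group = 4L,
                       depth = 2e5,
                       phi = 0.1,
                       n_mirna = 30L, n_trna = 8L, n_pirna = 30L,
                       n_other = 8L, n_tsrna = 36L, n_rsrna = 36L,
                       n_rescue_decoys = 6L,
                       fold_change = 8,
                       n_transgen = c(CD_DHT = 4L, HFHS_Veh = 12L, HFHS_DHT = 4L),
                       n_intergen = c(CD_DHT = 4L, HFHS_Veh = 4L, HFHS_DHT = 4L),
                       n_f1only = c(CD_DHT = 3L, HFHS_Veh = 3L, HFHS_DHT = 3L),
                       error_rate = 0,
                       adaptor_fraction = 0.95,
                       lowq_fraction = 0.02,
                       isomir_fraction = 0.3,
                       lib_jitter = 0.2,
                       adaptor = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       n_serum_per_group = 9L,
                       n_homologs = c(CD_DHT = 2L, HFHS_Veh = 3L, HFHS_DHT = 1L),
                       n_homolog_decoys = 8L) {
  stopifnot(fold_change > 1, phi >= 0, seed == as.integer(seed))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, len) {
  vapply(rep_len(len, n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_base <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  paste0(substr(seq, 1L, pos - 1L), new, substr(seq, pos + 1L, nchar(seq)))
}

#' Generate synthetic reference databases and a mini-genome
#'
#' Emits mature miRNAs, raw tRNA genes (one histidine, two with
#' introns), the full rRNA class set with 18S, 5.8S and 28S embedded
#' verbatim inside a 45S precursor (so Svedberg precedence is
#' exercised), piRNAs, other ncRNAs, and a single-contig mini-genome
#' concatenating all gene loci. A configurable number of piRNA-like
#' decoys are 1-mismatch mutants of rRNA/tRNA windows excluded from
#' the genome, to exercise the rescue pass; half of them are placed in
#' the piRNA database, half in no database.
#'
#' @param cfg [sim_config()].
#' @param .reseed set the seed from `cfg` (default `TRUE`; internal
#'   callers that manage the stream pass `FALSE`).
#' @return list with `refs` (processed reference set), `raw_trna`,
#'   `introns`, `genome` (character), and `rescue_decoys` (data.frame
#'   with the decoy truth).
#' @export
generate_references <- function(cfg = sim_config(), .reseed = TRUE) {
  if (.reseed) set.seed(cfg$seed)
  # --- miRNA: mature 22-mers
  mirna <- reference_set(
    ref_id = sprintf("mmu-miR-%03d-3p", seq_len(cfg$n_mirna)),
    sequence = random_dna(cfg$n_mirna, 22L),
    biotype = "miRNA"
  )
  # --- tRNA: raw genes; His and one Gly carry an intron
  aa_pool <- c("His", "Glu", "Gly", "Val", "Gln", "Lys", "mt-Glu", "mt-Val",
               "Ala", "Asp", "Ser", "Leu")
  aas <- aa_pool[seq_len(cfg$n_trna)]
  raw_len <- sample(70:76, cfg$n_trna, replace = TRUE)
  intron_carriers <- c(1L, 3L) # His and Gly genes get a 10/12-nt intron
  raw_len[intron_carriers] <- raw_len[intron_carriers] + c(10L, 12L)
  raw_trna <- reference_set(
    ref_id = sprintf("tRNA-%s-%d", aas, seq_len(cfg$n_trna)),
    sequence = random_dna(cfg$n_trna, raw_len),
    biotype = "tRNA", amino_acid = aas
  )
  introns <- data.frame(
    ref_id = raw_trna$ref_id[intron_carriers],
    start = c(38L, 40L),
    end = c(47L, 51L),
    stringsAsFactors = FALSE
  )
  trna <- preprocess_trna(raw_trna, introns)
  # --- rRNA: classes; 18S, 5.8S, 28S verbatim inside the 45S precursor
  r18 <- random_dna(1L, 500L); r58 <- random_dna(1L, 150L); r28 <- random_dna(1L, 700L)
  ets1 <- random_dna(1L, 80L); its1 <- random_dna(1L, 60L)
  its2 <- random_dna(1L, 60L); ets2 <- random_dna(1L, 70L)
  r45 <- paste0(ets1, r18, its1, r58, its2, r28, ets2)
  rrna <- reference_set(
    ref_id = c("rRNA-4.5S", "rRNA-5S", "rRNA-5.8S", "rRNA-12S-mt",
               "rRNA-16S-mt", "rRNA-18S", "rRNA-28S", "rRNA-45S"),
    sequence = c(random_dna(1L, 95L), random_dna(1L, 120L), r58,
                 random_dna(1L, 300L), random_dna(1L, 420L), r18, r28, r45),
    biotype = "rRNA",
    svedberg_class = c("4.5S", "5S", "5.8S", "12S", "16S", "18S", "28S", "45S")
  )
  # --- piRNA and other ncRNA
  pirna <- reference_set(
    ref_id = sprintf("piR-m%04d", seq_len(cfg$n_pirna)),
    sequence = random_dna(cfg$n_pirna, sample(26:31, cfg$n_pirna, replace = TRUE)),
    biotype = "piRNA"
  )
  other <- reference_set(
    ref_id = sprintf("ncRNA-%02d", seq_len(cfg$n_other)),
    sequence = random_dna(cfg$n_other, sample(80:150, cfg$n_other, replace = TRUE)),
    biotype = "other_ncRNA"
  )
  # --- mini-genome: concatenation of all gene loci (rDNA via the 45S
  #     precursor; miRNA/piRNA loci with flanks); rescue decoys are
  #     excluded by construction
  flank <- function(seqs, w = 25L) {
    vapply(seqs, function(s) paste0(random_dna(1L, w), s, random_dna(1L, w)),
           character(1), USE.NAMES = FALSE)
  }
  genome <- paste(c(flank(mirna$sequence),
                    raw_trna$sequence,
                    rrna$sequence[rrna$svedberg_class %in% c("4.5S", "5S", "12S", "16S", "45S")],
                    flank(pirna$sequence),
                    other$sequence),
                  collapse = "")
  refs <- rbind(mirna, rrna, trna, pirna, other)
  # --- rescue decoys: 1-mismatch mutants of rRNA/tRNA windows, absent
  #     from the genome and from every database at 0 mismatches
  idx0 <- build_annotation_index(refs, genome = genome)
  sources <- rep(c("rRNA-18S", "rRNA-28S", "rRNA-45S",
                   trna$ref_id[c(2L, 4L, 1L)]), length.out = cfg$n_rescue_decoys)
  decoys <- data.frame(feature_id = sprintf("rescue_%02d", seq_len(cfg$n_rescue_decoys)),
                       source_ref = sources, sequence = NA_character_,
                       in_pirna_db = seq_len(cfg$n_rescue_decoys) %% 2L == 1L,
                       exp_biotype = NA_character_, exp_subtype = NA_character_,
                       exp_parent_class = NA_character_,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(decoys))) {
    src <- refs[refs$ref_id == decoys$source_ref[i], ]
    for (try in 1:50) {
      w <- sample(24:30, 1L)
      if (src$biotype == "tRNA" && i %% 3L == 0L) {
        # anchor some tRNA decoys at the CCA end for a 3p_CCA rescue truth
        off <- nchar(src$sequence) - w + 1L
      } else {
        off <- sample(seq_len(nchar(src$sequence) - w + 1L), 1L)
      }
      win <- substr(src$sequence, off, off + w - 1L)
      mut <- mutate_base(win, sample(2:(w - 1L), 1L))
      clean <- !in_genome(mut, idx0) &&
        all(vapply(BIOTYPE_ORDER, function(bt)
          nrow(match_sequence(mut, idx0, biotype = bt, max_mismatch = 0L)) == 0L,
          logical(1)))
      if (clean) {
        decoys$sequence[i] <- mut
        if (src$biotype == "rRNA") {
          hits <- match_sequence(mut, idx0, biotype = "rRNA", max_mismatch = 1L)
          par <- assign_rsrna_parent(hits, refs)
          decoys$exp_biotype[i] <- "rsRNA"
          decoys$exp_parent_class[i] <- par$parent_class
        } else {
          decoys$exp_biotype[i] <- "tsRNA"
          decoys$exp_subtype[i] <- classify_tsrna(off, w, nchar(src$sequence))
        }
        break
      }
    }
    if (is.na(decoys$sequence[i])) stop("could not construct rescue decoy ", i)
  }
  pirna_extra <- reference_set(
    ref_id = sprintf("piR-x%02d", which(decoys$in_pirna_db)),
    sequence = decoys$sequence[decoys$in_pirna_db],
    biotype = "piRNA"
  )
  refs <- rbind(refs, pirna_extra)
  list(refs = refs, raw_trna = raw_trna, introns = introns,
       genome = genome, rescue_decoys = decoys)
}

# Feature panel: the distinct small-RNA sequences reads are drawn
# from, with their expected (truth) annotation.
build_feature_panel <- function(refdb, cfg) {
  refs <- refdb$refs
  panel <- list()
  add <- function(feature_id, biotype, sequence, subtype = NA_character_,
                  parent_class = NA_character_, parent_id = NA_character_,
                  rescued = FALSE) {
    data.frame(feature_id = feature_id, biotype = biotype, sequence = sequence,
               exp_subtype = subtype, exp_parent_class = parent_class,
               parent_id = parent_id, exp_rescued = rescued,
               stringsAsFactors = FALSE)
  }
  mir <- refs[refs$biotype == "miRNA", ]
  panel$mirna <- add(mir$ref_id, "miRNA", mir$sequence, parent_id = mir$ref_id)
  # tsRNA fragments: cycle tRNA x subtype, lengths 27-36
  trna <- refs[refs$biotype == "tRNA", ]
  subtypes <- c("tsRNA_5p", "tsRNA_3p_CCA", "tsRNA_3p", "tsRNA_internal")
  ts <- list()
  for (k in seq_len(cfg$n_tsrna)) {
    repeat {
      tr <- trna[sample(nrow(trna), 1L), ]
      st <- subtypes[((k - 1L) %% 4L) + 1L]
      L <- nchar(tr$sequence)
      w <- sample(27:36, 1L)
      off <- switch(st,
                    tsRNA_5p = 1L,
                    tsRNA_3p_CCA = L - w + 1L,
                    tsRNA_3p = L - 3L - w + 1L,
                    tsRNA_internal = sample(2:(L - 4L - w + 1L), 1L))
      seq <- substr(tr$sequence, off, off + w - 1L)
      # a short fragment can satisfy several subtype definitions; keep
      # the truth consistent with classification precedence
      truth <- classify_tsrna(off, w, L)
      key <- seq
      if (!key %in% vapply(ts, `[[`, character(1), "sequence")) break
    }
    ts[[k]] <- add(sprintf("tsRNA_%03d", k), "tsRNA", seq, subtype = truth,
                   parent_id = tr$ref_id)
  }
  panel$tsrna <- do.call(rbind, ts)
  # rsRNA fragments: windows of rRNA class records (plus a few from the
  # 45S-only spacer regions), lengths 20-40
  rrna <- refs[refs$biotype == "rRNA", ]
  class_pool <- rep(c("18S", "28S", "5.8S", "12S", "16S", "5S", "4.5S", "45S"),
                    length.out = cfg$n_rsrna)
  rs <- list()
  for (k in seq_len(cfg$n_rsrna)) {
    cl <- class_pool[k]
    rec <- rrna[rrna$svedberg_class == cl, ]
    repeat {
      w <- sample(20:40, 1L)
      if (cl == "45S") {
        # draw from the 5' external spacer so the fragment is 45S-only
        off <- sample(seq_len(80L - w + 1L), 1L)
      } else {
        off <- sample(seq_len(nchar(rec$sequence) - w + 1L), 1L)
      }
      seq <- substr(rec$sequence, off, off + w - 1L)
      if (!seq %in% vapply(rs, `[[`, character(1), "sequence")) break
    }
    rs[[k]] <- add(sprintf("rsRNA_%03d", k), "rsRNA", seq, parent_class = cl,
                   parent_id = rec$ref_id)
  }
  panel$rsrna <- do.call(rbind, rs)
  pir <- refs[refs$biotype == "piRNA" & !grepl("^piR-x", refs$ref_id), ]
  panel$pirna <- add(pir$ref_id, "piRNA", pir$sequence, parent_id = pir$ref_id)
  oth <- refs[refs$biotype == "other_ncRNA", ]
  ot <- list()
  for (k in seq_len(cfg$n_other)) {
    rec <- oth[k, ]
    w <- sample(20:40, 1L)
    off <- sample(seq_len(nchar(rec$sequence) - w + 1L), 1L)
    ot[[k]] <- add(sprintf("oncRNA_%02d", k), "other_ncRNA",
                   substr(rec$sequence, off, off + w - 1L), parent_id = rec$ref_id)
  }
  panel$other <- do.call(rbind, ot)
  dec <- refdb$rescue_decoys
  panel$rescue <- add(dec$feature_id, dec$exp_biotype, dec$sequence,
                      subtype = dec$exp_subtype, parent_class = dec$exp_parent_class,
                      parent_id = dec$source_ref, rescued = TRUE)
  panel <- do.call(rbind, panel)
  rownames(panel) <- NULL
  if (anyDuplicated(panel$sequence)) stop("duplicate sequences in feature panel")
  panel
}

#' Default lineage-vs-control comparisons
#'
#' Each exposed lineage is compared with its parallel-bred control:
#' the androgenized and obese lineages against the unexposed control,
#' the combined lineage against the obese one.
#' @return data.frame `lineage`, `control`.
#' @export
default_comparisons <- function() {
  data.frame(lineage = c("CD_DHT", "HFHS_Veh", "HFHS_DHT"),
             control = c("CD_Veh", "CD_Veh", "HFHS_Veh"),
             stringsAsFactors = FALSE)
}

# Planted effects: feature x lineage x generation fold changes,
# direction-consistent for the transgenerational set.
plant_effects <- function(panel, cfg) {
  eligible <- panel$feature_id[!panel$exp_rescued]
  pool <- sample(eligible) # randomized, then consumed disjointly
  take <- function(n) {
    if (n > length(pool)) {
      stop("feature panel too small for the requested planted effects")
    }
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  rows <- list()
  for (lin in names(cfg$n_transgen)) {
    n_tg <- cfg$n_transgen[[lin]]
    tg <- take(n_tg)
    dir_tg <- rep(c("up", "down"), length.out = n_tg)
    for (g in cfg$generations) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = tg, lineage = lin, generation = g, direction = dir_tg,
        fold_change = cfg$fold_change, class = "transgenerational",
        stringsAsFactors = FALSE)
    }
    n_ig <- cfg$n_intergen[[lin]]
    ig <- take(n_ig)
    dir_ig <- rep(c("up", "down"), length.out = n_ig)
    for (g in c("F1", "F2")) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = ig, lineage = lin, generation = g, direction = dir_ig,
        fold_change = cfg$fold_change, class = "intergenerational",
        stringsAsFactors = FALSE)
    }
    n_f1 <- cfg$n_f1only[[lin]]
    f1 <- take(n_f1)
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = f1, lineage = lin, generation = "F1",
      direction = rep(c("up", "down"), length.out = n_f1),
      fold_change = cfg$fold_change, class = "F1_only",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate the multi-lineage count truth
#'
#' Draws per-feature baseline abundances (normalized so that realized
#' RPM matches the intended scale), applies the planted effects, and
#' draws NB counts for every sample of the design. Planted features
#' get baselines of at least 100 RPM so they clear the low-expression
#' filter by a wide margin.
#'
#' @param cfg [sim_config()].
#' @param panel feature panel from the reference generator.
#' @param .reseed see [generate_references()].
#' @return list with `counts`, `mu`, `samples` (sample sheet),
#'   `effects`, `lib_factors`, `base_rpm`.
#' @export
simulate_counts <- function(cfg, panel, .reseed = TRUE) {
  if (.reseed) set.seed(cfg$seed + 1L)
  effects <- plant_effects(panel, cfg)
  nf <- nrow(panel)
  planted <- panel$feature_id %in% effects$feature_id
  base_rpm <- numeric(nf)
  base_rpm[planted] <- exp(stats::runif(sum(planted), log(150), log(1000)))
  base_rpm[!planted] <- exp(stats::runif(sum(!planted), log(20), log(30000)))
  # scale the background so total abundance is one million RPM
  base_rpm[!planted] <- base_rpm[!planted] *
    (1e6 - sum(base_rpm[planted])) / sum(base_rpm[!planted])
  names(base_rpm) <- panel$feature_id
  samples <- expand.grid(rep = seq_len(cfg$n_per_group),
                         generation = cfg$generations,
                         lineage = cfg$lineages,
                         stringsAsFactors = FALSE)[, c("lineage", "generation", "rep")]
  samples$sample_id <- sprintf("%s_%s_s%d", samples$lineage, samples$generation,
                               samples$rep)
  # multiplier per feature x (lineage, generation); the combined
  # lineage inherits the obese multipliers and adds its own
  mult <- array(1, dim = c(nf, length(cfg$lineages), length(cfg$generations)),
                dimnames = list(panel$feature_id, cfg$lineages, cfg$generations))
  for (i in seq_len(nrow(effects))) {
    f <- effects$feature_id[i]; l <- effects$lineage[i]; g <- effects$generation[i]
    m <- if (effects$direction[i] == "up") effects$fold_change[i] else 1 / effects$fold_change[i]
    mult[f, l, g] <- mult[f, l, g] * m
  }
  comps <- default_comparisons()
  for (j in seq_len(nrow(comps))) {
    if (comps$control[j] != cfg$lineages[1L]) {
      mult[, comps$lineage[j], ] <- mult[, comps$lineage[j], ] *
        mult[, comps$control[j], ]
    }
  }
  lib_factors <- stats::runif(nrow(samples), 1 - cfg$lib_jitter, 1 + cfg$lib_jitter)
  names(lib_factors) <- samples$sample_id
  mu <- matrix(0, nrow = nf, ncol = nrow(samples),
               dimnames = list(panel$feature_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    mu[, s] <- base_rpm * mult[, samples$lineage[s], samples$generation[s]] *
      cfg$depth * lib_factors[s] / 1e6
  }
  counts <- matrix(0L, nrow = nf, ncol = nrow(samples), dimnames = dimnames(mu))
  for (s in seq_len(ncol(mu))) {
    counts[, s] <- if (cfg$phi > 0) {
      stats::rnbinom(nf, mu = mu[, s], size = 1 / cfg$phi)
    } else {
      stats::rpois(nf, lambda = mu[, s])
    }
  }
  list(counts = counts, mu = mu, samples = samples, effects = effects,
       lib_factors = lib_factors, base_rpm = base_rpm)
}

# qualities: one long draw converted to per-read strings
quality_strings <- function(lens, lowq, offset = 33L) {
  total <- sum(lens)
  q <- integer(total)
  is_low <- rep(lowq, lens)
  q[!is_low] <- sample(28:40, sum(!is_low), replace = TRUE)
  q[is_low] <- sample(c(10L, 35L), sum(is_low), replace = TRUE)
  chars <- intToUtf8(q + offset, multiple = FALSE)
  ends <- cumsum(lens)
  substring(chars, ends - lens + 1L, ends)
}

inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, error_rate)
  for (i in which(n_err > 0L)) {
    for (p in sample(lens[i], n_err[i])) seqs[i] <- mutate_base(seqs[i], p)
  }
  seqs
}

#' Synthesize FASTQ reads for one sample
#'
#' Emits `counts[f]` reads of each feature's sequence (miRNA features
#' emit the 3'-trimmed isomiR for a configurable fraction of reads),
#' appends the adaptor to the configured fraction, injects
#' substitution errors, assigns Phred+33 qualities (a configurable
#' fraction of reads gets low-quality bases), and writes FASTQ.
#'
#' @param feature_counts named integer vector (feature_id -> count).
#' @param panel feature panel.
#' @param cfg [sim_config()].
#' @param path output FASTQ path.
#' @param sample_id read-id prefix.
#' @return invisibly, the number of reads written.
#' @export
synthesize_reads <- function(feature_counts, panel, cfg, path, sample_id = "S") {
  idx <- rep(seq_len(nrow(panel)), feature_counts[panel$feature_id])
  seqs <- panel$sequence[idx]
  is_mir <- panel$biotype[idx] == "miRNA"
  iso <- is_mir & stats::runif(length(idx)) < cfg$isomir_fraction
  seqs[iso] <- substr(seqs[iso], 1L, nchar(seqs[iso]) - 1L)
  seqs <- inject_errors(seqs, cfg$error_rate)
  has_ad <- stats::runif(length(idx)) < cfg$adaptor_fraction
  full <- ifelse(has_ad, paste0(seqs, cfg$adaptor), seqs)
  lowq <- stats::runif(length(idx)) < cfg$lowq_fraction
  quals <- quality_strings(nchar(full), lowq)
  reads <- data.frame(
    read_id = sprintf("%s:%06d:%s", sample_id, seq_along(idx), panel$feature_id[idx]),
    sequence = full, qualities = quals, stringsAsFactors = FALSE)
  write_fastq(reads, path)
  invisible(nrow(reads))
}

#' Simulate the serum cross-species comparison
#'
#' Builds a serum feature set containing planted homologs of mouse
#' transgenerational features (first base and a sub-10%-of-length 3'
#' block mutated, guaranteeing seed-anchored acceptance), internally
#' mutated decoys (guaranteed rejection) that are nevertheless planted
#' DE, serum-specific DE features, and null features; then draws NB
#' counts for the two serum groups.
#'
#' @param cfg [sim_config()].
#' @param panel mouse feature panel.
#' @param effects planted mouse effects (for homolog sources and
#'   directions).
#' @param .reseed see [generate_references()].
#' @return list with `features` (serum panel incl. homology truth),
#'   `counts`, `samples`, `lib_sizes`, `pair_truth`.
#' @export
simulate_human_serum <- function(cfg, panel, effects, .reseed = TRUE) {
  if (.reseed) set.seed(cfg$seed + 2L)
  tg <- unique(effects[effects$class == "transgenerational",
                       c("feature_id", "lineage", "direction")])
  rows <- list(); pair_rows <- list()
  used <- character()
  for (lin in names(cfg$n_homologs)) {
    cand <- tg[tg$lineage == lin & !tg$feature_id %in% used, , drop = FALSE]
    pick <- cand[seq_len(min(cfg$n_homologs[[lin]], nrow(cand))), , drop = FALSE]
    used <- c(used, pick$feature_id)
    for (i in seq_len(nrow(pick))) {
      src <- panel[panel$feature_id == pick$feature_id[i], ]
      L <- nchar(src$sequence)
      t3 <- max(0L, as.integer(ceiling(0.1 * L - 1) - 1L))
      while (t3 > 0L && (L - 1L - t3) / L <= 0.9) t3 <- t3 - 1L
      hseq <- mutate_base(src$sequence, 1L)
      for (p in seq_len(t3)) hseq <- mutate_base(hseq, L - p + 1L)
      hid <- sprintf("hsa_hom_%s", src$feature_id)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = hid, biotype = src$biotype, sequence = hseq,
        role = "homolog", de_direction = pick$direction[i],
        mouse_feature = src$feature_id, stringsAsFactors = FALSE)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        query_id = hid, subject_id = src$feature_id, lineage = pick$lineage[i],
        biotype = src$biotype, stringsAsFactors = FALSE)
    }
  }
  # internally mutated decoys: DE in serum but must never pair
  decoy_src <- panel[panel$feature_id %in% setdiff(tg$feature_id, used), ]
  if (nrow(decoy_src) < cfg$n_homolog_decoys) {
    extra <- panel[!panel$feature_id %in% c(used, decoy_src$feature_id) &
                     !panel$exp_rescued, ]
    decoy_src <- rbind(decoy_src, extra[seq_len(cfg$n_homolog_decoys - nrow(decoy_src)), ])
  }
  decoy_src <- decoy_src[seq_len(cfg$n_homolog_decoys), ]
  for (i in seq_len(nrow(decoy_src))) {
    L <- nchar(decoy_src$sequence[i])
    dseq <- mutate_base(decoy_src$sequence[i], as.integer(floor(L / 2)))
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = sprintf("hsa_dec_%02d", i), biotype = decoy_src$biotype[i],
      sequence = dseq, role = "reject_decoy",
      de_direction = sample(c("up", "down"), 1L),
      mouse_feature = decoy_src$feature_id[i], stringsAsFactors = FALSE)
  }
  n_spec <- 5L
  rows[[length(rows) + 1L]] <- data.frame(
    feature_id = sprintf("hsa_de_%02d", seq_len(n_spec)),
    biotype = sample(c("miRNA", "piRNA", "rsRNA"), n_spec, replace = TRUE),
    sequence = random_dna(n_spec, sample(20:30, n_spec, replace = TRUE)),
    role = "serum_specific", de_direction = rep(c("up", "down"), length.out = n_spec),
    mouse_feature = NA_character_, stringsAsFactors = FALSE)
  n_null <- 30L
  rows[[length(rows) + 1L]] <- data.frame(
    feature_id = sprintf("hsa_null_%02d", seq_len(n_null)),
    biotype = sample(c("miRNA", "piRNA", "rsRNA", "tsRNA"), n_null, replace = TRUE),
    sequence = random_dna(n_null, sample(20:34, n_null, replace = TRUE)),
    role = "null", de_direction = NA_character_,
    mouse_feature = NA_character_, stringsAsFactors = FALSE)
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  n <- cfg$n_serum_per_group
  samples <- data.frame(
    sample_id = c(sprintf("serum_case_%02d", seq_len(n)),
                  sprintf("serum_ctrl_%02d", seq_len(n))),
    group = rep(c("case", "control"), each = n), stringsAsFactors = FALSE)
  nf <- nrow(features)
  de_feat <- !is.na(features$de_direction)
  # planted features are kept low-abundance so their fold changes do
  # not distort the library composition of the null features
  base_rpm <- numeric(nf)
  base_rpm[de_feat] <- exp(stats::runif(sum(de_feat), log(150), log(800)))
  base_rpm[!de_feat] <- exp(stats::runif(sum(!de_feat), log(500), log(50000)))
  base_rpm[!de_feat] <- base_rpm[!de_feat] *
    (1e6 - sum(base_rpm[de_feat])) / sum(base_rpm[!de_feat])
  names(base_rpm) <- features$feature_id
  lib_factors <- stats::runif(nrow(samples), 1 - cfg$lib_jitter, 1 + cfg$lib_jitter)
  mu <- outer(base_rpm, lib_factors * cfg$depth / 1e6)
  de <- !is.na(features$de_direction)
  m <- ifelse(features$de_direction[de] == "up", cfg$fold_change, 1 / cfg$fold_change)
  mu[de, samples$group == "case"] <- mu[de, samples$group == "case"] * m
  counts <- matrix(0L, nf, nrow(samples),
                   dimnames = list(features$feature_id, samples$sample_id))
  for (s in seq_len(ncol(mu))) {
    counts[, s] <- if (cfg$phi > 0) {
      stats::rnbinom(nf, mu = mu[, s], size = 1 / cfg$phi)
    } else {
      stats::rpois(nf, lambda = mu[, s])
    }
  }
  lib_sizes <- round(colSums(counts) / 0.98) # a few reads never cluster
  names(lib_sizes) <- samples$sample_id
  pair_truth <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(query_id = character(), subject_id = character(),
               lineage = character(), biotype = character())
  list(features = features, counts = counts, samples = samples,
       lib_sizes = lib_sizes, pair_truth = pair_truth)
}

#' DE feature key of a panel feature
#'
#' Quantified features are keyed by mature miRNA ID for miRNA and by
#' the exact sequence for every other biotype; this maps panel truth
#' onto that scheme.
#'
#' @param panel feature panel.
#' @param feature_id panel feature ids (default: all).
#' @return character vector of DE feature keys.
#' @export
feature_de_key <- function(panel, feature_id = panel$feature_id) {
  i <- match(feature_id, panel$feature_id)
  ifelse(panel$biotype[i] == "miRNA", panel$feature_id[i], panel$sequence[i])
}

#' Trace observed sequences back to their generating panel feature
#'
#' A retained read is either a feature sequence verbatim, its
#' 3'-trimmed isomiR (miRNA), or a 5' prefix left by a spurious
#' adaptor match inside an adaptor-free read; in every case the
#' observed sequence is a prefix of exactly one panel sequence.
#'
#' @param seqs observed distinct sequences.
#' @param panel feature panel.
#' @return integer row indices into `panel` (`NA` when untraceable).
#' @export
trace_panel_feature <- function(seqs, panel) {
  exact <- match(seqs, panel$sequence)
  todo <- which(is.na(exact))
  for (i in todo) {
    hit <- which(startsWith(panel$sequence, seqs[i]))
    if (length(hit) == 1L) exact[i] <- hit
  }
  exact
}

#' Score a pipeline run against the simulation truth
#'
#' Computes the truth-recovery metrics of a [run_pipeline()] result on
#' a [simulate_dataset()] study: annotation accuracy (every distinct
#' retained sequence traced back to its generating feature), tsRNA
#' subtype and rescue-flag accuracy on the panel sequences, DE
#' sensitivity and false-direction rate over all planted effects,
#' exact recovery of the per-lineage transgenerational sets, and exact
#' recovery of the planted cross-species homolog pairs (running the
#' serum DE and the pairing as part of the evaluation).
#'
#' @param sim output of [simulate_dataset()].
#' @param res output of [run_pipeline()] on the simulated FASTQ.
#' @return list of metrics; see details in the returned names.
#' @export
evaluate_truth_recovery <- function(sim, res) {
  pan <- sim$panel
  eff <- sim$mouse$effects
  # annotation accuracy over all distinct retained sequences
  tr <- trace_panel_feature(res$annotations$sequence, pan)
  ann_acc <- mean(!is.na(tr) & res$annotations$biotype == pan$biotype[tr])
  exact <- match(res$annotations$sequence, pan$sequence)
  on_panel <- !is.na(exact)
  sub_truth <- pan$exp_subtype[exact[on_panel]]
  sub_ok <- res$annotations$subtype[on_panel] == sub_truth
  subtype_acc <- mean(sub_ok[!is.na(sub_truth)])
  rescue_ok <- all(res$annotations$rescued[on_panel] == pan$exp_rescued[exact[on_panel]])
  # DE sensitivity / false direction over every planted effect
  hits <- 0L; wrong <- 0L; total <- 0L
  tg_equal <- logical()
  for (lin in unique(eff$lineage)) {
    for (g in unique(eff$generation[eff$lineage == lin])) {
      e <- eff[eff$lineage == lin & eff$generation == g, , drop = FALSE]
      keys <- feature_de_key(pan, e$feature_id)
      d <- res$de[[lin]][[g]]
      st <- d$de_status[match(keys, d$feature_id)]
      total <- total + nrow(e)
      hits <- hits + sum(st == e$direction, na.rm = TRUE)
      wrong <- wrong + sum(!is.na(st) & st != "not_de" & st != e$direction)
    }
    truth_keys <- sort(feature_de_key(
      pan, unique(eff$feature_id[eff$lineage == lin &
                                   eff$class == "transgenerational"])))
    got <- sort(c(res$transgen[[lin]]$transgenerational_up,
                  res$transgen[[lin]]$transgenerational_down))
    tg_equal[lin] <- identical(got, truth_keys)
  }
  # serum DE + cross-species pairing against the planted pair truth
  serum <- sim$serum
  case <- serum$samples$sample_id[serum$samples$group == "case"]
  ctrl <- serum$samples$sample_id[serum$samples$group == "control"]
  hde <- run_exact_de(serum$counts, serum$lib_sizes, case, ctrl)
  de_set <- hde[hde$de_status != "not_de", , drop = FALSE]
  i <- match(de_set$feature_id, serum$features$feature_id)
  query <- data.frame(feature_id = de_set$feature_id,
                      sequence = serum$features$sequence[i],
                      biotype = serum$features$biotype[i],
                      direction = de_set$de_status,
                      stringsAsFactors = FALSE)
  pairs <- list()
  for (lin in names(res$transgen)) {
    tgc <- res$transgen[[lin]]
    ids <- c(tgc$transgenerational_up, tgc$transgenerational_down)
    if (!length(ids)) next
    subj <- res$features[match(ids, res$features$feature_id), , drop = FALSE]
    subj$direction <- rep(c("up", "down"),
                          c(length(tgc$transgenerational_up),
                            length(tgc$transgenerational_down)))
    pr <- cross_species_pairs(query, subj)
    if (nrow(pr)) { pr$lineage <- lin; pairs[[lin]] <- pr }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(query_id = character(), subject_id = character())
  truth_pairs <- sim$serum$pair_truth
  truth_pairs$subject_key <- feature_de_key(pan, truth_pairs$subject_id)
  pairs_equal <- identical(sort(paste(pairs$query_id, pairs$subject_id)),
                           sort(paste(truth_pairs$query_id, truth_pairs$subject_key)))
  list(annotation_accuracy = ann_acc,
       subtype_accuracy = subtype_acc,
       rescue_flags_correct = rescue_ok,
       de_sensitivity = hits / total,
       false_direction_rate = wrong / total,
       transgen_sets_equal = tg_equal,
       n_planted_effects = total,
       serum_de_called = nrow(de_set),
       homolog_pairs = pairs,
       homolog_pairs_equal = pairs_equal,
       n_planted_pairs = nrow(truth_pairs))
}

#' Simulate a complete study with known truth
#'
#' One call, one seed, one pseudo-random stream: references and
#' mini-genome, mouse feature panel, planted effects, NB counts,
#' optional FASTQ synthesis, and the serum comparison.
#'
#' @param cfg [sim_config()].
#' @param fastq_dir when non-`NULL`, write per-sample FASTQ files
#'   there.
#' @return list with `cfg`, `refdb`, `panel`, `mouse` (counts, truth),
#'   `serum`, and `fastq` (named file paths or `NULL`).
#' @export
simulate_dataset <- function(cfg = sim_config(), fastq_dir = NULL) {
  set.seed(cfg$seed)
  refdb <- generate_references(cfg, .reseed = FALSE)
  panel <- build_feature_panel(refdb, cfg)
  mouse <- simulate_counts(cfg, panel, .reseed = FALSE)
  serum <- simulate_human_serum(cfg, panel, mouse$effects, .reseed = FALSE)
  fastq <- NULL
  if (!is.null(fastq_dir)) {
    dir.create(fastq_dir, showWarnings = FALSE, recursive = TRUE)
    fastq <- stats::setNames(
      file.path(fastq_dir, paste0(mouse$samples$sample_id, ".fastq")),
      mouse$samples$sample_id)
    for (s in mouse$samples$sample_id) {
      synthesize_reads(mouse$counts[, s], panel, cfg, fastq[[s]], sample_id = s)
    }
  }
  list(cfg = cfg, refdb = refdb, panel = panel, mouse = mouse, serum = serum,
       fastq = fastq)
}
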