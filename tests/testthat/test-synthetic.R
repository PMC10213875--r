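small_cfg <- function(...) {
  sim_config(seed = 11, depth = 4000, n_mirna = 8L, n_pirna = 10L,
             n_tsrna = 8L, n_rsrna = 8L, n_other = 4L,
             n_transgen = c(CD_DHT = 2L, HFHS_Veh = 3L, HFHS_DHT = 2L),
             n_intergen = c(CD_DHT = 1L, HFHS_Veh = 1L, HFHS_DHT = 1L),
             n_f1only = c(CD_DHT = 1L, HFHS_Veh = 1L, HFHS_DHT = 1L),
             n_homologs = c(CD_DHT = 1L, HFHS_Veh = 2L, HFHS_DHT = 1L),
             n_homolog_decoys = 3L, ...)
}

test_that("reference generation is deterministic and structurally correct", {
  cfg <- small_cfg()
  db1 <- generate_references(cfg)
  db2 <- generate_references(cfg)
  expect_identical(db1, db2)
  refs <- db1$refs
  # 18S embedded verbatim in 45S
  r18 <- refs$sequence[refs$ref_id == "rRNA-18S"]
  r45 <- refs$sequence[refs$ref_id == "rRNA-45S"]
  expect_true(grepl(r18, r45, fixed = TRUE))
  # processed tRNAs end in CCA; His starts with G
  trna <- refs[refs$biotype == "tRNA", ]
  expect_true(all(substr(trna$sequence, nchar(trna$sequence) - 2L,
                         nchar(trna$sequence)) == "CCA"))
  his <- trna[grepl("His", trna$amino_acid), ]
  expect_true(all(substr(his$sequence, 1, 1) == "G"))
  # rescue decoys: absent from the genome, Hamming-1 from an rRNA/tRNA window
  index <- build_annotation_index(refs, genome = db1$genome)
  for (i in seq_len(nrow(db1$rescue_decoys))) {
    d <- db1$rescue_decoys[i, ]
    expect_false(in_genome(d$sequence, index))
    bt <- if (d$exp_biotype == "rsRNA") "rRNA" else "tRNA"
    expect_equal(nrow(match_sequence(d$sequence, index, biotype = bt)), 0L)
    h1 <- match_sequence(d$sequence, index, biotype = bt, max_mismatch = 1L)
    expect_gt(nrow(h1), 0L)
  }
  # FASTA round-trip of the generated references
  path <- withr::local_tempfile(fileext = ".fa")
  rr <- refs[refs$biotype == "rRNA", ]
  write_reference_fasta(rr, path)
  expect_equal(read_reference_fasta(path, "rRNA")$sequence, rr$sequence)
})

test_that("simulated counts have the configured NB mean-variance structure", {
  cfg <- small_cfg()
  db <- generate_references(cfg)
  panel <- sncTrans:::build_feature_panel(db, cfg)
  # replicate draws at fixed mu: variance ~ mu (phi = 0) / mu + phi mu^2
  set.seed(100)
  mu <- 50
  x0 <- rpois(500, mu)
  expect_gt(var(x0) / mu, 0.8); expect_lt(var(x0) / mu, 1.2)
  x2 <- rnbinom(2000, mu = mu, size = 1 / 0.2)
  expect_gt(var(x2) / (mu + 0.2 * mu^2), 0.85)
  expect_lt(var(x2) / (mu + 0.2 * mu^2), 1.15)
  # planted 8-fold effects move the group means by about 8x
  sim <- simulate_counts(cfg, panel)
  eff <- sim$effects[sim$effects$class == "transgenerational" &
                       sim$effects$direction == "up", ]
  f <- eff$feature_id[1]; lin <- eff$lineage[1]
  ctl <- default_comparisons()$control[default_comparisons()$lineage == lin]
  mu_l <- sim$mu[f, sim$samples$lineage == lin]
  mu_c <- sim$mu[f, sim$samples$lineage == ctl]
  lf <- sim$lib_factors
  ratio <- mean(mu_l / lf[sim$samples$lineage == lin]) /
    mean(mu_c / lf[sim$samples$lineage == ctl])
  expect_equal(ratio, 8, tolerance = 1e-9)
  # planted transgenerational directions are generation-consistent
  tg <- sim$effects[sim$effects$class == "transgenerational", ]
  bad <- tapply(tg$direction, paste(tg$feature_id, tg$lineage),
                function(d) length(unique(d)))
  expect_true(all(bad == 1L))
  # realized biotype composition tracks the configured abundances
  # within sampling error (control samples only: no planted effects)
  ctl <- sim$samples$sample_id[sim$samples$lineage == "CD_Veh"]
  got <- tapply(rowSums(sim$counts[, ctl]), panel$biotype, sum)
  want <- tapply(rowSums(sim$mu[, ctl]), panel$biotype, sum)
  expect_lt(max(abs(got / sum(got) - want / sum(want))), 0.02)
})

test_that("read synthesis conserves counts and encodes the planted structure", {
  cfg <- small_cfg(error_rate = 0, adaptor_fraction = 1, lowq_fraction = 0,
                   isomir_fraction = 0)
  sim <- simulate_dataset(cfg)
  s <- sim$mouse$samples$sample_id[5]
  fq <- withr::local_tempfile(fileext = ".fastq")
  n <- synthesize_reads(sim$mouse$counts[, s], sim$panel, cfg, fq, s)
  expect_equal(n, sum(sim$mouse$counts[, s]))
  reads <- read_fastq(fq)
  expect_equal(nrow(reads), n)
  # with full adaptor and no errors, QC retains everything
  qc <- run_qc(reads, qc_config(), s)
  expect_equal(qc$stats$retained_fraction, 1)
  # a planted 5' tsRNA feature's reads all start at parent position 1
  p5 <- sim$panel[sim$panel$exp_subtype %in% "tsRNA_5p", ][1, ]
  parent <- sim$refdb$refs[sim$refdb$refs$ref_id == p5$parent_id, ]
  expect_equal(substr(parent$sequence, 1, nchar(p5$sequence)), p5$sequence)
  # determinism: identical config -> byte-identical FASTQ
  cfg2 <- small_cfg(error_rate = 0, adaptor_fraction = 1, lowq_fraction = 0,
                    isomir_fraction = 0)
  sim2 <- simulate_dataset(cfg2)
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(sim2$mouse$counts[, s], sim2$panel, cfg2, fq2, s)
  expect_identical(readLines(fq), readLines(fq2))
})

test_that("feature panel matches its own truth under annotation", {
  cfg <- small_cfg()
  sim <- simulate_dataset(cfg)
  index <- build_annotation_index(sim$refdb$refs, genome = sim$refdb$genome)
  ann <- annotate_sequences(sim$panel$sequence, index)
  expect_equal(ann$biotype, sim$panel$biotype)
  has_sub <- !is.na(sim$panel$exp_subtype)
  expect_equal(ann$subtype[has_sub], sim$panel$exp_subtype[has_sub])
  has_cl <- !is.na(sim$panel$exp_parent_class)
  expect_equal(ann$parent_class[has_cl], sim$panel$exp_parent_class[has_cl])
  expect_equal(ann$rescued, sim$panel$exp_rescued)
})

test_that("serum homologs are accepted and decoys rejected by construction", {
  cfg <- small_cfg()
  sim <- simulate_dataset(cfg)
  feats <- sim$serum$features
  hom <- feats[feats$role == "homolog", ]
  for (i in seq_len(nrow(hom))) {
    src <- sim$panel[sim$panel$feature_id == hom$mouse_feature[i], ]
    expect_false(is.null(seed_anchored_match(hom$sequence[i], src$sequence)))
  }
  dec <- feats[feats$role == "reject_decoy", ]
  for (i in seq_len(nrow(dec))) {
    src <- sim$panel[sim$panel$feature_id == dec$mouse_feature[i], ]
    expect_null(seed_anchored_match(dec$sequence[i], src$sequence))
  }
  expect_equal(nrow(sim$serum$pair_truth), sum(cfg$n_homologs))
  # library sizes dominate the column sums
  expect_true(all(sim$serum$lib_sizes >= colSums(sim$serum$counts)))
})
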