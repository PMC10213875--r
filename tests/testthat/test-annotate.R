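test_that("Hamming substring matching finds all hits at the allowed distance", {
  db <- toy_refdb()
  index <- build_annotation_index(db$refs, genome = db$genome)
  trna <- db$refs[db$refs$ref_id == "tRNA-Glu-1", ]
  frag <- substr(trna$sequence, 5L, 27L)
  hits <- match_sequence(frag, index, biotype = "tRNA", max_mismatch = 0L)
  expect_equal(hits$offset, 5L)
  expect_equal(hits$mismatches, 0L)
  # one substitution: invisible at 0 mismatches, found at 1
  mut <- paste0(substr(frag, 1, 9), "N", substr(frag, 11, 23))
  mut <- sub("N", setdiff(c("A", "C", "G", "T"), substr(frag, 10, 10))[1], mut)
  expect_equal(nrow(match_sequence(mut, index, biotype = "tRNA")), 0L)
  h1 <- match_sequence(mut, index, biotype = "tRNA", max_mismatch = 1L)
  expect_equal(h1$offset, 5L)
  expect_equal(h1$mismatches, 1L)
  # a sequence inside the embedded 18S is reported in both rRNA records
  win <- substr(db$refs$sequence[db$refs$ref_id == "rRNA-18S"], 10, 35)
  h2 <- match_sequence(win, index, biotype = "rRNA")
  expect_setequal(h2$ref_id, c("rRNA-18S", "rRNA-45S"))
  # N never matches
  expect_equal(nrow(match_sequence(paste0("N", substr(win, 2, 26)), index,
                                   biotype = "rRNA", max_mismatch = 1L)), 0L)
})

test_that("the cascade honours biotype precedence and Svedberg order", {
  set.seed(21)
  mir <- rand_seq(1, 22)
  r18 <- paste0(rand_seq(1, 30), mir, rand_seq(1, 60))
  r45 <- paste0(rand_seq(1, 40), r18, rand_seq(1, 50))
  refs <- rbind(
    reference_set("mir-a", mir, "miRNA"),
    reference_set(c("rRNA-18S", "rRNA-45S"), c(r18, r45), "rRNA",
                  svedberg_class = c("18S", "45S")))
  index <- build_annotation_index(refs)
  # present verbatim in both the miRNA set and an rRNA record -> miRNA
  ann <- annotate_sequence(mir, index)
  expect_equal(ann$biotype, "miRNA")
  expect_equal(ann$primary_parent, "mir-a")
  # a fragment of the embedded 18S -> rsRNA with class 18S, not 45S
  ann2 <- annotate_sequence(substr(r18, 5, 30), index)
  expect_equal(ann2$biotype, "rsRNA")
  expect_equal(ann2$parent_class, "18S")
  expect_equal(ann2$primary_parent, "rRNA-18S")
  # a 45S-only fragment -> 45S
  ann3 <- annotate_sequence(substr(r45, 3, 30), index)
  expect_equal(ann3$parent_class, "45S")
  # absent everywhere -> no_annotation
  ann4 <- annotate_sequence(rand_seq(1, 25), index)
  expect_equal(ann4$biotype, "no_annotation")
  expect_equal(ann4$parent_ids, NA_character_)
})

test_that("Svedberg precedence picks the smallest class among multi-hits", {
  db <- toy_refdb()
  refs <- db$refs
  hits <- data.frame(ref_id = c("rRNA-18S", "rRNA-45S"), offset = c(1L, 41L),
                     mismatches = c(0L, 0L))
  expect_equal(assign_rsrna_parent(hits, refs)$parent_class, "18S")
  expect_equal(assign_rsrna_parent(hits[2, ], refs)$parent_class, "45S")
  expect_error(assign_rsrna_parent(data.frame(ref_id = "mir-01", offset = 1L,
                                              mismatches = 0L), refs),
               "Svedberg")
})

test_that("tsRNA subtypes follow the match position with 5p > 3p_CCA > 3p", {
  expect_equal(classify_tsrna(1L, 18L, 75L), "tsRNA_5p")
  expect_equal(classify_tsrna(54L, 22L, 75L), "tsRNA_3p_CCA")
  expect_equal(classify_tsrna(51L, 22L, 75L), "tsRNA_3p")
  expect_equal(classify_tsrna(5L, 26L, 75L), "tsRNA_internal")
  # boundary: ends one base before the CCA boundary -> internal
  expect_equal(classify_tsrna(50L, 22L, 75L), "tsRNA_internal")
  # full-length hit satisfies 5p and 3p_CCA; 5p wins
  expect_equal(classify_tsrna(1L, 75L, 75L), "tsRNA_5p")
})

test_that("rescue re-annotates off-genome piRNA/no-annotation sequences", {
  db <- toy_refdb()
  refs <- db$refs
  r18 <- refs$sequence[refs$ref_id == "rRNA-18S"]
  # decoy: 1-mismatch mutant of an 18S window, in the piRNA database
  # but excluded from the genome
  win <- substr(r18, 21, 48)
  decoy <- paste0(substr(win, 1, 13),
                  setdiff(c("A", "C", "G", "T"), substr(win, 14, 14))[1],
                  substr(win, 15, 28))
  refs2 <- rbind(refs, reference_set("piR-decoy", decoy, "piRNA"))
  index <- build_annotation_index(refs2, genome = db$genome)
  ann <- annotate_sequences(decoy, index, rescue = FALSE)
  expect_equal(ann$biotype, "piRNA")
  resc <- rescue_reannotate(ann, index)
  expect_equal(resc$biotype, "rsRNA")
  expect_equal(resc$parent_class, "18S")
  expect_true(resc$rescued)
  expect_equal(resc$mismatches_used, 1L)
  # a genuine piRNA is in the genome and must not be touched
  real <- annotate_sequences(refs$sequence[refs$ref_id == "piR-01"], index)
  expect_equal(real$biotype, "piRNA")
  expect_false(real$rescued)
  # Hamming-2 from everything stays no_annotation
  far <- rand_seq(1, 30)
  annf <- annotate_sequences(far, index)
  expect_equal(annf$biotype, "no_annotation")
})

test_that("rescue never touches first-pass miRNA/rsRNA/tsRNA calls", {
  db <- toy_refdb()
  index <- build_annotation_index(db$refs, genome = db$genome)
  mir <- db$refs$sequence[db$refs$ref_id == "mir-01"]
  tfrag <- substr(db$refs$sequence[db$refs$ref_id == "tRNA-Glu-1"], 1, 20)
  first <- annotate_sequences(c(mir, tfrag), index, rescue = FALSE)
  after <- rescue_reannotate(first, index)
  expect_identical(first, after)
})

test_that("annotation is deterministic and matches the brute-force oracle", {
  db <- toy_refdb()
  index <- build_annotation_index(db$refs, genome = db$genome)
  set.seed(31)
  # mixture: exact windows, 1-mismatch mutants, random sequences
  seqs <- character(300)
  for (i in seq_along(seqs)) {
    kind <- sample(3, 1)
    if (kind < 3) {
      row <- db$refs[sample(nrow(db$refs), 1), ]
      w <- sample(15:min(40, nchar(row$sequence)), 1)
      off <- sample(nchar(row$sequence) - w + 1, 1)
      s <- substr(row$sequence, off, off + w - 1)
      if (kind == 2) {
        p <- sample(w, 1)
        s <- paste0(substr(s, 1, p - 1),
                    sample(setdiff(c("A", "C", "G", "T"), substr(s, p, p)), 1),
                    substr(s, p + 1, w))
      }
      seqs[i] <- s
    } else {
      seqs[i] <- rand_seq(1, sample(15:45, 1))
    }
  }
  seqs <- unique(seqs)
  ann <- annotate_sequences(seqs, index)
  ann2 <- annotate_sequences(seqs, index)
  expect_identical(ann, ann2)
  for (i in seq_along(seqs)) {
    o <- oracle_annotate(seqs[i], db$refs, db$genome)
    expect_equal(ann$biotype[i], o$biotype, info = seqs[i])
    expect_equal(ann$rescued[i], o$rescued, info = seqs[i])
    if (!is.na(ann$parent_class[i]) || !is.na(o$parent_class)) {
      expect_equal(ann$parent_class[i], o$parent_class, info = seqs[i])
    }
    if (!is.na(ann$subtype[i]) || !is.na(o$subtype)) {
      expect_equal(ann$subtype[i], o$subtype, info = seqs[i])
    }
  }
})
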