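test_that("seed-anchored matching implements the >90% coverage rule", {
  set.seed(71)
  s30 <- rand_seq(1, 30)
  # identical from base 2 onward, different first base: m = 29, 29/30 > 0.9
  q <- paste0(setdiff(c("A", "C", "G", "T"), substr(s30, 1, 1))[1],
              substr(s30, 2, 30))
  hit <- seed_anchored_match(q, s30)
  expect_equal(hit$matched_length, 29L)
  expect_gt(hit$coverage_query, 0.9)
  # 20 vs 30 nt: m = 19 covers only 19/30 of the subject -> rejected
  expect_null(seed_anchored_match(substr(s30, 1, 20), s30))
  # mismatch at position 10 stops the block: m = 8 -> rejected
  mid <- paste0(substr(s30, 1, 9),
                setdiff(c("A", "C", "G", "T"), substr(s30, 10, 10))[1],
                substr(s30, 11, 30))
  expect_null(seed_anchored_match(mid, s30))
  # reflexivity: any sequence matches itself (m = L - 1)
  for (L in c(15, 22, 34, 45)) {
    s <- rand_seq(1, L)
    expect_equal(seed_anchored_match(s, s)$matched_length, L - 1L)
  }
})

test_that("matching is symmetric with coverages swapped", {
  set.seed(72)
  for (i in 1:200) {
    a <- rand_seq(1, sample(15:40, 1))
    b <- if (runif(1) < 0.5) {
      L <- nchar(a)
      paste0(sample(c("A", "C", "G", "T"), 1), substr(a, 2, L))
    } else rand_seq(1, sample(15:40, 1))
    ab <- seed_anchored_match(a, b)
    ba <- seed_anchored_match(b, a)
    expect_equal(is.null(ab), is.null(ba))
    if (!is.null(ab)) {
      expect_equal(ab$matched_length, ba$matched_length)
      expect_equal(ab$coverage_query, ba$coverage_subject)
    }
  }
})

test_that("decisions agree with the character-by-character oracle", {
  set.seed(73)
  for (i in 1:500) {
    L <- sample(15:40, 1)
    a <- rand_seq(1, L)
    # bias the mix toward near-misses around the coverage boundary
    b <- switch(sample(3, 1),
                rand_seq(1, sample(15:40, 1)),
                { t3 <- sample(0:4, 1)
                  s <- paste0(sample(c("A", "C", "G", "T"), 1), substr(a, 2, L))
                  for (p in seq_len(t3)) s <- paste0(substr(s, 1, L - p),
                                                     sample(c("A", "C", "G", "T"), 1),
                                                     substr(s, L - p + 2, L))
                  s },
                { p <- sample(2:L, 1)
                  paste0(substr(a, 1, p - 1),
                         sample(setdiff(c("A", "C", "G", "T"), substr(a, p, p)), 1),
                         substr(a, p + 1, L)) })
    got <- !is.null(seed_anchored_match(a, b))
    expect_equal(got, oracle_seed_match(a, b), info = paste(a, b))
  }
})

test_that("cross-species pairing finds planted homologs among decoys", {
  set.seed(74)
  n <- 50
  mouse <- data.frame(feature_id = sprintf("m%02d", 1:n),
                      sequence = rand_seq(n, sample(20:34, n, TRUE)),
                      biotype = sample(c("miRNA", "tsRNA", "rsRNA"), n, TRUE),
                      direction = sample(c("up", "down"), n, TRUE),
                      stringsAsFactors = FALSE)
  human <- data.frame(feature_id = sprintf("h%02d", 1:n),
                      sequence = rand_seq(n, sample(20:34, n, TRUE)),
                      biotype = sample(c("miRNA", "tsRNA", "rsRNA"), n, TRUE),
                      direction = sample(c("up", "down"), n, TRUE),
                      stringsAsFactors = FALSE)
  # plant 4 homolog pairs: copy, mutate base 1 only
  planted <- c(3, 17, 28, 44)
  for (i in planted) {
    L <- nchar(mouse$sequence[i])
    human$sequence[i] <- paste0(
      setdiff(c("A", "C", "G", "T"), substr(mouse$sequence[i], 1, 1))[1],
      substr(mouse$sequence[i], 2, L))
    human$biotype[i] <- mouse$biotype[i]
  }
  pairs <- cross_species_pairs(human, mouse)
  expect_equal(nrow(pairs), 4L)
  expect_setequal(pairs$query_id, sprintf("h%02d", planted))
  expect_equal(pairs$subject_id, sub("h", "m", pairs$query_id))
  # brute-force all-pairs oracle agrees
  brute <- 0L
  for (i in 1:n) for (j in 1:n) {
    if (human$biotype[i] == mouse$biotype[j] &&
        oracle_seed_match(human$sequence[i], mouse$sequence[j])) brute <- brute + 1L
  }
  expect_equal(nrow(pairs), brute)
  # disjoint sequence content -> no pairs
  none <- cross_species_pairs(
    data.frame(feature_id = "a", sequence = strrep("AC", 10), biotype = "miRNA"),
    data.frame(feature_id = "b", sequence = strrep("GT", 10), biotype = "miRNA"))
  expect_equal(nrow(none), 0L)
  # many-to-many: one mouse feature homologous to two human features
  two <- human[planted[1:2], ]
  two$sequence <- c(paste0("A", substr(mouse$sequence[3], 2, nchar(mouse$sequence[3]))),
                    paste0("C", substr(mouse$sequence[3], 2, nchar(mouse$sequence[3]))))
  two$biotype <- mouse$biotype[3]
  mm <- cross_species_pairs(two, mouse[3, , drop = FALSE])
  expect_equal(nrow(mm), 2L)
})
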