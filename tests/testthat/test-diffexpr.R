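test_that("low-expression filter keeps log2 mean RPM >= 1 (boundary kept)", {
  rpm <- rbind(kept = c(2, 2, 2, 2), border = c(1.5, 1.5, 1.5, 1.5),
               zero = c(0, 0, 0, 0), high = c(100, 100, 100, 100))
  colnames(rpm) <- paste0("s", 1:4)
  keep <- filter_low_expression(rpm)
  expect_equal(unname(keep), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("exact test: symmetric null, antisymmetry, and the binomial limit", {
  # identical counts in both groups, equal libraries
  expect_equal(exact_nb_pvalue(30L, 30L, 3L, 3L, 0.1), 1)
  # swapping groups leaves p unchanged
  expect_equal(exact_nb_pvalue(8L, 40L, 4L, 4L, 0.2),
               exact_nb_pvalue(40L, 8L, 4L, 4L, 0.2))
  # phi = 0, equal libraries, totals 5 vs 15 of 20 over 2+2 samples:
  # two-sided binomial tail 2 * sum_{k<=5} C(20,k) / 2^20
  expect_equal(exact_nb_pvalue(5L, 15L, 2L, 2L, 0),
               2 * sum(choose(20, 0:5)) / 2^20, tolerance = 1e-12)
  # all-zero feature
  expect_equal(exact_nb_pvalue(0L, 0L, 2L, 2L, 0.1), 1)
  # p-values are probabilities
  set.seed(51)
  for (i in 1:25) {
    s <- sample(1:300, 1); y1 <- sample(0:s, 1)
    p <- exact_nb_pvalue(y1, s - y1, sample(2:5, 1), sample(2:5, 1), runif(1, 0, 0.5))
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("exact test agrees with edgeR's small-p exact test", {
  skip_if_not_installed("edgeR")
  set.seed(52)
  nf <- 200
  counts <- matrix(rnbinom(nf * 8, mu = 60, size = 5), nf, 8)
  phi <- 0.2
  p_ours <- vapply(seq_len(nf), function(i) {
    exact_nb_pvalue(sum(counts[i, 1:4]), sum(counts[i, 5:8]), 4L, 4L, phi)
  }, numeric(1))
  p_edger <- edgeR::exactTestBySmallP(counts[, 1:4], counts[, 5:8],
                                      dispersion = phi)
  expect_lt(max(abs(p_ours - p_edger)), 1e-10)
})

test_that("common dispersion recovery: NB, Poisson and degenerate data", {
  set.seed(53)
  nf <- 2000
  mu <- exp(runif(nf, log(20), log(500)))
  grp <- rep(c("a", "b"), each = 4)
  # parameter recovery at phi = 0.2
  c02 <- sapply(1:8, function(s) rnbinom(nf, mu = mu, size = 1 / 0.2))
  expect_lt(abs(estimate_common_dispersion(c02, grp) - 0.2), 0.05)
  # Poisson data: phi-hat collapses toward zero
  cp <- sapply(1:8, function(s) rpois(nf, mu))
  expect_lte(estimate_common_dispersion(cp, grp), 0.02)
  # constant, equal counts: no excess variance at all
  cc <- matrix(7L, nrow = 50, ncol = 8)
  expect_equal(estimate_common_dispersion(cc, grp), 0)
  expect_error(estimate_common_dispersion(cc, c("a", rep("b", 7))), "2 samples")
})

test_that("common dispersion agrees with edgeR on equal-library counts", {
  skip_if_not_installed("edgeR")
  set.seed(54)
  counts <- matrix(rnbinom(500 * 8, mu = 80, size = 4), 500, 8)
  grp <- rep(c("a", "b"), each = 4)
  ours <- estimate_common_dispersion(counts, grp)
  d <- edgeR::DGEList(counts = counts, group = grp,
                      lib.size = rep(mean(colSums(counts)), 8))
  ref <- edgeR::estimateCommonDisp(d)$common.dispersion
  expect_lt(abs(ours - ref), 0.01)
})

test_that("DE calls use strict thresholds on log2FC and raw p", {
  expect_equal(call_de(1.0, 0.01), "not_de")  # boundary log2fc
  expect_equal(call_de(2.3, 0.002), "up")
  expect_equal(call_de(-1.5, 0.2), "not_de")
  expect_equal(call_de(-1.5, 0.01), "down")
  expect_equal(call_de(2.0, 0.05), "not_de")  # boundary p
})

test_that("run_exact_de recovers planted fold changes with correct direction", {
  set.seed(55)
  nf <- 400
  libs <- setNames(round(2e5 * runif(8, 0.8, 1.2)), paste0("s", 1:8))
  mu <- exp(runif(nf, log(10), log(400)))
  counts <- sapply(seq_along(libs), function(s)
    rnbinom(nf, mu = mu * libs[s] / 2e5, size = 10))
  dimnames(counts) <- list(paste0("f", 1:nf), names(libs))
  up <- 1:10; down <- 11:20
  counts[up, 1:4] <- matrix(rnbinom(40, mu = mu[up] * 8, size = 10), 10, 4)
  counts[down, 1:4] <- matrix(rnbinom(40, mu = mu[down] / 8, size = 10), 10, 4)
  res <- run_exact_de(counts, libs, paste0("s", 1:4), paste0("s", 5:8))
  # high-abundance planted features are called with the right direction
  strong <- mu >= 50
  expect_gte(mean(res$de_status[up][strong[up]] == "up"), 0.9)
  expect_gte(mean(res$de_status[down][strong[down]] == "down"), 0.9)
  # swapping the groups negates log2fc and preserves p
  swap <- run_exact_de(counts, libs, paste0("s", 5:8), paste0("s", 1:4))
  expect_equal(swap$log2fc, -res$log2fc, tolerance = 1e-12)
  expect_equal(swap$p_value, res$p_value, tolerance = 1e-9)
  # p-values are invariant to feature order
  perm <- sample(nf)
  res_perm <- run_exact_de(counts[perm, ], libs, paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(res_perm$p_value[match(res$feature_id, res_perm$feature_id)],
               res$p_value)
  # de_status != not_de implies the thresholds and not filtered
  de <- res[res$de_status != "not_de", ]
  expect_true(all(abs(de$log2fc) > 1 & de$p_value < 0.05 & !de$filtered))
})
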