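# Differential expression: low-expression filter, equal-library
# pseudo-counts, common-dispersion estimation by conditional maximum
# likelihood, and the conditional negative-binomial exact test.

#' Filter features by log2 mean RPM
#'
#' Retains a feature iff the log2 of its mean RPM across the
#' comparison's samples is at least `min_log2_mean` (default 1, i.e.
#' mean RPM >= 2; the boundary is kept).
#'
#' @param rpm RPM matrix.
#' @param sample_ids columns belonging to the comparison.
#' @param min_log2_mean threshold on `log2(mean RPM)`.
#' @return logical vector over rows of `rpm`.
#' @export
filter_low_expression <- function(rpm, sample_ids = colnames(rpm),
                                  min_log2_mean = 1) {
  m <- rowMeans(rpm[, sample_ids, drop = FALSE])
  m >= 2^min_log2_mean
}

#' Scale counts to equal library sizes (pseudo-counts)
#'
#' Proportional scaling of each sample's counts to the geometric mean
#' library size, rounded to the nearest integer. The conditional
#' dispersion estimator and the exact test both assume equal effective
#' library sizes.
#'
#' @param counts feature x sample count matrix.
#' @param library_sizes named vector covering every column.
#' @return list with `pseudo` (integer matrix) and `common_lib`.
#' @export
equalize_libraries <- function(counts, library_sizes) {
  libs <- library_sizes[colnames(counts)]
  if (any(libs <= 0) || anyNA(libs)) stop("invalid library sizes")
  common <- exp(mean(log(libs)))
  pseudo <- round(sweep(counts, 2L, common / libs, `*`))
  storage.mode(pseudo) <- "integer"
  list(pseudo = pseudo, common_lib = common)
}

# Conditional log-likelihood of a common dispersion phi for one group
# block of equal-library counts, summed over features (terms constant
# in phi dropped). y: feature x sample matrix of one group.
cond_loglik_group <- function(y, phi) {
  n <- ncol(y)
  z <- rowSums(y)
  if (phi <= 0) stop("phi must be positive here")
  r <- 1 / phi
  sum(lgamma(y + r)) - n * nrow(y) * lgamma(r) +
    sum(lgamma(n * r) - lgamma(z + n * r))
}

#' Estimate the common dispersion by conditional maximum likelihood
#'
#' Maximizes, over a single dispersion shared by all features, the
#' conditional likelihood of the within-group counts given the group
#' totals, computed on equal-library pseudo-counts. The estimate is
#' clamped to `[0, 10]`; data with no excess variance return 0.
#'
#' @param counts feature x sample count matrix (retained features).
#' @param group factor/vector of group membership over columns; every
#'   group needs at least 2 samples.
#' @param library_sizes named vector; when omitted the counts are
#'   assumed already equal-library.
#' @return dispersion estimate `phi_hat` (scalar).
#' @export
estimate_common_dispersion <- function(counts, group, library_sizes = NULL) {
  group <- as.factor(group)
  if (any(table(group) < 2L)) stop("every group needs at least 2 samples")
  if (!is.null(library_sizes)) {
    counts <- equalize_libraries(counts, library_sizes)$pseudo
  }
  blocks <- lapply(levels(group), function(g) counts[, group == g, drop = FALSE])
  ll <- function(phi) sum(vapply(blocks, cond_loglik_group, numeric(1), phi = phi))
  # optimize on the delta = phi/(1+phi) scale, as is usual for qCML
  obj <- function(delta) ll(delta / (1 - delta))
  opt <- stats::optimize(obj, interval = c(1e-6, 10 / 11), maximum = TRUE)
  phi_hat <- opt$maximum / (1 - opt$maximum)
  # boundary: likelihood still rising as phi -> 0 means no overdispersion
  if (phi_hat < 2e-6 || obj(1e-6) >= opt$objective) phi_hat <- 0
  min(phi_hat, 10)
}

#' Conditional NB exact test p-value for one feature
#'
#' Two-sided exact test of the split of the grand total between two
#' groups of equal-library samples under a negative-binomial model
#' with common dispersion `phi`: conditional on `y1 + y2`, the p-value
#' is the sum of the probabilities of all splits at most as probable
#' as the observed one. At `phi = 0` the conditional distribution is
#' binomial (Poisson limit).
#'
#' @param y1,y2 group total counts.
#' @param n1,n2 samples per group.
#' @param phi common dispersion (>= 0).
#' @return p-value in (0, 1].
#' @export
exact_nb_pvalue <- function(y1, y2, n1, n2, phi) {
  s <- y1 + y2
  if (s == 0L) return(1)
  k <- 0:s
  if (phi <= 0) {
    logp <- stats::dbinom(k, size = s, prob = n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi
    r2 <- n2 / phi
    # conditional probabilities: NB(r1) x NB(r2) given the total;
    # the mean parameter cancels under equal per-sample means
    logp <- lgamma(k + r1) - lgamma(k + 1) + lgamma(s - k + r2) - lgamma(s - k + 1)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  p_obs <- logp[y1 + 1L]
  sum(exp(logp[logp <= p_obs + 1e-7])) / sum(exp(logp))
}

#' Call differential expression status
#'
#' `up` iff `log2fc > lfc` and `p < alpha`; `down` iff
#' `log2fc < -lfc` and `p < alpha` (strict inequalities); otherwise
#' `not_de`. Raw p-values (not FDR) drive the calls.
#'
#' @param log2fc,p numeric vectors.
#' @param lfc,alpha thresholds (defaults 1 and 0.05).
#' @return character vector `up`/`down`/`not_de`.
#' @export
call_de <- function(log2fc, p, lfc = 1, alpha = 0.05) {
  ifelse(p < alpha & log2fc > lfc, "up",
         ifelse(p < alpha & log2fc < -lfc, "down", "not_de"))
}

#' Run the exact-test differential expression workflow
#'
#' For one two-group comparison: RPM-based low-expression filter,
#' equal-library pseudo-counts, common-dispersion estimation,
#' per-feature conditional exact test, log2 fold change from
#' prior-count-augmented group mean RPM, BH-adjusted FDR (reported,
#' not used for calling) and DE status.
#'
#' @param counts feature x sample count matrix.
#' @param library_sizes named vector of library depths.
#' @param group_a,group_b sample ids of the two groups (a over b in
#'   the fold change); each >= 2 samples, disjoint.
#' @param lfc,alpha DE thresholds passed to [call_de()].
#' @param min_log2_mean filter threshold passed to
#'   [filter_low_expression()].
#' @param prior_count added to each group mean RPM before the log
#'   ratio (default 0.5).
#' @param dispersion optional fixed dispersion; estimated when `NULL`.
#' @return data.frame `feature_id`, `mean_rpm`, `log2fc`, `p_value`,
#'   `fdr`, `dispersion_used`, `filtered`, `de_status`; filtered
#'   features carry `NA` test results.
#' @export
run_exact_de <- function(counts, library_sizes, group_a, group_b,
                         lfc = 1, alpha = 0.05, min_log2_mean = 1,
                         prior_count = 0.5, dispersion = NULL) {
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples")
  }
  samples <- c(group_a, group_b)
  cc <- counts[, samples, drop = FALSE]
  rpm <- rpm_normalize(cc, library_sizes)
  keep <- filter_low_expression(rpm, min_log2_mean = min_log2_mean)
  eq <- equalize_libraries(cc[keep, , drop = FALSE], library_sizes[samples])
  grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  phi <- dispersion
  if (is.null(phi)) {
    phi <- if (sum(keep) > 0L) estimate_common_dispersion(eq$pseudo, grp) else 0
  }
  n1 <- length(group_a); n2 <- length(group_b)
  y1 <- rowSums(eq$pseudo[, seq_len(n1), drop = FALSE])
  y2 <- rowSums(eq$pseudo[, n1 + seq_len(n2), drop = FALSE])
  pvals <- mapply(exact_nb_pvalue, y1, y2,
                  MoreArgs = list(n1 = n1, n2 = n2, phi = phi))
  mean_a <- rowMeans(rpm[keep, group_a, drop = FALSE])
  mean_b <- rowMeans(rpm[keep, group_b, drop = FALSE])
  log2fc <- log2((mean_a + prior_count) / (mean_b + prior_count))
  res <- data.frame(feature_id = rownames(cc),
                    mean_rpm = rowMeans(rpm),
                    log2fc = NA_real_, p_value = NA_real_, fdr = NA_real_,
                    dispersion_used = phi,
                    filtered = !keep,
                    de_status = "not_de",
                    stringsAsFactors = FALSE)
  res$log2fc[keep] <- log2fc
  res$p_value[keep] <- pvals
  res$fdr[keep] <- stats::p.adjust(pvals, method = "BH")
  res$de_status[keep] <- call_de(log2fc, pvals, lfc = lfc, alpha = alpha)
  rownames(res) <- NULL
  res
}
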