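test_that("size factors: median-of-ratios hand example and basic cases", {
  m <- matrix(c(10, 20, 100, 200, 4, 8), nrow = 3, byrow = TRUE)
  expect_equal(unname(estimate_size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  ident <- matrix(rep(c(5, 10, 20), 3), nrow = 3)
  expect_equal(unname(estimate_size_factors(ident)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(estimate_size_factors(matrix(c(5, 7), 2, 1))), 1)
  expect_error(estimate_size_factors(matrix(c(0, 1, 1, 0), 2)), "zero-free")
})

test_that("size factors are scale-equivariant in each column", {
  # multiplying one column by c rescales every geometric mean by c^(1/n), so
  # equivariance holds for factor *ratios*, not the raw factors
  set.seed(1)
  m <- matrix(rpois(60, 50) + 1, nrow = 10)
  sf <- estimate_size_factors(m)
  for (c_mult in c(2, 5)) {
    m2 <- m
    m2[, 3] <- m[, 3] * c_mult
    sf2 <- estimate_size_factors(m2)
    expect_equal((sf2[3] / sf2[1]) / (sf[3] / sf[1]), c_mult, tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg: hand examples and brute-force property", {
  expect_equal(benjamini_hochberg(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(rep(0.05, 10)), rep(0.05, 10))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0,1\\]")
  # NA passthrough: missing excluded from m
  p <- c(0.01, NA, 0.04)
  expect_equal(benjamini_hochberg(p), c(0.02, NA, 0.04))
  # property: equals the step-up definition on random vectors
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), bh_brute_force(p), tolerance = 1e-12)
    expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t exactly", {
  mat <- rbind(g1 = c(1, 2, 3, 3, 4, 5))
  grp <- factor(rep(c("T1", "T2"), each = 3), levels = c("T1", "T2"))
  fit <- gonodyn:::moderated_t_core(mat, grp, d0 = 0)
  expect_equal(unname(fit$stat), 2 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(unname(fit$stat),
               unname(t.test(c(3, 4, 5), c(1, 2, 3), var.equal = TRUE)$statistic),
               tolerance = 1e-10)
  # zero mean difference: t = 0, p = 1 regardless of d0
  mat2 <- rbind(a = c(1, 2, 3, 3, 2, 1))
  for (d0 in list(0, 5, Inf)) {
    f <- gonodyn:::moderated_t_core(mat2, grp, d0 = d0)
    expect_equal(unname(f$stat), 0)
    expect_equal(unname(f$pvalue), 1)
  }
})

test_that("moderated t denominator tends to the prior variance as d0 grows", {
  set.seed(2)
  mat <- matrix(rnorm(100 * 6), 100, dimnames = list(sprintf("g%d", 1:100), NULL))
  grp <- factor(rep(c("T1", "T2"), each = 3), levels = c("T1", "T2"))
  f_inf <- gonodyn:::moderated_t_core(mat, grp, d0 = Inf)
  s0 <- sqrt(f_inf$s0_sq)
  expect_equal(unname(f_inf$stat),
               unname(f_inf$log2fc / (s0 * sqrt(2 / 3))), tolerance = 1e-10)
  f_big <- gonodyn:::moderated_t_core(mat, grp, d0 = 1e8)
  expect_equal(unname(f_big$stat), unname(f_inf$stat), tolerance = 1e-5)
})

test_that("moderated t null p-values are uniform", {
  set.seed(9)
  mat <- matrix(rnorm(5000 * 8, mean = 7, sd = 1), 5000,
                dimnames = list(sprintf("g%d", 1:5000), NULL))
  grp <- factor(rep(c("T1", "T2"), each = 4), levels = c("T1", "T2"))
  fit <- gonodyn:::moderated_t_core(mat, grp)
  expect_gt(ks.test(fit$pvalue, "punif")$p.value, 0.01)
})

test_that("moderated variance prior agrees with limma's squeezeVar", {
  skip_if_not_installed("limma")
  set.seed(4)
  s2 <- exp(rnorm(2000, 0, 0.8)) * rchisq(2000, 4) / 4
  ours <- fit_variance_prior(s2, 4)
  theirs <- limma::squeezeVar(s2, 4)
  expect_equal(ours$d0, theirs$df.prior, tolerance = 0.05)
  expect_equal(ours$s0_sq, theirs$var.prior, tolerance = 0.05)
  post <- (ours$d0 * ours$s0_sq + 4 * s2) / (ours$d0 + 4)
  expect_equal(post, theirs$var.post, tolerance = 0.05)
})

test_that("moderated t pipeline agrees with limma's lmFit/eBayes", {
  skip_if_not_installed("limma")
  sim <- simulate_dataset(recovery_config(platform = "intensity", n_genes = 500))
  ds <- sim$dataset
  keep <- ds$samples$sex == "F"
  mat <- ds$values[, keep]
  grp <- factor(ds$samples$stage[keep], levels = c("T1", "T2"))
  ours <- gonodyn:::moderated_t_core(mat, grp)
  design <- model.matrix(~grp)
  eb <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(unname(ours$log2fc), unname(eb$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(unname(ours$stat), unname(eb$t[, 2]), tolerance = 0.01)
  expect_equal(unname(ours$pvalue), unname(eb$p.value[, 2]), tolerance = 0.01)
})

test_that("NB Wald recovers a planted 4-fold change (median over 200 genes)", {
  set.seed(12)
  n_sig <- 200; n_null <- 1800
  mu_sig1 <- 500
  counts <- rbind(
    cbind(matrix(rnbinom(n_sig * 6, mu = mu_sig1, size = 100), n_sig),
          matrix(rnbinom(n_sig * 6, mu = 4 * mu_sig1, size = 100), n_sig)),
    matrix(rnbinom(n_null * 12, mu = 100, size = 100), n_null))
  rownames(counts) <- sprintf("g%d", seq_len(n_sig + n_null))
  grp <- factor(rep(c("T1", "T2"), each = 6), levels = c("T1", "T2"))
  res <- gonodyn:::nb_wald_core(counts, grp, if_alpha = NA, cooks_cutoff = NA)
  expect_lt(abs(median(res$log2fc[1:n_sig]) - 2), 0.1)
  # identical group distributions: fold change near 0 (up to the small
  # compositional bias the 10% shifted genes impose on the size factors)
  expect_lt(abs(median(res$log2fc[-(1:n_sig)])), 0.1)
})

test_that("NB Wald handles degenerate genes as untested", {
  ds <- toy_counts_dataset(n_genes = 6, reps = 3, seed = 2)
  ds$values[1, ] <- 0                                  # all-zero row
  ds$values[2, ds$samples$sex == "F" & ds$samples$stage == "T1"] <- 0  # zero group
  ds$values[2, ds$samples$sex == "F" & ds$samples$stage == "T2"] <-
    ds$values[2, ds$samples$sex == "F" & ds$samples$stage == "T2"] + 50
  res <- nb_wald_test(ds, "F", min_total_count = 1, if_alpha = NA)
  expect_equal(res$status[1], "untested")
  expect_equal(res$status[2], "untested")
  expect_true(all(is.na(res$pvalue[1:2])))
  expect_true(all(res$status[3:6] == "tested"))
})

test_that("NB Wald log2FC is invariant to a common count scaling", {
  sim <- simulate_dataset(recovery_config(n_genes = 300, seed = 21))
  ds <- sim$dataset
  keep <- ds$samples$sex == "M"
  counts <- ds$values[, keep]
  x <- as.numeric(ds$samples$stage[keep] == "T2")
  sf <- estimate_size_factors(counts)
  alpha_g <- rep(0.05, nrow(counts))
  # exact form of the absorption property: a common constant folded into the
  # size factors shifts only the intercept, never the group coefficient
  f1 <- gonodyn:::nb_glm_two_group(counts, x, sf, alpha_g)
  f2 <- gonodyn:::nb_glm_two_group(counts, x, sf * 3, alpha_g)
  expect_equal(f1$beta1, f2$beta1, tolerance = 1e-6)
  expect_equal(f1$beta0, f2$beta0 + log(3), tolerance = 1e-6)
  # full pipeline re-estimates the dispersion, so invariance is approximate
  # and degrades at very low counts
  res1 <- nb_wald_test(ds, "M", if_alpha = NA, cooks_cutoff = NA)
  ds2 <- ds
  ds2$values <- ds$values * 3L
  res2 <- nb_wald_test(ds2, "M", if_alpha = NA, cooks_cutoff = NA)
  ok <- res1$status == "tested" & res2$status == "tested"
  expect_gt(mean(ok), 0.95)
  drift <- abs(res1$log2fc[ok] - res2$log2fc[ok])
  expect_lt(median(drift), 0.02)
  expect_lt(max(drift[res1$base_mean[ok] >= 50]), 0.05)
})

test_that("Cook's distances match the closed-form oracle for group-mean fits", {
  # sf = 1 and fixed dispersion: the NB GLM fit is the group means, weights
  # are constant within groups, so h_j = 1/n_g and
  # D_j = r_j^2 (1/n_g) / (2 (1 - 1/n_g)^2) with Pearson residuals r_j.
  counts <- rbind(gA = c(10, 10, 10000, 20, 25, 30),
                  gB = c(10, 12, 11, 20, 25, 30),
                  gC = c(50, 50, 50, 80, 80, 80))
  grp <- factor(rep(c("T1", "T2"), each = 3), levels = c("T1", "T2"))
  alpha_g <- rep(0.05, 3)
  flags <- cooks_outlier_flags(counts, grp, cutoff = 19.17,
                               size_factors = rep(1, 6), alpha_g = alpha_g)
  oracle_d <- function(y, alpha) {
    n <- length(y); mu <- mean(y); h <- 1 / n
    r2 <- (y - mu)^2 / (mu * (1 + alpha * mu))
    r2 * h / (2 * (1 - h)^2)
  }
  d_oracle <- t(apply(counts, 1, function(y) {
    c(oracle_d(y[1:3], 0.05), oracle_d(y[4:6], 0.05))
  }))
  expect_equal(unname(flags), unname(apply(d_oracle > 19.17, 1, any)))
  expect_true(flags[["gA"]])
  expect_false(flags[["gB"]])
  # identical counts within groups: D = 0 everywhere, never flagged
  expect_false(flags[["gC"]])
})

test_that("two-replicate groups are never flagged as Cook's outliers", {
  counts <- rbind(g = c(10, 10000, 20, 25))
  grp <- factor(rep(c("T1", "T2"), each = 2), levels = c("T1", "T2"))
  flags <- cooks_outlier_flags(counts, grp, cutoff = 19.17,
                               size_factors = rep(1, 4), alpha_g = 0.05)
  expect_false(any(flags))
})

test_that("a flagged outlier gene gets a missing adjusted p", {
  ds <- toy_counts_dataset(n_genes = 50, reps = 3, seed = 3)
  ds$values[1, 1] <- 100000L
  res <- nb_wald_test(ds, "F", min_total_count = 1)
  expect_equal(res$status[1], "cooks_outlier")
  expect_true(is.na(res$padj[1]))
  expect_false(res$is_deg[1])
})

test_that("independent filtering maximizes rejections over the grid", {
  # low-mean all-null genes dilute the BH correction for high-mean signals
  set.seed(8)
  n_low <- 400; n_high <- 100
  res <- gonodyn:::de_result(
    gene_id = sprintf("g%d", 1:(n_low + n_high)),
    base_mean = c(runif(n_low, 1, 5), runif(n_high, 50, 100)),
    log2fc = 0, stat = 0,
    pvalue = c(runif(n_low), rbeta(n_high, 0.05, 1)),
    status = "tested", platform = "counts", contrast = "x")
  filtered <- independent_filtering(res, if_alpha = 0.1)
  expect_gt(attr(filtered, "filter_threshold"), 0)
  rej_filtered <- sum(filtered$padj < 0.1, na.rm = TRUE)
  rej_naive <- sum(benjamini_hochberg(res$pvalue) < 0.1, na.rm = TRUE)
  expect_gt(rej_filtered, rej_naive)
  # grid-search oracle: recompute the best threshold by brute force
  probs <- seq(0, 0.95, by = 0.01)
  thetas <- unique(quantile(res$base_mean, probs, names = FALSE))
  n_rej <- vapply(thetas, function(th) {
    keep <- res$base_mean >= th
    sum(p.adjust(res$pvalue[keep], "BH") < 0.1)
  }, numeric(1))
  expect_equal(rej_filtered, max(n_rej))
  # flagged genes lose padj but keep their raw p
  expect_true(all(is.na(filtered$padj[filtered$status == "filtered_low_expression"])))
  # identical base means: nothing can be filtered
  res2 <- gonodyn:::de_result(gene_id = c("a", "b"), base_mean = c(10, 10),
                              log2fc = 0, stat = 0, pvalue = c(0.01, 0.5),
                              status = "tested", platform = "counts", contrast = "x")
  f2 <- independent_filtering(res2)
  expect_true(all(f2$status == "tested"))
  # no tested genes: error
  res3 <- res2; res3$status <- "untested"; res3$pvalue <- NA_real_
  expect_error(independent_filtering(res3), "no tested genes")
})

test_that("DEG filter applies both thresholds on the right scale", {
  res <- gonodyn:::de_result(gene_id = c("a", "b", "c", "d"),
                             base_mean = 10, log2fc = c(2, -1.7, 1.2, 2),
                             stat = 0, pvalue = c(0.001, 0.004, 1e-4, 0.2),
                             status = "tested", platform = "counts", contrast = "x")
  res$padj <- c(0.01, 0.04, 0.001, 0.3)
  out <- apply_deg_filter(res)
  expect_equal(out$is_deg, c(TRUE, TRUE, FALSE, FALSE))
  # linear scale: threshold 1.5-fold = 0.585 log2 units
  out2 <- apply_deg_filter(res, fc_scale = "linear")
  expect_equal(out2$is_deg, c(TRUE, TRUE, TRUE, FALSE))
})
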