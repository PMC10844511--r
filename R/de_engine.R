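#' Median-of-ratios size factors
#'
#' Per-sample normalization factors for count data: each sample's factor is
#' the median, over genes with all-positive counts (the reference set), of the
#' ratio of its count to the per-gene geometric mean across samples.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return numeric vector of positive factors, one per column.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) stop("no zero-free gene rows; cannot estimate size factors")
  log_geo <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
  sf
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone step-up FDR adjustment, capped at 1. Missing p-values are
#' excluded from the number of tests and propagate as missing.
#'
#' @param pvalues numeric vector in [0,1], NA allowed.
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m == 0) return(out)
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[ord]))[order(ord)]
  out[ok] <- adj
  out
}

# --- empirical-Bayes variance moderation -----------------------------------

#' Inverse of the trigamma function (Newton iteration)
#' @keywords internal
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Fit prior df and variance by matching moments of log sample variances
#'
#' Under the hierarchical model s_g^2 | sigma_g^2 ~ sigma_g^2 chi^2_d/d and
#' 1/sigma_g^2 ~ (1/(d0 s0^2)) chi^2_d0, log s_g^2 has known digamma/trigamma
#' moments; equating them to the empirical mean and variance of log s_g^2
#' yields (d0, s0^2). Non-positive excess variance means the s_g^2 are no more
#' dispersed than chi^2 sampling alone allows: d0 = Inf.
#'
#' @param s2 per-gene sample variances (positive entries used).
#' @param df residual degrees of freedom (scalar or per-gene).
#' @return list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  keep <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[keep]; df <- df[keep]
  if (length(s2) < 2) return(list(d0 = Inf, s0_sq = stats::median(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(z) - mean(trigamma(df / 2))
  if (is.finite(ev) && ev > 0) {
    d0 <- 2 * trigamma_inverse(ev)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  }
  if (!is.finite(s0_sq) || s0_sq <= 0) {
    warning("variance prior fit failed; using unmoderated variances")
    return(list(d0 = 0, s0_sq = NA_real_))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# two-group moderated t on a log2-intensity matrix; group2 relative to group1
moderated_t_core <- function(mat, group, d0 = NULL) {
  stopifnot(is.factor(group), nlevels(group) == 2)
  g1 <- group == levels(group)[1]
  g2 <- group == levels(group)[2]
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  rv1 <- rowSums((mat[, g1, drop = FALSE] - m1)^2)
  rv2 <- rowSums((mat[, g2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (rv1 + rv2) / dg
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, dg)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else if (is.finite(d0) && d0 > 0) {
    s0_sq <- fit_variance_prior(s2, dg)$s0_sq
  } else {
    s0_sq <- if (is.finite(d0)) NA_real_ else fit_variance_prior(s2, dg)$s0_sq
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    if (d0 > 0) (d0 * s0_sq + dg * s2) / (d0 + dg) else s2
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  lfc <- m2 - m1
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, NA_real_))
  df_total <- d0 + dg
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  # delta = 0 with zero variance is a well-defined null result
  pval[se == 0 & lfc == 0] <- 1
  list(log2fc = lfc, stat = tstat, pvalue = pval,
       base_mean = (n1 * m1 + n2 * m2) / (n1 + n2),
       d0 = d0, s0_sq = s0_sq, df_residual = dg)
}

#' Moderated t-test for a two-group intensity contrast
#'
#' Gene-wise two-group comparison on log2 intensities with empirical-Bayes
#' variance shrinkage: the pooled residual variance of each gene is squeezed
#' towards a prior variance `s0^2` with prior degrees of freedom `d0`, both
#' estimated by matching moments of the log sample variances across genes.
#' The moderated statistic is referred to a t distribution with `d0 + d_g`
#' degrees of freedom. With `d0 = 0` this is exactly the ordinary pooled
#' two-sample t-test.
#'
#' @param dataset an `ExpressionDataset` with `platform = "intensity"`.
#' @param sex which sex's samples to use (`"F"` or `"M"`).
#' @param contrast length-2 stage vector; log2FC is the second level relative
#'   to the first (default `c("T1","T2")`, i.e. T2 vs T1).
#' @param d0 optional fixed prior df (NULL = estimate; 0 = ordinary t;
#'   Inf = fully shrunk).
#' @param fc_threshold,alpha,fc_scale DEG calling thresholds, see
#'   [apply_deg_filter()].
#' @return A `DEResult` data.frame.
#' @export
moderated_t_test <- function(dataset, sex, contrast = c("T1", "T2"), d0 = NULL,
                             fc_threshold = 1.5, alpha = 0.05,
                             fc_scale = c("log2", "linear")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (dataset$platform != "intensity") stop("moderated_t_test requires platform = 'intensity'")
  fc_scale <- match.arg(fc_scale)
  keep <- dataset$samples$sex == sex & dataset$samples$stage %in% contrast
  mat <- dataset$values[, keep, drop = FALSE]
  group <- factor(dataset$samples$stage[keep], levels = contrast)
  fit <- moderated_t_core(mat, group, d0 = d0)
  res <- de_result(gene_id = rownames(dataset$values),
                   base_mean = fit$base_mean, log2fc = fit$log2fc,
                   stat = fit$stat, pvalue = fit$pvalue,
                   status = ifelse(is.na(fit$pvalue), "untested", "tested"),
                   platform = "intensity",
                   contrast = paste0(sex, ":", contrast[2], "-vs-", contrast[1]))
  res$padj <- benjamini_hochberg(res$pvalue)
  attr(res, "d0") <- fit$d0
  attr(res, "s0_sq") <- fit$s0_sq
  apply_deg_filter(res, fc_threshold = fc_threshold, alpha = alpha, fc_scale = fc_scale)
}

# --- negative-binomial Wald engine -----------------------------------------

# vectorized two-group NB GLM (log link, offsets log s_j) across genes.
# Returns coefficient, SE, fitted means, weights and hat values.
nb_glm_two_group <- function(counts, x, size_factors, alpha_g, max_iter = 25L,
                             tol = 1e-8) {
  n <- nrow(counts)
  J <- ncol(counts)
  ls <- log(size_factors)
  q <- sweep(counts, 2, size_factors, "/")
  m1 <- rowMeans(q[, x == 0, drop = FALSE])
  m2 <- rowMeans(q[, x == 1, drop = FALSE])
  beta0 <- log(pmax(m1, 0.1))
  beta1 <- log(pmax(m2, 0.1)) - beta0
  xm <- matrix(rep(x, each = n), nrow = n)
  for (it in seq_len(max_iter)) {
    eta <- beta0 + beta1 * xm + rep(ls, each = n)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha_g * mu)
    z <- (eta - rep(ls, each = n)) + (counts - mu) / mu
    sw <- rowSums(w)
    swx <- rowSums(w * xm)
    swz <- rowSums(w * z)
    swxz <- rowSums(w * xm * z)
    det <- sw * swx - swx^2          # x binary: sum(w x^2) = sum(w x)
    det[det <= 0] <- NA_real_
    b1_new <- (sw * swxz - swx * swz) / det
    b0_new <- (swz - swx * b1_new) / sw
    delta <- pmax(abs(b1_new - beta1), abs(b0_new - beta0))
    beta0 <- b0_new
    beta1 <- b1_new
    if (all(is.na(delta) | delta < tol)) break
  }
  eta <- pmin(pmax(beta0 + beta1 * xm + rep(ls, each = n), -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha_g * mu)
  sw <- rowSums(w)
  swx <- rowSums(w * xm)
  det <- sw * swx - swx^2
  det[det <= 0] <- NA_real_
  se <- sqrt(sw / det)
  # hat values h_j = w_j x_j' (X'WX)^{-1} x_j for x_j = (1, x_j)
  h <- w * ((swx - 2 * swx * xm + sw * xm) / det)  # x binary: x^2 = x
  list(beta0 = beta0, beta1 = beta1, se = se, mu = mu, w = w, h = h)
}

#' Cook's-distance outlier flags for count data
#'
#' Computes per-observation Cook's distances from a gene-wise two-group NB
#' GLM fit, in the standardized Pearson-residual form
#' `D = r^2 h / (p (1 - h)^2)` with `p = 2` model coefficients, and flags a
#' gene when any sample belonging to a group with at least 3 replicates
#' exceeds the cutoff. Two-replicate groups cannot single out an outlier and
#' never trigger a flag.
#'
#' @param counts count matrix (genes x samples).
#' @param groups two-level factor over columns.
#' @param cutoff Cook's distance cutoff (default 19.17).
#' @param size_factors optional; estimated if missing.
#' @param alpha_g optional per-gene dispersions, used as given; when missing,
#'   a robust mean-dispersion trend is fitted to per-gene moment estimates
#'   (see [fit_dispersion_trend()]).
#' @return logical per-gene flag vector.
#' @export
cooks_outlier_flags <- function(counts, groups, cutoff = 19.17,
                                size_factors = NULL, alpha_g = NULL) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(alpha_g)) {
    mom <- estimate_dispersions(counts, groups, size_factors)
    bm <- rowMeans(sweep(counts, 2, size_factors, "/"))
    alpha_g <- fit_dispersion_trend(mom, bm)(bm)
  }
  x <- as.numeric(groups == levels(groups)[2])
  fit <- nb_glm_two_group(counts, x, size_factors, alpha_g)
  cooks_from_fit(counts, fit, alpha_g, groups, cutoff)
}

cooks_from_fit <- function(counts, fit, alpha_g, groups, cutoff) {
  v <- fit$mu * (1 + alpha_g * fit$mu)
  r2 <- (counts - fit$mu)^2 / v
  h <- pmin(fit$h, 1 - 1e-8)
  d <- r2 * h / (2 * (1 - h)^2)
  eligible <- table(groups)[as.character(groups)] >= 3
  flag_mat <- sweep(d > cutoff, 2, as.logical(eligible), "&")
  rowSums(flag_mat, na.rm = TRUE) > 0
}

#' Robust mean-dispersion trend
#'
#' Fits `alpha(mu) = a1 + a0/mu` to per-gene moment dispersion estimates with
#' median-based (breakdown-resistant) estimators: the asymptote `a1` is the
#' median dispersion of the high-expression half, the Poisson-like term `a0`
#' the median of `(alpha - a1) * mu`. Used for Cook's distance: a count
#' outlier inflates its own gene's moment dispersion and would mask itself,
#' so outlier flagging needs a dispersion that no single gene can drag.
#'
#' @param alpha_g per-gene dispersion estimates.
#' @param mu per-gene mean normalized counts.
#' @return function mapping means to trended dispersions.
#' @export
fit_dispersion_trend <- function(alpha_g, mu) {
  ok <- is.finite(alpha_g) & is.finite(mu) & mu > 0
  if (sum(ok) < 10) {
    a1 <- max(stats::median(alpha_g[ok]), 1e-8)
    return(function(m) rep(a1, length(m)))
  }
  high <- ok & mu >= stats::median(mu[ok])
  a1 <- max(stats::median(alpha_g[high]), 1e-8)
  a0 <- max(stats::median((alpha_g[ok] - a1) * mu[ok]), 0)
  function(m) a1 + a0 / pmax(m, 1e-8)
}

#' Method-of-moments NB dispersion estimates
#'
#' Per-gene dispersion `alpha_g` from normalized counts: pooled within-group
#' variance v and mean m give `alpha = (v - xim * m) / m^2`, where
#' `xim = mean(1/s_j)` accounts for the Poisson component under size-factor
#' scaling. Floored at 1e-8.
#'
#' @param counts count matrix.
#' @param groups two-level factor over columns.
#' @param size_factors per-sample factors.
#' @return per-gene dispersion vector.
#' @export
estimate_dispersions <- function(counts, groups, size_factors) {
  q <- sweep(counts, 2, size_factors, "/")
  groups <- as.factor(groups)
  ss <- 0; df <- 0
  for (lev in levels(groups)) {
    sub <- q[, groups == lev, drop = FALSE]
    mu <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu)^2)
    df <- df + ncol(sub) - 1
  }
  v <- ss / df
  m <- rowMeans(q)
  xim <- mean(1 / size_factors)
  alpha <- (v - xim * m) / m^2
  pmax(alpha, 1e-8)
}

#' Negative-binomial Wald test for a two-group count contrast
#'
#' Gene-wise NB GLM (log link) with a group indicator and log size-factor
#' offsets. The group coefficient is tested with a Wald statistic referred to
#' a t distribution with residual degrees of freedom (a small-sample
#' correction over the asymptotic normal reference). Genes flagged by Cook's
#' distance get missing p-values; independent filtering removes
#' low-expression genes before the BH adjustment.
#'
#' Genes with total count below `min_total_count`, with all-zero rows, or
#' with a zero total count in one group are reported as untested.
#'
#' @param dataset an `ExpressionDataset` with `platform = "counts"`.
#' @param sex which sex's samples to use.
#' @param contrast length-2 stage vector, second level relative to first.
#' @param cooks_cutoff Cook's distance cutoff (default 19.17; NA disables).
#' @param if_alpha independent-filtering target alpha (default 0.1; NA
#'   disables filtering).
#' @param min_total_count pre-filter: drop genes with total count below this
#'   before dispersion estimation (default 10).
#' @param fc_threshold,alpha,fc_scale DEG calling thresholds, see
#'   [apply_deg_filter()].
#' @return A `DEResult` data.frame.
#' @export
nb_wald_test <- function(dataset, sex, contrast = c("T1", "T2"),
                         cooks_cutoff = 19.17, if_alpha = 0.1,
                         min_total_count = 10, fc_threshold = 1.5,
                         alpha = 0.05, fc_scale = c("log2", "linear")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (dataset$platform != "counts") stop("nb_wald_test requires platform = 'counts'")
  fc_scale <- match.arg(fc_scale)
  keep <- dataset$samples$sex == sex & dataset$samples$stage %in% contrast
  counts <- dataset$values[, keep, drop = FALSE]
  group <- factor(dataset$samples$stage[keep], levels = contrast)
  res <- nb_wald_core(counts, group,
                      contrast_label = paste0(sex, ":", contrast[2], "-vs-", contrast[1]),
                      cooks_cutoff = cooks_cutoff, if_alpha = if_alpha,
                      min_total_count = min_total_count)
  apply_deg_filter(res, fc_threshold = fc_threshold, alpha = alpha, fc_scale = fc_scale)
}

nb_wald_core <- function(counts, group, contrast_label = "",
                         cooks_cutoff = 19.17, if_alpha = 0.1,
                         min_total_count = 10) {
  stopifnot(is.factor(group), nlevels(group) == 2)
  n <- nrow(counts)
  sf <- estimate_size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(q)
  g1 <- group == levels(group)[1]
  g2 <- group == levels(group)[2]

  testable <- rowSums(counts) >= max(min_total_count, 1) &
    rowSums(counts[, g1, drop = FALSE]) > 0 &
    rowSums(counts[, g2, drop = FALSE]) > 0

  log2fc <- rep(NA_real_, n)
  stat <- rep(NA_real_, n)
  pvalue <- rep(NA_real_, n)
  status <- ifelse(testable, "tested", "untested")

  if (any(testable)) {
    sub <- counts[testable, , drop = FALSE]
    alpha_g <- estimate_dispersions(sub, group, sf)
    x <- as.numeric(g2)
    fit <- nb_glm_two_group(sub, x, sf, alpha_g)
    df_resid <- ncol(counts) - 2
    z <- fit$beta1 / fit$se
    p <- 2 * stats::pt(-abs(z), df = df_resid)
    lfc <- fit$beta1 / log(2)
    if (!is.na(cooks_cutoff)) {
      # refit with the trended dispersion so an outlier cannot mask itself
      # by inflating its own gene's dispersion estimate
      alpha_c <- fit_dispersion_trend(alpha_g, base_mean[testable])(base_mean[testable])
      fit_c <- nb_glm_two_group(sub, x, sf, alpha_c)
      flagged <- cooks_from_fit(sub, fit_c, alpha_c, group, cooks_cutoff)
      p[flagged] <- NA_real_
      status[testable][flagged] <- "cooks_outlier"
    }
    bad <- is.na(fit$se) | !is.finite(z)
    p[bad & status[testable] == "tested"] <- NA_real_
    status[testable][bad & status[testable] == "tested"] <- "untested"
    log2fc[testable] <- lfc
    stat[testable] <- z
    pvalue[testable] <- p
  }

  res <- de_result(gene_id = rownames(counts), base_mean = base_mean,
                   log2fc = log2fc, stat = stat, pvalue = pvalue,
                   status = status, platform = "counts",
                   contrast = contrast_label)
  if (!is.na(if_alpha)) {
    res <- independent_filtering(res, if_alpha = if_alpha)
  } else {
    res$padj <- benjamini_hochberg(res$pvalue)
  }
  res
}

#' Independent filtering of low-expression genes
#'
#' Scans base-mean quantile thresholds (0%, 1%, ..., 95%), removes genes
#' whose base mean falls below each candidate threshold, and keeps the
#' threshold that maximizes the number of BH rejections at `if_alpha` (the
#' smallest such threshold on ties, so the result never rejects fewer genes
#' than no filtering). Filtered genes get status `filtered_low_expression`
#' and a missing adjusted p-value; the BH adjustment is then computed on the
#' surviving genes.
#'
#' @param result a `DEResult` with `base_mean` and `pvalue` columns.
#' @param if_alpha target alpha for the rejection count (default 0.1).
#' @return the `DEResult` with `padj` and filter flags set.
#' @export
independent_filtering <- function(result, if_alpha = 0.1) {
  tested <- result$status == "tested" & !is.na(result$pvalue)
  if (!any(tested)) stop("no tested genes to filter")
  bm <- result$base_mean[tested]
  p <- result$pvalue[tested]
  probs <- seq(0, 0.95, by = 0.01)
  thetas <- unique(stats::quantile(bm, probs, names = FALSE, type = 7))
  n_rej <- vapply(thetas, function(th) {
    keep <- bm >= th
    if (!any(keep)) return(0L)
    sum(benjamini_hochberg(p[keep]) < if_alpha, na.rm = TRUE)
  }, integer(1))
  theta_star <- thetas[which.max(n_rej)]   # smallest maximizer: which.max takes first
  filtered <- tested & result$base_mean < theta_star
  result$status[filtered] <- "filtered_low_expression"
  keep <- result$status == "tested"
  result$padj <- rep(NA_real_, nrow(result))
  result$padj[keep] <- benjamini_hochberg(result$pvalue[keep])
  attr(result, "filter_threshold") <- theta_star
  result
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when it was tested, its |log2FC| reaches the fold-change
#' threshold, and its BH-adjusted p is below `alpha`. The threshold is in
#' log2 units by default (`fc_scale = "log2"`, i.e. 1.5 means 2^1.5-fold);
#' `fc_scale = "linear"` reinterprets it as a linear fold change
#' (log2 threshold `log2(fc_threshold)`).
#'
#' @param result a `DEResult` with `padj` computed.
#' @param fc_threshold fold-change threshold (default 1.5).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param fc_scale `"log2"` or `"linear"`.
#' @return the `DEResult` with logical column `is_deg`.
#' @export
apply_deg_filter <- function(result, fc_threshold = 1.5, alpha = 0.05,
                             fc_scale = c("log2", "linear")) {
  fc_scale <- match.arg(fc_scale)
  thr <- if (fc_scale == "linear") log2(fc_threshold) else fc_threshold
  result$is_deg <- result$status == "tested" & !is.na(result$padj) &
    abs(result$log2fc) >= thr & result$padj < alpha
  attr(result, "fc_threshold_log2") <- thr
  attr(result, "alpha") <- alpha
  result
}

de_result <- function(gene_id, base_mean, log2fc, stat, pvalue, status,
                      platform, contrast) {
  df <- data.frame(gene_id = gene_id, base_mean = base_mean, log2fc = log2fc,
                   stat = stat, pvalue = pvalue, padj = NA_real_,
                   status = status, is_deg = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("DEResult", "data.frame")
  attr(df, "platform") <- platform
  attr(df, "contrast") <- contrast
  df
}

#' Write a DE result table as TSV
#' @param result a `DEResult`.
#' @param path output path.
#' @export
write_de_result <- function(result, path) {
  utils::write.table(result[, c("gene_id", "log2fc", "pvalue", "padj",
                                "base_mean", "status", "is_deg")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(result)
}
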