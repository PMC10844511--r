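#' Between-sex contrast at stage T2
#'
#' Runs the platform-appropriate DE engine on male vs female samples at T2
#' (log2FC is male relative to female), with the same thresholds as the
#' within-sex stage contrasts. A significant positive fold change marks a
#' gene as male-enriched at T2; negative as female-enriched.
#'
#' @param dataset an `ExpressionDataset`.
#' @param stage stage at which to contrast the sexes (default `"T2"`).
#' @param ... engine options passed to [nb_wald_test()] /
#'   [moderated_t_test()]-style internals (`fc_threshold`, `alpha`,
#'   `fc_scale`, and for counts `cooks_cutoff`, `if_alpha`,
#'   `min_total_count`).
#' @return A `DEResult` (M vs F at the given stage).
#' @export
between_sex_contrast_t2 <- function(dataset, stage = "T2", ...) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  keep <- dataset$samples$stage == stage
  if (sum(dataset$samples$sex[keep] == "F") < 2 ||
      sum(dataset$samples$sex[keep] == "M") < 2) {
    stop("need >= 2 samples per sex at stage ", stage)
  }
  sub <- dataset$values[, keep, drop = FALSE]
  group <- factor(dataset$samples$sex[keep], levels = c("F", "M"))
  dots <- list(...)
  fc_threshold <- dots$fc_threshold %||% 1.5
  alpha <- dots$alpha %||% 0.05
  fc_scale <- dots$fc_scale %||% "log2"
  label <- paste0(stage, ":M-vs-F")
  if (dataset$platform == "counts") {
    res <- nb_wald_core(sub, group, contrast_label = label,
                        cooks_cutoff = dots$cooks_cutoff %||% 19.17,
                        if_alpha = dots$if_alpha %||% 0.1,
                        min_total_count = dots$min_total_count %||% 10)
  } else {
    fit <- moderated_t_core(sub, group, d0 = dots$d0)
    res <- de_result(gene_id = rownames(sub), base_mean = fit$base_mean,
                     log2fc = fit$log2fc, stat = fit$stat, pvalue = fit$pvalue,
                     status = ifelse(is.na(fit$pvalue), "untested", "tested"),
                     platform = "intensity", contrast = label)
    res$padj <- benjamini_hochberg(res$pvalue)
  }
  apply_deg_filter(res, fc_threshold = fc_threshold, alpha = alpha,
                   fc_scale = fc_scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the fold-change-plane table for one species
#'
#' Merges the two within-sex stage contrasts and the between-sex T2 contrast
#' into one point per gene on the FC plane (female T1->T2 log2FC on X, male
#' on Y) and classifies each point:
#' \itemize{
#'   \item `NONSIG` - not a DEG in either sex;
#'   \item `MEG` / `FEG` - a DEG in at least one sex whose T2 between-sex
#'     contrast is significantly male- / female-enriched;
#'   \item `SHARED` - a DEG in at least one sex without significant sex
#'     enrichment at T2.
#' }
#' MEG mechanisms: `both` when the male upregulation and the female
#' downregulation are both significant; `own-up-only` when only the male
#' upregulation is; `opposite-down-only` when only the female downregulation
#' is (FEG mirrored). Rare residual cases (a MEG/FEG whose only significant
#' per-sex change points against the enrichment direction, possible when the
#' between-sex test is driven by a sub-threshold change in the other sex) are
#' attributed to the sex carrying the significant change.
#'
#' Genes with a missing adjusted p in both sexes (outliers / filtered) are
#' dropped; the dropped count is recorded in attribute `n_dropped`.
#'
#' @param de_female,de_male `DEResult`s of the within-sex T1->T2 contrasts.
#' @param t2_contrast `DEResult` of the M-vs-F contrast at T2.
#' @param rule `"contrast"` (default: classify MEG/FEG by the significant T2
#'   between-sex test) or `"fc_margin"` (no extra test: classify by the sign
#'   of `fc_male - fc_female` when its magnitude reaches `margin`).
#' @param margin log2 margin for `rule = "fc_margin"` (default 1.5).
#' @return A `DynamicsTable` data.frame with one row per retained gene:
#'   `gene_id`, `fc_female`, `fc_male`, `sig_female`, `sig_male`,
#'   `padj_female`, `padj_male`, `t2_log2fc`, `t2_padj`, `t2_sig`,
#'   `base_mean`, `class`, `mechanism`.
#' @export
build_dynamics_table <- function(de_female, de_male, t2_contrast,
                                 rule = c("contrast", "fc_margin"),
                                 margin = 1.5) {
  rule <- match.arg(rule)
  common <- intersect(intersect(de_female$gene_id, de_male$gene_id),
                      t2_contrast$gene_id)
  if (length(common) == 0) stop("disjoint gene universes across DE results")
  f <- de_female[match(common, de_female$gene_id), ]
  m <- de_male[match(common, de_male$gene_id), ]
  t2 <- t2_contrast[match(common, t2_contrast$gene_id), ]

  keep <- !(is.na(f$padj) & is.na(m$padj))
  n_dropped <- sum(!keep) + (length(de_female$gene_id) - length(common))
  f <- f[keep, ]; m <- m[keep, ]; t2 <- t2[keep, ]

  sig_f <- f$is_deg
  sig_m <- m$is_deg
  t2_sig <- t2$is_deg

  cls <- rep("NONSIG", nrow(f))
  any_sig <- sig_f | sig_m
  if (rule == "contrast") {
    cls[any_sig & t2_sig & t2$log2fc > 0] <- "MEG"
    cls[any_sig & t2_sig & t2$log2fc < 0] <- "FEG"
    cls[any_sig & cls == "NONSIG"] <- "SHARED"
  } else {
    diff <- m$log2fc - f$log2fc
    cls[any_sig & diff >= margin] <- "MEG"
    cls[any_sig & diff <= -margin] <- "FEG"
    cls[any_sig & cls == "NONSIG"] <- "SHARED"
  }

  mech <- rep("n/a", nrow(f))
  is_meg <- cls == "MEG"
  is_feg <- cls == "FEG"
  m_up <- sig_m & m$log2fc > 0
  f_dn <- sig_f & f$log2fc < 0
  f_up <- sig_f & f$log2fc > 0
  m_dn <- sig_m & m$log2fc < 0
  mech[is_meg & m_up & f_dn] <- "both"
  mech[is_meg & m_up & !f_dn] <- "own-up-only"
  mech[is_meg & !m_up & f_dn] <- "opposite-down-only"
  # residual MEGs: attribute to the sex with the significant change
  resid <- is_meg & mech == "n/a"
  mech[resid & sig_m] <- "own-up-only"
  mech[resid & !sig_m & sig_f] <- "opposite-down-only"
  mech[is_feg & f_up & m_dn] <- "both"
  mech[is_feg & f_up & !m_dn] <- "own-up-only"
  mech[is_feg & !f_up & m_dn] <- "opposite-down-only"
  resid <- is_feg & mech == "n/a"
  mech[resid & sig_f] <- "own-up-only"
  mech[resid & !sig_f & sig_m] <- "opposite-down-only"

  out <- data.frame(gene_id = f$gene_id,
                    fc_female = f$log2fc, fc_male = m$log2fc,
                    sig_female = sig_f, sig_male = sig_m,
                    padj_female = f$padj, padj_male = m$padj,
                    t2_log2fc = t2$log2fc, t2_padj = t2$padj, t2_sig = t2_sig,
                    base_mean = (f$base_mean + m$base_mean) / 2,
                    class = cls, mechanism = mech,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DynamicsTable", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Construct a mechanism summary
#'
#' The disjoint per-category DEG counts of the standard summary table: MEGs
#' upregulated in males (`males_up`, covering the own-up-only and both
#' mechanisms) vs MEGs achieved only by downregulation in females
#' (`females_down`); FEGs mirrored (`females_up`, `males_down`); plus shared
#' stage-regulated genes (`both_sexes`). `total_degs` is their sum.
#'
#' @param males_up,females_down,females_up,males_down,both_sexes category
#'   counts.
#' @param total_genes size of the gene universe.
#' @return A `MechanismSummary` list.
#' @export
mechanism_summary <- function(males_up, females_down, females_up, males_down,
                              both_sexes, total_genes) {
  total_degs <- males_up + females_down + females_up + males_down + both_sexes
  if (total_degs > total_genes) stop("total DEGs exceed total genes")
  structure(list(males_up = as.integer(males_up),
                 males_down = as.integer(males_down),
                 females_up = as.integer(females_up),
                 females_down = as.integer(females_down),
                 both_sexes = as.integer(both_sexes),
                 total_degs = as.integer(total_degs),
                 total_genes = as.integer(total_genes)),
            class = "MechanismSummary")
}

#' @export
print.MechanismSummary <- function(x, ...) {
  cat(sprintf(paste0("MechanismSummary: males up %d / down %d; ",
                     "females up %d / down %d; both sexes %d; ",
                     "total DEGs %d of %d genes\n"),
              x$males_up, x$males_down, x$females_up, x$females_down,
              x$both_sexes, x$total_degs, x$total_genes))
  invisible(x)
}

#' Summarize classified points into mechanism categories
#'
#' @param points a `DynamicsTable`.
#' @param total_genes gene-universe size (default: rows of `points`).
#' @return A `MechanismSummary`; categories are disjoint and sum to
#'   `total_degs`.
#' @export
summarize_mechanisms <- function(points, total_genes = nrow(points)) {
  meg <- points$class == "MEG"
  feg <- points$class == "FEG"
  mechanism_summary(
    males_up = sum(meg & points$mechanism %in% c("own-up-only", "both")),
    females_down = sum(meg & points$mechanism == "opposite-down-only"),
    females_up = sum(feg & points$mechanism %in% c("own-up-only", "both")),
    males_down = sum(feg & points$mechanism == "opposite-down-only"),
    both_sexes = sum(points$class == "SHARED"),
    total_genes = total_genes
  )
}

#' Activation/repression percentages per sex-enriched group
#'
#' Of all MEGs, the percentage achieved by upregulation in males vs by
#' downregulation in females; likewise for FEGs. Zero denominators give NA.
#'
#' @param summary a `MechanismSummary`.
#' @return named numeric vector `meg_up_pct`, `meg_down_pct`, `feg_up_pct`,
#'   `feg_down_pct`.
#' @export
mechanism_percentages <- function(summary) {
  meg_tot <- summary$males_up + summary$females_down
  feg_tot <- summary$females_up + summary$males_down
  c(meg_up_pct = if (meg_tot > 0) 100 * summary$males_up / meg_tot else NA_real_,
    meg_down_pct = if (meg_tot > 0) 100 * summary$females_down / meg_tot else NA_real_,
    feg_up_pct = if (feg_tot > 0) 100 * summary$females_up / feg_tot else NA_real_,
    feg_down_pct = if (feg_tot > 0) 100 * summary$males_down / feg_tot else NA_real_)
}

#' Write a dynamics table as TSV
#' @param points a `DynamicsTable`.
#' @param path output path.
#' @export
write_dynamics_table <- function(points, path) {
  utils::write.table(points, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(points)
}

#' @rdname write_dynamics_table
#' @export
read_dynamics_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("DynamicsTable", "data.frame")
  df
}

#' Write a mechanism summary as TSV
#' @param summary a `MechanismSummary`.
#' @param path output path.
#' @export
write_mechanism_summary <- function(summary, path) {
  df <- as.data.frame(unclass(summary))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}
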