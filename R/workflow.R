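#' Per-species analysis configuration
#'
#' @param fc_threshold fold-change threshold (default 1.5, log2 units).
#' @param fc_scale `"log2"` or `"linear"` (see [apply_deg_filter()]).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param cooks_cutoff Cook's distance cutoff for counts (default 19.17).
#' @param if_alpha independent-filtering alpha for counts (default 0.1).
#' @param min_total_count count pre-filter (default 10).
#' @param classify_rule `"contrast"` or `"fc_margin"` (see
#'   [build_dynamics_table()]).
#' @param top_fraction top-gene fraction (default 0.10).
#' @param panel key-gene panel symbols.
#' @param min_species sharing/conservation threshold (default 3).
#' @param n_perm permutations for the SD sex-difference test (default 999).
#' @param seed integer seed for the stochastic steps.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(fc_threshold = 1.5, fc_scale = "log2", alpha = 0.05,
                            cooks_cutoff = 19.17, if_alpha = 0.1,
                            min_total_count = 10,
                            classify_rule = "contrast", top_fraction = 0.10,
                            panel = default_key_panel(), min_species = 3,
                            n_perm = 999, seed = 1L) {
  stopifnot(fc_threshold > 0, alpha > 0, top_fraction > 0)
  structure(list(fc_threshold = fc_threshold, fc_scale = fc_scale,
                 alpha = alpha, cooks_cutoff = cooks_cutoff,
                 if_alpha = if_alpha, min_total_count = min_total_count,
                 classify_rule = classify_rule, top_fraction = top_fraction,
                 panel = panel, min_species = min_species, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full per-species pipeline
#'
#' Executes, for one species dataset: the within-sex T1->T2 contrast in each
#' sex, the between-sex contrast at T2, the FC-plane classification, the
#' mechanism summary and the top-gene screen. Per-stage gene counts are
#' logged to stderr (`verbose = TRUE`).
#'
#' @param dataset an `ExpressionDataset`.
#' @param config a `PipelineConfig`.
#' @param out_dir optional directory: when given, all result tables are
#'   written there as TSV.
#' @param verbose log per-stage counts to stderr.
#' @return list: `de_female`, `de_male`, `t2_contrast` (`DEResult`s),
#'   `dynamics` (`DynamicsTable`), `summary` (`MechanismSummary`), `top`
#'   (top-gene table).
#' @export
run_species <- function(dataset, config = pipeline_config(), out_dir = NULL,
                        verbose = TRUE) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  say <- function(...) if (verbose) message(sprintf(...))
  engine <- function(sex) {
    if (dataset$platform == "counts") {
      nb_wald_test(dataset, sex, cooks_cutoff = config$cooks_cutoff,
                   if_alpha = config$if_alpha,
                   min_total_count = config$min_total_count,
                   fc_threshold = config$fc_threshold, alpha = config$alpha,
                   fc_scale = config$fc_scale)
    } else {
      moderated_t_test(dataset, sex, fc_threshold = config$fc_threshold,
                       alpha = config$alpha, fc_scale = config$fc_scale)
    }
  }
  say("[%s] %d genes, %d samples (%s)", dataset$species, nrow(dataset$values),
      ncol(dataset$values), dataset$platform)
  de_f <- engine("F")
  de_m <- engine("M")
  say("[%s] DEGs T1->T2: %d in females, %d in males", dataset$species,
      sum(de_f$is_deg), sum(de_m$is_deg))
  t2 <- between_sex_contrast_t2(dataset, fc_threshold = config$fc_threshold,
                                alpha = config$alpha, fc_scale = config$fc_scale,
                                cooks_cutoff = config$cooks_cutoff,
                                if_alpha = config$if_alpha,
                                min_total_count = config$min_total_count)
  dyn <- build_dynamics_table(de_f, de_m, t2, rule = config$classify_rule,
                              margin = config$fc_threshold)
  summ <- summarize_mechanisms(dyn, total_genes = nrow(dataset$values))
  say("[%s] classified: %d MEG, %d FEG, %d shared (%d DEGs of %d genes)",
      dataset$species, sum(dyn$class == "MEG"), sum(dyn$class == "FEG"),
      sum(dyn$class == "SHARED"), summ$total_degs, summ$total_genes)
  top <- top_genes(dyn, fraction = config$top_fraction)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_de_result(de_f, file.path(out_dir, "de_female.tsv"))
    write_de_result(de_m, file.path(out_dir, "de_male.tsv"))
    write_de_result(t2, file.path(out_dir, "t2_contrast.tsv"))
    write_dynamics_table(dyn, file.path(out_dir, "dynamics.tsv"))
    write_mechanism_summary(summ, file.path(out_dir, "summary.tsv"))
    utils::write.table(top, file.path(out_dir, "top_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(de_female = de_f, de_male = de_m, t2_contrast = t2, dynamics = dyn,
       summary = summ, top = top)
}

#' Run the cross-species comparison
#'
#' Harmonizes symbols, builds the key-gene panel report and FC statistics,
#' runs the SD sex-difference permutation tests, the shared/novel top-gene
#' screen, and (when a collection is supplied) the per-species FEG/MEG
#' enrichment plus conserved-pathway calling.
#'
#' @param species_results named list (by species) of [run_species()] outputs.
#' @param config a `PipelineConfig`.
#' @param map optional `OrthologMap`.
#' @param collection optional `GeneSetCollection` for enrichment.
#' @param out_dir optional output directory for TSV artifacts.
#' @return list: `aligned`, `panel_report`, `panel_stats`, `sd_tests`,
#'   `top_lists`, `shared_top`, `novel`, and (with a collection)
#'   `enrichment`, `conserved`.
#' @export
run_comparison <- function(species_results, config = pipeline_config(),
                           map = NULL, collection = NULL, out_dir = NULL) {
  if (length(species_results) < 2) stop("need >= 2 species for a comparison")
  tables <- lapply(species_results, `[[`, "dynamics")
  aligned <- harmonize_symbols(tables, map = map)
  panel_report <- key_gene_panel(aligned, panel = config$panel,
                                 min_species = config$min_species)
  panel_stats <- panel_fc_stats(aligned, panel = config$panel)
  meg_panel <- config$panel[1:min(3, length(config$panel))]
  feg_panel <- config$panel[-seq_along(meg_panel)]
  try_sd <- function(genes, seed) {
    if (length(genes) == 0 || !any(toupper(genes) %in% aligned$symbol)) return(NULL)
    sd_sex_difference_test(aligned, genes, n_perm = config$n_perm, seed = seed)
  }
  sd_tests <- list(meg_panel = try_sd(meg_panel, config$seed),
                   feg_panel = try_sd(feg_panel, config$seed + 1L))
  top_lists <- lapply(names(species_results), function(sp) {
    top_genes(aligned[aligned$species == sp, , drop = FALSE],
              fraction = config$top_fraction)
  })
  names(top_lists) <- names(species_results)
  shared <- shared_top_genes(top_lists, min_species = config$min_species)
  novel <- novel_markers(shared, key_panel = config$panel)
  out <- list(aligned = aligned, panel_report = panel_report,
              panel_stats = panel_stats, sd_tests = sd_tests,
              top_lists = top_lists, shared_top = shared, novel = novel)
  if (!is.null(collection)) {
    enr <- lapply(names(species_results), function(sp) {
      sub <- aligned[aligned$species == sp, , drop = FALSE]
      enrich_all(sub$symbol[sub$class == "FEG"], sub$symbol[sub$class == "MEG"],
                 background = sub$symbol, collection = collection,
                 alpha = config$alpha)
    })
    names(enr) <- names(species_results)
    out$enrichment <- enr
    out$conserved <- conserved_pathways(enr, min_species = config$min_species)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(aligned, file.path(out_dir, "aligned_fc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(panel_report$grid, file.path(out_dir, "panel_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(panel_stats, file.path(out_dir, "panel_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(shared, file.path(out_dir, "shared_top_genes.txt"))
    writeLines(novel, file.path(out_dir, "novel_markers.txt"))
    if (!is.null(out$conserved)) {
      utils::write.table(out$conserved, file.path(out_dir, "conserved_pathways.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
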