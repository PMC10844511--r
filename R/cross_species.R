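#' Harmonize gene symbols across species
#'
#' Maps each species' native gene/probe identifiers to canonical uppercase
#' symbols (via an [ortholog_map()] when supplied, uppercase fallback
#' otherwise) and collapses multiple probes of one gene to a single row. The
#' collapse keeps the probe with the largest max(|fc_female|, |fc_male|) over
#' its significant per-sex changes; if no probe is significant, the probe
#' with the largest base mean (largest absolute FC when base means are
#' missing). Idempotent: harmonizing an already-harmonized table is a no-op.
#'
#' @param tables named list (by species label) of `DynamicsTable`s.
#' @param map optional `OrthologMap`.
#' @return An `AlignedFCTable`: long data.frame with columns `symbol`,
#'   `species`, and the dynamics-table columns. Attribute `n_unmapped` counts
#'   per species the ids that fell back to plain uppercasing while a map was
#'   supplied.
#' @export
harmonize_symbols <- function(tables, map = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  n_unmapped <- integer(0)
  rows <- lapply(names(tables), function(sp) {
    tab <- tables[[sp]]
    sym <- map_symbols(map, sp, tab$gene_id)
    if (!is.null(map)) {
      mapped <- toupper(tab$gene_id) %in%
        toupper(map$native_symbol[map$species %in% c(sp, "*")])
      n_unmapped[[sp]] <<- sum(!mapped)
    }
    tab$symbol <- sym
    tab$species <- sp
    collapse_probes(tab)
  })
  if (length(n_unmapped) && any(n_unmapped > 0)) {
    warning(sum(n_unmapped), " identifier(s) not in the ortholog map; kept uppercased")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("AlignedFCTable", "data.frame")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

collapse_probes <- function(tab) {
  sig_fc <- pmax(ifelse(tab$sig_female, abs(tab$fc_female), -Inf),
                 ifelse(tab$sig_male, abs(tab$fc_male), -Inf))
  any_sig <- is.finite(sig_fc)
  fallback <- if (!is.null(tab$base_mean) && !all(is.na(tab$base_mean))) {
    ifelse(is.na(tab$base_mean), -Inf, tab$base_mean)
  } else {
    pmax(abs(tab$fc_female), abs(tab$fc_male))
  }
  # significant probes always outrank non-significant ones
  key <- ifelse(any_sig, sig_fc, -1 / (1 + pmax(fallback, 0)))
  ord <- order(tab$symbol, -key)
  tab <- tab[ord, , drop = FALSE]
  tab[!duplicated(tab$symbol), , drop = FALSE]
}

default_key_panel <- function() c("AMH", "SOX9", "DMRT1", "CYP19A1", "FOXL2", "FST")

#' Key-gene panel report
#'
#' Extracts the per-species FC-plane points for a panel of canonical sex
#' differentiation genes (default: the male-associated trio amh, sox9, dmrt1
#' and the female-associated trio cyp19a1, foxl2, fst) and flags each gene as
#' panel-reportable when it has a significant change in at least
#' `min_species` species in at least one sex (the species count is taken per
#' sex; the best sex decides).
#'
#' @param aligned an `AlignedFCTable`.
#' @param panel character vector of canonical symbols.
#' @param min_species reportability threshold (default 3).
#' @return A `PanelReport`: list with `grid` (long data.frame of panel gene x
#'   species points, NA rows for absent species) and `reportable` (named
#'   logical per panel gene).
#' @export
key_gene_panel <- function(aligned, panel = default_key_panel(), min_species = 3) {
  if (length(panel) == 0) stop("empty key-gene panel")
  panel <- toupper(panel)
  species <- unique(aligned$species)
  grid <- expand.grid(symbol = panel, species = species,
                      stringsAsFactors = FALSE)
  idx <- match(paste(grid$symbol, grid$species),
               paste(aligned$symbol, aligned$species))
  for (col in c("fc_female", "fc_male", "padj_female", "padj_male")) {
    grid[[col]] <- aligned[[col]][idx]
  }
  grid$sig_female <- aligned$sig_female[idx]
  grid$sig_male <- aligned$sig_male[idx]
  grid$class <- aligned$class[idx]
  reportable <- vapply(panel, function(g) {
    rows <- grid[grid$symbol == g & !is.na(grid$class), , drop = FALSE]
    max(sum(rows$sig_female, na.rm = TRUE), sum(rows$sig_male, na.rm = TRUE)) >= min_species
  }, logical(1))
  structure(list(grid = grid, reportable = reportable, panel = panel),
            class = "PanelReport")
}

#' Per-gene per-sex FC mean and SD across species
#'
#' Arithmetic mean and sample SD (n-1 denominator) of the estimated per-sex
#' log2 fold changes across the species where the gene is present.
#' Non-significant estimates are included (they are estimates, not zeros);
#' fewer than 2 non-NA species give an NA SD with a warning.
#'
#' @param aligned an `AlignedFCTable`.
#' @param panel character vector of canonical symbols.
#' @return data.frame: `symbol`, `sex`, `n_species`, `mean_fc`, `sd_fc`.
#' @export
panel_fc_stats <- function(aligned, panel = default_key_panel()) {
  panel <- toupper(panel)
  rows <- lapply(panel, function(g) {
    sub <- aligned[aligned$symbol == g, , drop = FALSE]
    do.call(rbind, lapply(c(F = "fc_female", M = "fc_male"), function(col) {
      v <- sub[[col]][!is.na(sub[[col]])]
      data.frame(symbol = g, sex = if (col == "fc_female") "F" else "M",
                 n_species = length(v),
                 mean_fc = if (length(v) >= 1) mean(v) else NA_real_,
                 sd_fc = if (length(v) >= 2) stats::sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$n_species == 1)) {
    warning("panel gene(s) present in a single species: SD undefined")
  }
  out
}

#' Permutation test for sex differences in cross-species FC variability
#'
#' Tests whether the across-species SD of the fold change differs between
#' males and females over a group of genes (e.g. the three male-associated or
#' the three female-associated panel genes). The statistic is
#' mean(SD_male) - mean(SD_female) over the group. The null is built by
#' independently swapping each gene-by-species (fc_male, fc_female) pair's
#' sex labels with probability 1/2 and recomputing the statistic; the
#' two-sided p-value is `(1 + #{|T*| >= |T|}) / (n_perm + 1)`.
#'
#' @param aligned an `AlignedFCTable`.
#' @param genes canonical symbols of the gene group.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed (deterministic result).
#' @return list with `statistic`, `p_value`, `n_perm`.
#' @export
sd_sex_difference_test <- function(aligned, genes, n_perm = 999, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  genes <- toupper(genes)
  sub <- aligned[aligned$symbol %in% genes &
                   !is.na(aligned$fc_female) & !is.na(aligned$fc_male), ,
                 drop = FALSE]
  if (nrow(sub) == 0) stop("no gene-species pairs with both FCs available")
  stat_fun <- function(fc_f, fc_m) {
    sds <- vapply(genes, function(g) {
      i <- sub$symbol == g
      c(f = if (sum(i) >= 2) stats::sd(fc_f[i]) else NA_real_,
        m = if (sum(i) >= 2) stats::sd(fc_m[i]) else NA_real_)
    }, numeric(2))
    mean(sds["m", ], na.rm = TRUE) - mean(sds["f", ], na.rm = TRUE)
  }
  observed <- stat_fun(sub$fc_female, sub$fc_male)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i) {
    swap <- stats::runif(nrow(sub)) < 0.5
    f <- ifelse(swap, sub$fc_male, sub$fc_female)
    m <- ifelse(swap, sub$fc_female, sub$fc_male)
    stat_fun(f, m)
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(observed))) / (n_perm + 1)
  list(statistic = observed, p_value = p, n_perm = n_perm)
}

#' Top genes of one species by absolute fold change
#'
#' Ranks the DEGs (points classified MEG, FEG or SHARED) by the largest
#' absolute per-sex log2 fold change among their significant changes and
#' keeps the top `fraction` (list size `ceiling(fraction * nDEG)`). Ties are
#' broken by the smaller of the two per-sex adjusted p-values, then by
#' symbol.
#'
#' @param dynamics_table a `DynamicsTable` (or a harmonized per-species slice
#'   with a `symbol` column, used for ranking identity if present).
#' @param fraction fraction of DEGs to keep (default 0.10).
#' @return data.frame of the retained genes with `rank_fc` (the ranking key),
#'   ordered best-first; zero rows when there are no DEGs.
#' @export
top_genes <- function(dynamics_table, fraction = 0.10) {
  deg <- dynamics_table[dynamics_table$class != "NONSIG", , drop = FALSE]
  if (nrow(deg) == 0) return(deg)
  rank_fc <- pmax(ifelse(deg$sig_female, abs(deg$fc_female), -Inf),
                  ifelse(deg$sig_male, abs(deg$fc_male), -Inf))
  min_padj <- pmin(ifelse(is.na(deg$padj_female), Inf, deg$padj_female),
                   ifelse(is.na(deg$padj_male), Inf, deg$padj_male))
  id <- if (!is.null(deg$symbol)) deg$symbol else deg$gene_id
  ord <- order(-rank_fc, min_padj, id)
  n_keep <- ceiling(fraction * nrow(deg))
  out <- deg[ord[seq_len(n_keep)], , drop = FALSE]
  out$rank_fc <- rank_fc[ord[seq_len(n_keep)]]
  rownames(out) <- NULL
  out
}

#' Top genes shared across species
#'
#' @param per_species_lists named list of per-species top-gene tables (with a
#'   `symbol` column) or plain character vectors of symbols.
#' @param min_species minimum number of species a symbol must appear in
#'   (default 3).
#' @return sorted character vector of shared canonical symbols.
#' @export
shared_top_genes <- function(per_species_lists, min_species = 3) {
  if (length(per_species_lists) < min_species) {
    stop("fewer species lists (", length(per_species_lists),
         ") than min_species (", min_species, ")")
  }
  syms <- lapply(per_species_lists, function(x) {
    unique(toupper(if (is.data.frame(x)) x$symbol %||% x$gene_id else x))
  })
  counts <- table(unlist(syms))
  sort(names(counts)[counts >= min_species])
}

#' Novel markers: shared top genes outside the key panel
#'
#' @param shared_set character vector of shared top-gene symbols.
#' @param key_panel character vector of key-gene symbols.
#' @return sorted character vector of novel marker symbols.
#' @export
novel_markers <- function(shared_set, key_panel = default_key_panel()) {
  sort(setdiff(toupper(shared_set), toupper(key_panel)))
}
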