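#' One-sided hypergeometric overrepresentation test
#'
#' Exact upper-tail probability that a query list drawn from the background
#' contains at least the observed number of members of a gene set:
#' `p = P(X >= overlap)` for X hypergeometric with population `|background|`,
#' successes `|set ∩ background|`, draws `|query|`, computed by exact
#' summation of the pmf. The set is intersected with the background before
#' testing; every query gene must be in the background.
#'
#' @param query_genes character vector (the annotated FEGs or MEGs).
#' @param background_genes character vector (the dataset's annotated
#'   universe).
#' @param gene_set character vector of set member symbols.
#' @param set_id optional set identifier carried into the record.
#' @return An `EnrichmentRecord` one-row data.frame: `set_id`, `query_size`,
#'   `background_size`, `set_size`, `overlap`, `gene_ratio`, `p_value`.
#' @export
overrepresentation_test <- function(query_genes, background_genes, gene_set,
                                    set_id = NA_character_) {
  query <- unique(toupper(query_genes))
  bg <- unique(toupper(background_genes))
  set <- unique(toupper(gene_set))
  missing <- setdiff(query, bg)
  if (length(missing) > 0) {
    stop("query gene(s) absent from background: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  k <- length(intersect(set, bg))
  n_bg <- length(bg)
  n_q <- length(query)
  ov <- length(intersect(intersect(set, bg), query))
  p <- hypergeom_upper_tail(ov, k, n_bg, n_q)
  data.frame(set_id = set_id, query_size = n_q, background_size = n_bg,
             set_size = k, overlap = ov,
             gene_ratio = if (n_q > 0) ov / n_q else 0,
             p_value = p, stringsAsFactors = FALSE)
}

# P(X >= ov) by exact pmf summation; X ~ Hypergeom(pop n_bg, succ k, draws n_q)
hypergeom_upper_tail <- function(ov, k, n_bg, n_q) {
  if (ov <= 0) return(1)
  upper <- min(k, n_q)
  if (ov > upper) return(0)
  sum(stats::dhyper(ov:upper, k, n_bg - k, n_q))
}

#' Overrepresentation of FEGs and MEGs against a gene-set collection
#'
#' Runs the hypergeometric test for every set against both query lists, using
#' the dataset-specific background restricted to the collection's universe
#' (genes without any set annotation drop from query and background alike).
#' P-values are deliberately left uncorrected. Sets disjoint from the
#' background are skipped with a warning.
#'
#' @param feg_list,meg_list character vectors of canonical symbols.
#' @param background character vector: the dataset's annotated universe.
#' @param collection a `GeneSetCollection`.
#' @param alpha enrichment call threshold on the uncorrected p (default
#'   0.05).
#' @return list of two data.frames (`feg`, `meg`) of `EnrichmentRecord` rows
#'   sorted by p, each with a logical `enriched` column.
#' @export
enrich_all <- function(feg_list, meg_list, background, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (length(collection$sets) == 0) stop("empty gene-set collection")
  universe <- unique(toupper(unlist(collection$sets)))
  bg <- intersect(unique(toupper(background)), universe)
  run <- function(query) {
    q <- intersect(unique(toupper(query)), bg)
    rows <- lapply(names(collection$sets), function(id) {
      set <- collection$sets[[id]]
      if (length(intersect(toupper(set), bg)) == 0) {
        warning("set ", id, " disjoint from background; skipped")
        return(NULL)
      }
      overrepresentation_test(q, bg, set, set_id = id)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) stop("no testable sets")
    tab$enriched <- tab$p_value < alpha
    tab[order(tab$p_value, tab$set_id), , drop = FALSE]
  }
  list(feg = run(feg_list), meg = run(meg_list))
}

#' Conserved pathways across species
#'
#' A pathway is FEG-conserved when enriched in the FEGs of at least
#' `min_species` species (same for MEGs); pathways conserved on both sides
#' are labeled `both`, else `FEG-only` / `MEG-only`. Pathways enriched in
#' fewer species are excluded.
#'
#' @param per_species_tables named list (by species) of [enrich_all()]
#'   outputs.
#' @param min_species conservation threshold (default 3).
#' @return data.frame: `set_id`, `label`, `n_species_feg`, `n_species_meg`,
#'   plus per-species FEG gene-ratio columns `ratio_feg.<species>` for
#'   plotting.
#' @export
conserved_pathways <- function(per_species_tables, min_species = 3) {
  if (min_species > length(per_species_tables)) {
    stop("min_species exceeds the number of species")
  }
  species <- names(per_species_tables)
  count_side <- function(side) {
    ids <- unique(unlist(lapply(per_species_tables, function(x) x[[side]]$set_id)))
    sapply(ids, function(id) {
      sum(vapply(per_species_tables, function(x) {
        tab <- x[[side]]
        any(tab$set_id == id & tab$enriched)
      }, logical(1)))
    })
  }
  n_feg <- count_side("feg")
  n_meg <- count_side("meg")
  ids <- union(names(n_feg), names(n_meg))
  nf <- ifelse(ids %in% names(n_feg), n_feg[ids], 0L)
  nm <- ifelse(ids %in% names(n_meg), n_meg[ids], 0L)
  feg_cons <- nf >= min_species
  meg_cons <- nm >= min_species
  keep <- feg_cons | meg_cons
  label <- ifelse(feg_cons & meg_cons, "both",
                  ifelse(feg_cons, "FEG-only", "MEG-only"))
  out <- data.frame(set_id = ids[keep], label = label[keep],
                    n_species_feg = as.integer(nf[keep]),
                    n_species_meg = as.integer(nm[keep]),
                    stringsAsFactors = FALSE)
  for (sp in species) {
    tab <- per_species_tables[[sp]]$feg
    out[[paste0("ratio_feg.", sp)]] <- tab$gene_ratio[match(out$set_id, tab$set_id)]
  }
  rownames(out) <- NULL
  out[order(out$set_id), , drop = FALSE]
}
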