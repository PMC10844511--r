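#' Construct and validate an expression dataset
#'
#' Bundles a gene-by-sample expression matrix with its sample metadata into a
#' validated `ExpressionDataset`. The design must be a full two-sex
#' (`F`/`M`) by two-stage (`T1`/`T2`) layout with at least two replicates in
#' every sex-stage cell, mirroring the minimal design used for comparative
#' gonadal transcriptomics.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns. Non-negative integers when `platform = "counts"`; real values
#'   (interpreted as log2-scale normalized intensities) when
#'   `platform = "intensity"`.
#' @param samples data.frame with columns `sample_id`, `sex`, `stage` (one row
#'   per matrix column, same order). Sex/stage tokens are normalized
#'   case-insensitively: "female"/"f" to `F`, "male"/"m" to `M`, "t1"/"t2" to
#'   `T1`/`T2`.
#' @param platform `"counts"` or `"intensity"`.
#' @param species free-text species label.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `samples` (with added `replicate` index within each sex-stage
#'   cell), `platform`, `species`.
#' @export
expression_dataset <- function(values, samples, platform = c("counts", "intensity"),
                               species = "unspecified") {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("matrix must have gene ids as rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyNA(values)) stop("missing values in expression matrix")
  if (!is.numeric(values)) stop("expression matrix must be numeric")
  if (platform == "counts") {
    if (any(values < 0)) stop("negative values in counts matrix")
    if (any(values != round(values))) stop("non-integer count in counts matrix")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "sex", "stage")
  if (!all(required %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(required, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (nrow(samples) != ncol(values)) {
    stop("sample sheet rows (", nrow(samples), ") do not match matrix columns (",
         ncol(values), ")")
  }
  if (!is.null(colnames(values))) {
    if (!setequal(colnames(values), samples$sample_id)) {
      stop("sample id mismatch between matrix and sample sheet")
    }
    # preserve matrix column order; reorder the sheet to it
    samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  } else {
    colnames(values) <- samples$sample_id
  }
  samples$sex <- normalize_sex(samples$sex)
  samples$stage <- normalize_stage(samples$stage)
  if (!setequal(unique(samples$sex), c("F", "M"))) stop("exactly two sexes (F, M) required")
  if (!setequal(unique(samples$stage), c("T1", "T2"))) stop("exactly two stages (T1, T2) required")
  cell <- interaction(samples$sex, samples$stage, drop = FALSE)
  tab <- table(factor(cell, levels = c("F.T1", "M.T1", "F.T2", "M.T2")))
  if (any(tab < 2)) {
    bad <- names(tab)[tab < 2]
    stop("fewer than 2 replicates in sex-stage cell(s): ", paste(bad, collapse = ", "))
  }
  samples$replicate <- stats::ave(seq_len(nrow(samples)), cell, FUN = seq_along)
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, platform = platform,
                 species = species),
            class = "ExpressionDataset")
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- ifelse(x %in% c("F", "FEMALE"), "F", ifelse(x %in% c("M", "MALE"), "M", NA))
  if (anyNA(out)) stop("unrecognized sex token(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

normalize_stage <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (!all(x %in% c("T1", "T2"))) {
    stop("unrecognized stage token(s): ",
         paste(setdiff(unique(x), c("T1", "T2")), collapse = ", "))
  }
  x
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$platform, x$species))
  print(table(sex = x$samples$sex, stage = x$samples$stage))
  invisible(x)
}

#' Read an expression dataset from delimited text
#'
#' The matrix file has the gene id in the first column (header `gene_id` or
#' any name) and one column per sample; the sample sheet has columns
#' `sample_id`, `sex`, `stage`. Delimiter is auto-detected (tab or comma).
#'
#' @param matrix_path path to the expression matrix.
#' @param samples_path path to the sample sheet.
#' @inheritParams expression_dataset
#' @return An `ExpressionDataset`.
#' @export
read_expression_dataset <- function(matrix_path, samples_path,
                                    platform = c("counts", "intensity"),
                                    species = "unspecified") {
  platform <- match.arg(platform)
  mat_df <- read_delim_auto(matrix_path)
  if (ncol(mat_df) < 2) stop("expression matrix needs a gene id column and >=1 sample")
  ids <- as.character(mat_df[[1]])
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(values) <- ids
  samples <- read_delim_auto(samples_path)
  expression_dataset(values, samples, platform = platform, species = species)
}

#' Write an expression dataset to delimited text
#'
#' Writes the matrix (first column `gene_id`) and the sample sheet as
#' tab-separated text; `read_expression_dataset` round-trips the result.
#'
#' @param dataset an `ExpressionDataset`.
#' @param matrix_path,samples_path output paths.
#' @return Invisibly, `dataset`.
#' @export
write_expression_dataset <- function(dataset, matrix_path, samples_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  out <- data.frame(gene_id = rownames(dataset$values), dataset$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$samples[, c("sample_id", "sex", "stage")],
                     samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT format: one set per line, tab-separated fields
#' `set_id`, `description`, then member gene symbols. Member symbols are
#' canonicalized to uppercase; duplicates within a line are dropped.
#'
#' @param gmt_path path to the GMT file.
#' @return A `GeneSetCollection`: list with `sets` (named list of uppercase
#'   character vectors) and `descriptions` (named character vector).
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 3)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(n_fields < 3), collapse = ", "))
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate set_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- ids
  desc <- vapply(parts, `[[`, "", 2L)
  names(desc) <- ids
  structure(list(sets = sets, descriptions = desc), class = "GeneSetCollection")
}

#' Read an ortholog/alias symbol map
#'
#' Three-column delimited text: `species` (or `*` for a global alias row),
#' `native_symbol`, `canonical_symbol`. Canonical symbols are uppercased.
#' The map must be a function: one canonical symbol per (species, native) key.
#'
#' @param path path to the map file (TSV or CSV, with header).
#' @return An `OrthologMap` data.frame with columns `species`,
#'   `native_symbol`, `canonical_symbol`.
#' @export
read_ortholog_map <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 3) stop("ortholog map needs 3 columns: species, native_symbol, canonical_symbol")
  names(df)[1:3] <- c("species", "native_symbol", "canonical_symbol")
  ortholog_map(df)
}

#' @rdname read_ortholog_map
#' @param df data.frame with the three map columns.
#' @export
ortholog_map <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$species <- as.character(df$species)
  df$native_symbol <- as.character(df$native_symbol)
  df$canonical_symbol <- toupper(as.character(df$canonical_symbol))
  key <- paste(df$species, toupper(df$native_symbol), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    # identical duplicate rows are tolerated; conflicting ones are an error
    first <- match(key, key)
    if (any(df$canonical_symbol != df$canonical_symbol[first])) {
      stop("conflicting duplicate keys in ortholog map")
    }
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, class = c("OrthologMap", "data.frame"))
}

#' Look up canonical symbols in an ortholog map
#'
#' Species-specific rows take precedence over global (`*`) alias rows; symbols
#' absent from the map fall back to their uppercase form. Lookup is
#' case-insensitive on the native symbol.
#'
#' @param map an `OrthologMap` or NULL (pure uppercase fallback).
#' @param species species label of the symbols.
#' @param symbols character vector of native symbols.
#' @return Character vector of canonical (uppercase) symbols.
#' @export
map_symbols <- function(map, species, symbols) {
  out <- toupper(symbols)
  if (is.null(map)) return(out)
  stopifnot(inherits(map, "OrthologMap"))
  up <- toupper(symbols)
  glob <- map[map$species == "*", , drop = FALSE]
  hit <- match(up, toupper(glob$native_symbol))
  out[!is.na(hit)] <- glob$canonical_symbol[hit[!is.na(hit)]]
  spec_rows <- map[map$species == species, , drop = FALSE]
  hit <- match(up, toupper(spec_rows$native_symbol))
  out[!is.na(hit)] <- spec_rows$canonical_symbol[hit[!is.na(hit)]]
  out
}
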