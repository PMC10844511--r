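#' Simulation configuration for two-sex, two-stage expression data
#'
#' Describes the world the generator emulates: a gonadal transcriptome sampled
#' in both sexes at the onset (T1) and towards the end (T2) of sex
#' differentiation, with genes planted as male-enriched (MEG), female-enriched
#' (FEG), shared stage-regulated, or null. Sex enrichment is planted via the
#' three mechanisms observed in such data: upregulation in the enriched sex
#' only, downregulation in the opposite sex only, or both simultaneously.
#'
#' @param n_genes number of genes.
#' @param replicates replicates per sex-stage cell (>= 2).
#' @param platform `"counts"` (negative-binomial RNA-seq-like) or
#'   `"intensity"` (Gaussian log2 microarray-like).
#' @param proportions named numeric vector summing to 1 over the nine planted
#'   classes `meg_up`, `meg_down_opp`, `meg_both`, `feg_up`, `feg_down_opp`,
#'   `feg_both`, `shared_up`, `shared_down`, `null`.
#' @param effect_range range of planted |log2 fold change|, drawn uniformly;
#'   lower bound must be > 0 (default starts at the 1.5 log2 DEG threshold so
#'   every planted effect is detectable in principle).
#' @param baseline_log_mean,baseline_log_sd counts platform: mean/sd of the
#'   per-gene log (natural) baseline expected count, i.e. baseline means are
#'   log-normal.
#' @param dispersion_a0,dispersion_a1 counts platform: per-gene NB dispersion
#'   `alpha_g = dispersion_a1 + dispersion_a0 / mu_g` (set `dispersion_a0 = 0`
#'   for a constant dispersion).
#' @param libsize_range counts platform: library-size factors drawn
#'   log-uniformly within this range.
#' @param intensity_mean,intensity_sd intensity platform: mean/sd of the
#'   per-gene baseline log2 intensity.
#' @param residual_sd intensity platform: within-group residual sd (log2).
#' @param seed integer seed; all draws flow from this single seed.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 20000,
                              replicates = 3,
                              platform = c("counts", "intensity"),
                              proportions = c(meg_up = 0.04, meg_down_opp = 0.03,
                                              meg_both = 0.01, feg_up = 0.04,
                                              feg_down_opp = 0.03, feg_both = 0.01,
                                              shared_up = 0.01, shared_down = 0.01,
                                              null = 0.82),
                              effect_range = c(1.5, 4),
                              baseline_log_mean = log(100),
                              baseline_log_sd = 1,
                              dispersion_a0 = 0.5,
                              dispersion_a1 = 0.01,
                              libsize_range = c(0.5, 2),
                              intensity_mean = 7,
                              intensity_sd = 2,
                              residual_sd = 0.3,
                              seed = 1L) {
  platform <- match.arg(platform)
  cls <- c("meg_up", "meg_down_opp", "meg_both", "feg_up", "feg_down_opp",
           "feg_both", "shared_up", "shared_down", "null")
  if (is.null(names(proportions))) names(proportions) <- cls[seq_along(proportions)]
  if (!setequal(names(proportions), cls)) {
    stop("proportions must be named over: ", paste(cls, collapse = ", "))
  }
  proportions <- proportions[cls]
  if (abs(sum(proportions) - 1) > 1e-9) stop("class proportions must sum to 1")
  if (any(proportions < 0)) stop("negative class proportion")
  if (effect_range[1] <= 0) stop("effect lower bound must be > 0")
  if (replicates < 2) stop("need >= 2 replicates per sex-stage cell")
  structure(list(n_genes = as.integer(n_genes), replicates = as.integer(replicates),
                 platform = platform, proportions = proportions,
                 effect_range = effect_range,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion_a0 = dispersion_a0, dispersion_a1 = dispersion_a1,
                 libsize_range = libsize_range,
                 intensity_mean = intensity_mean, intensity_sd = intensity_sd,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Largest-remainder apportionment of class counts
#'
#' Turns class proportions into integer counts summing exactly to `n`:
#' floor(p*n) per class, then the remaining units go to the classes with the
#' largest fractional remainders (ties broken by class order).
#' @keywords internal
apportion_counts <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

sim_class_table <- function() {
  data.frame(
    sim_class = c("meg_up", "meg_down_opp", "meg_both", "feg_up", "feg_down_opp",
                  "feg_both", "shared_up", "shared_down", "null"),
    class = c("MEG", "MEG", "MEG", "FEG", "FEG", "FEG", "SHARED", "SHARED", "NULL"),
    mechanism = c("own-up-only", "opposite-down-only", "both",
                  "own-up-only", "opposite-down-only", "both",
                  "n/a", "n/a", "n/a"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-sex, two-stage dataset with planted ground truth
#'
#' T1 is sex-balanced: every planted change happens between T1 and T2, within
#' one or both sexes, so that sex enrichment at T2 arises purely from the
#' planted mechanism. Counts are drawn negative-binomially with mean
#' `s_j * mu_g * 2^delta` and dispersion `alpha_g`; intensities are Gaussian
#' around `baseline + delta`. Draw order is fixed (gene-level quantities
#' first, then library sizes, then the data matrix), so results are
#' bitwise-reproducible given the seed.
#'
#' @param config a `SimulationConfig`.
#' @return list with `dataset` (an `ExpressionDataset`) and `truth` (a
#'   `PlantedTruth` data.frame: `gene_id`, `class`, `mechanism`, `delta_f`,
#'   `delta_m`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  tab <- sim_class_table()
  counts_per_class <- apportion_counts(config$proportions, n)
  sim_class <- rep(tab$sim_class, counts_per_class)
  gene_id <- sprintf("g%05d", seq_len(n))

  # planted per-sex log2 changes; "both"-mechanism genes get independent
  # magnitudes for the up and the down component
  d1 <- stats::runif(n, config$effect_range[1], config$effect_range[2])
  d2 <- stats::runif(n, config$effect_range[1], config$effect_range[2])
  delta_f <- numeric(n)
  delta_m <- numeric(n)
  delta_m[sim_class == "meg_up"] <- d1[sim_class == "meg_up"]
  delta_f[sim_class == "meg_down_opp"] <- -d1[sim_class == "meg_down_opp"]
  delta_m[sim_class == "meg_both"] <- d1[sim_class == "meg_both"]
  delta_f[sim_class == "meg_both"] <- -d2[sim_class == "meg_both"]
  delta_f[sim_class == "feg_up"] <- d1[sim_class == "feg_up"]
  delta_m[sim_class == "feg_down_opp"] <- -d1[sim_class == "feg_down_opp"]
  delta_f[sim_class == "feg_both"] <- d1[sim_class == "feg_both"]
  delta_m[sim_class == "feg_both"] <- -d2[sim_class == "feg_both"]
  delta_f[sim_class == "shared_up"] <- d1[sim_class == "shared_up"]
  delta_m[sim_class == "shared_up"] <- d1[sim_class == "shared_up"]
  delta_f[sim_class == "shared_down"] <- -d1[sim_class == "shared_down"]
  delta_m[sim_class == "shared_down"] <- -d1[sim_class == "shared_down"]

  r <- config$replicates
  samples <- expand.grid(replicate = seq_len(r), stage = c("T1", "T2"),
                         sex = c("F", "M"), stringsAsFactors = FALSE)
  samples <- samples[, c("sex", "stage", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$sex, samples$stage, samples$replicate)
  n_samp <- nrow(samples)

  # per-sample planted log2 shift: delta applies at T2 only
  delta_mat <- outer(delta_f, as.numeric(samples$sex == "F" & samples$stage == "T2")) +
    outer(delta_m, as.numeric(samples$sex == "M" & samples$stage == "T2"))

  if (config$platform == "counts") {
    mu_g <- exp(stats::rnorm(n, config$baseline_log_mean, config$baseline_log_sd))
    alpha_g <- config$dispersion_a1 + config$dispersion_a0 / mu_g
    ls_range <- log(config$libsize_range)
    s_j <- exp(stats::runif(n_samp, ls_range[1], ls_range[2]))
    mu <- (mu_g * 2^delta_mat) * rep(s_j, each = n)
    values <- matrix(stats::rnbinom(n * n_samp, mu = mu, size = rep(1 / alpha_g, n_samp)),
                     nrow = n, ncol = n_samp)
  } else {
    base_g <- stats::rnorm(n, config$intensity_mean, config$intensity_sd)
    values <- base_g + delta_mat +
      matrix(stats::rnorm(n * n_samp, 0, config$residual_sd), nrow = n, ncol = n_samp)
  }
  rownames(values) <- gene_id
  colnames(values) <- samples$sample_id

  truth <- data.frame(gene_id = gene_id,
                      class = tab$class[match(sim_class, tab$sim_class)],
                      mechanism = tab$mechanism[match(sim_class, tab$sim_class)],
                      delta_f = delta_f, delta_m = delta_m,
                      stringsAsFactors = FALSE)
  class(truth) <- c("PlantedTruth", "data.frame")
  dataset <- expression_dataset(values, samples[, c("sample_id", "sex", "stage")],
                                platform = config$platform, species = "synthetic")
  list(dataset = dataset, truth = truth)
}

#' Truth-side mechanism summary
#'
#' Tabulates planted classes into the same disjoint categories as the
#' estimated mechanism summary (see [summarize_mechanisms()]): MEGs split into
#' genes upregulated in males (mechanisms own-up-only and both) vs genes
#' downregulated in females only; FEGs mirrored; shared genes counted once.
#'
#' @param truth a `PlantedTruth` data.frame.
#' @return A `MechanismSummary`.
#' @export
planted_summary <- function(truth) {
  stopifnot(nrow(truth) > 0)
  meg <- truth$class == "MEG"
  feg <- truth$class == "FEG"
  mechanism_summary(
    males_up = sum(meg & truth$mechanism %in% c("own-up-only", "both")),
    females_down = sum(meg & truth$mechanism == "opposite-down-only"),
    females_up = sum(feg & truth$mechanism %in% c("own-up-only", "both")),
    males_down = sum(feg & truth$mechanism == "opposite-down-only"),
    both_sexes = sum(truth$class == "SHARED"),
    total_genes = nrow(truth)
  )
}

#' Write / read planted truth as TSV
#' @param truth a `PlantedTruth`.
#' @param path output path.
#' @return invisibly, `truth` (write) or the re-read `PlantedTruth` (read).
#' @export
write_planted_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}

#' @rdname write_planted_truth
#' @export
read_planted_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("PlantedTruth", "data.frame")
  df
}
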