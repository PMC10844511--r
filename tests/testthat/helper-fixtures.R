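# Fixture builders shared across test files. Everything is generated in code;
# no data files are read from disk except ones a test writes itself.

# minimal valid 2x2x2 design
toy_samples <- function(reps = 2) {
  grid <- expand.grid(replicate = seq_len(reps), stage = c("T1", "T2"),
                      sex = c("F", "M"), stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_%d", grid$sex, grid$stage, grid$replicate),
             sex = grid$sex, stage = grid$stage, stringsAsFactors = FALSE)
}

toy_counts_dataset <- function(n_genes = 4, reps = 2, seed = 1) {
  set.seed(seed)
  s <- toy_samples(reps)
  values <- matrix(rpois(n_genes * nrow(s), lambda = 50), nrow = n_genes,
                   dimnames = list(sprintf("g%d", seq_len(n_genes)), s$sample_id))
  expression_dataset(values, s, platform = "counts", species = "toy")
}

# standard recovery simulation: strong effects, 6 replicates, all mechanisms
recovery_config <- function(platform = "counts", n_genes = 2000, seed = 7) {
  simulation_config(
    n_genes = n_genes, replicates = 6, platform = platform,
    proportions = c(meg_up = 0.05, meg_down_opp = 0.05, meg_both = 0.05,
                    feg_up = 0.05, feg_down_opp = 0.05, feg_both = 0.05,
                    shared_up = 0.05, shared_down = 0.05, null = 0.60),
    effect_range = c(2, 4), seed = seed)
}

all_null_config <- function(platform = "counts", n_genes = 5000, reps = 3, seed = 11) {
  simulation_config(
    n_genes = n_genes, replicates = reps, platform = platform,
    proportions = c(meg_up = 0, meg_down_opp = 0, meg_both = 0, feg_up = 0,
                    feg_down_opp = 0, feg_both = 0, shared_up = 0,
                    shared_down = 0, null = 1),
    seed = seed)
}

# hand-built dynamics table with known classes, for cross_species tests
toy_dynamics <- function(df) {
  defaults <- data.frame(gene_id = df$gene_id, fc_female = 0, fc_male = 0,
                         sig_female = FALSE, sig_male = FALSE,
                         padj_female = NA_real_, padj_male = NA_real_,
                         t2_log2fc = 0, t2_padj = NA_real_, t2_sig = FALSE,
                         base_mean = 100, class = "NONSIG", mechanism = "n/a",
                         stringsAsFactors = FALSE)
  for (col in names(df)) defaults[[col]] <- df[[col]]
  class(defaults) <- c("DynamicsTable", "data.frame")
  defaults
}

# brute-force BH step-up from the definition, used as the oracle
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    k <- which(ord == i)  # rank of p[i]
    adj[i] <- min(vapply(k:m, function(j) min(1, m * p[ord[j]] / j), 0))
  }
  adj
}
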