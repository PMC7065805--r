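# Shared fixture builders. Everything is generated in code; no files.

# annotation for a complete design (WT replicates in every environment,
# mut_reps replicates per mutant cell)
make_design <- function(kinases, envs, wt_reps = 2L, mut_reps = 1L,
                        drop_cells = NULL) {
  ann <- rbind(
    expand.grid(kinase = "WT", environment = envs,
                replicate = seq_len(wt_reps),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    expand.grid(kinase = kinases, environment = envs,
                replicate = seq_len(mut_reps),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  )
  if (!is.null(drop_cells)) {
    ann <- ann[!paste(ann$kinase, ann$environment) %in%
                 paste(drop_cells$kinase, drop_cells$environment), ]
  }
  data.frame(sample_id = paste(ann$kinase, ann$environment, ann$replicate,
                               sep = "."),
             ann, row.names = NULL, stringsAsFactors = FALSE)
}

# fold-change matrix built directly from additive truth (no count layer):
# values = c_env + k_kinase (+ planted deltas) + Gaussian noise
make_additive_fc <- function(n_genes = 60L, kinases = c("K1", "K2", "K3"),
                             envs = c("YPD", "E1", "E2"), wt_reps = 2L,
                             mut_reps = 1L, noise_sd = 0, seed = 1L,
                             interactions = NULL, drop_cells = NULL,
                             k_sd = 0.8) {
  set.seed(seed)
  ann <- make_design(kinases, envs, wt_reps, mut_reps, drop_cells)
  genes <- sprintf("g%03d", seq_len(n_genes))
  c_true <- matrix(rnorm(n_genes * length(envs), 0, 1), n_genes,
                   dimnames = list(genes, envs))
  c_true[, "YPD"] <- 0
  k_true <- matrix(rnorm(n_genes * (length(kinases) + 1L), 0, k_sd), n_genes,
                   dimnames = list(genes, c("WT", kinases)))
  k_true[, "WT"] <- 0
  vals <- c_true[, ann$environment, drop = FALSE] +
    k_true[, ann$kinase, drop = FALSE]
  if (!is.null(interactions)) {
    for (r in seq_len(nrow(interactions))) {
      cols <- ann$kinase == interactions$kinase[r] &
        ann$environment == interactions$environment[r]
      vals[interactions$gene[r], cols] <-
        vals[interactions$gene[r], cols] + interactions$delta[r]
    }
  }
  if (noise_sd > 0) {
    vals <- vals + matrix(rnorm(length(vals), 0, noise_sd), nrow(vals))
  }
  colnames(vals) <- ann$sample_id
  fc <- structure(
    list(values = vals, annotation = ann, baseline = "global_wt_ypd",
         baseline_strain = "WT", baseline_environment = "YPD"),
    class = "fc_matrix"
  )
  list(fc = fc, c_true = c_true, k_true = k_true, annotation = ann)
}

# forge an additive_fit whose residual field is fully under test control
forge_fit <- function(residuals, ann) {
  structure(
    list(c_effects = NULL, k_effects = NULL,
         fitted = residuals * 0, residuals = residuals,
         r2 = rep(NA_real_, nrow(residuals)),
         pooled_mean = mean(residuals), global_sigma = stats::sd(residuals),
         annotation = ann, estimator = "forged",
         baseline_strain = "WT", baseline_environment = "YPD"),
    class = "additive_fit"
  )
}

# small full-generator config for pipeline-level tests
small_config <- function(n_genes = 300L, seed = 1L, ...) {
  args <- list(n_genes = n_genes, seed = seed, n_iesr = 20L, n_resr = 20L,
               n_tfs = 2L, targets_per_tf = 20L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# independent enumeration oracle for the upper-tail hypergeometric:
# P(X >= k) by summing counts of overlap configurations
hyper_upper_enum <- function(k, K, N, n) {
  js <- seq(max(k, 0L), min(K, n))
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
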