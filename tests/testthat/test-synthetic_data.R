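test_that("truth generation honors structural invariants and determinism", {
  cfg <- small_config(seed = 11)
  tr1 <- generate_truth(cfg)
  tr2 <- generate_truth(cfg)
  expect_identical(tr1, tr2)  # same seed, same truth

  expect_true(all(tr1$env_effects[, cfg$baseline_environment] == 0))
  expect_true(all(tr1$kinase_effects[, "WT"] == 0))
  # interactions live only on eligible cells
  expect_false(any(tr1$interaction_effects$kinase == "WT"))
  expect_false(any(tr1$interaction_effects$environment ==
                     cfg$baseline_environment))
  # iESR induced / rESR repressed in every stress environment
  stress <- setdiff(cfg$environments, c("YPD", "SDC"))
  expect_true(all(tr1$env_effects[tr1$iesr$members, stress] > 0))
  expect_true(all(tr1$env_effects[tr1$resr$members, stress] < 0))
  # master kinase coupling signs
  expect_true(all(tr1$kinase_effects[tr1$iesr$members, "Tpk123"] > 0))
  expect_true(all(tr1$kinase_effects[tr1$resr$members, "Tpk123"] < 0))
  expect_true(all(tr1$kinase_effects[tr1$iesr$members, "Pbs2"] < 0))

  cfg0 <- small_config(seed = 11, interaction_density = 0)
  expect_identical(nrow(generate_truth(cfg0)$interaction_effects), 0L)
})

test_that("default design reproduces the 301-sample layout", {
  cfg <- sim_config(n_genes = 40, seed = 2, n_iesr = 5, n_resr = 5,
                  n_tfs = 2, targets_per_tf = 10)
  sim <- simulate_counts(generate_truth(cfg), cfg)
  expect_identical(ncol(sim$counts), 301L)  # 28*10 - 19 + 4*10
  expect_identical(nrow(cfg$missing_cells), 19L)
  expect_true(any(cfg$missing_cells$kinase == "Tpk123" &
                    cfg$missing_cells$environment == "glucose_depletion"))
  # every kinase keeps its baseline sample
  ypd <- sim$annotation[sim$annotation$environment == "YPD", ]
  expect_setequal(unique(ypd$kinase), c("WT", cfg$kinases))
  # WT replicates per environment
  wt <- sim$annotation[sim$annotation$kinase == "WT", ]
  expect_true(all(table(wt$environment) == 4L))
})

test_that("simulated counts are deterministic under the seed", {
  cfg <- small_config(n_genes = 80, seed = 5)
  tr <- generate_truth(cfg)
  s1 <- simulate_counts(tr, cfg)
  s2 <- simulate_counts(tr, cfg)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_counts(generate_truth(small_config(n_genes = 80, seed = 6)),
                        small_config(n_genes = 80, seed = 6))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("noise-free dispersion-free simulation is exactly additive in log2", {
  cfg <- small_config(n_genes = 100, seed = 3, noise_sd_log2 = 0,
                      count_model = "deterministic",
                      interaction_density = 0,
                      baseline_log2_mean = 14, baseline_log2_sd = 0.2,
                      library_size_range = c(1, 1))
  tr <- generate_truth(cfg)
  sim <- simulate_counts(tr, cfg)
  l2 <- log2(sim$counts)
  ann <- sim$annotation
  # log2 ratio of any (kinase, env) cell to (WT, YPD) equals c + k
  ref <- rowMeans(l2[, ann$kinase == "WT" & ann$environment == "YPD"])
  for (s in c(10, 60, 150)) {
    expected <- tr$env_effects[, ann$environment[s]] +
      tr$kinase_effects[, ann$kinase[s]]
    expect_equal(unname(l2[, s] - ref), unname(expected), tolerance = 1e-3)
  }
})

test_that("column sums scale with the planted library size factors", {
  cfg <- small_config(n_genes = 150, seed = 9, noise_sd_log2 = 0,
                      count_model = "deterministic",
                      env_responsive_fraction = 0, kinase_responsive_fraction = 0,
                      interaction_density = 0, n_iesr = 2, n_resr = 2,
                      esr_env_effect = 0, master_effect = 0,
                      baseline_log2_mean = 10, baseline_log2_sd = 1)
  sim <- simulate_counts(generate_truth(cfg), cfg)
  ratio <- colSums(sim$counts) / sim$library_factors
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)
})

test_that("planted promoter motifs outscore the background 99th percentile", {
  cfg <- small_config(n_genes = 200, seed = 13)
  tr <- generate_truth(cfg)
  motifs <- generate_motif_library(names(tr$tf_target_map), seed = cfg$seed)
  prom <- generate_promoters(tr, motif_library = motifs)
  expect_identical(prom, generate_promoters(tr, motif_library = motifs))
  expect_true(all(nchar(prom) == cfg$promoter_length))

  sc <- scan_pwm(prom, motifs[[1]], score_threshold_fraction = 0.8)
  targets <- tr$tf_target_map[[1]]$members
  bg <- setdiff(names(prom), unlist(lapply(tr$tf_target_map, `[[`, "members")))
  q99 <- quantile(sc$best_score[sc$gene %in% bg], 0.99)
  expect_true(all(sc$best_score[sc$gene %in% targets] > q99))

  # motif longer than promoter is rejected
  expect_error(generate_promoters(tr, length = 4, motif_library = motifs),
               "longer than the promoter")
})

test_that("promoters without TF modules are pure background", {
  cfg <- small_config(n_genes = 50, seed = 4, n_tfs = 0)
  tr <- generate_truth(cfg)
  expect_length(tr$tf_target_map, 0L)
  prom <- generate_promoters(tr, motif_library = list())
  expect_length(prom, 50L)
})

test_that("annotation sets: sizes, determinism, null overlap matches hypergeometric mean", {
  cfg <- small_config(n_genes = 400, seed = 21, interaction_density = 0.005)
  tr <- generate_truth(cfg)
  one <- generate_annotation_sets(tr, n_sets = 1, set_size_range = c(5, 5),
                                  enriched_fraction = 0)
  expect_length(one[[1]]$members, 5L)
  expect_identical(generate_annotation_sets(tr, n_sets = 5),
                   generate_annotation_sets(tr, n_sets = 5))

  # with enriched_fraction = 0, overlap with interaction genes is
  # hypergeometric: E[k] = n * K / N
  K <- length(unique(tr$interaction_effects$gene))
  sets <- generate_annotation_sets(tr, n_sets = 400,
                                   set_size_range = c(30, 30),
                                   enriched_fraction = 0, seed = 77)
  ov <- vapply(sets, function(s) {
    length(intersect(s$members, unique(tr$interaction_effects$gene)))
  }, numeric(1))
  expected <- 30 * K / cfg$n_genes
  se <- sqrt(30 * (K / cfg$n_genes) * (1 - K / cfg$n_genes) / length(sets))
  expect_lt(abs(mean(ov) - expected), 4 * se + 1e-9)
})

test_that("config validation rejects inconsistent designs", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(interaction_density = 1), "interaction_density")
  expect_error(sim_config(n_genes = 100), "ESR modules")
  expect_error(
    sim_config(missing_cells = data.frame(kinase = "Tpk123",
                                          environment = "YPD")),
    "baseline")
  expect_error(small_config(kinases = c("A", "A")), "unique")
})
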