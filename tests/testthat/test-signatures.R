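test_that("master kinase and antagonist shift the ESR in opposite directions", {
  cfg <- small_config(n_genes = 300, seed = 41)
  tr <- generate_truth(cfg)
  sim <- simulate_counts(tr, cfg)
  expr <- normalize_log2(filter_low_expression(sim$counts))
  fcm <- fold_changes(expr, sim$annotation, "matched_environment_wt")
  d <- esr_distributions(fcm, tr$iesr, tr$resr, c("Tpk123", "Pbs2"))
  g <- function(grp, set) d[d$group == grp & d$set == set, ]
  # master (PKA-like): iESR up, rESR down relative to the remainder
  expect_gt(g("Tpk123", "iESR")$median, g("all_others", "iESR")$median)
  expect_lt(g("Tpk123", "rESR")$median, g("all_others", "rESR")$median)
  # antagonist: the reverse on both branches
  expect_lt(g("Pbs2", "iESR")$median, g("all_others", "iESR")$median)
  expect_gt(g("Pbs2", "rESR")$median, g("all_others", "rESR")$median)
  expect_true(all(g("Tpk123", "iESR")$p < 0.01, g("Pbs2", "iESR")$p < 0.01))
})

test_that("a kinase with no ESR coupling is indistinguishable from the pool", {
  ps <- vapply(1:10, function(s) {
    cfg <- small_config(n_genes = 200, seed = 500 + s)
    tr <- generate_truth(cfg)
    sim <- simulate_counts(tr, cfg)
    expr <- normalize_log2(filter_low_expression(sim$counts))
    fcm <- fold_changes(expr, sim$annotation, "matched_environment_wt")
    # Cdc7 has no planted ESR coupling and, at kinase_responsive_fraction,
    # only incidental effects on ESR genes
    d <- esr_distributions(fcm, tr$iesr, tr$resr, "Cdc7")
    d$p[d$group == "Cdc7" & d$set == "iESR"]
  }, numeric(1))
  expect_gte(sum(ps > 0.05), 7L)
})

test_that("single-value ESR distribution is flagged rather than tested", {
  sim <- make_additive_fc(n_genes = 10, kinases = "K1",
                          envs = c("YPD", "E1"), wt_reps = 2, seed = 2)
  ann <- sim$annotation
  one_col <- ann$kinase == "K1" & ann$environment == "E1"
  fcm <- structure(list(values = sim$fc$values[, one_col, drop = FALSE],
                        annotation = ann[one_col, ],
                        baseline = "matched_environment_wt",
                        baseline_strain = "WT", baseline_environment = "YPD"),
                   class = "fc_matrix")
  d <- esr_distributions(fcm, gene_set("iESR", "", "g001"),
                         gene_set("rESR", "", "g002"), "K1")
  expect_identical(d$flag[d$group == "K1" & d$set == "iESR"],
                   "too_few_values")
  expect_identical(d$n[d$group == "K1" & d$set == "iESR"], 1L)
})

test_that("gene-set response test finds the planted attenuated kinase only", {
  set.seed(61)
  sim <- make_additive_fc(n_genes = 60, kinases = c("K1", "K2", "K3"),
                          envs = c("YPD", "E1"), wt_reps = 4,
                          noise_sd = 0.15, seed = 61, k_sd = 0)
  ann <- sim$annotation
  vals <- sim$fc$values
  set_genes <- sprintf("g%03d", 1:12)
  # K1 loses 1 log2 of the response on the set genes in E1
  vals[set_genes, ann$kinase == "K1" & ann$environment == "E1"] <-
    vals[set_genes, ann$kinase == "K1" & ann$environment == "E1"] - 1
  # matched-baseline fold changes
  mm <- vals
  for (e in unique(ann$environment)) {
    cols <- ann$environment == e
    mm[, cols] <- vals[, cols] -
      rowMeans(vals[, cols & ann$kinase == "WT", drop = FALSE])
  }
  fcm <- structure(list(values = mm, annotation = ann,
                        baseline = "matched_environment_wt",
                        baseline_strain = "WT", baseline_environment = "YPD"),
                   class = "fc_matrix")
  res <- geneset_response_test(fcm, gene_set("probe", "", set_genes), "E1")
  expect_identical(res$direction[res$kinase == "K1"], "attenuation")
  expect_lt(res$padj[res$kinase == "K1"], 0.01)
  expect_true(all(res$padj[res$kinase != "K1"] > 0.05))
  expect_equal(res$effect[res$kinase == "K1"], -1, tolerance = 0.15)
  # BH is monotone in the raw p
  expect_identical(order(res$p), order(res$padj))

  expect_error(geneset_response_test(fcm, gene_set("tiny", "", "g001"), "E1"),
               ">= 3")
})

test_that("set-level z: single-gene identity and sqrt(n) aggregation", {
  set.seed(71)
  ann <- make_design(paste0("K", 1:6), c("YPD", paste0("E", 1:5)),
                     wt_reps = 2)
  res <- matrix(rnorm(400 * nrow(ann)), 400,
                dimnames = list(sprintf("g%03d", 1:400), ann$sample_id))
  fit <- forge_fit(res, ann)
  z_full <- residual_zscores(fit)

  one <- geneset_residual_scatter(fit, gene_set("solo", "", "g007"))
  expect_equal(one$z, unname(z_full["g007", ]), tolerance = 1e-12)

  # coordinated 1-sigma shift on a 20-gene set in one sample:
  # set-level z ~ sqrt(20) = 4.47 -> flagged
  set_genes <- sprintf("g%03d", 101:120)
  res2 <- res
  sigma <- sd(res)
  res2[set_genes, 5] <- res2[set_genes, 5] + sigma
  sc <- geneset_residual_scatter(forge_fit(res2, ann),
                                 gene_set("coord", "", set_genes))
  expect_gt(sc$z[5], 2.5)
  expect_true(sc$flagged[5])
  expect_equal(sc$z[5], sqrt(20), tolerance = 0.35 * sqrt(20))
})

test_that("set-level z is standard normal on an interaction-free field", {
  set.seed(81)
  ann <- make_design(paste0("K", 1:20), c("YPD", paste0("E", 1:16)),
                     wt_reps = 1)
  res <- matrix(rnorm(2000 * nrow(ann), 0, 0.6), 2000,
                dimnames = list(sprintf("g%04d", 1:2000), ann$sample_id))
  fit <- forge_fit(res, ann)
  # 50 disjoint 40-gene sets x 357 samples > 10^4 set-level z values
  zs <- unlist(lapply(0:49, function(i) {
    genes <- sprintf("g%04d", (i * 40 + 1):(i * 40 + 40))
    geneset_residual_scatter(fit, gene_set(paste0("s", i), "", genes))$z
  }))
  ks <- suppressWarnings(ks.test(zs, "pnorm"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("gene clustering separates planted anti-correlated modules", {
  set.seed(91)
  base <- sin(seq(0, 3 * pi, length.out = 24))
  up <- t(replicate(15, base + rnorm(24, 0, 0.2)))
  down <- t(replicate(15, -base + rnorm(24, 0, 0.2)))
  m <- rbind(up, down)
  rownames(m) <- sprintf("g%02d", 1:30)
  cl <- cluster_genes(m, 2)
  expect_identical(length(unique(cl$clusters[1:15])), 1L)
  expect_identical(length(unique(cl$clusters[16:30])), 1L)
  expect_false(cl$clusters[1] == cl$clusters[16])

  # duplicate rows always co-cluster
  m2 <- m; m2[2, ] <- m2[1, ]
  cl2 <- cluster_genes(m2, 5)
  expect_identical(cl2$clusters[[1]], cl2$clusters[[2]])

  # as many clusters as genes -> singletons
  cl3 <- cluster_genes(m[1:6, ], 6)
  expect_identical(sort(unname(cl3$clusters)), 1:6)
  expect_error(cluster_genes(m, 31), "exceeds")
  expect_error(cluster_genes(m, 1), ">= 2")
})
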