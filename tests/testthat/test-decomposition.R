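test_that("noise-free additive data yields zero residuals, R2 = 1 and estimator agreement", {
  sim <- make_additive_fc(n_genes = 50, wt_reps = 3, noise_sd = 0, seed = 2)
  fa <- fit_additive(sim$fc, "reference_plugin")
  fb <- fit_additive(sim$fc, "joint_ols")
  expect_lt(max(abs(fa$residuals)), 1e-10)
  expect_equal(unname(fa$r2), rep(1, 50))
  expect_equal(fa$c_effects, fb$c_effects, tolerance = 1e-9)
  expect_equal(fa$k_effects, fb$k_effects, tolerance = 1e-9)
  expect_equal(fa$fitted, fb$fitted, tolerance = 1e-9)
  # and both recover the planted truth exactly
  expect_equal(fa$c_effects, sim$c_true[, colnames(fa$c_effects)],
               tolerance = 1e-10)
  expect_equal(fa$k_effects, sim$k_true[, colnames(fa$k_effects)],
               tolerance = 1e-10)
})

test_that("plug-in residual equals the planted interaction in the 2x2 toy", {
  # 2 environments x 2 strains, one planted delta at (K1, E1)
  delta <- 0.75
  sim <- make_additive_fc(n_genes = 12, kinases = "K1", envs = c("YPD", "E1"),
                          wt_reps = 2, noise_sd = 0, seed = 5,
                          interactions = data.frame(gene = "g001",
                                                    kinase = "K1",
                                                    environment = "E1",
                                                    delta = delta))
  fit <- fit_additive(sim$fc, "reference_plugin")
  col <- which(sim$annotation$kinase == "K1" &
                 sim$annotation$environment == "E1")
  expect_equal(unname(fit$residuals["g001", col]), delta)
  expect_lt(max(abs(fit$residuals[-1, ])), 1e-12)
})

test_that("plug-in structure: mutant baseline residuals are zero; k_j is local", {
  sim <- make_additive_fc(n_genes = 30, noise_sd = 0.2, seed = 3)
  fit <- fit_additive(sim$fc, "reference_plugin")
  ann <- sim$annotation
  ypd_mut <- ann$kinase != "WT" & ann$environment == "YPD"
  expect_lt(max(abs(fit$residuals[, ypd_mut])), 1e-12)

  # dropping K3's samples entirely leaves K1/K2 estimates untouched
  keep <- ann$kinase != "K3"
  fc2 <- structure(list(values = sim$fc$values[, keep],
                        annotation = ann[keep, ],
                        baseline = "global_wt_ypd",
                        baseline_strain = "WT", baseline_environment = "YPD"),
                   class = "fc_matrix")
  fit2 <- fit_additive(fc2, "reference_plugin")
  expect_equal(fit$k_effects[, c("K1", "K2")], fit2$k_effects[, c("K1", "K2")])
  expect_equal(fit$c_effects, fit2$c_effects)
})

test_that("joint OLS flags a disconnected design as singular", {
  sim <- make_additive_fc(n_genes = 10, kinases = "K1", envs = c("YPD", "E1"),
                          wt_reps = 2, seed = 1,
                          drop_cells = data.frame(kinase = "K1",
                                                  environment = "YPD"))
  # K1 now appears only in E1: its k is aliased with the E1 effect only if
  # WT is absent there too; drop the WT E1 samples to force it
  ann <- sim$annotation
  keep <- !(ann$kinase == "WT" & ann$environment == "E1")
  fc2 <- structure(list(values = sim$fc$values[, keep],
                        annotation = ann[keep, ],
                        baseline = "global_wt_ypd",
                        baseline_strain = "WT", baseline_environment = "YPD"),
                   class = "fc_matrix")
  expect_error(fit_additive(fc2, "joint_ols"), "singular|disconnected")
})

test_that("r2_distribution summarizes the fit-quality pool", {
  sim <- make_additive_fc(n_genes = 120, noise_sd = 0, seed = 9)
  fit <- fit_additive(sim$fc)
  d <- r2_distribution(fit)
  expect_equal(d$mean, 1)
  expect_equal(sum(d$counts), 120)

  # pure-noise data: R2 near the null expectation for the design's
  # degrees of freedom, estimated by an independent permutation oracle
  sim2 <- make_additive_fc(n_genes = 200, kinases = c("K1", "K2", "K3"),
                           envs = c("YPD", "E1", "E2"), wt_reps = 3,
                           noise_sd = 1, seed = 10, k_sd = 0)
  vals <- sim2$fc$values
  vals <- vals - sim2$c_true[, sim2$annotation$environment]  # strip signal
  fc0 <- structure(list(values = vals, annotation = sim2$annotation,
                        baseline = "global_wt_ypd", baseline_strain = "WT",
                        baseline_environment = "YPD"), class = "fc_matrix")
  obs <- r2_distribution(fit_additive(fc0, "joint_ols"))$mean
  perm <- replicate(10, {
    ix <- sample(ncol(vals))
    vp <- vals[, ix]; colnames(vp) <- colnames(vals)
    r2_distribution(fit_additive(
      structure(list(values = vp, annotation = sim2$annotation,
                     baseline = "global_wt_ypd", baseline_strain = "WT",
                     baseline_environment = "YPD"), class = "fc_matrix"),
      "joint_ols"))$mean
  })
  expect_lt(abs(obs - mean(perm)), 3 * sd(perm) + 0.02)

  # monotone in noise: more noise, worse fit
  lo <- make_additive_fc(n_genes = 100, noise_sd = 0.1, seed = 11)
  hi <- make_additive_fc(n_genes = 100, noise_sd = 0.8, seed = 11)
  expect_gt(r2_distribution(fit_additive(lo$fc))$mean,
            r2_distribution(fit_additive(hi$fc))$mean)
})

test_that("global residual z-scores: center, Gaussian coverage, MAD consistency", {
  set.seed(20)
  ann <- make_design(paste0("K", 1:10), paste0("E", 0:9), wt_reps = 2)
  ann$environment[ann$environment == "E0"] <- "YPD"
  res <- matrix(rnorm(500 * nrow(ann), 0, 0.7), 500,
                dimnames = list(sprintf("g%03d", 1:500),
                                ann$sample_id))
  fit <- forge_fit(res, ann)
  z <- residual_zscores(fit)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  # Phi(2.5) - Phi(-2.5) = 0.98758
  expect_equal(mean(abs(z) <= 2.5), 0.9876, tolerance = 0.002)
  zm <- residual_zscores(fit, "global_mad")
  expect_lt(abs(attr(zm, "sigma") / attr(z, "sigma") - 1), 0.05)

  fit0 <- forge_fit(res * 0, ann)
  expect_error(suppressWarnings(residual_zscores(fit0)), "zero")
})

test_that("qq_normal tracks the bulk and exposes heavy tails", {
  set.seed(5)
  z <- rnorm(1e5)
  q <- qq_normal(z, band = 0.1)
  expect_gt(q$fraction_in_band, 0.97)
  bulk <- abs(q$theoretical) < 2
  expect_lt(max(abs(q$empirical[bulk] - q$theoretical[bulk])), 0.05)

  # 95% N(0,1) + 5% N(0,3^2): upper tail quantiles rise above the line
  zz <- c(rnorm(95000), rnorm(5000, 0, 3))
  zz <- (zz - mean(zz)) / sd(zz)
  qq <- qq_normal(zz)
  tail_idx <- qq$theoretical > 2.5
  expect_gt(mean(qq$empirical[tail_idx] - qq$theoretical[tail_idx]), 0)
  expect_lt(qq$fraction_in_band, q$fraction_in_band)

  expect_error(qq_normal(rep(1, 100)), "degenerate")
})

test_that("residual magnitude is uncorrelated with expression when homoskedastic", {
  set.seed(31)
  ann <- make_design(paste0("K", 1:20), paste0("E", 1:17), wt_reps = 2)
  ann$environment[ann$environment == "E1"] <- "YPD"
  n_g <- 300
  res <- matrix(rnorm(n_g * nrow(ann)), n_g,
                dimnames = list(sprintf("g%03d", 1:n_g), ann$sample_id))
  fit <- forge_fit(res, ann)
  me <- setNames(runif(n_g, 2, 12), rownames(res))
  a <- residual_expression_association(fit, me)
  expect_identical(a$flag, "ok")
  expect_lt(abs(a$correlation), 0.05)   # > 1e5 points

  # planted mean-dependent noise -> positive association
  res2 <- res * rep(sqrt(me / mean(me)), ncol(res))
  a2 <- residual_expression_association(forge_fit(res2, ann), me)
  expect_gt(a2$correlation, 0.1)

  a3 <- residual_expression_association(fit, setNames(rep(5, n_g),
                                                      rownames(res)))
  expect_identical(a3$flag, "degenerate")
})

test_that("interaction calling: tail rate, planted detection, ordering, guards", {
  set.seed(77)
  ann <- make_design(paste0("K", 1:14), c("YPD", paste0("E", 1:9)),
                     wt_reps = 1)
  n_g <- 700
  res <- matrix(rnorm(n_g * nrow(ann)), n_g,
                dimnames = list(sprintf("g%03d", 1:n_g), ann$sample_id))
  fit <- forge_fit(res, ann)
  calls <- call_interactions(fit, threshold = 2.5)
  # iid Gaussian field: call rate matches 2*(1-Phi(2.5)) = 1.24%
  n_cells <- n_g * (length(unique(paste(ann$kinase, ann$environment))) - 1L)
  rate <- nrow(calls) / n_cells
  se <- sqrt(0.0124 * 0.9876 / n_cells)
  expect_lt(abs(rate - 0.0124), 4 * se)
  # no baseline cell ever called
  expect_false(any(calls$kinase == "WT" & calls$environment == "YPD"))
  # sorted by |z| descending
  expect_true(all(diff(abs(calls$z)) <= 1e-12))

  # planted 5 sigma interaction is called with the right sign
  res2 <- res
  res2["g001", ann$kinase == "K1" & ann$environment == "E1"] <- -5
  calls2 <- call_interactions(forge_fit(res2, ann), 2.5)
  hit <- calls2[calls2$gene == "g001" & calls2$kinase == "K1" &
                  calls2$environment == "E1", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$sign, -1L)

  expect_identical(nrow(call_interactions(fit, Inf)), 0L)
})

test_that("replicate-mean aggregation drives cell-level calls", {
  # 4 replicates at 2 sigma each -> cell mean z = 2, below 2.5 threshold
  # on the per-sample scale? No: cell residual is the replicate MEAN, and
  # it is standardized against the per-sample sigma, so mean = 2 -> z = 2.
  ann <- make_design("K1", c("YPD", "E1"), wt_reps = 1, mut_reps = 4)
  set.seed(8)
  res <- matrix(rnorm(4000 * nrow(ann)), 4000,
                dimnames = list(sprintf("g%04d", 1:4000), ann$sample_id))
  res["g0001", ann$kinase == "K1" & ann$environment == "E1"] <- c(4, -4, 4, -4)
  calls <- call_interactions(forge_fit(res, ann), 2.5)
  expect_false("g0001" %in% calls$gene[calls$environment == "E1"])
})
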