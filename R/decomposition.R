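#' Fit the additive environment + kinase model per gene
#'
#' The central model: the log2 fold change of a gene in a sample with
#' environment i and inhibited kinase j (relative to wild type in the
#' baseline environment) is modeled as `delta_e = c_i + k_j`, with the
#' treatment-coding constraints `c[baseline env] = 0`, `k[WT] = 0`. A
#' departure of the measurement from this sum is the model residual, the
#' carrier of kinase-by-environment interaction signal.
#'
#' Two estimators are provided. `"reference_plugin"` (default) takes
#' `c_i` as the mean wild-type fold change in environment i and `k_j` as
#' the fold change of kinase j's strain in the baseline environment; this
#' is the direct reference-based construction. `"joint_ols"` solves the
#' two-factor no-interaction least-squares problem over all of a gene's
#' samples, tolerant of missing cells. The two coincide exactly on
#' complete, balanced, noise-free additive designs.
#'
#' @param fc A `global_wt_ypd`-baseline [fold_changes()] result.
#' @param estimator `"reference_plugin"` or `"joint_ols"`.
#' @return Object of class `additive_fit`: list with `c_effects`
#'   (genes x environments), `k_effects` (genes x strains, WT column 0),
#'   `fitted` and `residuals` (genes x samples), `r2` (per gene, the
#'   coefficient of determination across that gene's samples),
#'   `global_sigma` and `pooled_mean` (scale and center of the pooled
#'   residuals), `annotation`, `estimator`.
#' @export
fit_additive <- function(fc, estimator = c("reference_plugin", "joint_ols")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(fc, "fc_matrix"))
  if (fc$baseline != "global_wt_ypd") {
    stop("fit_additive requires fold changes against the global WT baseline")
  }
  ann <- fc$annotation
  vals <- fc$values
  bstrain <- fc$baseline_strain
  benv <- fc$baseline_environment
  envs <- unique(ann$environment)
  envs <- c(benv, setdiff(envs, benv))
  strains <- c(bstrain, setdiff(unique(ann$kinase), bstrain))
  genes <- rownames(vals)

  if (estimator == "reference_plugin") {
    c_mat <- matrix(NA_real_, length(genes), length(envs),
                    dimnames = list(genes, envs))
    for (e in envs) {
      cols <- ann$kinase == bstrain & ann$environment == e
      if (!any(cols)) stop("no ", bstrain, " samples in environment '", e, "'")
      c_mat[, e] <- rowMeans(vals[, cols, drop = FALSE])
    }
    c_mat[, benv] <- 0
    k_mat <- matrix(NA_real_, length(genes), length(strains),
                    dimnames = list(genes, strains))
    k_mat[, bstrain] <- 0
    for (k in setdiff(strains, bstrain)) {
      cols <- ann$kinase == k & ann$environment == benv
      if (any(cols)) {
        k_mat[, k] <- rowMeans(vals[, cols, drop = FALSE])
      }
    }
    miss_k <- strains[colSums(is.na(k_mat)) > 0]
    if (length(miss_k)) {
      warning("no baseline-environment sample for kinase(s): ",
              paste(miss_k, collapse = ", "), "; their k is NA")
    }
    fitted <- c_mat[, ann$environment, drop = FALSE] +
      k_mat[, ann$kinase, drop = FALSE]
  } else {
    X <- cbind(
      sapply(setdiff(envs, benv), function(e) as.numeric(ann$environment == e)),
      sapply(setdiff(strains, bstrain), function(k) as.numeric(ann$kinase == k))
    )
    colnames(X) <- c(paste0("c.", setdiff(envs, benv)),
                     paste0("k.", setdiff(strains, bstrain)))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("singular design: kinase/environment incidence is disconnected ",
           "at ", paste(dropped, collapse = ", "))
    }
    coef <- qr.coef(qrX, t(vals))            # p x genes
    c_mat <- matrix(0, length(genes), length(envs),
                    dimnames = list(genes, envs))
    c_mat[, setdiff(envs, benv)] <-
      t(coef[paste0("c.", setdiff(envs, benv)), , drop = FALSE])
    k_mat <- matrix(0, length(genes), length(strains),
                    dimnames = list(genes, strains))
    k_mat[, setdiff(strains, bstrain)] <-
      t(coef[paste0("k.", setdiff(strains, bstrain)), , drop = FALSE])
    fitted <- t(X %*% coef)
  }
  colnames(fitted) <- colnames(vals)
  residuals <- vals - fitted

  ss_res <- rowSums(residuals^2, na.rm = TRUE)
  ok <- !is.na(residuals)
  mny <- rowSums(vals * ok, na.rm = TRUE) / rowSums(ok)
  ss_tot <- rowSums(((vals - mny)^2) * ok, na.rm = TRUE)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)

  pooled <- residuals[is.finite(residuals)]
  structure(
    list(c_effects = c_mat, k_effects = k_mat, fitted = fitted,
         residuals = residuals, r2 = r2,
         pooled_mean = mean(pooled), global_sigma = stats::sd(pooled),
         annotation = ann, estimator = estimator,
         baseline_strain = bstrain, baseline_environment = benv),
    class = "additive_fit"
  )
}

#' @export
print.additive_fit <- function(x, ...) {
  cat("<additive_fit> ", nrow(x$residuals), " genes x ", ncol(x$residuals),
      " samples (", x$estimator, "); mean R2 = ",
      round(mean(x$r2, na.rm = TRUE), 3), ", global sigma = ",
      round(x$global_sigma, 4), "\n", sep = "")
  invisible(x)
}

#' Distribution of per-gene model fit quality
#'
#' Pools the per-gene coefficients of determination and returns the mean
#' plus binned frequencies (the model-quality histogram).
#'
#' @param fit An [fit_additive()] result.
#' @param n_bins Number of histogram bins (default 20).
#' @return List with `mean`, `breaks`, `counts`, `r2` (the pooled
#'   values).
#' @export
r2_distribution <- function(fit, n_bins = 20L) {
  r2 <- fit$r2[is.finite(fit$r2)]
  lo <- min(r2, 0)
  h <- graphics::hist(r2, breaks = seq(lo, 1, length.out = n_bins + 1L),
                      plot = FALSE)
  list(mean = mean(r2), breaks = h$breaks, counts = h$counts, r2 = r2)
}

pooled_sigma <- function(fit, sigma_mode = c("global_sd", "global_mad")) {
  sigma_mode <- match.arg(sigma_mode)
  pooled <- fit$residuals[is.finite(fit$residuals)]
  n <- length(pooled)
  if (n < 2L) stop("need at least 2 pooled residuals")
  if (n < 1000L) {
    warning("only ", n, " pooled residuals; the global scale is intended ",
            "for pools of >= 1000")
  }
  mu <- mean(pooled)
  sigma <- switch(sigma_mode,
                  global_sd = stats::sd(pooled),
                  global_mad = stats::mad(pooled, center = mu))
  if (!is.finite(sigma) || sigma == 0) stop("pooled residual scale is zero")
  c(mean = mu, sigma = sigma)
}

#' Globally standardized model residuals
#'
#' One scale for the whole dataset: the residuals of all genes and
#' samples are pooled, a single center (mean) and scale (SD, or
#' 1.4826 x MAD) are estimated, and every residual is expressed in units
#' of that scale.
#'
#' @param fit An [fit_additive()] result.
#' @param sigma_mode `"global_sd"` (default) or `"global_mad"`.
#' @return Matrix of z-scores, same shape as `fit$residuals`, with
#'   attributes `sigma` and `center`.
#' @export
residual_zscores <- function(fit, sigma_mode = c("global_sd", "global_mad")) {
  ms <- pooled_sigma(fit, sigma_mode)
  z <- (fit$residuals - ms[["mean"]]) / ms[["sigma"]]
  attr(z, "sigma") <- ms[["sigma"]]
  attr(z, "center") <- ms[["mean"]]
  z
}

#' Normal quantile-quantile summary of residual z-scores
#'
#' Sorted z-scores against standard-normal quantiles at plotting
#' positions (i - 0.5)/n, plus the fraction of points within a declared
#' band of the x = y line (the "how much of the pool is normal"
#' diagnostic).
#'
#' @param z Numeric vector or matrix of z-scores.
#' @param band Half-width of the agreement band around x = y
#'   (default 0.1).
#' @return List with `theoretical`, `empirical`, `fraction_in_band`,
#'   `band`.
#' @export
qq_normal <- function(z, band = 0.1) {
  z <- as.numeric(z)
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 2L) stop("need at least 2 z values")
  if (stats::sd(z) == 0) stop("degenerate (constant) z input")
  emp <- sort(z)
  theo <- stats::qnorm((seq_len(n) - 0.5) / n)
  list(theoretical = theo, empirical = emp,
       fraction_in_band = mean(abs(emp - theo) <= band), band = band)
}

#' Association between residual magnitude and expression level
#'
#' Correlates |residual| with the gene's mean expression across all
#' (gene, sample) points and returns a binned 2D density table — the
#' check that interaction calling is not confounded by expression level.
#'
#' @param fit An [fit_additive()] result.
#' @param mean_expr Named per-gene mean expression (log2).
#' @param n_bins Bins per axis for the density table (default 50).
#' @return List with `correlation`, `density` (n_bins x n_bins counts),
#'   `flag` (`"ok"` or `"degenerate"`).
#' @export
residual_expression_association <- function(fit, mean_expr, n_bins = 50L) {
  mean_expr <- mean_expr[rownames(fit$residuals)]
  res <- fit$residuals
  x <- rep(mean_expr, times = ncol(res))
  y <- as.numeric(abs(res))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(correlation = NA_real_, density = NULL, flag = "degenerate"))
  }
  bx <- cut(x, breaks = n_bins)
  by <- cut(y, breaks = n_bins)
  list(correlation = stats::cor(x, y), density = table(bx, by), flag = "ok")
}

#' Call kinase-by-environment interactions from residual z-scores
#'
#' Aggregates residuals to (gene, kinase, environment) cells (replicate
#' mean), standardizes them against the pooled global scale, and returns
#' every cell with |z| strictly above the threshold, excluding the
#' baseline (WT, baseline-environment) cell. Calls are sorted by |z|
#' descending, ties broken by gene id.
#'
#' @param fit An [fit_additive()] result.
#' @param threshold z threshold (default 2.5).
#' @param sigma_mode Passed to the pooled scale estimate.
#' @return data.frame: gene, kinase, environment, residual, z, sign.
#' @export
call_interactions <- function(fit, threshold = 2.5,
                              sigma_mode = c("global_sd", "global_mad")) {
  ms <- pooled_sigma(fit, sigma_mode)
  ann <- fit$annotation
  cell <- paste(ann$kinase, ann$environment, sep = "@")
  cells <- unique(cell)
  keep_cell <- cells != paste(fit$baseline_strain, fit$baseline_environment,
                              sep = "@")
  cells <- cells[keep_cell]
  ind <- sapply(cells, function(cl) as.numeric(cell == cl))
  ind <- sweep(ind, 2L, colSums(ind), "/")
  res <- fit$residuals
  res[!is.finite(res)] <- NA
  cellres <- res %*% ind                       # genes x cells, replicate means
  z <- (cellres - ms[["mean"]]) / ms[["sigma"]]
  hit <- which(abs(z) > threshold & is.finite(z), arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(data.frame(gene = character(), kinase = character(),
                      environment = character(), residual = numeric(),
                      z = numeric(), sign = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(cells[hit[, 2L]], "@", fixed = TRUE)
  out <- data.frame(
    gene = rownames(res)[hit[, 1L]],
    kinase = vapply(parts, `[[`, character(1), 1L),
    environment = vapply(parts, `[[`, character(1), 2L),
    residual = cellres[hit],
    z = z[hit],
    sign = as.integer(sign(z[hit])),
    stringsAsFactors = FALSE
  )
  out[order(-abs(out$z), out$gene), , drop = FALSE]
}
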