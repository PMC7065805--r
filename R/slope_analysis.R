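#' Regression of a mutant's response on the wild-type response
#'
#' For one (kinase, environment) cell: ordinary least squares (with
#' intercept) of the mutant's log2 fold change relative to wild type in
#' the same environment on the wild type's log2 fold change relative to
#' the baseline environment, over a set of differentially expressed
#' genes. A slope near 0 means the mutant tracks the wild-type response;
#' negative slopes indicate attenuation, positive slopes amplification.
#' Outliers are genes with |internally studentized residual| above
#' `outlier_z`.
#'
#' @param de_genes A [gene_set()] or character vector of DE genes.
#' @param wt_fc Named per-gene log2 fold change of WT in the environment
#'   vs baseline.
#' @param mut_fc Named per-gene log2 fold change of the mutant vs WT in
#'   the same environment.
#' @param kinase,environment Labels recorded in the result.
#' @param outlier_z Studentized-residual threshold (default 2.5).
#' @param min_genes Minimum usable genes (default 10).
#' @return One-row data.frame: kinase, environment, slope, intercept,
#'   n_genes, r, n_outliers, status.
#' @export
fit_slope <- function(de_genes, wt_fc, mut_fc, kinase = NA_character_,
                      environment = NA_character_, outlier_z = 2.5,
                      min_genes = 10L) {
  genes <- if (inherits(de_genes, "gene_set")) de_genes$members else
    as.character(de_genes)
  genes <- intersect(genes, intersect(names(wt_fc), names(mut_fc)))
  x <- wt_fc[genes]; y <- mut_fc[genes]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_genes) {
    stop("only ", length(x), " usable DE genes (< ", min_genes, ")")
  }
  fit <- stats::lm(y ~ x)
  rs <- stats::rstandard(fit)
  data.frame(
    kinase = kinase, environment = environment,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n_genes = length(x),
    r = if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_,
    n_outliers = sum(abs(rs) > outlier_z, na.rm = TRUE),
    status = "ok", stringsAsFactors = FALSE
  )
}

#' Slope fits for every (kinase, environment) cell
#'
#' Convenience driver looping over all mutant cells of a design: per
#' environment, takes the DE set and the WT response from a
#' [call_de()] result and regresses each mutant's matched-baseline fold
#' change on it. Cells absent from the design are reported with
#' `status = "missing_sample"` and no fit.
#'
#' @param de_results Named list of [call_de()] results (one per
#'   non-baseline environment; names are environments).
#' @param fc_matched A matched-environment-baseline [fold_changes()]
#'   result.
#' @param outlier_z,min_genes Passed to [fit_slope()].
#' @return data.frame with one row per (kinase, environment).
#' @export
slope_fits <- function(de_results, fc_matched, outlier_z = 2.5,
                       min_genes = 10L) {
  stopifnot(inherits(fc_matched, "fc_matrix"),
            fc_matched$baseline == "matched_environment_wt")
  ann <- fc_matched$annotation
  kinases <- setdiff(unique(ann$kinase), fc_matched$baseline_strain)
  out <- list()
  for (env in names(de_results)) {
    de <- de_results[[env]]
    wt_fc <- stats::setNames(de$table$log2fc, de$table$gene)
    for (k in kinases) {
      cols <- ann$kinase == k & ann$environment == env
      if (!any(cols)) {
        out[[length(out) + 1L]] <- data.frame(
          kinase = k, environment = env, slope = NA_real_,
          intercept = NA_real_, n_genes = 0L, r = NA_real_,
          n_outliers = NA_integer_, status = "missing_sample",
          stringsAsFactors = FALSE)
        next
      }
      mut_fc <- rowMeans(fc_matched$values[, cols, drop = FALSE])
      out[[length(out) + 1L]] <- fit_slope(
        de$de_genes, wt_fc, mut_fc, kinase = k, environment = env,
        outlier_z = outlier_z, min_genes = min_genes)
    }
  }
  do.call(rbind, out)
}

#' Kinase x environment slope matrix
#'
#' Reshapes [slope_fits()] output into a kinases x environments matrix of
#' slopes; cells with `status = "missing_sample"` are `NA` (no
#' imputation).
#'
#' @param fits data.frame from [slope_fits()] (or rbind-ed
#'   [fit_slope()] rows).
#' @return Numeric matrix, kinases in rows, environments in columns.
#' @export
slope_matrix <- function(fits) {
  kin <- unique(fits$kinase)
  env <- unique(fits$environment)
  m <- matrix(NA_real_, length(kin), length(env), dimnames = list(kin, env))
  ok <- fits$status == "ok"
  m[cbind(match(fits$kinase[ok], kin), match(fits$environment[ok], env))] <-
    fits$slope[ok]
  m
}
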