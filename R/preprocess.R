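#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median across genes (among
#' genes with all-positive counts) of the ratio of the sample's count to
#' the gene's geometric mean across samples. Factors are rescaled to have
#' geometric mean 1.
#'
#' @param counts Gene x sample count matrix.
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has a positive count in every sample; ",
         "filter low-expression genes first")
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  f <- apply(exp(lg - geo), 2L, stats::median)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Log2 normalized expression
#'
#' `log2(count / factor + pseudocount)`; an approximately
#' variance-stabilized log scale for downstream fold-change analysis.
#'
#' @param counts Gene x sample count matrix.
#' @param factors Size factors from [size_factors()] (default computed).
#' @param pseudocount Positive pseudocount (default 1).
#' @return Numeric matrix, same shape as `counts`.
#' @export
normalize_log2 <- function(counts, factors = size_factors(counts),
                           pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  counts <- as.matrix(counts)
  if (is.null(names(factors))) names(factors) <- colnames(counts)
  factors <- factors[colnames(counts)]
  if (anyNA(factors)) stop("factors missing for some samples")
  log2(sweep(counts, 2L, factors, "/") + pseudocount)
}

#' Fold changes against a wild-type baseline
#'
#' Subtracts, per gene, the mean log2 expression of the appropriate
#' wild-type replicate columns: either the wild type in the baseline
#' environment for every sample (`"global_wt_ypd"`) or the wild type in
#' each sample's own environment (`"matched_environment_wt"`).
#'
#' @param expr Gene x sample log2 expression matrix.
#' @param ann Sample annotation data.frame (sample_id, kinase,
#'   environment, replicate).
#' @param baseline `"global_wt_ypd"` or `"matched_environment_wt"`.
#' @param baseline_strain,baseline_environment Labels of the reference
#'   cell (defaults `"WT"`, `"YPD"`).
#' @return Object of class `fc_matrix`: list with `values` (matrix),
#'   `annotation`, `baseline`, `baseline_strain`, `baseline_environment`.
#' @export
fold_changes <- function(expr, ann,
                         baseline = c("global_wt_ypd", "matched_environment_wt"),
                         baseline_strain = "WT", baseline_environment = "YPD") {
  baseline <- match.arg(baseline)
  expr <- as.matrix(expr)
  stopifnot(identical(colnames(expr), ann$sample_id))
  if (baseline == "global_wt_ypd") {
    ref <- ann$kinase == baseline_strain & ann$environment == baseline_environment
    if (!any(ref)) {
      stop("no (", baseline_strain, ", ", baseline_environment, ") samples")
    }
    vals <- expr - rowMeans(expr[, ref, drop = FALSE])
  } else {
    vals <- expr
    for (e in unique(ann$environment)) {
      in_env <- ann$environment == e
      ref <- in_env & ann$kinase == baseline_strain
      if (!any(ref)) {
        stop("matched_environment_wt baseline: no ", baseline_strain,
             " samples in environment '", e, "'")
      }
      vals[, in_env] <- expr[, in_env, drop = FALSE] -
        rowMeans(expr[, ref, drop = FALSE])
    }
  }
  structure(
    list(values = vals, annotation = ann, baseline = baseline,
         baseline_strain = baseline_strain,
         baseline_environment = baseline_environment),
    class = "fc_matrix"
  )
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("<fc_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples, baseline = ", x$baseline, "\n", sep = "")
  invisible(x)
}

#' Remove low-expression genes
#'
#' Drops genes whose total count across samples is below `min_total`;
#' gene order is preserved.
#'
#' @param counts Gene x sample count matrix.
#' @param min_total Minimum total count; default one per sample.
#' @return Filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_total = ncol(counts)) {
  if (min_total < 0) stop("min_total must be >= 0")
  counts <- as.matrix(counts)
  keep <- rowSums(counts) >= min_total
  if (!any(keep)) stop("min_total = ", min_total, " removes every gene")
  counts[keep, , drop = FALSE]
}
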