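#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sorted p-values are multiplied by `m / rank`,
#' a running minimum from the largest rank down enforces monotonicity,
#' and results are capped at 1. Output order matches input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NAs propagate).
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  p <- as.numeric(pvalues)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m > 0L) {
    o <- order(pp)
    adj <- pp[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    res <- numeric(m)
    res[o] <- adj
    out[ok] <- res
  }
  out
}

#' Per-environment differential expression from wild-type replicates
#'
#' For one environment, runs a per-gene Welch two-sample t-test of the
#' wild-type replicates in that environment against the wild-type
#' replicates in the baseline environment, on log2 expression, followed by
#' Benjamini-Hochberg adjustment across genes. Genes with zero variance in
#' both groups are assigned p = 1 (conservative).
#'
#' @param expr Gene x sample log2 expression matrix.
#' @param ann Sample annotation data.frame.
#' @param environment Environment to test.
#' @param cutoff Adjusted-p cutoff defining the DE set (default 0.05).
#' @param baseline_strain,baseline_environment Reference cell labels.
#' @return Object of class `de_result`: list with `environment`, `table`
#'   (data.frame gene, log2fc, stat, p, padj, is_de) and `de_genes`
#'   (a [gene_set()], or NULL when empty).
#' @export
call_de <- function(expr, ann, environment, cutoff = 0.05,
                    baseline_strain = "WT", baseline_environment = "YPD") {
  expr <- as.matrix(expr)
  stopifnot(identical(colnames(expr), ann$sample_id))
  g1 <- ann$kinase == baseline_strain & ann$environment == environment
  g0 <- ann$kinase == baseline_strain & ann$environment == baseline_environment
  if (sum(g1) < 2L || sum(g0) < 2L) {
    stop("need >= 2 ", baseline_strain, " replicates in both '", environment,
         "' (", sum(g1), ") and '", baseline_environment, "' (", sum(g0), ")")
  }
  x1 <- expr[, g1, drop = FALSE]
  x0 <- expr[, g0, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  stat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  degenerate <- se2 == 0
  p[degenerate] <- 1
  stat[degenerate] <- 0
  tab <- data.frame(gene = rownames(expr), log2fc = m1 - m0, stat = stat,
                    p = p, padj = benjamini_hochberg(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$is_de <- tab$padj < cutoff
  de <- tab$gene[tab$is_de]
  structure(
    list(environment = environment, cutoff = cutoff, table = tab,
         de_genes = if (length(de)) {
           gene_set(paste0("DE@", environment),
                    paste0("adjusted p < ", cutoff, " vs ",
                           baseline_environment), de)
         } else NULL),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> ", x$environment, ": ", sum(x$table$is_de), " / ",
      nrow(x$table), " genes DE at padj < ", x$cutoff, "\n", sep = "")
  invisible(x)
}
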