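#' ESR fold-change distributions per focal kinase
#'
#' For each focal kinase and for the pooled remainder of strains,
#' collects the matched-environment-baseline fold changes of the iESR
#' (pan-stress induced) and rESR (pan-stress repressed) genes across all
#' of the strain's samples, and tests each focal kinase against the
#' remainder with a rank-sum (Wilcoxon) location test. A master ESR
#' kinase (PKA-like) shows iESR up / rESR down upon inhibition; an
#' antagonist shows the reverse.
#'
#' @param fc_matched A matched-environment-baseline [fold_changes()]
#'   result.
#' @param iesr,resr [gene_set()]s of the two ESR branches.
#' @param focal_kinases Character vector of kinases given their own
#'   distribution (e.g. `c("Tpk123", "Pbs2")`).
#' @return data.frame with one row per (group, set): group, set, n,
#'   median, q25, q75, p (rank-sum vs pooled remainder; NA for the
#'   remainder rows and for single-value distributions, flagged in
#'   `flag`).
#' @export
esr_distributions <- function(fc_matched, iesr, resr, focal_kinases) {
  stopifnot(inherits(fc_matched, "fc_matrix"),
            fc_matched$baseline == "matched_environment_wt")
  ann <- fc_matched$annotation
  vals <- fc_matched$values
  absent <- setdiff(focal_kinases, ann$kinase)
  if (length(absent)) {
    stop("focal kinase(s) not in design: ", paste(absent, collapse = ", "))
  }
  sets <- list(iESR = iesr, rESR = resr)
  out <- list()
  for (sn in names(sets)) {
    genes <- intersect(sets[[sn]]$members, rownames(vals))
    if (length(genes) == 0L) {
      stop("no ", sn, " genes present in the fold-change matrix")
    }
    rest_cols <- !(ann$kinase %in% c(focal_kinases, fc_matched$baseline_strain))
    rest <- as.numeric(vals[genes, rest_cols, drop = FALSE])
    groups <- c(stats::setNames(as.list(focal_kinases), focal_kinases),
                list("all_others" = NULL))
    for (gn in names(groups)) {
      v <- if (is.null(groups[[gn]])) rest else
        as.numeric(vals[genes, ann$kinase == groups[[gn]], drop = FALSE])
      flag <- "ok"
      p <- NA_real_
      if (!is.null(groups[[gn]])) {
        if (length(v) < 2L || length(rest) < 2L) {
          flag <- "too_few_values"
        } else {
          p <- stats::wilcox.test(v, rest, exact = FALSE)$p.value
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        group = gn, set = sn, n = length(v),
        median = stats::median(v),
        q25 = unname(stats::quantile(v, 0.25)),
        q75 = unname(stats::quantile(v, 0.75)),
        p = p, flag = flag, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Gene-set response test per kinase in one environment
#'
#' For a signature set (e.g. an Hsf1 regulon) in one environment, tests
#' each kinase strain against wild type with a two-factor (strain x
#' gene) analysis of the matched-baseline fold changes: per kinase, the
#' set's per-(gene, sample) fold changes for that strain and the
#' wild-type replicates are modeled as `value ~ strain + gene` and the
#' strain main effect is tested. BH adjustment across kinases; the
#' reported direction is the sign of the strain effect (negative =
#' attenuation).
#'
#' @param fc_matched A matched-environment-baseline [fold_changes()]
#'   result.
#' @param set A [gene_set()] with at least 3 members present.
#' @param environment Environment to test in.
#' @return data.frame: kinase, effect (strain-effect log2), direction
#'   (`"attenuation"`/`"enhancement"`), p, padj, n_genes.
#' @export
geneset_response_test <- function(fc_matched, set, environment) {
  stopifnot(inherits(fc_matched, "fc_matrix"),
            fc_matched$baseline == "matched_environment_wt")
  ann <- fc_matched$annotation
  genes <- intersect(set$members, rownames(fc_matched$values))
  if (length(genes) < 3L) {
    stop("need >= 3 set genes present, found ", length(genes))
  }
  in_env <- ann$environment == environment
  wt_cols <- in_env & ann$kinase == fc_matched$baseline_strain
  if (!any(wt_cols)) stop("no WT samples in environment '", environment, "'")
  kinases <- setdiff(unique(ann$kinase[in_env]), fc_matched$baseline_strain)
  if (!length(kinases)) stop("no mutant samples in environment '", environment, "'")
  rows <- lapply(kinases, function(k) {
    mut_cols <- in_env & ann$kinase == k
    cols <- which(wt_cols | mut_cols)
    vals <- fc_matched$values[genes, cols, drop = FALSE]
    df <- data.frame(
      value = as.numeric(vals),
      strain = factor(rep(ifelse(ann$kinase[cols] == k, "mut", "WT"),
                          each = length(genes)), levels = c("WT", "mut")),
      gene = factor(rep(genes, times = length(cols)))
    )
    fit <- stats::lm(value ~ strain + gene, data = df)
    an <- stats::anova(fit)
    eff <- unname(stats::coef(fit)["strainmut"])
    data.frame(kinase = k, effect = eff,
               direction = ifelse(eff < 0, "attenuation", "enhancement"),
               p = an["strain", "Pr(>F)"], n_genes = length(genes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$padj <- benjamini_hochberg(out$p)
  out
}

#' Measured vs predicted expression of a gene set, per sample
#'
#' Averages the additive model's fitted and measured values over the
#' set's genes per sample and standardizes the set-level mean residual
#' as `z = mean(residual) * sqrt(|set|) / sigma` (averaging n
#' independent residuals tightens the null by sqrt(n)). Samples with
#' |z| > `flag_threshold` are flagged — the quantitative version of the
#' set-level measured-vs-predicted scatter.
#'
#' @param fit An [fit_additive()] result.
#' @param set A [gene_set()]; members absent from the fit are dropped.
#' @param flag_threshold Threshold on |z| (default 2.5).
#' @param sigma_mode Passed to the pooled scale estimate.
#' @return data.frame: sample_id, kinase, environment, mean_predicted,
#'   mean_measured, z, flagged.
#' @export
geneset_residual_scatter <- function(fit, set, flag_threshold = 2.5,
                                     sigma_mode = c("global_sd", "global_mad")) {
  genes <- intersect(set$members, rownames(fit$residuals))
  if (length(genes) == 0L) stop("no set genes covered by the fit")
  ms <- pooled_sigma(fit, sigma_mode)
  n <- length(genes)
  pred <- colMeans(fit$fitted[genes, , drop = FALSE])
  meas <- colMeans(fit$fitted[genes, , drop = FALSE] +
                   fit$residuals[genes, , drop = FALSE])
  z <- (meas - pred - ms[["mean"]]) * sqrt(n) / ms[["sigma"]]
  data.frame(sample_id = fit$annotation$sample_id,
             kinase = fit$annotation$kinase,
             environment = fit$annotation$environment,
             mean_predicted = unname(pred), mean_measured = unname(meas),
             z = unname(z), flagged = unname(abs(z) > flag_threshold),
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering of genes for heatmap display
#'
#' Agglomerative clustering with correlation distance (1 - Pearson,
#' computed across samples) and average linkage, cut at `n_clusters`.
#' Deterministic given input order. Genes with zero variance (undefined
#' correlation) are assigned distance 1 to everything.
#'
#' @param fc A [fold_changes()] result or a numeric matrix.
#' @param n_clusters Number of clusters (>= 2).
#' @param subset Optional [gene_set()] restricting the genes.
#' @return List with `clusters` (named integer vector gene -> cluster),
#'   `order` (gene ids in dendrogram order), `hclust`.
#' @export
cluster_genes <- function(fc, n_clusters, subset = NULL) {
  vals <- if (inherits(fc, "fc_matrix")) fc$values else as.matrix(fc)
  if (!is.null(subset)) {
    vals <- vals[intersect(subset$members, rownames(vals)), , drop = FALSE]
  }
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (n_clusters > nrow(vals)) {
    stop("n_clusters (", n_clusters, ") exceeds number of genes (",
         nrow(vals), ")")
  }
  cc <- suppressWarnings(stats::cor(t(vals)))
  cc[!is.finite(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = n_clusters)
  list(clusters = cl, order = rownames(vals)[hc$order], hclust = hc)
}
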