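#' Hash a configuration object
#'
#' MD5 of the canonical JSON serialization; changes iff a semantic field
#' changes. Used to stamp pipeline outputs.
#'
#' @param config Any list-like configuration.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate a full on-disk dataset
#'
#' Generates ground truth, counts, promoters, motif library and
#' annotation/signature gene sets for a [sim_config()], and writes the
#' whole fixture bundle (counts TSV, annotation TSV, truth tables,
#' promoters FASTA, PFM text, GMT files) plus a YAML manifest to
#' `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list (paths + config hash + seed).
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  truth <- generate_truth(config)
  sim <- simulate_counts(truth, config)
  motifs <- generate_motif_library(names(truth$tf_target_map),
                                   width = config$motif_width,
                                   seed = config$seed)
  promoters <- generate_promoters(truth, motif_library = motifs)
  ann_sets <- generate_annotation_sets(truth)

  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    env_effects = file.path(out_dir, "truth_env_effects.tsv"),
    kinase_effects = file.path(out_dir, "truth_kinase_effects.tsv"),
    interactions = file.path(out_dir, "truth_interactions.tsv"),
    gene_params = file.path(out_dir, "truth_gene_params.tsv"),
    promoters = file.path(out_dir, "promoters.fasta"),
    pfms = file.path(out_dir, "motifs.pfm"),
    signatures = file.path(out_dir, "signatures.gmt"),
    annotation_sets = file.path(out_dir, "annotation_sets.gmt"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write_count_matrix(sim$counts, sim$annotation, paths$counts,
                     paths$annotation)
  write_matrix_tsv(truth$env_effects, paths$env_effects, "gene")
  write_matrix_tsv(truth$kinase_effects, paths$kinase_effects, "gene")
  utils::write.table(truth$interaction_effects, paths$interactions,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = truth$genes, baseline_log2 = truth$baseline_log2,
               dispersion = truth$dispersion, row.names = NULL),
    paths$gene_params, sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta_promoters(promoters, paths$promoters)
  write_jaspar_pfm(motifs, paths$pfms)
  write_gmt(c(list(truth$iesr, truth$resr), truth$tf_target_map),
            paths$signatures)
  write_gmt(ann_sets, paths$annotation_sets)

  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   n_samples = ncol(sim$counts), n_genes = nrow(sim$counts),
                   files = lapply(paths[names(paths) != "manifest"], basename))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(manifest)
}

write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on an on-disk dataset
#'
#' Executes preprocessing (filtering, size factors, log2 normalization,
#' both fold-change baselines), per-environment differential expression,
#' slope analysis, the additive decomposition with residual z-scoring
#' and interaction calling, gene-set and promoter-motif enrichment with
#' kinase-TF network assembly, and ESR signature analysis, writing every
#' stage's table under `out_dir`. Any stage error aborts with the stage
#' name.
#'
#' @param paths List with elements `counts`, `annotation`, and optionally
#'   `promoters`, `pfms`, `signatures`, `annotation_sets` (as written by
#'   [run_simulate()]).
#' @param out_dir Output directory.
#' @param de_cutoff Adjusted-p DE cutoff (default 0.05).
#' @param residual_threshold Interaction-call threshold in global-sigma
#'   units (default 2.5).
#' @param enrichment_cutoff Adjusted-p cutoff for enrichment edges
#'   (default 0.05).
#' @param pwm_fraction Motif-hit score fraction (default 0.8).
#' @param estimator Additive-model estimator (default
#'   `"reference_plugin"`).
#' @param sigma_mode Pooled residual scale mode (default `"global_sd"`).
#' @param focal_kinases Kinases given their own ESR distribution
#'   (default `c("Tpk123", "Pbs2")`, intersected with the design).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_all <- function(paths, out_dir, de_cutoff = 0.05,
                    residual_threshold = 2.5, enrichment_cutoff = 0.05,
                    pwm_fraction = 0.8,
                    estimator = c("reference_plugin", "joint_ols"),
                    sigma_mode = c("global_sd", "global_mad"),
                    focal_kinases = c("Tpk123", "Pbs2")) {
  estimator <- match.arg(estimator)
  sigma_mode <- match.arg(sigma_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[run_all] %-12s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  dat <- stage("read", read_count_matrix(paths$counts, paths$annotation))
  validate_annotation(dat$annotation, "WT", "YPD")

  pre <- stage("preprocess", {
    counts <- filter_low_expression(dat$counts)
    sf <- size_factors(counts)
    expr <- normalize_log2(counts, sf)
    list(counts = counts, size_factors = sf, expr = expr,
         fc_global = fold_changes(expr, dat$annotation, "global_wt_ypd"),
         fc_matched = fold_changes(expr, dat$annotation,
                                   "matched_environment_wt"))
  })

  envs <- setdiff(unique(dat$annotation$environment), "YPD")
  de <- stage("diffexpr", {
    res <- lapply(envs, function(e) {
      call_de(pre$expr, dat$annotation, e, cutoff = de_cutoff)
    })
    names(res) <- envs
    res
  })

  slopes <- stage("slopes", {
    usable <- Filter(function(d) !is.null(d$de_genes) &&
                       length(d$de_genes$members) >= 10L, de)
    if (length(usable)) slope_fits(usable, pre$fc_matched) else NULL
  })

  fit <- stage("decompose", fit_additive(pre$fc_global, estimator))
  z <- stage("zscores", residual_zscores(fit, sigma_mode))
  calls <- stage("calls", call_interactions(fit, residual_threshold,
                                            sigma_mode))
  r2 <- r2_distribution(fit)

  enrich <- NULL
  if (!is.null(paths$annotation_sets)) {
    enrich <- stage("enrich_sets", {
      sets <- read_gmt(paths$annotation_sets)
      groups <- split(calls$gene,
                      paste(calls$kinase, calls$environment, sep = "@"))
      groups <- Filter(function(g) length(unique(g)) >= 5L, groups)
      if (!length(groups)) return(NULL)
      do.call(rbind, lapply(names(groups), function(g) {
        hypergeometric_enrichment(unique(groups[[g]]), sets,
                                  rownames(pre$expr), query_name = g)
      }))
    })
  }

  network <- NULL
  motif <- NULL
  if (!is.null(paths$promoters) && !is.null(paths$pfms)) {
    motif <- stage("enrich_motifs", {
      promoters <- read_fasta_promoters(paths$promoters)
      pwms <- read_jaspar_pfm(paths$pfms)
      motif_enrichment(calls[calls$gene %in% names(promoters), ],
                       promoters, pwms,
                       score_threshold_fraction = pwm_fraction)
    })
    network <- stage("network",
                     build_kinase_tf_network(motif, enrichment_cutoff))
  }

  signatures <- NULL
  if (!is.null(paths$signatures)) {
    signatures <- stage("signatures", {
      sig <- read_gmt(paths$signatures)
      focal <- intersect(focal_kinases, dat$annotation$kinase)
      if (all(c("iESR", "rESR") %in% names(sig)) && length(focal)) {
        esr_distributions(pre$fc_matched, sig$iESR, sig$rESR, focal)
      } else NULL
    })
  }

  stage("write", {
    utils::write.table(data.frame(sample_id = names(pre$size_factors),
                                  size_factor = pre$size_factors,
                                  row.names = NULL),
                       file.path(out_dir, "size_factors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (e in names(de)) {
      utils::write.table(de[[e]]$table,
                         file.path(out_dir, paste0("de_", e, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(slopes)) {
      utils::write.table(slopes, file.path(out_dir, "slopes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_matrix_tsv(fit$c_effects, file.path(out_dir, "env_effects.tsv"))
    write_matrix_tsv(fit$k_effects, file.path(out_dir, "kinase_effects.tsv"))
    write_matrix_tsv(z, file.path(out_dir, "residual_z.tsv"))
    utils::write.table(calls, file.path(out_dir, "interaction_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene = rownames(fit$residuals),
                                  r2 = fit$r2, row.names = NULL),
                       file.path(out_dir, "r2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrich)) {
      utils::write.table(enrich, file.path(out_dir, "geneset_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(motif)) {
      utils::write.table(motif, file.path(out_dir, "motif_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(network)) {
      utils::write.table(network$edges,
                         file.path(out_dir, "kinase_tf_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(signatures)) {
      utils::write.table(signatures,
                         file.path(out_dir, "esr_distributions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    yaml::write_yaml(
      list(config_hash = config_hash(list(
             de_cutoff = de_cutoff, residual_threshold = residual_threshold,
             enrichment_cutoff = enrichment_cutoff,
             pwm_fraction = pwm_fraction, estimator = estimator,
             sigma_mode = sigma_mode)),
           mean_r2 = r2$mean, global_sigma = fit$global_sigma,
           n_calls = nrow(calls)),
      file.path(out_dir, "run_summary.yaml"))
    NULL
  })

  invisible(list(preprocess = pre, de = de, slopes = slopes, fit = fit,
                 zscores = z, calls = calls, r2 = r2, enrich = enrich,
                 motif = motif, network = network, signatures = signatures))
}
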