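#' Default kinase panel
#'
#' The 28 analog-sensitive kinase strain labels used by the default
#' simulated design, alongside the wild-type label `"WT"`. `"Tpk123"`
#' denotes the triple analog-sensitive PKA strain (Tpk1/2/3).
#'
#' @return Character vector of 28 kinase labels (WT not included).
#' @export
default_kinases <- function() {
  c("Tpk123", "Pbs2", "Hog1", "Ste11", "Sch9", "Ypk1", "Ypk3", "Cdc15",
    "Snf1", "Ire1", "Cdc5", "Cdc7", "Ctk1", "Fus3", "Kin1", "Ksp1",
    "Mrk1", "Rim11", "Rim15", "Ssn3", "Yak1", "Ygk3", "Atg1", "Bck1",
    "Slt2", "Gcn2", "Pho85", "Rad53")
}

#' Default environment panel
#'
#' Ten environments: rich media baseline (YPD), synthetic media (SDC) and
#' eight stress conditions.
#'
#' @return Character vector of 10 environment labels; the first is the
#'   baseline.
#' @export
default_environments <- function() {
  c("YPD", "SDC", "heat_shock", "NaCl", "glucose_depletion", "tunicamycin",
    "menadione", "AZC", "rapamycin", "fluconazole")
}

#' Default set of missing (kinase, environment) cells
#'
#' The real design is missing a handful of mutant samples; the published
#' sample count (301 = 28 x 10 - 19 + 4 x 10) implies 19 missing mutant
#' cells but their identity is not enumerated, so the simulator picks 19
#' cells once, at a fixed internal seed, always including
#' (Tpk123, glucose_depletion) which is known to be absent. Only
#' non-baseline environments are eligible so every kinase keeps its YPD
#' sample (required by the plug-in estimator).
#'
#' @param kinases,environments Design labels; first environment is baseline.
#' @param n_missing Number of missing cells (default 19).
#' @return data.frame with columns `kinase`, `environment`.
#' @export
default_missing_cells <- function(kinases = default_kinases(),
                                  environments = default_environments(),
                                  n_missing = 19L) {
  forced <- data.frame(kinase = "Tpk123", environment = "glucose_depletion",
                       stringsAsFactors = FALSE)
  if (!forced$kinase %in% kinases || !forced$environment %in% environments) {
    forced <- forced[0L, ]
  }
  eligible <- expand.grid(kinase = kinases, environment = environments[-1L],
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(eligible$kinase, eligible$environment)
  eligible <- eligible[!key %in% paste(forced$kinase, forced$environment), ]
  extra <- n_missing - nrow(forced)
  picked <- local({
    # fixed internal seed: the missing-cell pattern is part of the design,
    # not of the stochastic draw, so it must not move with config$seed
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(104729L)
    idx <- sample(nrow(eligible), extra)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    idx
  })
  out <- rbind(forced, eligible[picked, ])
  rownames(out) <- NULL
  out[order(out$kinase, out$environment), , drop = FALSE]
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic study. Defaults reproduce the
#' emulated design: 28 kinase strains plus wild type, 10 environments,
#' 4 wild-type replicates per environment, a single mutant replicate per
#' cell, 19 missing mutant cells (301 samples in total), additive
#' environment and kinase effects on log2 expression, coordinated
#' iESR/rESR modules with a master-kinase/antagonist pair, sparse planted
#' interactions, and negative-binomial counts over a log-normal mean.
#'
#' @param n_genes Number of genes (default 6000).
#' @param kinases Kinase labels (default [default_kinases()]).
#' @param environments Environment labels, baseline first
#'   (default [default_environments()]).
#' @param wt_replicates Wild-type replicates per environment (default 4).
#' @param mutant_replicates Mutant replicates per cell (default 1).
#' @param missing_cells data.frame(kinase, environment) of absent mutant
#'   cells (default [default_missing_cells()]).
#' @param noise_sd_log2 SD of Gaussian biological noise on log2 scale
#'   (default 0.12).
#' @param env_responsive_fraction Fraction of genes responding to each
#'   environment (default 0.35).
#' @param env_effect_sd SD of non-zero environment effects, log2
#'   (default 1.5).
#' @param kinase_responsive_fraction Fraction of genes responding to each
#'   kinase inhibition (default 0.1).
#' @param kinase_effect_sd SD of non-zero kinase effects, log2 (default 1.2).
#' @param interaction_density Fraction of eligible (gene, kinase != WT,
#'   environment != baseline) cells carrying a planted interaction
#'   (default 0.002).
#' @param interaction_effect_size Absolute log2 size of planted
#'   interactions (default 2).
#' @param n_iesr,n_resr Sizes of the pan-stress induced / repressed
#'   modules (default 150 each).
#' @param esr_env_effect Mean absolute log2 stress effect on ESR genes
#'   (default 2).
#' @param master_kinases Named numeric vector kinase -> {+1, -1} giving
#'   the ESR coupling sign of master kinases: +1 means inhibition
#'   de-represses the iESR and represses the rESR (PKA-like), -1 the
#'   opposite (default `c(Tpk123 = 1, Pbs2 = -1)`).
#' @param master_effect Absolute log2 kinase effect on ESR genes for
#'   master kinases (default 1.5).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline log2 mean
#'   expression distribution (default 8 and 1.5).
#' @param dispersion_range Range of per-gene NB dispersion alpha
#'   (variance mu + alpha mu^2), drawn log-uniform (default c(0.002, 0.05)).
#' @param count_model `"nb"` for negative-binomial counts (default) or
#'   `"deterministic"` for rounded expected counts, leaving the Gaussian
#'   log2 noise as the only stochastic term.
#' @param library_size_range Per-sample library size factor range,
#'   uniform (default c(0.6, 1.6)).
#' @param n_tfs,targets_per_tf,motif_width Planted TF module structure
#'   (default 6 TFs x 40 targets, width-8 motifs).
#' @param promoter_length Promoter length in bp (default 500).
#' @param seed Global seed; all sub-generators derive child seeds from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 6000L,
                       kinases = default_kinases(),
                       environments = default_environments(),
                       wt_replicates = 4L,
                       mutant_replicates = 1L,
                       missing_cells = NULL,
                       noise_sd_log2 = 0.12,
                       env_responsive_fraction = 0.35,
                       env_effect_sd = 1.5,
                       kinase_responsive_fraction = 0.1,
                       kinase_effect_sd = 1.2,
                       interaction_density = 0.002,
                       interaction_effect_size = 2,
                       n_iesr = 150L,
                       n_resr = 150L,
                       esr_env_effect = 2,
                       master_kinases = c(Tpk123 = 1, Pbs2 = -1),
                       master_effect = 1.5,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       dispersion_range = c(0.002, 0.05),
                       count_model = c("nb", "deterministic"),
                       library_size_range = c(0.6, 1.6),
                       n_tfs = 6L,
                       targets_per_tf = 40L,
                       motif_width = 8L,
                       promoter_length = 500L,
                       seed = 1L) {
  count_model <- match.arg(count_model)
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (anyDuplicated(kinases) || "WT" %in% kinases) {
    stop("kinases must be unique and must not include 'WT'")
  }
  if (anyDuplicated(environments)) stop("environments must be unique")
  if (interaction_density < 0 || interaction_density >= 1) {
    stop("interaction_density must lie in [0, 1)")
  }
  if (wt_replicates < 1 || mutant_replicates < 1) {
    stop("replicate counts must be >= 1")
  }
  if (noise_sd_log2 < 0) stop("noise_sd_log2 must be >= 0")
  if (is.null(missing_cells)) {
    missing_cells <- if (identical(kinases, default_kinases()) &&
                         identical(environments, default_environments())) {
      default_missing_cells(kinases, environments)
    } else {
      data.frame(kinase = character(), environment = character())
    }
  }
  if (nrow(missing_cells)) {
    if (!all(missing_cells$kinase %in% kinases) ||
        !all(missing_cells$environment %in% environments)) {
      stop("missing_cells refer to unknown kinase or environment labels")
    }
    if (any(missing_cells$environment == environments[1L])) {
      stop("missing_cells may not remove baseline-environment samples")
    }
  }
  if (!all(names(master_kinases) %in% kinases)) {
    stop("master_kinases must name members of the kinase panel")
  }
  if (n_iesr + n_resr > n_genes) stop("ESR modules exceed n_genes")
  if (n_tfs > 0 && targets_per_tf > n_genes - n_iesr - n_resr) {
    stop("targets_per_tf exceeds the pool of non-ESR genes")
  }
  structure(
    list(n_genes = as.integer(n_genes), kinases = kinases,
         environments = environments,
         baseline_environment = environments[1L], baseline_strain = "WT",
         wt_replicates = as.integer(wt_replicates),
         mutant_replicates = as.integer(mutant_replicates),
         missing_cells = missing_cells,
         noise_sd_log2 = noise_sd_log2,
         env_responsive_fraction = env_responsive_fraction,
         env_effect_sd = env_effect_sd,
         kinase_responsive_fraction = kinase_responsive_fraction,
         kinase_effect_sd = kinase_effect_sd,
         interaction_density = interaction_density,
         interaction_effect_size = interaction_effect_size,
         n_iesr = as.integer(n_iesr), n_resr = as.integer(n_resr),
         esr_env_effect = esr_env_effect,
         master_kinases = master_kinases, master_effect = master_effect,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         dispersion_range = dispersion_range,
         count_model = count_model,
         library_size_range = library_size_range,
         n_tfs = as.integer(n_tfs),
         targets_per_tf = as.integer(targets_per_tf),
         motif_width = as.integer(motif_width),
         promoter_length = as.integer(promoter_length),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# deterministic child seed, kept below 2^31
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

#' Generate simulation ground truth
#'
#' Draws the full latent structure of the synthetic study: per-gene
#' environment effects (zero in the baseline environment, a sparse
#' Gaussian mixture elsewhere), kinase effects (zero for WT), pan-stress
#' coordinated iESR (induced) and rESR (repressed) modules, master-kinase
#' coupling to the ESR, sparse planted kinase-by-environment interaction
#' effects, per-gene baseline expression and NB dispersion, and a planted
#' TF -> target-gene map.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_truth` with elements `env_effects`
#'   (genes x environments), `kinase_effects` (genes x (WT + kinases)),
#'   `interaction_effects` (data.frame gene, kinase, environment, effect),
#'   `baseline_log2`, `dispersion`, `iesr`, `resr` ([gene_set()]s),
#'   `tf_target_map` (named list of gene_sets), `master_kinase_sign`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  ng <- config$n_genes
  genes <- sprintf("G%05d", seq_len(ng))
  envs <- config$environments
  kinases <- config$kinases
  stress_envs <- setdiff(envs, c(config$baseline_environment, "SDC"))
  if (!length(stress_envs)) stress_envs <- setdiff(envs, config$baseline_environment)

  env_eff <- matrix(0, ng, length(envs), dimnames = list(genes, envs))
  for (e in setdiff(envs, config$baseline_environment)) {
    on <- stats::runif(ng) < config$env_responsive_fraction
    env_eff[on, e] <- stats::rnorm(sum(on), 0, config$env_effect_sd)
  }

  kin_eff <- matrix(0, ng, length(kinases) + 1L,
                    dimnames = list(genes, c("WT", kinases)))
  for (k in kinases) {
    on <- stats::runif(ng) < config$kinase_responsive_fraction
    kin_eff[on, k] <- stats::rnorm(sum(on), 0, config$kinase_effect_sd)
  }

  # coordinated ESR modules: induced in every stress, repressed in every
  # stress, with master kinases coupled by sign
  iesr_idx <- seq_len(config$n_iesr)
  resr_idx <- seq_len(config$n_resr) + config$n_iesr
  iesr <- genes[iesr_idx]
  resr <- genes[resr_idx]
  for (e in stress_envs) {
    env_eff[iesr_idx, e] <- config$esr_env_effect *
      stats::runif(length(iesr_idx), 0.75, 1.25)
    env_eff[resr_idx, e] <- -config$esr_env_effect *
      stats::runif(length(resr_idx), 0.75, 1.25)
  }
  sign_map <- stats::setNames(rep(0, length(kinases)), kinases)
  sign_map[names(config$master_kinases)] <- config$master_kinases
  for (k in names(config$master_kinases)) {
    s <- config$master_kinases[[k]]
    kin_eff[iesr_idx, k] <- s * config$master_effect *
      stats::runif(length(iesr_idx), 0.75, 1.25)
    kin_eff[resr_idx, k] <- -s * config$master_effect *
      stats::runif(length(resr_idx), 0.75, 1.25)
  }

  eligible <- expand.grid(kinase = kinases,
                          environment = setdiff(envs, config$baseline_environment),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(config$missing_cells)) {
    drop <- paste(eligible$kinase, eligible$environment) %in%
      paste(config$missing_cells$kinase, config$missing_cells$environment)
    eligible <- eligible[!drop, , drop = FALSE]
  }
  n_cells <- ng * nrow(eligible)
  n_inter <- round(config$interaction_density * n_cells)
  if (n_inter > 0) {
    pick <- sample.int(n_cells, n_inter)
    gi <- ((pick - 1L) %% ng) + 1L
    ci <- ((pick - 1L) %/% ng) + 1L
    interactions <- data.frame(
      gene = genes[gi],
      kinase = eligible$kinase[ci],
      environment = eligible$environment[ci],
      effect = sample(c(-1, 1), n_inter, replace = TRUE) *
        config$interaction_effect_size,
      stringsAsFactors = FALSE
    )
  } else {
    interactions <- data.frame(gene = character(), kinase = character(),
                               environment = character(), effect = numeric(),
                               stringsAsFactors = FALSE)
  }

  baseline <- stats::rnorm(ng, config$baseline_log2_mean, config$baseline_log2_sd)
  baseline <- pmax(baseline, 2)
  names(baseline) <- genes
  lr <- log(config$dispersion_range)
  dispersion <- exp(stats::runif(ng, lr[1L], lr[2L]))
  names(dispersion) <- genes

  tf_map <- list()
  if (config$n_tfs > 0) {
    pool <- genes[-(c(iesr_idx, resr_idx))]
    for (t in seq_len(config$n_tfs)) {
      nm <- sprintf("TF%02d", t)
      tf_map[[nm]] <- gene_set(nm, "planted TF target module",
                               sample(pool, config$targets_per_tf))
    }
  }

  structure(
    list(genes = genes, env_effects = env_eff, kinase_effects = kin_eff,
         interaction_effects = interactions, baseline_log2 = baseline,
         dispersion = dispersion,
         iesr = gene_set("iESR", "pan-stress induced module", iesr),
         resr = gene_set("rESR", "pan-stress repressed module", resr),
         tf_target_map = tf_map, master_kinase_sign = sign_map,
         config = config),
    class = "sim_truth"
  )
}

#' Simulate the count matrix and sample annotation
#'
#' Builds the full design (WT replicates in every environment; mutant
#' replicates per (kinase, environment) cell minus the configured missing
#' cells) and draws counts. Per sample and gene the expected expression is
#' `2^(baseline + c_env + k_kinase + interaction + eps)` with
#' `eps ~ N(0, noise_sd_log2^2)`, scaled by a per-sample library size
#' factor; counts are negative binomial with per-gene dispersion (or the
#' rounded expectation under `count_model = "deterministic"`).
#'
#' @param truth A [generate_truth()] result.
#' @param config The matching [sim_config()] (defaults to the one stored
#'   in `truth`).
#' @return List with `counts` (integer matrix), `annotation` (data.frame)
#'   and `library_factors` (named numeric).
#' @export
simulate_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(child_seed(config$seed, 2L))
  envs <- config$environments
  ann <- rbind(
    expand.grid(kinase = "WT", environment = envs,
                replicate = seq_len(config$wt_replicates),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    expand.grid(kinase = config$kinases, environment = envs,
                replicate = seq_len(config$mutant_replicates),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  )
  if (nrow(config$missing_cells)) {
    drop <- paste(ann$kinase, ann$environment) %in%
      paste(config$missing_cells$kinase, config$missing_cells$environment)
    ann <- ann[!drop, , drop = FALSE]
  }
  ann <- ann[order(match(ann$environment, envs),
                   match(ann$kinase, c("WT", config$kinases)),
                   ann$replicate), , drop = FALSE]
  ann <- data.frame(
    sample_id = paste(ann$kinase, ann$environment, ann$replicate, sep = "."),
    ann, row.names = NULL, stringsAsFactors = FALSE
  )

  ng <- config$n_genes
  ns <- nrow(ann)
  log2mu <- matrix(truth$baseline_log2, ng, ns) +
    truth$env_effects[, ann$environment, drop = FALSE] +
    truth$kinase_effects[, ann$kinase, drop = FALSE]
  if (nrow(truth$interaction_effects)) {
    ie <- truth$interaction_effects
    gi <- match(ie$gene, truth$genes)
    for (r in seq_len(nrow(ie))) {
      cols <- which(ann$kinase == ie$kinase[r] &
                    ann$environment == ie$environment[r])
      log2mu[gi[r], cols] <- log2mu[gi[r], cols] + ie$effect[r]
    }
  }
  if (config$noise_sd_log2 > 0) {
    log2mu <- log2mu + matrix(stats::rnorm(ng * ns, 0, config$noise_sd_log2),
                              ng, ns)
  }
  lib <- stats::runif(ns, config$library_size_range[1L],
                      config$library_size_range[2L])
  names(lib) <- ann$sample_id
  mu <- sweep(2^log2mu, 2L, lib, "*")
  counts <- if (config$count_model == "nb") {
    matrix(stats::rnbinom(ng * ns, mu = mu, size = 1 / truth$dispersion),
           ng, ns)
  } else {
    round(mu)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truth$genes, ann$sample_id)
  list(counts = counts, annotation = ann, library_factors = lib)
}

#' Generate a library of sharply informative motifs
#'
#' One PWM per TF name; each column concentrates probability
#' `concentration` on one base chosen at random. Used to plant detectable
#' promoter motifs for the enrichment stage.
#'
#' @param tf_names Character vector of TF names.
#' @param width Motif width (default 8).
#' @param concentration Probability of the dominant base per column
#'   (default 0.85).
#' @param seed Seed.
#' @return Named list of [pwm()] objects.
#' @export
generate_motif_library <- function(tf_names, width = 8L, concentration = 0.85,
                                   seed = 1L) {
  set.seed(child_seed(seed, 3L))
  out <- list()
  for (nm in tf_names) {
    m <- matrix((1 - concentration) / 3, 4L, width,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    dom <- sample.int(4L, width, replace = TRUE)
    m[cbind(dom, seq_len(width))] <- concentration
    out[[nm]] <- pwm(nm, m)
  }
  out
}

consensus_instance <- function(p) {
  bases <- rownames(p$matrix)
  paste(bases[apply(p$matrix, 2L, which.max)], collapse = "")
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Generate promoter sequences with planted motif instances
#'
#' Promoters are i.i.d. background sequence at a yeast-like base
#' composition; for each TF in `truth$tf_target_map`, one consensus
#' instance of the TF's motif is embedded at a random position (random
#' strand) in each target gene's promoter. Non-target genes receive no
#' planted instance.
#'
#' @param truth A [generate_truth()] result.
#' @param length Promoter length in bp (default from config).
#' @param motif_library Named list of [pwm()]s covering all TF names in
#'   `truth$tf_target_map`.
#' @param seed Seed (default from config).
#' @param base_composition Background base frequencies A, C, G, T
#'   (default yeast-like c(0.31, 0.19, 0.19, 0.31)).
#' @return Named character vector gene -> sequence.
#' @export
generate_promoters <- function(truth, length = truth$config$promoter_length,
                               motif_library,
                               seed = truth$config$seed,
                               base_composition = c(0.31, 0.19, 0.19, 0.31)) {
  stopifnot(inherits(truth, "sim_truth"))
  absent <- setdiff(names(truth$tf_target_map), names(motif_library))
  if (length(absent) > 0L) {
    stop("motif_library lacks PWM(s): ", paste(absent, collapse = ", "))
  }
  for (nm in names(truth$tf_target_map)) {
    if (ncol(motif_library[[nm]]$matrix) > length) {
      stop("motif '", nm, "' is longer than the promoter")
    }
  }
  set.seed(child_seed(seed, 4L))
  bases <- c("A", "C", "G", "T")
  n <- base::length(truth$genes)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(bases, length, replace = TRUE, prob = base_composition),
          collapse = "")
  }, character(1))
  names(seqs) <- truth$genes
  for (nm in names(truth$tf_target_map)) {
    p <- motif_library[[nm]]
    w <- ncol(p$matrix)
    for (g in truth$tf_target_map[[nm]]$members) {
      inst <- consensus_instance(p)
      if (stats::runif(1) < 0.5) inst <- revcomp(inst)
      pos <- sample.int(length - w + 1L, 1L)
      substr(seqs[[g]], pos, pos + w - 1L) <- inst
    }
  }
  seqs
}

#' Generate GO-style annotation gene sets
#'
#' Random gene sets over the simulated genome, with a controlled fraction
#' constructed to overlap the planted interaction genes so that
#' enrichment power can be tested against ground truth.
#'
#' @param truth A [generate_truth()] result.
#' @param n_sets Number of sets (default 50).
#' @param set_size_range Inclusive size range (default c(10, 50)).
#' @param enriched_fraction Fraction of sets biased toward planted
#'   interaction genes (default 0.2).
#' @param seed Seed (default from config).
#' @return Named list of [gene_set()]s; enriched sets carry the
#'   description `"interaction-enriched"`.
#' @export
generate_annotation_sets <- function(truth, n_sets = 50L,
                                     set_size_range = c(10L, 50L),
                                     enriched_fraction = 0.2,
                                     seed = truth$config$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_sets < 1) stop("n_sets must be >= 1")
  set.seed(child_seed(seed, 5L))
  inter_genes <- unique(truth$interaction_effects$gene)
  n_enriched <- round(enriched_fraction * n_sets)
  if (length(inter_genes) == 0L) n_enriched <- 0L
  out <- list()
  for (i in seq_len(n_sets)) {
    size <- if (set_size_range[1L] == set_size_range[2L]) set_size_range[1L]
            else sample(seq(set_size_range[1L], set_size_range[2L]), 1L)
    nm <- sprintf("SET%03d", i)
    if (i <= n_enriched) {
      n_hit <- min(length(inter_genes), max(1L, round(0.7 * size)))
      members <- c(sample(inter_genes, n_hit),
                   sample(setdiff(truth$genes, inter_genes), size - n_hit))
      out[[nm]] <- gene_set(nm, "interaction-enriched", members)
    } else {
      out[[nm]] <- gene_set(nm, "random", sample(truth$genes, size))
    }
  }
  out
}
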