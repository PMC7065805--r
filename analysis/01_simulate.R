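#!/usr/bin/env Rscript
# Generate the synthetic study: 28 analog-sensitive kinase strains plus
# wild type across 10 environments (4 WT replicates per environment, one
# mutant replicate per cell, 19 missing cells -> 301 samples), with known
# additive effects, coordinated iESR/rESR modules, sparse planted
# kinase x environment interactions, planted promoter motifs and
# GO-style annotation sets. Everything downstream reads this bundle.

suppressPackageStartupMessages(library(kindecomp))

out_dir <- "results/data"
config <- sim_config(n_genes = 2000L, seed = 20260925L)

manifest <- run_simulate(config, out_dir)
message("wrote ", manifest$n_genes, " genes x ", manifest$n_samples,
        " samples to ", out_dir, " (config ", manifest$config_hash, ")")
truth_int <- read.delim(file.path(out_dir, "truth_interactions.tsv"))
message("planted interactions: ", nrow(truth_int),
        " (density ", config$interaction_density, ", effect +/-",
        config$interaction_effect_size, " log2)")
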