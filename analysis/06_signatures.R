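#!/usr/bin/env Rscript
# Gene-set-level views: iESR/rESR fold-change distributions for the
# master-kinase/antagonist pair vs all other strains, a per-kinase
# regulon response test in heat shock, the set-level
# measured-vs-predicted diagnostic for the iESR, and hierarchical
# clustering of the most variable genes for heatmap display.

suppressPackageStartupMessages(library(kindecomp))

src <- "results/data"
out <- "results/signatures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dat <- read_count_matrix(file.path(src, "counts.tsv"),
                         file.path(src, "annotation.tsv"))
counts <- filter_low_expression(dat$counts)
expr <- normalize_log2(counts, size_factors(counts))
fcm <- fold_changes(expr, dat$annotation, "matched_environment_wt")
fcg <- fold_changes(expr, dat$annotation, "global_wt_ypd")
sig <- read_gmt(file.path(src, "signatures.gmt"))

# iESR/rESR distributions, master kinase vs antagonist vs the rest
esr <- esr_distributions(fcm, sig$iESR, sig$rESR,
                         focal_kinases = c("Tpk123", "Pbs2"))
write.table(esr, file.path(out, "esr_distributions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
show <- function(g, s) {
  r <- esr[esr$group == g & esr$set == s, ]
  sprintf("%s/%s median %+.2f", g, s, r$median)
}
message(paste(c(show("Tpk123", "iESR"), show("Tpk123", "rESR"),
                show("Pbs2", "iESR"), show("Pbs2", "rESR"),
                show("all_others", "iESR")), collapse = "; "))

# dedicated-regulon probe: which kinases shift a 42-gene induced module
# in heat shock? (a synthetic stand-in for a TF regulon test)
probe <- gene_set("heat_regulon_probe", "42 most heat-induced genes",
                  names(sort(fcg$values[, which(
                    dat$annotation$kinase == "WT" &
                    dat$annotation$environment == "heat_shock")[1]],
                    decreasing = TRUE))[1:42])
reg <- geneset_response_test(fcm, probe, "heat_shock")
write.table(reg, file.path(out, "regulon_response_heat_shock.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sum(reg$padj < 0.05), " kinases significantly shift the probe ",
        "regulon in heat shock")

# set-level measured vs predicted for the iESR
fit <- fit_additive(fcg, "reference_plugin")
sc <- geneset_residual_scatter(fit, sig$iESR)
write.table(sc, file.path(out, "iesr_measured_vs_predicted.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sum(sc$flagged), " samples where the iESR departs from the ",
        "additive prediction at set-level |z| > 2.5")

# gene clustering for the heatmap ordering
vars <- apply(fcg$values, 1, var)
top <- gene_set("top_var", "most variable genes",
                names(sort(vars, decreasing = TRUE))[1:500])
cl <- cluster_genes(fcg, n_clusters = 7, subset = top)
write.table(data.frame(gene = names(cl$clusters), cluster = cl$clusters,
                       row.names = NULL),
            file.path(out, "gene_clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("clustered ", length(cl$clusters), " genes into ",
        length(unique(cl$clusters)), " groups")
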