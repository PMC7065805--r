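#!/usr/bin/env Rscript
# Annotate the interaction calls: hypergeometric enrichment of each
# (kinase, environment) call group against GO-style annotation sets, and
# promoter motif enrichment against the supplied PWM library, assembled
# into the kinase -> TF bipartite network.

suppressPackageStartupMessages(library(kindecomp))

src <- "results/data"
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

calls <- read.delim("results/decomposition/interaction_calls.tsv",
                    stringsAsFactors = FALSE)
universe <- read.delim("results/decomposition/r2.tsv")$gene
sets <- read_gmt(file.path(src, "annotation_sets.gmt"))
promoters <- read_fasta_promoters(file.path(src, "promoters.fasta"))
pwms <- read_jaspar_pfm(file.path(src, "motifs.pfm"))

groups <- split(calls$gene, paste(calls$kinase, calls$environment, sep = "@"))
groups <- Filter(function(g) length(unique(g)) >= 5, groups)
message(length(groups), " call groups with >= 5 genes")

gse <- do.call(rbind, lapply(names(groups), function(g) {
  hypergeometric_enrichment(unique(groups[[g]]), sets, universe,
                            query_name = g)
}))
write.table(gse, file.path(out, "geneset_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sum(gse$padj < 0.05), " (group, set) pairs enriched at BH 0.05")

me <- motif_enrichment(calls[calls$gene %in% names(promoters), ],
                       promoters, pwms, score_threshold_fraction = 0.8)
write.table(me, file.path(out, "motif_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

net <- build_kinase_tf_network(me, cutoff = 0.05,
                               focus_environments = c("heat_shock",
                                                      "menadione"))
write.table(net$edges, file.path(out, "kinase_tf_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(nrow(net$edges), " kinase-TF edges at BH 0.05 (",
        nrow(net$subgraphs$heat_shock), " heat shock, ",
        nrow(net$subgraphs$menadione), " menadione, ",
        nrow(net$subgraphs$other), " other)")
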