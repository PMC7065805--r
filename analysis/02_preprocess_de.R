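#!/usr/bin/env Rscript
# Normalize counts (median-of-ratios + log2), compute fold changes
# against both baselines (WT in rich media; matched-environment WT), and
# call per-environment differentially expressed genes from the wild-type
# replicates (Welch t on log2 expression, BH-adjusted, padj < 0.05).

suppressPackageStartupMessages(library(kindecomp))

src <- "results/data"
out <- "results/de"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dat <- read_count_matrix(file.path(src, "counts.tsv"),
                         file.path(src, "annotation.tsv"))
counts <- filter_low_expression(dat$counts)
message("kept ", nrow(counts), "/", nrow(dat$counts),
        " genes after the low-expression filter")

sf <- size_factors(counts)
expr <- normalize_log2(counts, sf)
write.table(data.frame(sample_id = names(sf), size_factor = sf,
                       row.names = NULL),
            file.path(out, "size_factors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (env in setdiff(unique(dat$annotation$environment), "YPD")) {
  de <- call_de(expr, dat$annotation, env, cutoff = 0.05)
  write.table(de$table, file.path(out, paste0("de_", env, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%-18s %5d DE genes (padj < 0.05)", env,
                  sum(de$table$is_de)))
}
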