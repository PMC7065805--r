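#!/usr/bin/env Rscript
# For every (kinase, environment) cell, regress the mutant's response
# (fold change vs matched-environment WT) on the wild-type environmental
# response over that environment's DE genes. Slope < 0 = attenuated
# response, > 0 = enhanced, ~0 with many outliers = dysregulated.

suppressPackageStartupMessages(library(kindecomp))

src <- "results/data"
dir.create("results", showWarnings = FALSE)

dat <- read_count_matrix(file.path(src, "counts.tsv"),
                         file.path(src, "annotation.tsv"))
counts <- filter_low_expression(dat$counts)
expr <- normalize_log2(counts, size_factors(counts))
fcm <- fold_changes(expr, dat$annotation, "matched_environment_wt")

de <- list()
for (env in setdiff(unique(dat$annotation$environment), "YPD")) {
  d <- call_de(expr, dat$annotation, env)
  if (!is.null(d$de_genes) && length(d$de_genes$members) >= 10) {
    de[[env]] <- d
  }
}

fits <- slope_fits(de, fcm)
write.table(fits, "results/slopes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
m <- slope_matrix(fits)
write.table(data.frame(kinase = rownames(m), m, check.names = FALSE),
            "results/slope_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ok <- fits[fits$status == "ok", ]
message(nrow(ok), " fitted cells, ", sum(fits$status == "missing_sample"),
        " missing cells")
strongest <- ok[order(ok$slope), ][1:5, c("kinase", "environment", "slope")]
message("strongest attenuators (most negative slopes):")
print(strongest, row.names = FALSE)
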