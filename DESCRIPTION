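Package: kindecomp
Title: Additive Decomposition of Kinase-by-Environment Perturbation Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping kinase-environment epistasis from perturbation
    RNA-seq designs in which a panel of analog-sensitive kinase mutants is
    profiled across a battery of environmental conditions. Implements
    median-of-ratios count normalization, fold-change computation against a
    wild-type baseline, per-environment differential expression, slope-based
    quantification of response attenuation, the additive per-gene
    environment-plus-kinase log-expression model with residual z-scoring and
    interaction calling, hypergeometric gene-set and promoter motif
    enrichment with kinase-to-transcription-factor network assembly, and
    environmental stress response (iESR/rESR) signature analysis. Ships a
    synthetic-data generator that emulates the full study design (28 kinase
    strains, 10 environments, replicate structure, missing cells, planted
    interactions and promoter motifs) with known ground truth for every
    downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
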