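# kindecomp

Mapping kinase–environment epistasis from perturbation transcriptomes.

The package targets a common design in stress-signaling biology: a panel
of analog-sensitive (AS) kinase mutants — here 28 strains plus wild type —
is chemically inhibited and exposed to one of 10 environmental conditions,
and each sample's transcriptome is measured once (wild type in
quadruplicate). `kindecomp` provides the complete analysis over such a
gene × sample count matrix, together with a ground-truth synthetic-data
generator that emulates the design end to end, so every statistical claim
the pipeline makes can be tested against planted truth.

## The model

For gene $g$ in environment $i$ with kinase $j$ inhibited, the log2 fold
change against wild type in rich media is modeled additively:

$$\Delta e_{g,ij} = c_{g,i} + k_{g,j}, \qquad c_{g,\mathrm{YPD}} = 0,\; k_{g,\mathrm{WT}} = 0,$$

where $c$ is the environment effect (mean wild-type response) and $k$ the
kinase-inhibition effect (mutant vs wild type in rich media). Residuals
pooled over all genes and samples are standardized against a single global
$\sigma$; cells with $|z| > 2.5$ are candidate kinase × environment
interactions — the transcriptional analogue of epistasis. Around this core
the package implements:

* median-of-ratios normalization and `log2(count/sf + 1)` expression
  (`size_factors()`, `normalize_log2()`), fold changes against either the
  global or the matched-environment wild-type baseline (`fold_changes()`);
* per-environment differential expression from wild-type replicates
  (Welch *t*, own BH step-up; `call_de()`, `benjamini_hochberg()`);
* per-(kinase, environment) response slopes over DE genes — attenuation
  (< 0) vs enhancement (> 0) of the wild-type response (`fit_slope()`,
  `slope_fits()`, `slope_matrix()`);
* the additive decomposition itself with two estimators (reference
  plug-in, joint OLS), fit-quality and residual-normality diagnostics and
  interaction calling (`fit_additive()`, `r2_distribution()`,
  `residual_zscores()`, `qq_normal()`, `call_interactions()`);
* hypergeometric gene-set enrichment, promoter PWM scanning and motif
  enrichment, and kinase → TF network assembly
  (`hypergeometric_enrichment()`, `scan_pwm()`, `motif_enrichment()`,
  `build_kinase_tf_network()`);
* environmental stress response (iESR/rESR) signature distributions,
  regulon response tests, set-level measured-vs-predicted diagnostics and
  gene clustering (`esr_distributions()`, `geneset_response_test()`,
  `geneset_residual_scatter()`, `cluster_genes()`);
* the synthetic study with full ground truth (`sim_config()`,
  `generate_truth()`, `simulate_counts()`, `generate_promoters()`,
  `generate_annotation_sets()`) and file-based orchestration
  (`run_simulate()`, `run_all()`).

Formats: count/annotation/effect tables as TSV, gene sets as GMT, motifs
as JASPAR-style text PFMs, promoters as FASTA.

## Worked example

Simulate a 1000-gene study under the full 301-sample design, decompose
it, and call interactions:

```r
library(kindecomp)

cfg   <- sim_config(n_genes = 1000, seed = 7, n_iesr = 60, n_resr = 60)
truth <- generate_truth(cfg)
sim   <- simulate_counts(truth, cfg)

counts <- filter_low_expression(sim$counts)
expr   <- normalize_log2(counts, size_factors(counts))
fc     <- fold_changes(expr, sim$annotation, "global_wt_ypd")
fit    <- fit_additive(fc, "reference_plugin")
fit
#> <additive_fit> 1000 genes x 301 samples (reference_plugin); mean R2 = 0.731, global sigma = 0.3667

calls <- call_interactions(fit, threshold = 2.5)
head(calls, 3)
#>        gene kinase environment  residual         z sign
#> 2041 G00545   Ygk3        NaCl -3.789265 -10.33878   -1
#> 3957 G00802   Ypk3   menadione -3.669104 -10.01105   -1
#> 4312 G00085   Ssn3   menadione  3.418087   9.31853    1
```

The additive model explains ~73% of per-gene variance on average
(`r2_distribution(fit)$mean`), and the strongest calls are the planted
interactions: here 99.6% of the planted (gene, kinase, environment)
triples are recovered,

```r
planted <- with(truth$interaction_effects, paste(gene, kinase, environment))
mean(planted %in% with(calls, paste(gene, kinase, environment)))
#> [1] 0.9957082
```

## The analysis workflow

`analysis/` holds the numbered drivers that reproduce the full study on a
2000-gene simulated dataset (fixed seed), writing tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | generate the data bundle (counts, annotation, truth, promoters, PFMs, GMTs) |
| `02_preprocess_de.R` | normalization and per-environment DE calls |
| `03_slopes.R` | response-attenuation slopes for every (kinase, environment) cell |
| `04_decompose.R` | the additive fit, R² distribution, residual diagnostics, interaction calls |
| `05_enrichment.R` | gene-set and promoter-motif enrichment, kinase→TF network |
| `06_signatures.R` | iESR/rESR distributions, regulon probe, set-level diagnostics, clustering |

Run them in order from the repository root
(`Rscript analysis/01_simulate.R`, ...). In the shipped configuration the
run reports, among other things, a mean per-gene R² of 0.741, ~700–760 DE
genes per stress environment, the master-kinase signature (Tpk123: iESR
median +1.50, rESR −1.46; its antagonist Pbs2: −1.47/+1.47; all other
strains ≈ 0), and Pbs2 as the strongest slope attenuator across stresses.

## Documentation

The methods vignette
(`vignettes/kinase-environment-decomposition.Rmd`) describes the model
and its assumptions, the generator's calibration, the estimators'
operating characteristics (including the known variance-propagation
effects of reference-based estimation), and all numerical conventions.
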