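---
title: "Additive decomposition of kinase-by-environment perturbation transcriptomes"
author: "kindecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive decomposition of kinase-by-environment perturbation transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

A perturbation RNA-seq design crosses a panel of analog-sensitive (AS)
kinase strains with a battery of environmental conditions: every strain is
chemically inhibited and exposed to one environment, and its transcriptome
is compared to wild type. The scientific question is epistatic: which
kinases participate in which environmental responses, beyond what each
perturbation does on its own?

`kindecomp` answers this with a deliberately simple null model. Let
$\Delta e_{g,ij}$ be the log2 fold change of gene $g$ in environment $i$
with kinase $j$ inhibited, relative to wild type in the baseline rich-media
environment. The model assumes the two perturbations act independently and
additively on log expression:

$$\Delta e_{g,ij} = c_{g,i} + k_{g,j},$$

with the treatment-coding constraints $c_{g,\mathrm{baseline}} = 0$ and
$k_{g,\mathrm{WT}} = 0$. Everything interesting lives in the residuals:
where a measurement departs strongly from $c_{g,i} + k_{g,j}$, the kinase
and the environment interact for that gene, in the same spirit as
genetic-interaction (epistasis) analysis.

## Two estimators

* **Reference plug-in** (default): $c_{g,i}$ is the mean wild-type fold
  change in environment $i$; $k_{g,j}$ is the fold change of strain $j$ in
  the baseline environment. This is the construction that reference-based
  designs describe directly, and it is *local*: removing one kinase's
  samples cannot change another kinase's estimate.
* **Joint OLS**: per gene, the two-factor no-interaction least-squares fit
  over all samples, tolerant of missing cells. On a complete, balanced,
  noise-free additive design the two coincide exactly (this is a tested
  invariant).

The plug-in is the default because it matches the reference-based
construction exactly; joint OLS is exposed as the alternative reading and
used where a homogeneous residual variance matters (see *Operating
characteristics* below).

## Residual standardization and interaction calling

Residuals of all genes and samples are pooled and standardized against one
global scale $\sigma$ (SD by default, $1.4826\cdot\mathrm{MAD}$ as a robust
alternative). A per-gene scale is deliberately not offered: the calling
statistic is defined against the global pool, and silently switching to
per-gene scales would change what "$2.5\sigma$" means. For calling, the
residuals of a (gene, kinase, environment) cell are first averaged over
replicates; every cell with $|z| > 2.5$ (strictly) is reported, excluding
the (WT, baseline) cell, sorted by $|z|$ with ties broken by gene id.

Diagnostics mirror the calling logic: a normal QQ summary of the pooled
z-scores (plotting positions $(i - 0.5)/n$, with the fraction of points
inside a declared band of $x = y$), and the correlation of $|z|$ with mean
expression (interaction calls should not be an expression-level artifact).

# The synthetic study

The generator (`sim_config()`, `generate_truth()`, `simulate_counts()`)
emulates the design the analysis targets: 28 kinase strains plus wild
type, 10 environments (rich-media baseline, synthetic media, and eight
stresses), 4 wild-type replicates per environment, a single mutant
replicate per cell, and 19 missing mutant cells, reproducing the 301-sample
bookkeeping. The missing-cell set is fixed by an internal seed (it is part
of the design, not of a stochastic draw) and always contains the PKA
triple mutant under glucose depletion; which other cells are missing is
configurable because the original design does not enumerate them.

Per gene, expected expression is
$2^{b_g + c_{g,i} + k_{g,j} + \delta_{g,ij} + \varepsilon}$ with
$\varepsilon \sim N(0, \texttt{noise\_sd\_log2}^2)$, scaled by a per-sample
library factor; counts are negative binomial with per-gene dispersion
$\alpha_g$ (variance $\mu + \alpha\mu^2$). `count_model = "deterministic"`
rounds the expectation instead, leaving the Gaussian log-scale term as the
only noise — the profile used for residual-normality calibration runs.

Structure planted with known ground truth, so every downstream stage has
an oracle:

* sparse additive effects: each environment moves a fraction of genes
  (default 0.35) with $N(0, 1.5^2)$ log2 effects; each kinase moves fewer
  genes (0.1) with $N(0, 1.2^2)$ effects;
* coordinated ESR modules: iESR genes induced in every stress, rESR genes
  repressed, with a master kinase (PKA-like, `Tpk123`) whose inhibition
  de-represses the iESR and represses the rESR, and an antagonist
  (`Pbs2`) with the opposite coupling;
* sparse interactions $\delta_{g,ij}$ at density 0.002 on eligible cells,
  $|\delta| = 2$ log2;
* promoter motifs: for each planted TF module, one consensus instance of
  the TF's PWM embedded at a random position and strand in each target
  promoter (a PWM-sampled instance would routinely miss a
  0.8-of-maximum score threshold — one non-consensus base costs more than
  the allowed slack — so consensus planting is what makes the detection
  oracle sharp);
* GO-style annotation sets, a controlled fraction biased toward the
  planted interaction genes.

## Calibration of the defaults

The noise defaults were set once, against the observable scale of the
emulated study: with `noise_sd_log2 = 0.12`, dispersions log-uniform in
$[0.002, 0.05]$ (deep sequencing), baseline log2 expression $N(8, 1.5^2)$
and the effect mixtures above, the per-gene additive model explains on
average $\approx 0.74$ of variance (`r2_distribution()`), the fit-quality
scale reported for the real dataset. They were not revisited afterwards.

## What the generator does not emulate

Real data have correlated gene modules beyond the ESR, batch structure,
length/GC biases, and effect distributions with heavier tails than a
Gaussian mixture; fold-change normalization here is `log2(count/sf + 1)`
rather than a variance-stabilizing transform fitted to the mean-dispersion
trend. Passing tests therefore demonstrate correctness of the machinery
and its operating characteristics under the stated generative model — not
that the biological conclusions of any particular real dataset are
reproduced.

# Operating characteristics worth knowing

**Residual normality.** Under the Gaussian-noise profile the pooled
$|z| \le 2.5$ fraction is $\approx 98.1\%$, slightly below the ideal
$2\Phi(2.5) - 1 = 98.76\%$. The gap is structural, not a bug: plug-in
residuals are a variance mixture — mutant stress cells carry the noise of
four measurements ($\mathrm{Var} \approx 2.5\sigma^2$ at 4 WT replicates
and 1 mutant replicate), wild-type cells $0.75\sigma^2$, and mutant
baseline cells exactly 0 — so a single global $\sigma$ over-covers some
classes and under-covers others. Under the default NB count model the
fraction drops further ($\approx 97.6\%$) because per-gene dispersions add
a scale mixture across genes.

**False-positive calls.** For the same reason, the closed-form call rate
$2(1 - \Phi(2.5)) = 1.24\%$ holds exactly only for an i.i.d. Gaussian
residual field (a tested invariant of `call_interactions()`). Through the
plug-in estimator the empirical mutant-cell rate is $\approx 2.4\%$; joint
OLS gives $\approx 1.1\%$ (leverage deflation). Users who need calibrated
false-positive control should use `estimator = "joint_ols"` or treat the
2.5$\sigma$ list as a candidate ranking, which is how it is used here.

**Kinase-effect recovery.** With one mutant replicate, $k_{g,j}$ rests on
a single baseline sample: its error is
$\sigma\sqrt{1 + 1/R}$ ($R$ = WT replicates), about 0.23 log2 at the
defaults. Against a realistic per-gene kinase-effect spread
($\approx 0.4$ log2) this caps the median per-gene truth correlation near
0.85; environment effects, averaged over four replicates, recover at
$\approx 0.99$. This asymmetry is a property of the single-replicate
design itself, worth keeping in mind when interpreting $k$ heatmaps.

# Choices in the surrounding machinery

* **Normalization**: median-of-ratios size factors (computed over genes
  positive in all samples, median with the midpoint convention, rescaled
  to geometric mean 1 — verified against the DESeq2 implementation), then
  `log2(count/sf + pseudocount)` with pseudocount 1.
* **Differential expression**: per-gene Welch $t$ on log2 expression of
  WT replicates (environment vs baseline), BH adjustment, `padj < 0.05`,
  no fold-change cutoff. Genes with zero variance in both groups get
  $p = 1$ (conservative). A count-model Wald test is deliberately out of
  scope; at 4-vs-4 replicates on the log scale the Welch test is a
  standard approximation.
* **BH**: own step-up implementation (monotone enforcement, capped at 1),
  cross-checked against `p.adjust`; order-invariant, NAs propagate.
* **Slopes**: unweighted OLS with intercept of mutant fold change
  (vs matched-environment WT) on the WT response over the environment's
  DE genes; the intercept absorbs strain-level basal shifts. Outliers are
  counted at internally studentized residuals $|r_i| > 2.5$; raw slopes
  are reported without attenuation/enhancement thresholds.
* **PFM handling**: JASPAR text parsing with pseudocount 0.5 by default
  (keeps log-odds finite on zero counts). Motif scanning scores both
  strands with log2-odds against the empirical promoter base composition
  (0-order background); a gene is a hit at $\ge$ `fraction` of the PWM's
  maximum achievable score (default 0.8); `N` bases score 0; promoters
  shorter than the motif are flagged non-hits; degenerate PWMs whose
  maximum score is $\le 0$ produce no hits. De novo motif discovery is
  intentionally replaced by known-motif scanning + hypergeometric
  enrichment: it is fully testable against planted truth and ends, as the
  original analysis does, in a list of database TFs.
* **Enrichment**: upper-tail hypergeometric with BH per query (across
  annotation sets) or per call group (across PWMs); groups under 5 genes
  are skipped (hypergeometric power floor). Network edges are
  enrichments below the adjusted-p cutoff, split per focus environment
  plus a pooled remainder.
* **Signatures**: the regulon response test is a two-factor
  (strain $\times$ gene) fixed-effects analysis per kinase vs WT with BH
  across kinases — the factors and correction are explicit because
  "two-way ANOVA" alone underdetermines them. Set-level
  measured-vs-predicted uses $z = \bar r \sqrt{|S|} / \sigma$ (averaging
  $|S|$ residuals tightens the null by $\sqrt{|S|}$). Clustering is
  1 − Pearson distance with average linkage, deterministic given input
  order.
* **Gene identifiers** are opaque case-sensitive strings throughout; any
  systematic/common-name mapping is the caller's responsibility.

# Problem sizes used by the tests

The test suite exercises the full 301-sample design at 40–6000 genes:
structural and oracle tests run at tens to hundreds of genes; operating
characteristics (recovery, sensitivity, ESR sign pattern, TF-edge
recovery) use 250–400 genes over 20 seeds; the residual-normality check
runs the full 6000-gene design once. The bundled analysis scripts use
2000 genes with a fixed seed. These sizes were chosen to make every
distributional claim measurable with comfortable Monte-Carlo margins.

# Known limitations

* The additive model is fit per gene with no shrinkage; genes with little
  signal have noisy effect estimates and can show negative $R^2$ under
  the plug-in (allowed; $R^2 \le 1$ is the invariant).
* One global $\sigma$ is a modeling commitment, not an estimate of
  per-cell uncertainty; see *Operating characteristics*.
* The motif stage tests membership of known motifs only; it cannot find
  novel motifs and inherits the planted-motif idealizations above.
* The generator's missing-cell pattern is one fixed draw; analyses that
  depend on *which* cells are missing should set `missing_cells`
  explicitly.
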