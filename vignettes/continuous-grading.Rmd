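---
title: "Continuous methylation-based grading: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous methylation-based grading: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgcgrader)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the parameters that matter,
what the synthetic cohort does and does not emulate, and the design
choices made where the design was genuinely open.

## The continuous grading coefficient

Methylation classifiers for CNS tumours output calibrated class
probabilities. For IDH-mutant astrocytoma, the two relevant classes are a
low-grade (`A_IDH_LG`) and a high-grade (`A_IDH_HG`) methylation class.
The continuous grading coefficient is their log-odds,

$$\mathrm{CGC} = \ln\frac{\mathrm{cal}_{HG}}{\mathrm{cal}_{LG}},$$

computed by `compute_cgc()`. Calibrated scores of exactly 0 or 1 occur in
practice when the classifier saturates; the raw log-ratio is then
undefined, so both scores are clamped into `[eps, 1 - eps]` with
`eps = 1e-6` before the ratio. The clamp bounds the CGC at about ±13.8,
and the coefficient is exactly antisymmetric under swapping the two
classes. Samples assigned to other classifier classes (e.g. the
oligodendroglioma classes) are not graded; the score columns pass through
the reader untouched so they can be inspected.

## Cut-point derivation

The published subgroup boundaries are low < −4.5 and high > +4.5, with
both boundaries belonging to the medium interval; `cgc_cutoffs()` ships
them with provenance `"published-default"` so re-derived values never
silently replace them.

The derivation procedure itself is specified only as "the rate of change
of the calibrated high-grade score per unit CGC", with the medium
subgroup comprising 95% of the total cumulative rate. Our reconstruction
in `derive_cutoffs()`:

1. fit a monotone non-decreasing curve $f(\mathrm{cgc}) \approx
   \mathrm{cal}_{HG}$ by isotonic regression (replicated abscissae are
   averaged first so the fit is single-valued);
2. interpolate $f$ piecewise-linearly onto a uniform grid
   (`grid_size = 1001`);
3. because the integral of the rate $f'$ is $f$ itself, the normalised
   cumulative rate is $F(x) = (f(x) - f_{\min})/(f_{\max} - f_{\min})$;
4. the low cut is the smallest grid point with $F \ge (1-m)/2$ and the
   high cut the smallest with $F \ge 1-(1-m)/2$, for central mass
   $m = 0.95$.

The symmetric split (2.5% per tail) is the only symmetric reading of "95%
of the total cumulative rate"; both $m$ and the grid size are exposed. On
a noise-free logistic calibration curve, $F$ is the logistic itself and
the cuts land at $\pm\mathrm{logit}(0.975) \approx \pm 3.66$ — the
closed form used by the tests. A flat calibration curve has zero total
rate and is rejected as degenerate.

```{r cutpoints}
gen <- generate_calibrated_scores(500, seed = 1)
cgc <- compute_cgc(gen$scores)
derive_cutoffs(cgc$cgc, gen$scores$A_IDH_HG)
```

## Differential methylation

Beta values (methylated intensity fraction) are transformed to M-values
$M = \log_2(\beta/(1-\beta))$, which are approximately homoscedastic;
probes on sex chromosomes and probes without a gene annotation are
removed beforehand (`filter_probes()`). `fit_dmp()` then fits, per probe,
ordinary least squares of $M$ on an intercept plus the CGC (optional
extra covariates are supported — the original model's covariates are not
stated, so the default is the CGC alone).

Residual variances are moderated by empirical Bayes: on the log scale,
sample variances around their expected value follow a known
distribution, so the prior degrees of freedom $d_0$ are obtained by
trigamma inversion of the excess variance of log residual variances and
the prior variance $s_0^2$ by matching the mean. Posterior variances
$(d_0 s_0^2 + d s^2)/(d_0 + d)$ give the moderated $t$ with $d + d_0$
degrees of freedom. When the log-variances show no excess spread the
prior df is infinite and the fit reduces to a pooled-variance t; forcing
`prior_df = 0` recovers the ordinary per-probe t — both limits are
tested, and the default estimate is cross-checked against an independent
moderated-regression implementation in the test suite.

"LFC" for a continuous covariate is the regression slope per CGC unit
(the convention of moderated-regression software); the significance rule
is |LFC| > 0.5 and BH FDR < 0.01. Zero-variance probes are flagged
untestable (NA p) and excluded from the FDR family. Context enrichment
(`context_enrichment()`) compares hyper- vs hypomethylated significant
probes across CpG-context classes (island / shores / shelves / open sea)
with two-sided Fisher exact tests, reporting the context distribution of
all tested probes as the genome-wide reference.

Gene-level methylation (`aggregate_gene_m()`) is the median M over all
probes annotated to a gene (semicolon-separated annotations contribute
the probe to every listed gene once). The hypermethylation signature
(`methylation_signature()`) returns both the per-sample median M of a
probe set and the PC1 of the per-probe standardised submatrix, with the
PC1 sign oriented to correlate positively with the median so that risk
groups ("hypermethylation phenotype" = oriented PC1 > 0) are reproducible
across runs.

## Copy-number analysis

Per-bin log2 intensities over a fixed 50-kb grid are labelled
HD ≤ −0.415 < loss ≤ −0.10 < neutral < 0.10 ≤ gain < 0.35 ≤ amp, with the
deeper call taking precedence. CNV load is the summed width of all
non-neutral bins in Mb, "high" strictly above 350 Mb. The association
scan compares the CGC of event carriers versus non-carriers per bin. The
comparison is an unpaired two-group one, so the Mann–Whitney rank-sum
test is the applicable rank test (exact for small untied groups, normal
approximation with tie correction otherwise). Bins where either group has
fewer than `min_group = 3` samples are untestable and excluded from the
BH family — the sparsity rule is our choice, as the original analysis is
silent on it. Results are signed by convention: log10(p) for
losses, −log10(p) for gains.

## Expression analysis

Genes with mean raw count below 3, and genes whose type is neither
protein-coding nor lncRNA, are removed. Normalisation uses
median-of-ratios size factors followed by `log2(count/sf + 1)`. This
started-log transform approximates a variance-stabilising transform
without a fitted dispersion trend; the downstream uses (correlation,
PCA, signature scores) depend only on per-gene standardised values and
are robust to the exact stabilising curve. This divergence from a
dispersion-trend VST is deliberate and documented here.

`fit_dgr()` fits a per-gene negative-binomial log-linear model with the
CGC as continuous condition and log size factors as offset, gene-wise ML
dispersion (no shrinkage toward a trend — a documented divergence from
shrinkage-based tools), and a Wald z on the log2 scale with two-sided
normal p and BH FDR. Non-convergent genes are flagged with NA statistics.
In the dispersion → 0 limit the slope agrees with Poisson regression.

Recursive correlation clustering (`recursive_cluster()`): the gene–gene
Pearson correlation matrix is itself correlated column-wise
("correlation of correlation"), which sharpens block structure; Ward
linkage on 1 − corr-of-corr is cut at the k (from 2–10) maximising mean
silhouette width, and clusters of 50 genes or fewer are excluded. The
original tool's recursion depth is not described; one corr-of-corr pass
is the default and the depth, linkage and k-range are exposed. Module
labels are deterministic: C0 is the surviving module with most negative
mean LFC, the rest are numbered by descending size. Signature scores are
oriented PC1s of per-gene z-scored module submatrices, with the sign
anchored to the mean module expression — without the anchor, PCA signs
are arbitrary and risk groups would not be reproducible.

For methylation/expression concordance, per-gene z-statistics
(slope / SE from each analysis) are inner-joined and summarised by
Spearman correlation. Top-variable-feature PCA (`pca_top_features()`)
ranks features by variance (on the M scale for methylation — the scale
choice is exposed, as the original is silent), keeps the top n, and can
report the Spearman correlation of any PC with the CGC.

## Single-nucleus enrichment scores

For a gene set G, all genes are ranked by mean expression across nuclei
and split into 30 near-equal rank bins (ties broken by gene id, so bins
are stable); for every query gene, 100 control genes are drawn from its
bin — without replacement when the bin is large enough, with replacement
otherwise, never including the query gene itself — forming a reference
multiset R with |R| = 100·|G|. The score of a nucleus is mean(G) −
mean(R). Draws are seeded per scorer, scores are invariant to adding a
per-nucleus constant, and the expected score under exchangeable
expression is zero.

## Survival

Kaplan–Meier estimation, log-rank tests and Cox proportional-hazards
models wrap the standard survival machinery with Efron tie handling
(exposed) and model-level likelihood-ratio tests; medians that are never
reached are reported as a distinct "not reached" state, never as a
number. Monotone likelihoods (complete separation) are raised as errors
naming the covariate. Risk groups from signature scores follow the sign
rule: strictly positive is high-risk; an exact zero is low-risk (the
boundary choice is arbitrary and documented). The histology model
regresses the CGC on all scored features jointly by OLS with
per-coefficient t-tests, erroring on rank-deficient designs with the
collinear columns named.

## The synthetic cohort

`generate_cohort()` emulates the statistical structure the analysis
assumes; it is the package's test bed, not a biological simulator.

* **Latent gradient.** Malignancy is a two-component Gaussian mixture
  (modes ±`malignancy_spread`, unit SD), so low- and high-grade modes are
  both populated. The calibrated high-grade score is a logistic function
  of the latent value with steepness `calibration_slope = 2`: the
  calibrated curve saturates realistically while the CGC (≈ ±9 at the
  defaults) stays inside the linear range of the clamped log-odds
  transform, so the CGC is a faithful linear readout of the gradient.
  The default calibration is the deterministic logistic map;
  `calibration_noise_sd` adds logit-scale calibration error when
  robustness to a noisy readout is being studied. All planted effect
  sizes are expressed per CGC unit.
* **Methylation.** 8% of probes carry a planted slope: 99% of them
  hypomethylate (−0.8 M-units per CGC unit) and sit in the open sea, 1%
  hypermethylate on CpG islands — mirroring global demethylation with
  focal island hypermethylation. Hypermethylated probes are annotated to
  C2 module genes so the methylation/expression concordance has shared
  signal. Baseline M-values follow context (unmethylated islands,
  methylated open sea); betas are inverse-logit M, hence strictly in
  (0, 1).
* **Expression.** NB counts (dispersion 0.1) with four planted modules
  sized 149/175/176/97 (C0 down, C1–C3 up, slopes −0.7 to +0.9 log2 per
  CGC unit). Each module also shares a latent co-regulation factor
  orthogonalised against the gradient (`module_factor_sd = 1.5` log2
  units). The orthogonalisation keeps the planted per-CGC-unit slopes
  identifiable, and the factor magnitude keeps the counts close enough
  to the NB sampling model that Wald standard errors stay calibrated;
  stronger factors make the modules more cleanly separable by
  correlation clustering but invalidate the NB model. A consequence of
  the default: on full-cohort data the silhouette-chosen k typically
  merges the three up-regulated modules, whose mutual correlation
  through the shared gradient dominates; clean four-module recovery is
  demonstrated on constructed block-correlation data, which isolates
  what the clustering algorithm itself does.
* **CNV.** Gaussian bin noise (SD 0.08) with sporadic
  malignancy-independent gain/loss segments (a tenth of them deep enough
  to cross the amp/HD thresholds, providing null-associated background
  events) plus two planted focal events whose carrier probability rises
  with the gradient: an HD on chr9 and an amplification on chr12.
* **Survival.** Exponential event times with log hazard increasing by
  ln 2 per CGC subgroup step and independent exponential censoring whose
  rate is solved (not approximated) to hit the 40% target censoring
  fraction exactly in expectation.
* **Single nucleus.** Five labelled populations; the cycling-tumour
  population over-expresses the C1 genes by 1.5 units.

What the generator does **not** emulate: genome-wide probe maps and
probe-density structure, segmentation/linkage realism in CNV noise,
mixture-of-cell-types purity effects in bulk expression, doublets or
ambient RNA in the single-nucleus data, and informative censoring.
Passing tests therefore demonstrate the correctness and calibration of
the algorithms under the assumed generative structure, not robustness to
the full messiness of patient data.

## Numerical choices and degenerate inputs

* Calibrated scores clamped at 1e-6 before the log-ratio; beta values at
  1e-6 before the logit.
* Isotonic fit aggregates replicated abscissae by mean; interpolation is
  linear with constant extrapolation at the range ends; a flat curve is a
  hard error.
* Trigamma inversion by Newton iteration (50 iterations, relative
  tolerance 1e-8); non-positive excess variance yields an infinite prior
  df (pooled variance).
* Zero-variance features: NA statistics, excluded from FDR families;
  constant signature submatrices are hard errors ("zero variance").
* Rank tests: exact p for small untied groups, normal approximation with
  tie correction otherwise (the exact/approximate switch follows the
  standard implementation and is verified against brute-force
  enumeration for all group sizes up to 6).
* Subgroup boundaries are inclusive to medium; risk-group zero scores are
  low-risk.
* Cox fits flag monotone likelihood by the emitted infinite-coefficient
  diagnostic plus an SE-to-coefficient ratio guard.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen so that each statistical
guarantee is measurable well above its Monte Carlo noise floor: null
error control at 5,000–6,000 features and 120 samples; slope recovery at
50,000 probes / 2,000 genes and 120 samples (≈4,600 planted features, so
the binomial SE of the coverage estimate is ~0.3%); CNV localisation over
50 cohorts of 200 samples × 2,000 bins; hazard-ratio recovery over 100
cohorts of 500 samples; cluster recovery on 570 genes in 5 blocks. These
are the package's own choices of scale.

## Known limitations

* The cut-point reconstruction is one defensible reading of a briefly
  described procedure; the published ±4.5 boundaries are therefore
  shipped as the default and derived values are clearly marked.
* NB dispersion is estimated per gene without shrinkage; at small sample
  sizes per-gene Wald tests are slightly anti-conservative compared to
  shrinkage-based pipelines.
* The started-log normalisation is not a dispersion-trend VST; absolute
  normalised values differ from such tools although rank- and
  correlation-based downstream results are insensitive.
* The per-bin CNV scan is unadjusted (no covariates), matching the
  described analysis.
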