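---
title: "Methods and design notes for the clockscape pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the clockscape pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the statistical models behind each pipeline stage, the
choices that were genuinely open when the package was designed, and what the
synthetic cohort generator does and does not emulate. The companion README
shows a worked example; here the emphasis is on *why* each piece looks the
way it does.

## The data model

All assays travel as `omics_matrix` objects: a features × samples numeric
matrix with a declared kind. The kind carries hard range invariants —
methylation beta values in [0, 1], copy-number status in {−2, −1, 0, +1, +2}
— enforced on construction and on every TSV read, with errors that name the
offending cell. Orientation is fixed as features × samples; a transposed
file surfaces as an ID mismatch downstream rather than being guessed at.
`NA`, `NaN` and empty cells all parse as missing, and missingness survives a
write/read round trip. Missing data are handled pairwise-complete inside
correlations, and samples lacking an assay are dropped from that stage only.

Multiple-testing correction is Benjamini–Hochberg throughout, applied
*within each analysis family* — one cohort × one stage (and for drug
screens, one gene's family of drugs) — never pooled across cohorts. This
matches the per-cohort, per-panel way such results are usually presented
and keeps a strong effect in one stage from distorting discovery in
another. The FDR procedure is a deliberate choice, exposed through
`benjamini_hochberg()` and checked in the tests against a brute-force
step-up implementation.

## Pathway activity from RPPA

"Normalization by standard deviation" is implemented as center-and-scale
per protein (mean 0, SD 1 across samples, denominator n − 1): signed sums
across antibodies are meaningless unless every protein is on a common,
centered scale. Zero-variance proteins carry no signal and are dropped with
a warning rather than erroring, since single flat antibodies are common in
real panels.

The pathway activity score is the signed sum of standardized member
abundances (positive regulators minus negative regulators), with missing
members simply omitted. The ten hallmark pathway definitions (TSC/mTOR,
RTK, RAS/MAPK, PI3K/AKT, Hormone ER, Hormone AR, EMT, DNA Damage Response,
Cell Cycle, Apoptosis) ship as an editable TSV following the widely used
pan-cancer RPPA pathway annotation; membership and signs are a data file,
not code, because antibody panels differ between cohorts.

Per-gene activation calls split samples at the gene's median expression.
Ties go to the low group — a deterministic, documented rule used
consistently everywhere a median split occurs. The two groups' PAS values
are compared with a two-sided Mann–Whitney U test (rank-based, robust to
RPPA outliers; Welch's t is available via `test = "welch"`). The reported
`pct_influenced` is the absolute rank-biserial correlation clipped to
[0, 1]: a standardized effect size for how cleanly the split separates the
pathway score. It is an explicit stand-in — no per-patient attribution is
defined by the group comparison, and the number should not be read as "the
fraction of patients in whom the gene drives the pathway".

## Epigenomics

Differential methylation uses the Wilcoxon rank-sum test: beta values are
bounded and typically skewed, so a rank test is the safer default. The
effect is the difference of group means on the beta scale, which is the
quantity practitioners plot. Significance is FDR strictly below the
threshold. Gene-level betas are assumed pre-aggregated (e.g. promoter
means); probe-to-gene mapping is an upstream contract, not something this
package attempts.

The methylation → expression effect is a Spearman correlation across tumor
samples: silencing is a monotone claim, and Spearman is invariant to the
choice of expression transform. Copy-number summaries count the four
categories per gene; a gene is `displayed` only when some category exceeds
the display fraction *strictly* (exactly 5 % of samples does not pass the
default 0.05 threshold).

## Survival

The Kaplan–Meier estimator and the two-group log-rank test are implemented
from first principles (product-limit over distinct event times;
(Σ(O−E))²/ΣV against χ²₁ with the hypergeometric variance, ties handled
exactly). The test suite cross-checks both against the `survival` package
and against an independent risk-set enumeration oracle on exhaustive small
configurations, including tied event times.

Survival significance uses the *raw* per-gene log-rank p-value with no
FDR correction — per-gene survival results for a small fixed panel are
conventionally reported that way, and the panel has only nine members. The
reported direction compares the restricted mean survival of the two KM
curves up to the smaller of the two groups' last follow-up times, and is
reported regardless of significance so that effect direction is never
censored by the significance filter.

Differential expression reads the conventional "|Fold Change| > 1" filter
as |log2 FC| > 1: a raw fold change of one is no change at all, so the
literal reading would be vacuous; the threshold is configurable
(`log2fc_threshold`). Group means get a pseudocount of 10⁻³ RPKM before the
ratio so that all-zero genes produce a defined effect of zero rather than
NaN.

## Drug sensitivity and immune infiltration

Drug–gene association is a Pearson correlation across cell lines,
variance-stabilized with Fisher's Z (z = atanh r) and tested with the
normal approximation z·√(n−3) ~ N(0, 1); the exact t-distribution p-value
is available via `p_method = "t"` and the two agree closely for n ≥ 50
(asserted in the tests). A correlation of exactly ±1 would send z to
infinity; it is reported as an infinite sentinel with p = 0 and a warning
rather than erroring, since it almost always indicates a degenerate input.
Because higher AUC means a less responsive line, positive significant
correlations are labelled "resistance" and negative ones "sensitivity".

The immune signature score — per cell type, the mean of per-gene z-scored
log2(RPKM + 1) over marker genes — is a deliberately transparent stand-in
for full deconvolution methods, which need purity adjustment and reference
profiles well outside this package's scope. The marker lists (six cell
types, canonical lineage markers, disjoint from the clock panel) ship as an
editable TSV, and externally computed infiltration matrices are accepted
through the same matrix contract, which is the recommended route for real
data. A single observed marker is accepted (the score then reduces to that
gene's z-scores); only a cell type with *no* observed marker degrades to a
missing row.

## Cosinor rhythmicity

Rhythm detection is the canonical minimal choice: a single-component
cosinor at a fixed period (default 24 h, configurable), i.e. ordinary least
squares on intercept, cos(ωt) and sin(ωt). Amplitude and acrophase derive
from the two rhythm coefficients; the acrophase is the peak time of the
fitted cosine, wrapped to [0, period). Significance is the F-test of the
two rhythm terms against the intercept-only model on (2, n − 3) df.
Degenerate designs — fewer than three distinct sampling times modulo the
period — are a hard error ("degenerate sampling"), because the three
coefficients are then unidentifiable. A perfectly flat response returns
amplitude 0 with p = 1 (F = 0), and an exactly noiseless cosine returns
p = 0; both edge cases are resolved by comparing the regression and
residual sums of squares at relative tolerance 10⁻¹², not by trusting
floating-point F ratios. Timestamps are assumed known; estimating phase
from unordered samples is out of scope.

## The synthetic cohort generator

The generator is the package's ground-truth instrument: every effect the
pipeline claims to detect can be planted with a known size, and every
stage's test is a parameter-recovery experiment. Defaults are desk-scale
but realistic in structure: 200 tumor / 50 normal samples, 100 cell lines,
24 time points over 48 h (2 h spacing, two full cycles), a 6-drug screen,
and ~30 % right-censoring.

Mechanisms, in brief:

* **Expression** is log-normal (per-gene log-mean ~ N(log 10, 1), log-SD
  0.5 in tissue, 0.35 across cell lines, where panels are more
  homogeneous). The underlying standard-normal latents are retained so that
  other assays can be coupled to expression by correlation.
* **Correlation targets are planted through a Gaussian copula**: a latent
  correlation r = 2·sin(πρ/6) yields Spearman ρ for bivariate normal
  latents, and rank-preserving marginal transforms (exp, logistic) leave
  Spearman untouched. Downstream stages use both rank and Pearson
  correlations, and the copula makes the effect visible to both (Pearson
  sees a mildly attenuated value under the log-normal marginal).
* **Methylation** is logit-normal (logit-scale SD 0.5 around a per-gene
  baseline beta in [0.2, 0.6]). A silenced gene's tumor mean is shifted on
  the beta scale by approximately Δβ (the logit-normal mean is not exactly
  the inverse-logit of its location, but at SD 0.5 the approximation error
  is small relative to the planted shifts) and its methylation latent is
  coupled to the expression latent at the target Spearman ρ.
* **RPPA** proteins are standard normal; for a planted activation, the
  pathway's positive regulators gain `effect_sd` (in protein SD units) in
  samples whose driver-gene expression is above its median — exactly the
  contrast the activation caller tests.
* **Survival** is exponential with baseline median two years, the hazard
  multiplied by the planted hazard ratio for above-median expression.
  Censoring is independent uniform on [0, 4.5 × median event time]; the
  4.5 factor is calibrated analytically so the uniform mechanism yields
  ≈ 30 % censoring for exponential event times (E[e^{−λC}] =
  (1 − e^{−λb})/(λb) ≈ 0.30 at λb ≈ 3.1), a typical fraction for
  TCGA-style overall survival.
* **Time series** are mesor + A·cos(2π(t − acrophase)/24) + N(0, 0.5²).

The same seed reproduces the bundle byte-identically, including its TSV
serialization. What the generator deliberately does **not** emulate: batch
structure, tumor purity, platform-specific noise, probe-level methylation,
dose–response curve shape, or realistic gene–gene correlation networks.
Passing recovery tests therefore demonstrates that the estimators find
effects of the planted size under clean marginals — not that they are
robust to every artifact of real TCGA/TCPA/CTRP data.

## Simulation sizes in the test suite

The deeper simulation tests use sizes chosen so Monte Carlo error is small
against the asserted bounds: 100-seed recovery runs for the activation,
methylation and drug-label calls at the cohort sizes above; 2,000 null
genes (and 2,000 null log-rank replicates) for calibration checks, where a
nominal 5 % test has a standard error of ~0.5 %; 500 replicates for
log-rank power at hazard ratio 2 with 100 + 100 uncensored subjects; 200
replicates for cosinor amplitude recovery at amplitude 1, noise SD 0.5,
24 points over 48 h. Exhaustive oracle comparisons (all event/censor
patterns and group splits for up to six subjects, with and without ties)
cover the survival arithmetic exactly.

## Known limitations

* The activation caller conditions on a median split; graded or non-linear
  dependence of pathway activity on expression is diluted.
* `pct_influenced` is an effect size, not a patient fraction (see above).
* The marker-mean immune score shares markers' ambiguity (e.g. CD8A is
  expressed on other cytotoxic populations); no attempt is made to resolve
  it.
* Single-component cosinor cannot represent non-sinusoidal waveforms;
  genes rhythmic only at harmonics of the configured period will be
  missed.
* No Cox regression or multivariate adjustment; survival analysis is the
  unadjusted two-group comparison by design.
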