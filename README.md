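# clockscape

Multi-omics characterization of the core circadian clock gene panel —
CLOCK, ARNTL (BMAL1), CRY1, CRY2, NR1D1, PER1, PER2, PER3 and RORA — across
tumor cohorts. The package is aimed at computational biologists who want a
tested, reusable version of the analysis battery commonly applied to a gene
panel in TCGA-style data: protein-level pathway activity, promoter
methylation, copy number, survival, drug sensitivity, immune infiltration
and circadian rhythmicity. Real data enter through a plain TSV contract; a
synthetic cohort generator with *planted, recoverable effects* gives every
stage a parameter-recovery test.

## What it computes

**Pathway activity (RPPA).** Proteins are standardized per row
(mean 0, SD 1) and the pathway activity score of pathway *P* in sample *s* is

  PAS(P, s) = Σ_{i ∈ P, sign=+1} x̃_is − Σ_{i ∈ P, sign=−1} x̃_is,

the signed sum over the pathway's positive- and negative-regulator proteins.
For each panel gene, samples are split at the gene's median expression and
each pathway's PAS is compared between the high and low groups
(Mann–Whitney U, BH-corrected over all gene × pathway tests); a significant
positive difference is an "activate" call, a negative one "inhibit".

**Epigenomics.** Tumor-vs-normal differential methylation of gene-level beta
values (Wilcoxon rank-sum, BH FDR < 0.05), Spearman methylation–expression
effects within tumors, and copy-number frequency summaries (heterozygous
−1/+1 vs homozygous −2/+2, displayed only above a strict 5 % threshold).

**Survival.** Median-RPKM split into high/low expression groups, a
first-principles Kaplan–Meier product-limit estimator and two-group
log-rank test (χ² = (Σ(O−E))²/ΣV on 1 df), with direction read off the
restricted mean survival of the two curves.

**Drug sensitivity.** Pearson correlation *r* between transcript level and
drug AUC across cell lines, variance-stabilized as z = atanh(r) (Fisher's
Z); z·√(n−3) is referred to the standard normal. Significant positive
correlations are "resistance" (higher AUC = less responsive), negative ones
"sensitivity".

**Immune infiltration.** A transparent marker-mean z-score signature for six
immune cell types (externally computed infiltration matrices are accepted
through the same matrix contract), correlated with the panel by Spearman.

**Circadian rhythmicity.** Single-component cosinor regression
y = M + β_c·cos(ωt) + β_s·sin(ωt) at a fixed 24 h period, with amplitude
√(β_c² + β_s²), acrophase atan2(β_s, β_c)·period/2π, and an F-test of the
rhythm terms on (2, n−3) df.

**Differential expression.** |log2 FC| > 1 together with BH FDR ≤ 0.05
(Wilcoxon), with a 10⁻³ RPKM pseudocount.

## Worked example

```r
library(clockscape)
cfg <- analysis_config(seed = 42)
bundle <- generate_cohort(cfg, truth = default_truth())

pas   <- compute_pas(normalize_rppa(bundle$rppa), read_pathways())
calls <- call_pathway_effects(bundle$expression, pas, cfg)
subset(calls, direction != "none")
#>    gene pathway direction pas_diff  p_value     fdr pct_influenced n_high n_low
#> 89 RORA     RTK  activate     4.17 2.11e-20 1.9e-18          0.758    100   100

sr <- survival_by_median_split(bundle$expression, bundle$survival, cfg)
subset(sr, significant)
#>    gene logrank_chi2  p_value n_high n_low rmst_high rmst_low  direction significant
#> 2 ARNTL         26.6 2.48e-07    100   100       403      773 low_better        TRUE

fit_cosinor(bundle$timeseries$values["ARNTL", ], bundle$times_hours)
#> Cosinor fit (period 24 h, n = 24)
#>   mesor     5.023
#>   amplitude 1.227
#>   acrophase 6.16 h
#>   R-squared 0.795
#>   p-value   5.88e-08
```

The cohort was generated with `default_truth()`, which plants (among other
effects) a RORA→RTK activation of 0.8 SD, a hazard ratio of 2 on
above-median ARNTL expression, and a 24 h ARNTL rhythm with amplitude 1.2
peaking at 6 h — all three are recovered above: the activation call with a
mean PAS difference of 4.17 standardized units, the survival split with the
high-expression group faring worse (restricted mean survival 403 vs 773
days), and the cosinor fit with amplitude 1.23 and acrophase 6.2 h.

To run the whole pipeline over simulated cohorts from a shell:

```sh
Rscript inst/cli/clockscape.R simulate --seed 1 --out sim/
Rscript inst/cli/clockscape.R run --out results/ \
    --cohort sim/cohort_1 --cohort sim/cohort_2 --cohort sim/cohort_3
```

Each cohort directory gets per-stage TSV tables; a combined long-format
`results.tsv` and a `manifest.yaml` (config + seed, sufficient to re-run
bit-identically) land at the top level.

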