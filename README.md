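# glycopanelr

Quantitative intact-glycopeptide biomarker panel analysis for TMT-labelled
glycoproteomics, built around urinary cohort comparisons such as prostate
cancer (PCa) versus benign prostatic hyperplasia (BPH) — two conditions
that serum PSA stratifies poorly. The package is aimed at glycoproteomics
analysts who have search-engine output (Byonic/MaxQuant-shaped PSM tables
with TMT10 reporter intensities) for four peptide populations — intact
N-glycopeptides, desialylated O-glycopeptides, PNGase F-generated
de-N-glycosylated peptides, and non-modified peptides — and want a tested,
reproducible path from those tables to a validated differential
glycopeptide panel.

## What it computes

**Glycan mass algebra.** Compositions over {HexNAc, Hex, Fuc, NeuAc,
NeuGc} in the `Name(count)` dialect, monoisotopic masses from elemental
composition, oxonium diagnostic ions ([NeuAc+H]⁺ at m/z 292.1027,
[NeuAc+H−H₂O]⁺ at 274.0921; 308.0976/290.0870 for NeuGc), sequon detection
(N-X-S/T/C, X ≠ P), and isobaric collision enumeration. Two identities
matter: Fuc + NeuGc = Hex + NeuAc, and NeuGc − NeuAc = one oxidation
(+15.995 Da), which makes nominal NeuGc assignments in human samples
suspect; `check_diagnostic_ions()` / `reassign_composition()` implement
the spectrum-level validation and mass-conserving correction.

**Quantification.** PIF (> 0.75) and PEP-2D (< 0.001) gates, target-decoy
FDR filtering, summation of redundant PSMs to feature level, log2 +
per-channel median (or mean) normalization, and PRM-style normalized
quantification for targeted confirmation.

**Statistics.** An empirical-Bayes moderated two-group t implemented from
the closed-form machinery: per-feature variances $s_g^2$ with $d_g$ df are
shrunk toward a prior $(d_0, s_0^2)$ estimated by digamma/trigamma moment
matching on $\log s_g^2$,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  \tilde t_g = \frac{\bar y_{g,1} - \bar y_{g,2}}
  {\tilde s_g \sqrt{1/n_1 + 1/n_2}} \sim t_{d_0 + d_g},$$

with Benjamini–Hochberg q-values. PCA with outlier-channel QC, Euclidean
hierarchical clustering, and PLS-DA leave-one-out ROC (rank-sum AUC)
evaluate the panel.

**Panel selection.** The four-gate cascade — q ≤ 0.25 (inclusive), ratio
> 1.3 or < 0.77 (strict), de-N glycosite corroboration, serum-glycoform
whitelist — plus protein-level cross-referencing against non-modified
peptides to flag glyco-specific regulation.

**Synthetic cohorts.** `simulate_cohort()` generates PSM-level tables with
ground truth (baselines, planted fold-changes, 20% CV noise, PSM
redundancy, PIF contamination with ratio compression, an outlier channel,
missingness, decoys, NeuGc mislabels), so the full pipeline is testable
without any data download. A packaged 56-entry reference panel
(`load_table1_fixture()`) provides realistic effect sizes.

## Worked example

```r
library(glycopanelr)

cohort <- simulate_cohort(cohort_config(
  effects = load_table1_fixture(),          # 56 planted PCa/BPH ratios
  n_features = c(intact_N = 1000, desialo_O = 60),
  seed = 42))

res <- run_pipeline(cohort$psm, cohort$design, panel_sizes = c(20, 28, 56))
res
#> Glycoproteomics pipeline run
#>   channels: 9 (removed: 129N)
#>   intact features tested: 950
#>   panel entries: 61
#>   ROC: 20->1.00, 28->1.00, 56->1.00

glance(res$diff$intact_N)
#> # A tibble: 1 × 4
#>   n_features    d0  s0_sq n_q25
#>        <int> <dbl>  <dbl> <int>
#> 1        950  52.6 0.0818    61
```

Reading this output: the generator produced a 5-case vs 5-control TMT10
cohort with one degraded control channel; PCA QC flagged and removed
exactly that channel (`129N`), leaving the 5 vs 4 design. Of 950
quantifiable intact glycopeptides, 61 passed all four panel gates (the 56
planted effects minus a few near the fold-change boundary, plus a
BH-controlled share of nulls). The variance prior (d0 ≈ 53 extra degrees
of freedom) shows how strongly moderation helps at n = 9. Cross-validated
PLS-DA separates the groups perfectly (AUC = 1.0) at panel sizes 20, 28
and 56 — the headline behaviour of the 56-glycopeptide urinary panel.

`autoplot(res$pca)`, `autoplot(res$roc)`, `autoplot(res$diff$intact_N)`
and `plot_heatmap(res$quant$intact_N, res$design)` give the standard
figures; `tidy()`/`glance()` return tibbles; `write_pipeline_results()`
writes tab-separated tables.

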