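---
title: "Methods: from glycopeptide PSMs to a validated biomarker panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from glycopeptide PSMs to a validated biomarker panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopanelr)
```

# The problem

Urinary glycoproteins are an attractive, non-invasively sampled source of
candidate markers for distinguishing prostate cancer (PCa) from benign
prostatic hyperplasia (BPH), two conditions that serum PSA separates poorly.
Measuring *intact* glycopeptides — the peptide with its glycan still
attached — gives site-specific glycan composition information that neither
released-glycan profiling nor deglycosylated-peptide analysis provides.
`glycopanelr` implements the computational arm of a TMT10-multiplexed
quantitative glycoproteomics workflow for this setting: it ingests
search-engine-shaped glycopeptide PSM tables for four peptide populations
(intact N-glycopeptides, desialylated O-glycopeptides, PNGase F-generated
de-N-glycosylated peptides, and non-modified peptides), applies the
identification-quality and quantification filters, computes moderated
differential statistics, and distils a multi-criteria biomarker panel that
is evaluated by cross-validated PLS-DA ROC.

Because no raw cohort data are publicly deposited for this design, the
package ships a first-class synthetic-cohort generator with ground truth;
every downstream stage is exercised and tested end-to-end against it.

# Glycan composition model

Compositions are multisets over five monosaccharides — HexNAc, Hex, Fuc
(deoxyhexose), NeuAc and NeuGc — written in the `Name(count)` dialect, e.g.
`HexNAc(5)Hex(6)Fuc(1)NeuAc(3)`. Masses are monoisotopic residue masses
derived from elemental composition and carried at full precision; printed
three-decimal values elsewhere are display rounding.

Two isobaric identities drive composition mis-assignment and are central to
the validation chemistry:

* `Fuc + NeuGc = Hex + NeuAc` (identical within `1e-5` Da), so e.g.
  `HexNAc(5)Hex(6)Fuc(1)NeuAc(2)NeuGc(1)` has the same mass as
  `HexNAc(5)Hex(7)NeuAc(3)`;
* `NeuGc − NeuAc = +O`, exactly one Met-oxidation mass, so a NeuGc
  assignment can equally be an oxidized peptide carrying NeuAc.

NeuGc is a non-human sialic acid; a nominal NeuGc assignment in human urine
is suspect a priori. `check_diagnostic_ions()` looks for the theoretical
oxonium ions of NeuAc (m/z 292.1027 / 274.0921) and NeuGc (308.0976 /
290.0870) in the HCD spectrum at a 10 ppm tolerance; a NeuGc composition
with NeuAc-only evidence is a flagged conflict, and
`reassign_composition()` applies the mass-conserving rewrite, preferring
the Fuc/NeuGc → Hex/NeuAc exchange (no extra hypothesis) and otherwise
NeuGc → NeuAc plus one peptide oxidation (which requires an oxidizable
residue when the sequence is known). Theoretical ion masses are used for
matching throughout; nominal integer values (292/274, 308/290) appear only
as display. By default either of the two diagnostic ions suffices as
evidence (`require = "either"`); requiring both is available and stricter.

Glycan classes form a total five-way partition used for class-level
comparisons: high-mannose (`HexNAc(2)Hex(>=5)`, no Fuc, no sialic acid) and
complex/hybrid split by terminal features into C/H, C/H+Fuc, C/H+NeuAc and
C/H+Fuc/Sia. "Sialylated" means NeuAc + NeuGc > 0 — the class describes the
terminal feature, not the sialic species. Paucimannosidic/truncated
compositions such as `HexNAc(2)Hex(2)` fold into C/H so that the partition
stays five-way; a dedicated paucimannose bin would be a reasonable
alternative but would change the reporting granularity.

# Quantification model

Reporter-ion quantification follows the standard TMT discipline:

1. **PSM-level quality gates.** Quantification uses only PSMs with
   precursor ion fraction (PIF) strictly above 0.75 — co-isolated
   precursors compress reporter ratios toward 1 — and posterior error
   probability (PEP-2D) strictly below 0.001 for the glycopeptide classes
   (the non-modified class is not PEP-2D scored and is exempt). Both
   comparisons are strict, so boundary values are excluded.
   Target-decoy filtering then keeps the deepest score prefix whose running
   FDR (`#decoys/#targets`) stays within the threshold; at the default of
   0 this keeps targets outscoring the best decoy.
   The PIF gate protects *quantification* only: identification-level
   evidence (the de-N glycosite list used for corroboration) is filtered on
   PEP-2D and FDR but not PIF (`filter_psms(pif_min = NULL)`).
2. **Aggregation.** Features are peptide + modifications + composition;
   charge states are merged and redundant PSMs summed channel-wise, which
   makes aggregation order-independent.
3. **Normalization.** Summed intensities are log2-transformed (zeros are
   missing, not log of zero) and each channel centered at zero. Median
   centering is the default; mean centering is kept as an option since both
   conventions are common for TMT reporter matrices, and the two differ
   under skew. Centering is idempotent and rank-preserving. No imputation
   is performed; features must be quantified in at least 70% of channels to
   enter the statistics.

A PRM-style quantifier (`prm_quantify()`) is included for targeted
confirmation: reporter intensities of a glycopeptide's PSMs inside a closed
retention-time window are summed and normalized to each channel's total
reporter signal over the run, with group differences assessed by a plain
t-test rather than the moderated machinery (targeted data have ample
spectra per analyte and no multiplicity).

# Outlier-sample QC

One sample that behaves globally aberrantly (degraded specimen, labeling
failure) should be removed before group statistics. The pipeline runs PCA
on the **uncentered** log2 matrix and flags samples whose PC1–PC2 distance
from the centroid exceeds `k_mad = 3` times the median distance. The order
matters: per-channel median centering would absorb exactly the global
intensity shift that characterises such a channel, whereas PCA's
feature-wise centering leaves it visible. On the default synthetic cohort
(one control channel shifted by +2 log2 units) exactly one of ten channels
is flagged, leaving the 5-case vs 4-control design the statistics expect.

# Moderated differential statistics

Per feature, group means and the pooled residual variance $s_g^2$ (with
$d_g = n_1 + n_2 - 2$ degrees of freedom) are computed over finite values.
An empirical-Bayes prior $(d_0, s_0^2)$ is estimated by moment matching on
$\log s_g^2$: with $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the
prior degrees of freedom solve
$\psi'(d_0/2) = \overline{(e_g - \bar e)^2\,\tfrac{n}{n-1}} - \overline{\psi'(d_g/2)}$
(via a Newton inversion of the trigamma function), and
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$; a non-positive
right-hand side yields $d_0 = \infty$. The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ gives the moderated
statistic
$\tilde t_g = \Delta\bar y_g \,/\, \tilde s_g \sqrt{1/n_1 + 1/n_2}$
on $d_0 + d_g$ degrees of freedom. Two limits anchor the implementation and
are tested numerically: $d_0 = 0$ recovers the ordinary pooled t, and
$d_0 \to \infty$ the fixed-variance z-like statistic. The test suite also
cross-checks the full fit (prior, t, p) against an independent reference
implementation of the same empirical-Bayes machinery. Trend and robust
variants of the prior fit are deliberately out of scope; the plain moment
estimator is used. p-values become Benjamini–Hochberg q-values
(step-up, permutation-invariant, never below p).

Ratios are reported as $2^{\Delta \text{mean log2}}$ (case/control), with
direction Up/Down by the sign of the contrast.

# Panel selection

The panel cascade intersects four independent predicates:

* `q <= 0.25` — inclusive, so entries printed exactly at the threshold
  pass. The permissive threshold reflects small-cohort reality (n = 5 vs 4
  with high biological variance); the multivariate evaluation below, not
  the q-value alone, carries the discrimination claim.
* ratio strictly greater than 1.3 or strictly less than 0.77.
* **site corroboration**: some de-N-glycosylated peptide of the same
  protein covers an overlapping sequon (N-X-S/T/C, X ≠ P; deamidation
  marks off a sequon are rejected upstream). With protein sequences
  supplied, sites are compared in protein coordinates (handles
  missed-cleavage variants); otherwise matching requires the identical
  stripped peptide.
* **glycoform whitelist**: the composition must be a commonly observed
  human serum glycoform. The curated public resource this concept derives
  from is not redistributable, so the packaged default whitelist is a
  synthetic stand-in (the compositions of the packaged reference panel)
  and should be replaced for real analyses.

Selected entries are annotated with protein-level behaviour from the
non-modified peptide fraction; a `glyco_specific` flag marks entries whose
protein-level average ratio is inside the unaltered band [0.77, 1.3] or
moves opposite to the glycopeptide — evidence that the glycosylation, not
protein abundance, is regulated.

# Panel evaluation

Features are ranked by absolute moderated t (the ranking criterion the
upstream web tooling uses is unstated; PLS-DA VIP ranking is available as a
config switch). For each panel size, a two-component PLS-DA is fitted under
leave-one-out cross-validation — the natural scheme at n = 9 — and the AUC
is computed from held-out predicted class scores by the Mann–Whitney
rank-sum formula with ties counted one half, making it invariant under
monotone transforms of the scores. Heat-map ordering uses agglomerative
clustering on Euclidean distance with average linkage (only the metric is
prescribed by the emulated workflow; linkage is a config switch).
PCA is centering-only by default; unit-variance scaling is available but
off, since log2 reporter intensities share a scale.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of the study design
rather than raw spectra:

* **Design**: 5 case channels (TMT 126–128C) vs 5 control channels
  (129N–131); one control channel carries a +2 log2 global shift and plays
  the outlier (the defect of the real removed sample is unknown; a global
  shift gives unambiguous PC-space separation).
* **Signal**: per-feature baselines are normal on the log2 scale
  (mean 20, sd 1.5 — reporter intensities around 10^6 with realistic
  spread); effects are linear-scale case/control ratios, by default the 56
  reference-panel ratios planted on top of 1,000 null intact features.
* **Noise**: multiplicative per-channel log-normal noise at 20% CV.
* **PSM structure**: Poisson-distributed redundancy (mean 2 PSMs/feature,
  as typical for data-dependent acquisition of glycopeptides), random
  intensity splits that sum back to the feature total, and a 10%
  co-isolation fraction whose PSMs get PIF < 0.75 and reporter ratios
  compressed toward 1 proportionally to (1 − PIF).
* **Nuisance**: decoy PSMs with separably lower scores; a 2% tail of
  targets with poor PEP-2D; 5% feature-wise missingness on the discovery
  classes. Missingness is feature-wise because TMT reporter blocks are
  complete per spectrum. It is *not* applied to the de-N and non-modified
  fractions: in the emulated workflow those are deeply pre-fractionated
  and serve as corroborating evidence, and modeling their dropout would
  conflate identification depth with selection performance.
* **Mislabels**: a configurable number of null features carry a spurious
  NeuGc composition whose true glycoform is the NeuAc isobar, with toy
  spectra exposing the true diagnostic ions.

What the generator does **not** model — and what passing tests therefore do
not show about real data: peptide fragmentation and spectral interference
beyond the PIF summary, retention-time structure, isotope-impurity
cross-talk between TMT channels, correlated biological variation between
glycoforms of one protein, and compositional constraints of real N-glycan
biosynthesis beyond the class rule.

# Numerical and design choices

* Thresholds default to the emulated workflow's printed values (PIF 0.75,
  PEP-2D 0.001, peptide FDR 0, q 0.25, fold-change 1.3/0.77, 10 ppm).
* The q gate is inclusive and the fold-change gates strict, chosen so that
  borderline printed entries (q = 0.25, ratio 0.76) behave as published.
* Collision enumeration searches HexNAc ≤ 9, Hex ≤ 10, Fuc ≤ 3,
  NeuAc ≤ 4, NeuGc ≤ 1 at 10 ppm by default.
* Degenerate inputs: zero reporter intensities are missing; all-NA
  channels and rank-0 PCA inputs error; zero-variance features are flagged
  and excluded from prior fitting; two-sample tests on
  zero-variance groups return a flagged 0/∞ statistic instead of erroring.
* Problem sizes in the shipped tests: the cohort property checks use the
  56 planted effects over 1,000 null intact features (one cohort, cached
  across tests), a 5,000-feature matrix for the null calibration, and
  2,000 features for p-value uniformity; these sizes give stable binomial
  tolerances while keeping a full suite run around a minute.
* Panel sensitivity in the recovery checks is measured among planted
  features present in the quantified matrix: identification dropout
  (missingness, all-PSM contamination) is generator-controlled and says
  nothing about the selection cascade.

# Known limitations

* The moderated model supports exactly two groups; contrast matrices,
  random effects and trend/robust priors are out of scope.
* The whitelist stand-in makes the whitelist gate structurally active but
  not biologically curated.
* PLS-DA significance is not permutation-tested; AUC = 1 at n = 9 is a
  small-cohort statement, not a clinical claim.
* mzML/raw spectral parsing is not included; the package starts from
  tabular PSM exports and two-column/MGF peak lists.

# A minimal run

```{r example, eval = FALSE}
cohort <- simulate_cohort(cohort_config(
  effects = load_table1_fixture(),
  n_features = c(intact_N = 1000, desialo_O = 60),
  seed = 42))

res <- run_pipeline(cohort$psm, cohort$design, panel_sizes = c(20, 28, 56))
res
glance(res$diff$intact_N)
autoplot(res$pca)
autoplot(res$roc)
```
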