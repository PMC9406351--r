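---
title: "Methods: models, parameters and design choices in radskin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in radskin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`radskin` models transcriptome-based biodosimetry in a mouse skin irradiation
design: groups of five animals receive 0, 1, 3, 6 or 20 Gy whole-body X-ray,
skin biopsies are profiled at 2 h and days 4, 7, 21 and 28, and the 20 Gy
(lethal) arm ends at day 7. This vignette documents the statistical models,
the tunable parameters and the decisions taken where the underlying study
left the design open.

## The differential-transcription model

Each (dose, time point) group is contrasted against the 0 Gy control at the
same time point — sham animals are biopsied on the same schedule, so the
time-matched control absorbs serial-biopsy (bystander) and handling effects.
We deliberately do not subtract a separate bystander term; the time-matched
contrast is our operationalization of that correction.

For gene $g$, with group sizes $n_1, n_0$ and pooled variance $s_g^2$ on
$d_g = n_1 + n_0 - 2$ df, the moderated t-statistic shrinks $s_g^2$ toward a
prior $(d_0, s_0^2)$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  t_g = \frac{\widehat{\mathrm{log_2FC}}_g}{\tilde s_g\sqrt{1/n_1 + 1/n_0}}
  \sim t_{d_0 + d_g}\ \text{under } H_0 .$$

The prior is fitted by method of moments on $\log s_g^2$: marginally
$s_g^2 = s_0^2 F(d_g, d_0)$, so
$\mathrm{Var}(\log s_g^2) = \psi_1(d_g/2) + \psi_1(d_0/2)$ identifies $d_0$
through a Newton inversion of the trigamma function, and the mean identifies
$s_0^2$. When the observed variance of $\log s_g^2$ does not exceed
$\psi_1(d_g/2)$, $d_0 = \infty$ (full shrinkage). Zero sample variances are
floored at $10^{-8}$ before taking logs. At $d_0 = 0$ the statistic reduces
exactly to the ordinary pooled two-sample t (a tested property), and the
implementation is cross-checked against an independent empirical-Bayes
implementation in the test suite.

A *significantly differentially transcribed gene* (SDTG) satisfies
BH-adjusted $p < 0.05$ and $|\mathrm{FC}| \ge 2$, where the signed linear
fold change is $2^{\mathrm{log_2FC}}$ for upregulation and
$-2^{|\mathrm{log_2FC}|}$ for downregulation. Two places needed a decision:

* **Adjusted vs raw p.** The methods of the underlying study state both
  "p < 0.05" and "BH-adjusted p < 0.05"; we threshold the adjusted p (the
  explicit statement wins) and expose `use_adjusted = FALSE` for the raw
  mode.
* **FC > 2 vs FC ≥ 2.** We use $\ge$, and apply it with an absolute
  tolerance of $10^{-9}$: group-mean arithmetic leaves $\sim 10^{-16}$
  floating-point dust, and an effect placed exactly on the threshold must
  pass it.

The BH family is one contrast's full gene list; contrasts are analyzed
separately, never pooled. When several probes map to one gene symbol,
`collapse_probes()` keeps the probe with the largest $|t|$.

## Preprocessing

The order is lowess detrending → quantile normalization → PCA outlier
exclusion (the study does not state the order; we fix normalization before
outlier judgment so that outliers are judged on comparable scales).

* `lowess_detrend(span = 0.3)` removes a smooth intensity-dependent trend
  from one sample; the span is the conventional two-color default. The
  *pipeline* default leaves detrending off: the generator emits trend-free
  log-ratio-like values, and detrending trend-free data against the only
  available per-probe covariate (the cross-sample mean) effectively
  gene-centers the matrix and lets quantile normalization distort tail fold
  changes. Detrending is exercised in the tests by injecting known intensity
  trends.
* `quantile_normalize()` maps every sample onto the mean of the cross-sample
  order statistics; ties receive the mean of their tied ranks' reference
  values. It is exactly idempotent (tested).
* `pca_outlier_filter(k_sd = 4)` removes samples whose PC1/PC2 scores deviate
  from their own (dose, time point) group median by more than `k_sd` robust
  SDs. The robust SD is the MAD of the *pooled* within-group deviations: a
  per-group MAD over five replicates is far too unstable to threshold on.
  Judging deviations within groups prevents the dose/time separation itself
  from looking like an artifact. The filter refuses to act when more than
  20% of samples would be lost, and never errors a run for it.

## Set dynamics

Venn partitions are exact set algebra on gene identities. "Unique" means
present in exactly one label's set, "common" means present in all; the full
membership-pattern table is kept for the intermediate blocks, and a
conservation property (blocks tile the union) plus equivalence with an
exhaustive per-gene oracle are tested. Partitions are identity-based: a gene
common to all time points may still flip direction between them, which is
why direction statistics are computed separately per (dose, time point).

Percentages are reported as $100\,\cdot$ count/union, rounded half away from
zero to two decimals (`round_half_up()`), matching how such tables are
conventionally printed. The stationarity index is common/union; the
unique/common ratio divides the first label's unique count by the all-common
count and is flagged `Inf` when nothing is common. Because the two
orientations of that ratio are easy to confuse, `stationarity_stats()`
reports both (`unique_common_ratio`, `common_unique_ratio`) with explicit
names and makes no attempt to privilege one.

Peak detection (`peak_tp_up`) is the arg-max of the upregulated count over
time points, ties broken to the earliest time point. An empty SDTG set at a
time point yields a *missing* percent-up, never zero.

## Dosimetry rules

The study states directional rules but no numeric cutoffs. The defaults sit
midway between the two observed signatures — lethal: ≈90% downregulation in
the first week and ≈59% of the union common to all time points; sublethal:
≈70% upregulation and ≤11% common:

| parameter | default | role |
|---|---|---|
| `lethal_down_fraction_min` | 0.60 | mean early downregulated fraction for the lethal rule |
| `lethal_stationarity_min`  | 0.40 | stationarity index for the lethal rule |
| `sublethal_up_fraction_min`| 0.55 | mean early upregulated fraction for the sublethal rule |
| `panel_fc_min` / `panel_mean_fc_min` | 2 / 3 | marker-panel cell and panel-average FC thresholds |

A lethal call requires both lethal rules to fire; a sublethal call requires
up-dominance *and* low stationarity; everything else is an explicit
indeterminate with a reason. Within the sublethal range the dose class is
ordinal evidence only (peak at 2 h/d4 → low, d7 → mid, later → high;
`sublethal_peak_order()` breaks ties by the unique/common ratio, which falls
with dose) — SDTG counts themselves are non-monotone in dose (1 Gy can
modulate more genes than 3 Gy), so no Gy regression is attempted. The
late-time-point "lethal-like inversion" sometimes seen at the highest
sublethal dose can optionally down-weight a sublethal call
(`late_inversion_downweight`, default off, reported in the evidence text
only): the study does not operationalize it, so neither do we by default.

## The synthetic-data generator

`sim_config_preset()` encodes the study conditions: ~20,000 probes, five
replicates per group, the truncated lethal arm, and a per-dose Venn skeleton
carrying the reported dose-wise union / all-common / time-point-unique SDTG
counts (619/1/…, 411/0/…, 765/4/…, 1038/609/…). Whatever the union holds
beyond the common and unique blocks is split evenly into blocks shared by
consecutive time-point pairs — this makes sublethal responses "roll" through
time while the lethal response stays stationary, without inventing counts the
study did not report. Up-fractions per (dose, time point) are chosen so that
the planted upregulation peak falls at day 4 for 1 and 3 Gy and day 7 for
6 Gy, with the lethal arm at 10% up throughout; effect sizes are uniform on
|log2FC| ∈ [1.5, 4.3] (|FC| ≈ 2.8–20), held constant across a dose's time
points. Five marker genes are planted up in every sublethal early cell and
down in every lethal cell, and three genes up only in sublethal cells.

Noise follows the same hierarchy the moderated t assumes: gene variances are
scaled inverse chi-square with $d_0 = 4$, $s_0^2 = 0.0625$ (log2 scale,
i.e. a typical replicate SD of ≈0.25–0.35), Gaussian noise on top of gene
baselines $\mathcal N(8, 1.5^2)$. Randomness is split per gene by a
counter-based seed derivation, so enlarging `n_genes` never reshuffles
earlier genes (tested). Two-color dye structure, spatial artifacts and
replicate attrition are *not* simulated: the generator emits already
log-ratio-like values, and full $n = 5$ is assumed throughout because the
study does not report per-group attrition. Consequently, passing recovery
tests demonstrate the pipeline's correctness under the stated noise model and
response architecture — not robustness to dye bias, batch structure, or
missing replicates in real arrays.

## Ordination

Sammon mapping minimizes $E = \big(\sum_{i<j} d_{ij}\big)^{-1}
\sum_{i<j} (d_{ij} - D_{ij})^2 / d_{ij}$ by the classical pseudo-Newton
coordinate update with step halving, started from the deterministic
classical-MDS configuration; the per-iteration stress trace is non-increasing
by construction and convergence is declared at a relative stress change below
`tol = 1e-9` or after `max_iter = 500` accepted iterations. Zero input
distances are perturbed by $10^{-12}$ with a warning (the $1/d$ weight is
undefined at zero). The test suite checks exact-embedding, descent,
rigid-motion invariance and agreement with an independent implementation.
For expression input the default distance is Euclidean on the 500
most-variable genes (the study does not state its choice; this is
configurable and not claimed faithful). Uncentered-Pearson distances feed
standard average-linkage agglomeration, exportable as Newick.

## Problem sizes in the test suite

Unit tests run on reduced instances (hundreds of genes, or the preset
architecture scaled proportionally to ~10%); the statistical acceptance
checks run one full-size null array (10,000 genes), one full preset cohort
for sensitivity/FDR, and 50 full preset cohorts (~20,000 genes × 115 samples
each) for call-accuracy and peak-order recovery. These sizes were chosen so
the whole suite completes in a few minutes while keeping every statistical
claim at the scale it is made about.

## Known limitations

* The classifier cutoffs are calibrated to this design's signatures; other
  tissues, doses or platforms will need re-tuning via `dosimetry_rules()`.
* Absolute dose (Gy) estimation is out of scope by design; the dose class is
  ordinal.
* The GEO series-matrix reader parses values and sample headers but does not
  attempt to interpret free-text characteristics; dose/time metadata must be
  mapped by the caller.
* Pathway/enrichment analysis of the SDTG lists is out of scope.
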