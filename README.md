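# radskin

Transcriptome-based radiation biodosimetry from dose-by-time skin expression
profiles.

## The problem

After an accidental or mass-casualty radiation exposure, the absorbed dose is
usually unknown, early symptoms are unspecific, and triage decisions (who
needs aggressive treatment, who will survive with minimal intervention) must
be made quickly. Skin is always exposed and easy to biopsy. In a mouse model,
whole-body X-ray doses of 1, 3 or 6 Gy are survivable while 20 Gy is lethal
within a week, and the skin transcriptome separates these outcomes long before
symptoms do: the lethal response is large, *stationary* (the same genes stay
modulated at every time point) and dominated by downregulation, while
sublethal responses are smaller, dynamic, dominated by upregulation, and their
response peak shifts to later time points as the dose increases.

`radskin` implements that analysis as a reusable, tested pipeline for
probes × samples log2 expression matrices with (dose, time point, replicate)
metadata, plus a synthetic-data generator that emulates the study design
(doses 0/1/3/6/20 Gy; biopsies at 2 h and days 4, 7, 21, 28; five replicates
per group; ~20,000 probes; the 20 Gy arm ends at day 7) so every stage is
testable without any download.

## What it computes

* **Preprocessing** — per-sample lowess detrending against a mean-intensity
  covariate, between-sample quantile normalization, PCA-based outlier
  exclusion judged within (dose, time point) groups.
* **SDTG calling** — significantly differentially transcribed genes per
  (dose, time point) contrast against the 0 Gy control at the same time
  point, using an empirical-Bayes moderated t-statistic. Gene-wise pooled
  variances s²_g (df d_g) are shrunk toward a prior (d₀, s₀²) fitted by
  method of moments on log s²_g:

      s̃²_g = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g)
      t_g   = log2FC_g / (s̃_g·√(1/n₁ + 1/n₀)),   t_g ~ t(d₀ + d_g) under H₀

  with Benjamini–Hochberg adjustment within each contrast and the SDTG rule
  *adjusted p < 0.05 and |FC| ≥ 2*, where FC is the signed linear fold change
  (2^log2FC for upregulation, −2^|log2FC| for downregulation).
* **Set dynamics** — exact Venn partitions of SDTG sets across time points
  within a dose, across doses within a time point, and globally;
  unique/common counts with percentages of the union; up/down counts,
  percent-upregulated trajectories and the time point of peak upregulation;
  the stationarity index (all-common / union) and the unique/common ratio.
* **Dosimetry** — a deterministic rule cascade: early down-dominance plus
  high stationarity calls *lethal*; early up-dominance plus low stationarity
  calls *sublethal* with an ordinal dose class from the peak shift; anything
  else is an explicit *indeterminate*. Plus a five-gene marker-panel
  sign-consistency score (up in every sublethal cell, down in every lethal
  cell) and an exact-set screen for genes unique to the sublethal response.
* **Ordination** — Sammon mapping (pseudo-Newton minimization of
  E = Σ(d−D)²/d ÷ Σd with step halving) and uncentered-Pearson
  average-linkage clustering with Newick export.

## Worked example

```r
library(radskin)
cfg <- sim_config_preset(seed = 42)          # the mouse-skin study preset
res <- run_pipeline(run_config(sim = cfg, seed = 42, out_dir = "demo_run"))
print(res$calls[["20"]])
print(res$calls[["6"]])
```

```
exposure call (20 Gy arm): LETHAL
  stationarity: 0.538 | early % up: 13.1, 14.4, 13 | peak: d4
  reason: early down fraction 0.87 >= 0.60 and stationarity 0.54 >= 0.40
exposure call (6 Gy arm): SUBLETHAL [dose class: mid ]
  stationarity: 0.0212 | early % up: 63.2, 66.2, 69.1 | peak: d7
  reason: early up fraction 0.66 >= 0.55 and stationarity 0.02 < 0.40
```

The 20 Gy arm is called lethal because ~87% of its first-week SDTGs are
downregulated and ~54% of its SDTG union is common to all three early time
points (the planted architecture carries 609/1038 ≈ 59%; detection attrition
lowers the recovered index slightly). The 6 Gy arm is up-dominated and
dynamic, and its upregulation peak at day 7 — later than the day-4 peaks at
1 and 3 Gy — places it in the higher sublethal dose class. `demo_run/`
contains the normalized matrix, one CSV per contrast, partition and
trajectory tables, the simulation ground truth, and `report.json` with the
calls and their evidence.

A thin command-line front end is installed with the package
(`exec/radskin`): `radskin run --preset --seed 42 --out demo_run`.

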