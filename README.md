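# tdevtools

Tumour-derived extracellular vesicles (tdEVs) — EpCAM+, cytokeratin+,
DNA−, CD45− particles of 1–14 µm — are captured alongside circulating
tumour cells (CTCs) when blood from metastatic cancer patients is
processed on CellSearch-style immunomagnetic platforms. They are roughly
an order of magnitude more frequent than CTCs and carry comparable
prognostic information for overall survival (OS). `tdevtools` is a
desk-scale, fully synthetic emulation of that analysis pipeline for
method developers and biostatisticians: it generates calibrated
multichannel cartridge images with known ground truth, re-detects and
gates the planted objects, simulates patient cohorts with realistic
count and survival structure, and runs the complete downstream survival
association analysis.

The package has three layers, each usable on its own:

* **Imaging** — `scene_config()` / `render_cartridge()` draw
  DAPI/CK/CD45/Marker-1/Marker-2 tile stacks (12-bit camera model:
  Poisson shot noise in photo-electrons, Gaussian read noise) with
  planted CTCs, tdEVs, leukocytes and debris; `detect_cartridge()`
  performs full detection (per-channel thresholding at background +
  *k*·noise SD, 8-connected components, cross-channel event merging) and
  measures ten morphology/intensity features per channel;
  `builtin_gate()` provides the canonical linear tdEV gates
  (`tdev_celltracks`, `tdev_cellspotter`, `tdev_nsclc`) and
  `enumerate_gate()` turns an event table into counts. A tdEV event must
  satisfy, e.g. for the CellTracks platform: mean CD45 ≤ 5, mean DNA ≤ 5,
  mean CK > 60, mean Marker 1 ≤ 5, mean Marker 2 ≤ 5, max CK > 90,
  CK size ≤ 150 µm², CK perimeter > 5 px, CK eccentricity ≤ 0.8 and CK
  perimeter-to-area ≤ 1.
* **Cohorts** — `cohort_config()` / `simulate_cohort()` couple
  zero-inflated negative-binomial CTC and tdEV counts through a Gaussian
  copula (`calibrate_copula_rho()` hits a Spearman target exactly) and
  attach exponential-baseline proportional-hazards survival,
  `T ~ Exp(λ₀·exp(β·x))`, with administrative and early censoring.
* **Statistics** — self-contained implementations of every procedure the
  analysis needs: `km_estimate()`, `logrank_test()`, `cox_fit()`
  (Newton–Raphson partial likelihood, Breslow/Efron ties, separation
  flagging), `stepwise_cox()` (forward LR entry at p < 0.05, removal at
  p > 0.10), `spearman_rho()`, `mann_whitney_u()`,
  `wilcoxon_signed_ranks()`, `roc_auc()`, `dichotomize()` /
  `bin_groups()`, the Cutoff-Finder-style `cutoff_scan()` and
  `favourable_subgroup_scan()`, and the healthy-donor
  `normal_reference_range()` (median + 2 SD). Fitted objects have
  broom-style `tidy()` / `glance()` methods and ggplot2 `autoplot()`s.

`run_study()` composes everything into a seeded end-to-end emulation and
writes a CSV/JSON report bundle; `inst/scripts/tdev-study.R` is a thin
command-line wrapper around it.

## Worked example

```r
library(tdevtools)

# Imaging: render the standard fixture (5 CTCs, 50 tdEVs, 20 leukocytes,
# 10 debris on 12 tiles), detect, and gate.
set    <- render_cartridge(standard_scene_config(seed = 7))
events <- detect_cartridge(set)
enumerate_gate(events, builtin_gate("tdev_celltracks"))
#>   gate                n
#> 1 tdev_celltracks    50

# Cohort: 200 patients, tdEV-driven hazard, dichotomised at the
# reference-range bound of 20 tdEVs per 7.5 mL.
cohort <- simulate_cohort(cohort_config(
  name = "demo", n_patients = 200,
  ctc = count_dist(mu = 5, size = 0.4),
  tdev = count_dist(mu = 60, size = 0.5),
  rho = 0.6, beta_tdev = 0.5, lambda0 = 0.04, horizon = 36, seed = 42))
cohort <- dichotomize(cohort, tdev_count, 20)

glance(km_estimate(cohort, os_months, event, unfavourable))
#>   group     n n_event median_os
#> 1 FALSE    97      78     10.3
#> 2 TRUE    103      97      7.84

tidy(cox_fit(cohort, os_months, event, unfavourable))
#>   term         estimate std.error statistic p.value    hr conf.low conf.high
#> 1 unfavourable    0.414     0.154      2.69 0.00720  1.51     1.12      2.05

glance(cutoff_scan(cohort, tdev_count, os_months, event))
#>   optimal_cutoff     min_p sig_fraction n_candidates     n
#> 1              7 0.0000641        0.656           90   200
```

The gate recovers all 50 planted tdEVs exactly. Patients at or above 20
tdEVs/7.5 mL ("unfavourable") die faster (median OS 7.8 vs 10.3 months);
the univariable Cox hazard ratio is 1.51 (95% CI 1.12–2.05), the
log-rank p ≈ 0.007, and the cutoff scan finds its most significant split
at 7 tdEVs with 66% of all candidate cutoffs giving a significant
dichotomisation — the qualitative signature of a genuinely prognostic
marker.

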