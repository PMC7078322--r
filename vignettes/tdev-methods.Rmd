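---
title: "Models and methods behind tdevtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tdevtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdevtools)
```

`tdevtools` emulates, end to end and on synthetic data, the automated
enumeration of tumour-derived extracellular vesicles (tdEVs) from
CellSearch-style multichannel fluorescence images and the survival
analyses built on those counts. This vignette records the models, the
parameter choices that matter, and the design decisions taken where the
problem left the design open. Nothing here states an empirical result
that the package's tests and acceptance script do not themselves
compute.

## The scientific setting

EpCAM-based immunomagnetic enrichment of 7.5 mL of blood captures both
nucleated circulating tumour cells (CTCs: DNA+, cytokeratin+, CD45−)
and anucleate tumour-derived vesicles (tdEVs: CK+, DNA−, CD45−,
diameter below 14 µm). Cartridges are imaged as a stack of tiles per
fluorescence channel (DAPI for DNA, PE for cytokeratin, APC for CD45,
FITC and PerCP for optional extra markers) on a 12-bit camera.
Automated analysis segments every object, measures per-channel
morphology and intensity features, and classifies objects with linear
gates — conjunctions of threshold predicates. tdEV counts are then used
like CTC counts: dichotomised at a healthy-donor-derived bound,
associated with overall survival through Kaplan–Meier curves, log-rank
tests and Cox models, and scanned over all candidate cutoffs to find
the most significant split.

The real patient archives behind that analysis are not public. The
package therefore contains two synthetic generators — a cartridge
renderer with planted ground truth, and a patient-cohort simulator —
whose outputs exercise every downstream step under known truth.

## The cartridge renderer

`render_cartridge()` plants four object classes with a fixed
class-to-channel signal model: CTCs are DNA+/CK+, tdEVs CK+ only,
leukocytes DNA+/CD45+, debris carries dim signal in one or two random
channels. Objects are anti-aliased ellipses with Gaussian edge
softening; the camera model is Poisson shot noise in photo-electrons
(`gain` electrons per count, default 4) plus Gaussian read noise
(default SD 3 counts), quantised and clamped to the 12-bit range.

Parameters that matter, with defaults:

* `pixel_size = 0.64` µm/px — chosen so a 6.4 µm scale bar spans ten
  pixels; the true camera pitch of the emulated platforms is not
  published, so this is a package convention, and every size feature is
  computed from the configured calibration rather than hard-coded.
* `n_tiles = 175`, the typical number of frames covering a cartridge;
  tests and examples use smaller stacks purely for compactness.
* Per-class diameter ranges: CTCs 8–25 µm and leukocytes 6–15 µm
  (typical cell sizes), debris 2–6 µm. **tdEVs default to 3.2–12 µm
  rather than the full 1–14 µm definition range.** This is deliberate:
  at 0.64 µm/px an object below ≈2.5 µm falls under the four-pixel
  minimum-size floor and the "perimeter > 5 px" and
  "perimeter-to-area ≤ 1" gate bounds, and above ≈13 µm a
  boundary-discretised mask can cross the 150 µm² size bound. The
  default range is exactly the gate-detectable range, so that the
  renderer's separability contract — every planted tdEV passes the
  tdEV gate, every leukocyte fails it — holds and gate fidelity is
  testable as an exact count. The range is configurable down to 1 µm,
  in which case that contract intentionally no longer holds (as it
  would not on a real instrument).
* Edge placement: the nominal object boundary is rendered at the
  ≈3.4%-of-peak contour (`pnorm(-1.83)`). With default peak intensities
  (400–720 counts above background) the detection threshold of the
  default segmentation (background + 3 robust SDs ≈ 18 counts) cuts the
  profile within ±0.15 edge-widths of that contour, so the detectable
  footprint matches the planted diameter to within a few percent across
  the whole size range. In other words, a planted "diameter" means the
  detectable extent of the object under the package's default imaging
  conditions — the natural definition for a generator whose purpose is
  ground-truth recovery.
* Objects are placed with a pairwise separation guard (footprint radii
  plus 10 px) so that cross-channel merging can never join two distinct
  planted objects; an object that does not fit on its assigned tile
  spills to another tile, and a scene that fits nowhere raises a
  packing-capacity error.

What the renderer does **not** emulate: optical point-spread functions,
tile-to-tile stitching overlap, cartridge meniscus artefacts, staining
heterogeneity within an object, or operator review. Passing tests
therefore demonstrate correctness of the detection/gating machinery
under a clean, calibrated image model — not robustness to real
CellSearch image artefacts.

## Detection and features

`detect_cartridge()` mirrors a "full detection" analysis. Per tile and
channel, the background is the tile median and the threshold is
`background + k × 1.4826·MAD` (default `k = 3`); components are
8-connected; components under `min_size = 4` pixels are dropped.
Detections from different channels whose centroids fall within
`r_merge = 5` px are merged into one event by transitive closure. Ten
features are measured per channel: mean, max, SD and total intensity
(background-subtracted), area (µm²), perimeter (count of object pixels
with a 4-neighbour outside the object — the gate states perimeter in
pixels), eccentricity (from second central moments of the binary mask),
perimeter-to-area, equivalent diameter and pixel count.

Two conventions deserve a note:

* **Intensity clipping.** Member-pixel values are background-subtracted
  and the *summary* statistics (mean, max, total) are clipped at zero.
  Clipping pixel-wise instead would bias the mean of a signal-free
  channel upward by E|noise| (≈4 counts at the default background),
  which would defeat gate bounds like "mean DNA ≤ 5" whose whole point
  is to sit just above zero after background removal.
* **Absent channels.** An event with no detection in some channel still
  gets features for that channel, measured over the union footprint.
  The gates require *low* values in absent channels, and this
  convention yields them naturally instead of leaving holes.
* Morphological features are computed per channel on that channel's own
  mask (falling back to the union footprint), so "Size CK" is the area
  of the CK detection — whether the original software measures the CK
  mask or the merged footprint is not documented, and the CK-mask
  reading is the one implemented here.

## Gates

`builtin_gate("tdev_celltracks")` is the canonical tdEV gate (mean
CD45 ≤ 5, mean DNA ≤ 5, mean CK > 60, mean Marker 1 ≤ 5, mean
Marker 2 ≤ 5, max CK > 90, size CK ≤ 150 µm², perimeter CK > 5 px,
eccentricity CK ≤ 0.8, perimeter-to-area CK ≤ 1). The CellSpotter
variant replaces the CK max-intensity bound with "SD CK > 40" (that
platform has higher PE background); the NSCLC variant drops the
Marker-1 bound (tdEVs there may be wheat-germ-agglutinin or pan-CK
positive) while keeping the Marker-2/CD16 exclusion. Comparator
strictness is taken literally and no epsilon slack is applied —
thresholds are exact, and a missing gated feature is an error, never a
silent `FALSE`. Gate files carry units, which are checked against the
feature table's units at load time. The `ctc_synthetic` and `leukocyte`
gates exist only so the synthetic pipeline can count those classes; the
emulated study scored CTCs manually, so these two gates are package
constructs.

Note an internal consistency of the tdEV definition that the test suite
checks: area ≤ 150 µm² bounds the equivalent diameter by
2·√(150/π) = 13.82 µm, just inside the stated "< 14 µm".

## The cohort simulator

`simulate_cohort()` draws CTC and tdEV counts from zero-inflated
negative-binomial marginals coupled by a Gaussian copula on latent
normals, then attaches survival:

* **Counts.** The copula-with-quantile-transform construction hits
  arbitrary rank-correlation targets with skewed integer marginals.
  Because heavy ties attenuate Spearman's rho, the latent correlation
  is *calibrated* against the target with common-random-number
  simulation and root finding (`calibrate_copula_rho()`, Monte Carlo
  size 2·10⁴, deterministic). Per-cohort Spearman targets are 0.87
  (CRPC), 0.70 (MBC and mCRC) and 0.44 (NSCLC).
* **Survival.** Times are exponential with rate
  `λ₀·exp(β_ctc·log10(ctc+1) + β_tdev·log10(tdev+1) +
  β_unfav·1[tdev ≥ cutoff] + Σ β_j x_j)`. An exponential baseline is the
  simplest proportional-hazards-consistent choice, and Cox estimation
  is baseline-free, so recovery tests are unaffected by it. Whether the
  emulated analyses log-transformed counts as log10(x+1) or with
  another offset is not documented; log10(x+1) is the convention here.
  The binary `β_unfav` term exists so a *dichotomised* hazard ratio can
  be planted exactly and recovered.
* **Censoring.** Administrative at a per-cohort horizon plus a uniform
  early-censoring fraction; with an infinite horizon and no early
  censoring every patient is an event (a tested invariant).
* **Presets.** `cohort_presets()` provides crpc/mbc/mcrc/nsclc/healthy
  configurations. No numeric count medians are published for the
  emulated cohorts (they appear only as dot plots), so the preset
  medians are package choices made once: they reproduce the documented
  qualitative ordering (CRPC highest, then MBC, mCRC, NSCLC), keep tdEV
  counts roughly an order of magnitude above CTC counts, and give the
  healthy-donor tdEV marginal (NB mean 7, size 1, n = 93) a
  median + 2 SD near the reported 0–20 normal range. Follow-up horizons
  (39/49/34/30 months) follow the published follow-up maxima. The
  hazard coefficients give dichotomised hazard ratios around 2, the
  magnitude reported for unfavourable counts.

The simulator does **not** emulate the real trials' covariate joint
distributions (a single optional binary "ECOG high" covariate stands in
for the clinical covariates), inter-platform count biases, or
non-proportional hazards. The published optimal favourable-CTC tdEV
cutoffs (≥89, ≥80, ≥40) are properties of the non-deposited clinical
data; the package treats them as interface anchors — its scans recover
*planted* change-points, which is the testable property.

## Survival statistics

All procedures are implemented in the package (the `survival` package
is used only as an independent cross-check in the test suite):

* **Kaplan–Meier**: product-limit with events preceding censorings at
  tied times; median OS is the first time the curve reaches 0.5, `NA`
  ("not reached") otherwise.
* **Log-rank**: hypergeometric observed-minus-expected sums on one
  degree of freedom; equal to the Cox score test at β = 0 (tested to
  1e-8 on tie-free fixtures).
* **Cox**: Newton–Raphson maximisation of the partial likelihood with
  step halving; Breslow tie handling by default (the convention of the
  statistics package the emulated analysis used), Efron behind a flag.
  Convergence requires a score below 1e-8 or a log-likelihood change
  below 1e-9, within 30 iterations. Monotone likelihood (separation) is
  detected when a coefficient passes 15 in absolute value (hazard
  ratios beyond e¹⁵ are never meaningful at these sample sizes) or the
  information matrix becomes singular; such fits are returned flagged
  (`monotone = TRUE, converged = FALSE`) rather than as silent huge
  coefficients.
* **Stepwise Cox**: "forward LR" convention — the candidate with the
  smallest likelihood-ratio entry p enters while p < 0.05; after each
  entry, included variables with removal p > 0.10 leave, largest first;
  ties break towards the earlier candidate; iteration stops at a
  fixpoint (with a hard cap as a loop guard). An empty model is a valid
  outcome.
* **Rank tests**: Spearman as Pearson on mid-ranks with the t
  approximation; Mann–Whitney U exact (via the null U distribution) for
  untied samples up to n = 25, else tie-corrected normal with
  continuity correction; Wilcoxon signed-ranks exact by full
  sign-pattern enumeration up to 12 nonzero pairs (this handles tied
  absolute differences exactly), via the null W distribution up to 25
  untied pairs, else tie-corrected normal. All p-values two-tailed.
* **ROC**: AUC by the rank (Mann–Whitney) formula, so tied scores count
  one half and the AUC equals the concordant-pair fraction exactly.
* **Dichotomisation**: unfavourable means `count ≥ cutoff` everywhere —
  including a CTC cutoff of 1, where any detected CTC is unfavourable —
  because "at least 20 tdEVs" is the one explicitly stated convention
  and consistency across markers matters more than per-marker lore.
  Bins for the ordinal risk-group analysis are left-closed right-open;
  the bin edges are *required configuration* with documented defaults
  (tdEV: 5/20/100 for four groups; CTC: 1/5/25, reduced to 1/5 — three
  groups — for the mCRC- and NSCLC-like cohorts where most patients
  have no CTCs), never silently chosen from the data.

## The cutoff scan

`cutoff_scan()` evaluates every candidate cutoff (default: all distinct
observed counts) that leaves at least `min_group = 5` patients on each
side — the guard keeps the per-cutoff Cox fits away from degenerate
risk sets. Each candidate gets the univariable hazard ratio with its
Wald interval and the log-rank p; the optimal cutoff is the most
significant split, ties breaking towards the smaller cutoff for
reproducibility. Scanned p-values are reported raw: the scan mirrors an
exploratory cutoff-determination tool, and the package documents rather
than corrects the multiplicity (the null-calibration check shows what
raw scanning does under no effect: the significant fraction stays near
the α level, nothing like the near-universal significance real effects
produce). `favourable_subgroup_scan()` applies the same scan to the
tdEV counts of patients below their cohort's CTC cutoff and reports the
fraction of that subgroup above the optimal cutoff.
`normal_reference_range()` returns median + 2·SD (n−1 denominator)
unrounded, with its ceiling as the downstream dichotomisation cutoff.

## Problem sizes and determinism

Every stochastic component takes an explicit integer seed and restores
the caller's RNG state; fixed seeds give bit-identical images, cohorts
and report bundles. The standard imaging fixture is 12 tiles of
160×160 px with 85 planted objects — small enough to re-render in
seconds, large enough that all four classes coexist on shared tiles.
The statistical checks use sample sizes chosen to make their Monte
Carlo error small relative to the tolerance being asserted: marginal
moments at n = 10⁴, Spearman and hazard-ratio recovery at n = 5000,
confidence-interval coverage and log-rank type-I error over 200
replicates, null cutoff scans over 50 cohorts of 200, and change-point
recovery over 100 cohorts of 300.

## Known limitations

* The renderer's separability contract ties the default tdEV size range
  to the gate; it is a fixture-design choice, not a claim that real
  sub-3 µm vesicles are detectable.
* Gate thresholds are interpreted on background-subtracted raw camera
  counts; the original software's internal intensity normalisation is
  not public, so absolute threshold transferability to real archives is
  untested.
* The cohort simulator's presets are qualitative emulations; no claim
  is made that their medians match the unpublished clinical counts.
* The stepwise procedure inherits the known instability of stepwise
  selection under collinearity; the duplicated-covariate test pins down
  only the deterministic tie-break, not scientific validity of stepwise
  modelling.
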