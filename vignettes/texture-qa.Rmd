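---
title: "Texture-based modulation indices for VMAT plan QA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based modulation indices for VMAT plan QA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texqa)
```

## The problem

Volumetric modulated arc therapy (VMAT) shapes dose by sweeping a
multi-leaf collimator (MLC) while the gantry rotates and the dose rate
varies.  Highly modulated plans — many small, irregular, fast-moving
apertures — are harder for the machine to deliver faithfully, and harder
for the dose engine to calculate, so their *delivery accuracy* tends to be
worse.  Routine patient-specific QA measures this after the fact, by
planar gamma analysis of a measured dose distribution or by comparing
machine log files against the plan.  A *modulation index* instead tries to
predict delivery accuracy from the plan alone, at planning time.

`texqa` implements one family of such indices: Haralick texture features
of the plan's integrated fluence map.  The intuition is that a homogeneous
fluence map comes from large, regular apertures that deliver accurately,
while a rough, fragmented map signals aggressive modulation.  The package
also implements the delivery-accuracy measures such indices are judged
against, and the Spearman correlation study that links the two, so the
whole methodology can be exercised end-to-end on synthetic plans.

## Fluence maps

A plan is an ordered sequence of control points, each carrying both MLC
bank positions, the gantry angle, jaw settings and the cumulative meterset
weight (the delivered fraction of the beam's monitor units, MU).
`integrate_fluence()` rasterizes each control point's aperture onto a 1 mm
grid and superposes the results, weighted by each control point's meterset
share.  All beams of a plan are pooled into one map.

Design choices worth knowing about:

* **Meterset sharing.**  A plan states cumulative weights at control
  points, not MU "belonging to" a control point.  The default trapezoidal
  rule assigns each meterset interval half to the aperture at either end,
  which is symmetric and sums exactly to the beam MU.  A `"left"` option
  assigns each interval to its starting control point instead; for the
  fine control-point spacing of clinical arcs the difference is small.
* **Partial pixels.**  Apertures are unions of axis-aligned rectangles
  (one per leaf pair, clipped by the jaws), so area-weighted pixel
  coverage is computed exactly, removing 1 mm aliasing at leaf tips.  A
  faster center-in test is available.
* **Map extent.**  Background zeros change every texture feature, so the
  map is cropped to the bounding box of nonzero fluence before
  quantization; the retained margin (`crop_margin_mm`, default 0 mm) is
  explicit and configurable.
* **Idealized fluence.**  No leaf transmission, tongue-and-groove,
  rounded leaf tips or scatter: the map is purely MLC positions and MU,
  which is what the modulation index is meant to capture.

`quantize()` then maps the fluence linearly to integer gray levels 0–127
(round-half-up, so exact halves are stable across platforms), giving every
nonzero map a maximum level of 127.  Quantization is invariant to the
absolute MU scale.

## Texture features

`glcm()` builds gray-level co-occurrence matrices at displacement
distances d ∈ {1, 5, 10} pixels (1 mm grid: 1/5/10 mm along the axes,
√2/5√2/10√2 mm diagonally) and angles θ ∈ {0°, 45°, 90°, 135°}.  The GLCM
is made symmetric (each pair counted in both orders, so four angles cover
all eight neighbor directions and the two marginals coincide) and
normalized to a probability distribution before features are computed —
published ASM values ≤ 1 imply the normalized convention.

`haralick_features()` computes, with p the normalized GLCM and p_x its
marginal with mean μ_x and SD σ_x:

* ASM = Σ p² (energy; overall homogeneity),
* IDM = Σ p / (1 + (i−j)²) (local homogeneity),
* contrast = Σ (i−j)² p,
* variance = Σ (i−μ_x)² p_x (Haralick's sum-of-squares variance about the
  marginal mean; a joint-mean variant is available but identical under
  symmetry),
* correlation = (Σ ij·p − μ_x μ_y)/(σ_x σ_y),
* entropy = −Σ p log p.

Two conventions are genuinely open in the literature and are fixed here
explicitly.  *Logarithm base*: base 10 (configurable to e or 2); with 128
levels this keeps entropy below 2·log₁₀128 ≈ 4.21, the magnitude range
typically reported for these maps, whereas natural log would roughly
double it.  *Degenerate correlation*: a GLCM concentrated in a single cell
has σ_x σ_y = 0; correlation is then NaN, never silently zero, and the
direction average uses only the defined directions while recording how
many there were.

`feature_panel()` chains the whole pipeline and returns the 6 features ×
3 distances = 18 values per plan in a long-format data frame.

## Delivery-accuracy measures

**Gamma analysis** (`gamma_analysis()`) implements the global 2D
gamma index on absolute-dose planes: for each measured point,
γ = min over nearby reference positions of
√(Δr²/Δ_dta² + ΔD²/(δ·D_max)²), with dose differences normalized to the
*reference plane's* global maximum (the usual "global gamma" reading; the
normalization point is configurable in principle but documented as the
reference maximum here).  Points whose measured dose is below 10% of that
maximum are excluded.  The search uses bilinear interpolation of the
reference on a grid of step DTA/10 out to a radius of 3·DTA; offsets are
visited in order of increasing radius, and a point stops updating once its
current γ can no longer be beaten, which is exact for the discretized
search.  Points whose final γ exceeds the cap ratio are flagged, since
their true minimum might lie outside the search radius.

**Mechanical errors** (`mechanical_errors()`) compare a plan with a
delivery-log record snapshot-matched to its control points: mean absolute
leaf-position difference over both banks and all control points, mean
absolute gantry difference (minimal difference on the circle, so 359.9°
vs 0.1° is 0.2°), and mean absolute cumulative-MU difference.  All leaf
pairs are averaged by default, including parked ones; a
`moving_leaves_only` flag restricts to pairs that move or open.  Logs
recorded on a finer time base can be aligned first with
`resample_record()`, which interpolates linearly in cumulative meterset.

**Spearman statistics** (`spearman_cor()`) use midranks for ties and an
exact permutation p-value for n ≤ 9 (all n! permutations enumerated); for
larger n the standard t approximation is used.  `correlation_panel()`
crosses every (feature, d) with every measure, flags cells at raw
p < 0.05 — deliberately without multiple-testing correction, matching how
such panels are reported in this field, though a Benjamini–Hochberg option
exists — and `significance_counts()` tallies significant cells per
feature.

## The synthetic generator

No clinical dataset ships with the package, so `generate_plan()` creates
arc plans whose modulation degree is a knob: leaf tips trace an elliptical
base aperture plus a smoothed Gaussian perturbation of SD σ_m mm
(`modulation_amplitude_mm`).  The perturbation is white noise smoothed by
a moving average along both the control-point and leaf axes
(`modulation_correlation`, default half-width 2), so trajectories are
smooth rather than jittery; closed rows stay parked, crossing pairs
collapse to their midpoint, and tips clip at ±200 mm travel.  Meterset is
uniform over control points and the gantry sweeps one full arc.  The
defaults — 48 control points, HD 120 geometry, 30 × 25 mm semi-axes,
400 MU — are a deliberately modest stand-in for a single clinical arc.

`simulate_log()` adds Gaussian noise to every recorded quantity.  With
`mlc_error_coupling`, leaf noise scales with the mean leaf travel since
the previous control point, so faster-moving (more modulated) deliveries
record larger errors — the mechanism by which real modulation degrades
delivery accuracy.  `simulate_dose_planes()` builds a reference plane by
Gaussian-blurring the fluence (detector response stand-in, 1 MU-pixel ≡
1 cGy, an arbitrary but documented scale that global gamma is invariant
to) and a measured plane by shifting it and applying multiplicative noise.

`run_study()` chains everything: by default 40 plans cycling σ_m through
{0, 1, 2, 4, 8} mm with MLC log noise coupled to σ_m
(σ_MLC = 0.02 + 0.03·σ_m mm, spanning the few-hundredths to few-tenths of
a millimeter range reported for clinical Varian deliveries), gamma at
2%/2mm, 2%/1mm, 1%/2mm and 1%/1mm, and the full 18 × 7 correlation panel.
Aperture sizes are varied deterministically across plans so equal-σ_m
plans are not clones.

```{r study, eval = FALSE}
study <- run_study(n_plans = 40, sigma_grid = c(0, 1, 2, 4, 8),
                   log_rule = "coupled", seed = 7)
subset(study$panel, feature == "ASM" & d == 10 & measure == "mlc_error_mm")
```

Under these conditions ASM(d = 10) is strongly negatively correlated with
the MLC error and entropy(d = 10) strongly positively — the sign structure
the clinical literature reports — and with `log_rule = "independent"` the
feature-vs-error panel is null-calibrated (≈5% of cells significant at
α = 0.05).

**What the generator does and does not emulate.**  It reproduces the
*causal chain* (modulation → rough fluence → mechanical/dosimetric error)
and the plan-file plumbing, so passing tests demonstrate the pipeline's
correctness and directional fidelity.  It does not emulate optimizer
geometry, dose-rate/gantry-speed servo dynamics, detector spatial
response, or inter-plan case mix; absolute feature values and correlation
magnitudes on clinical data will differ, and no tolerance levels should be
inferred from synthetic runs.

## Numerical choices and degenerate inputs

* Round-half-up quantization (not banker's rounding), for cross-platform
  reproducibility.
* GLCM normalization sums are exact to 1e-12; symmetric counts are
  integer and transpose-equal before normalization.
* All-zero fluence maps refuse to quantize; GLCMs refuse images smaller
  than the offset; constant inputs make Spearman correlation an error
  rather than a number.
* Gamma's discretization (step DTA/10, cap 3·DTA) is config-exposed; the
  test suite pins the implementation against an exhaustive no-early-exit
  search to 1e-3 in γ.
* Every generator is a pure function of its spec including the seed;
  repeated runs are byte-identical.

## Problem sizes used in the tests

The suite validates rasterization against 0.1 mm subsampling, GLCMs
against a double-loop counter on 200 random maps up to 32×32, gamma on
plane pairs of a few thousand points, Spearman against full permutation
enumeration up to n = 7, and the end-to-end study at 40 plans × 48
control points — sizes chosen so the whole suite runs in a few minutes
while leaving every code path exercised at full fidelity.

## Known limitations

* Planar 2D gamma only; cylindrical-detector geometries and 3D gamma are
  out of scope, as are dose reconstruction and dose-volumetric analyses,
  which require a treatment planning system.
* The DICOM-RT reader supports the explicit/implicit little-endian
  transfer syntaxes and MLCX-type leaf sequences (Varian-style plans);
  vendor binary trajectory logs are not parsed — logs enter via the JSON
  exchange format or DICOM-RT re-exports.
* Fluence is idealized (no transmission or leaf-end modeling), so
  absolute feature values are convention-dependent; comparisons are only
  meaningful within one configuration.
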