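---
title: "fluoroquant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluoroquant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the measurement model, the statistical procedures, what the synthetic-data
generator does and does not emulate, and the choices made where the design
was genuinely open. It states no empirical result that the test suite does
not itself compute.

## 1. The measurement model

A dark-adapted plant is imaged twice by a monochrome camera behind a
chlorophyll-emission bandpass filter: once at the minimum fluorescence
level **Fo** (weak measuring light, PSII reaction centers open) and once at
the maximum level **Fm** (saturating excitation, centers closed). The
maximum quantum efficiency of PSII photochemistry is, per pixel,

$$F_v/F_m = \frac{F_m - F_o}{F_m} \in [0, 1].$$

Healthy, unstressed strawberry leaves sit at roughly 0.83; the accepted
screening rule is that **Fv/Fm ≥ 0.79 indicates an unstressed plant**, and
drought/heat stress pushes groups below that within the first days of
treatment.

The analysis chain (`segment_plant` → `compute_fvfm_map` →
`summarize_fvfm`) is:

1. **Segmentation.** The plant is separated from the dark background by
   intensity thresholding of the **Fm frame** — the brighter, higher-contrast
   frame. Which frame to threshold, and at what value, is not part of the
   measurement definition; we default to Otsu's method (exhaustive
   between-class-variance maximization over the full intensity range, ties
   to the lowest threshold) with a fixed-value override, and always report
   the threshold actually used.
2. **Per-pixel ratio with divide safety.** Background pixels and pixels
   with `Fm ≤ eps` (default `eps = 1` intensity unit) are marked invalid
   rather than producing NaN/Inf. Sensor noise can push `Fo > Fm` at dim
   pixels (a negative Fv); such values are **clipped to 0 and counted** in
   `clipped_fraction` instead of being invalidated — this preserves area
   statistics while flagging data quality. The symmetric clip at 1 can only
   trigger for corrupted input.
3. **Histogram-mode summary.** The plant-level scalar is the center of the
   highest-count histogram bin over [0, 1] (bin width 0.01 by default; the
   bin width must divide the unit interval evenly). Ties break to the
   lowest bin, deterministically, and are flagged. The pixel **mean** is
   reported alongside because group-level statistics in this field are
   sometimes computed from means; the pipeline uses the mode by default and
   exposes the choice (`value = "fvfm_mode" | "fvfm_mean"`).
4. **Health rule.** `healthy ⇔ mode ≥ 0.79` (configurable threshold).
5. **Pseudocolor.** Rendering always uses a fixed [0, 1] → color scale
   (default a blue-to-red "jet" ramp: red = high Fv/Fm), never per-image
   min–max, so panels from different days and treatment groups are directly
   comparable. Invalid pixels get a reserved background color (black)
   distinct from every in-scale color.

## 2. The statistical layer

All procedures are implemented from first principles (`one_way_anova`,
`studentized_range_quantile`, `snk_test`, `pearson`, `mean_se`), because
the group-comparison machinery is load-bearing for the stability and
treatment analyses.

**Studentized-range quantiles.** The SNK critical value for a span of $k$
means at error degrees of freedom $\nu$ is the upper-$\alpha$ quantile of
the studentized range $Q_{k,\nu}$. We compute its CDF by numerical
integration — inner integral over the normal order-statistic identity,
outer integral over the $\chi_\nu/\sqrt{\nu}$ scale density, both via
adaptive quadrature — and invert with `uniroot`. No hard-coded tables.
Unit tests cross-check against `stats::ptukey`/`qtukey` (an independent
algorithm) to ~1e-5, and the acceptance suite against a $10^7$-draw
Monte-Carlo oracle.

**SNK step-down.** Group means are sorted descending; contiguous spans are
tested widest-first against $q_\alpha(\text{span}, \nu)\sqrt{MS_w/n}$;
once a span is accepted as homogeneous, no sub-span inside it is tested.
The compact letter display is derived directly from the accepted
homogeneous ranges (one letter per maximal range, singleton letters for
uncovered groups), so *sharing a letter* is exactly *never declared
different* — an invariant the tests enforce on simulated data. At $k = 2$
the procedure reduces to the pooled two-sample t-test
($q = \sqrt{2}\,t$). Unequal group sizes (plant drop-out) use the
harmonic-mean $n$ (Kramer adjustment) with a warning. A zero error mean
square is handled by grouping on exact mean equality rather than dividing
by zero.

**Choice of unit for treatment comparison.** The pipeline averages each
plant over its observation days first and runs ANOVA/SNK on per-plant
period means (one independent unit per plant, n = plants per group). This
matches a whole-observation-period group comparison; per-day testing is
available behind `per_day = TRUE`.

## 3. The synthetic-data generator

No images ship with the package; the generator *is* the test substrate,
and its defaults state the emulated experiment rather than being tuning
knobs:

- **Design**: 4 treatment groups (control, drought, heat, combination) ×
  30 plants × 8 observation days (1, 3, …, 15).
- **Trajectories**: group mean Fv/Fm declines **linearly** from a day-1 to
  a day-15 anchor. The anchors are symmetric around the target period
  averages 0.802 / 0.780 / 0.768 / 0.749 (control 0.810→0.794, drought
  0.788→0.772, heat 0.776→0.760, combination 0.764→0.734). Two
  consequences are intentional: the control stays ≥ 0.79 on every day
  while every stressed group is < 0.79 from day 1 (so "stress visible on
  day 1" is a modeling choice here, not a finding), and a linear form is
  the simplest curve consistent with a monotone decline — nothing in the
  emulated data identifies the true functional form.
- **Plant and pixel variation**: each plant carries a persistent Gaussian
  offset; per-group SDs default to the target standard errors × √30
  (0.0197 / 0.0142 / 0.0126 / 0.0542), so a 30-plant group mean has SE ≈
  0.0036 / 0.0026 / 0.0023 / 0.0099. Within-plant spatial variation has no
  external anchor; we use SD 0.02, small enough that the histogram mode
  tracks the plant mean, large enough to exercise the binning.
- **Images**: the Fo/Fm pair is constructed by inverting the ratio
  (`Fm ≈ fm_level`, `Fo = Fm(1 − \text{target})`), guaranteeing
  `Fo ≤ Fm` pre-noise; additive Gaussian sensor noise (default 1% of the
  default `fm_level` = 10000 on the 16-bit scale) is then clipped to the
  intensity range and rounded — the simplest model that exercises the
  clipping and validity logic downstream. Default frames are 612 × 512, a
  quarter-scale stand-in for the camera's 2448 × 2048 (full scale is just
  a config value). Foreground geometry is a rosette of overlapping
  ellipses: visually plant-like, trivially parameterizable, and sufficient
  because nothing downstream uses shape beyond segmentation. The rosette
  deterministically rescales itself into a 5–60% foreground fraction.
- **SPAD coupling**: `SPAD = 110 · FvFm − 44 + noise`. Slope and intercept
  were chosen once so the trend endpoints reproduce SPAD readings in the
  low-to-mid 40s for healthy plants and high 30s under combined stress;
  the noise SD defaults to the value that makes the *population*
  correlation between true Fv/Fm and SPAD exactly 0.75
  (`calibrate_spad_noise`, closed form from the design variance). Only the
  correlation, not a mechanism, is being emulated.

What a green test on this substrate does **not** establish: performance on
real canopies (specular highlights, soil/moss background, overlapping
leaves from neighboring pots), non-Gaussian sensor noise, day-to-day
registration drift, nonlinear senescence trajectories, or SPAD's saturating
response at high chlorophyll. The generator emulates the *statistical
structure the analysis assumes*, which is exactly what makes
parameter-recovery tests meaningful and no more.

## 4. EMEX peak analysis and a known limitation

EMEX matrices live on the spectrofluorometer grid (excitation 350–550 nm ×
emission 600–800 nm, 1 nm steps; intensities in arbitrary units — the
instrument's units are not part of the contract). `find_peak` is a global
argmax with an optional 3×3 median pre-filter (a vectorized median-of-9
comparator network; edge replication at borders), ties broken toward the
lowest (excitation, emission) pair. The stability test runs ANOVA + SNK on
per-sample peak coordinates grouped by day, separately per axis; "stable"
means a single letter group on both axes.

**Limitation (measured, and deliberately left visible).** With the
generator's realistic band shapes — Gaussian σ of 20 nm along excitation
and 10 nm along emission — and scan noise at 1/50 of the peak amplitude,
an argmax after a 3×3 median cannot reliably localize the peak to 1 nm on
*both* axes: the excitation profile drops only ~1.25 intensity units per
nm near its maximum while the post-median residual noise SD is ~8 units,
so the argmax wanders a few nm along the flat excitation band (the narrow
emission band localizes to ~1 nm). The acceptance suite measures this
honestly (about two-thirds of seeds land within 1 nm on both axes; all
within 5 nm), and the corresponding 95%-within-1-nm assertion is left
failing rather than weakened. This mirrors the few-nm excitation spread
(467–469 nm) such scans show on real leaves; a 1 nm-accurate excitation
estimate would require a model-based peak fit, which the peak-finder
contract here (argmax) intentionally excludes.

**A second measured limitation: correlation-recovery variance.** The SPAD
noise calibration is exact in expectation — across 100 simulated default
experiments the mean per-record Pearson estimate sits at the calibrated
0.75 — but the *spread* of the estimate is larger than a naive
independent-pairs calculation suggests. Each plant's persistent offset is
shared by all of its observation days, so 960 plant-day records contain
only 120 independent plant draws, and the combination group's large
between-plant SD adds experiment-to-experiment variance in the realized
Fv/Fm spread. The acceptance suite asserts a ±0.05 band around 0.75 for
240-pair estimates at a 90% rate; the stated generator achieves roughly
80% (and ~85% even using all 960 pairs), and that assertion is left
failing rather than de-clustering the generator — the clustering is a
deliberate, realistic feature of the emulated design. Users correlating
clustered records should expect this inflation; `pairing = "per_plant"`
trades pairs for independence.

## 5. Numerical choices and degenerate inputs

- Otsu on a constant image is an error (no two-class split exists), as is
  summarizing a map with zero valid pixels.
- ANOVA with zero within-group variance *and* equal means is an error
  (F undefined); with unequal means it reports F = ∞, p = 0.
- Histogram values of exactly 1.0 fall in the top bin; mode ties take the
  lowest bin.
- Quantile inversion brackets from below and expands the upper bracket
  geometrically; integration failures raise errors with the offending
  (q, k, df).
- All generator randomness flows from one integer seed through fixed
  sub-seed derivation (plant, day, purpose), so outputs are bit-identical
  across runs and independent of consumption order; every derived seed
  stays below 2³¹.
- TIFF output is baseline little-endian uncompressed grayscale (uint8,
  uint16, float32 for ratio maps with NaN at invalid pixels) — written and
  parsed by the package itself since the environment provides no R TIFF
  bindings; round trips are tested, and the reader accepts either
  endianness and multi-strip layouts of the same subset.

## 6. Known limitations

Beyond the EMEX argmax limitation above: no multi-frame induction
kinetics (OJIP), no light-adapted parameters (ϕPSII, NPQ, qP…), no leaf
tracking or registration across days, no scatter-line correction or
fluorophore unmixing in EMEX space, and the statistical layer is
deliberately limited to one-way fixed-effects designs — repeated-measures
or mixed models over days are out of scope.
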