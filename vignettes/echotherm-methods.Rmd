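---
title: "Texture-based ultrasound thermometry: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based ultrasound thermometry: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(echotherm)
```

## The problem

Microwave ablation destroys tissue wherever the temperature stays above
the lethal threshold, commonly taken as 54 °C. The clinical proxy for the
coagulation zone — the bright hyperechoic bubble cloud on B-mode
ultrasound — systematically overshoots it, while the quantity that
actually matters, the temperature field, is invisible to B-mode. Heating,
however, changes the *texture* of the speckle pattern in reproducible
ways, and a regression from local texture to local temperature turns an
ordinary grayscale frame into a thermometer.

`echotherm` implements that regression pipeline end to end, together with
a synthetic ablation generator that reproduces the statistical structure
the method relies on, so every stage is testable without any imaging
hardware.

## The estimation pipeline

**Sampling.** Thermocouple logs (7 channels, 2 Hz) start 15 s before the
ablation; `trim_preheat()` keeps the `[15, 195)` s window and re-zeroes
the clock, so 180 s of heating gives 360 readings per channel.
`extract_keyframes()` keeps the first and sixth frame of each second of
the 12 fps recording — two keyframes per second to match the 2 Hz log.
The spacing is necessarily uneven (5/12 s then 7/12 s), so
`pair_samples()` matches frames to readings by nearest timestamp with a
0.25 s tolerance (half the log period) rather than assuming a uniform
grid. Each of the 7 marked probe positions contributes a 64 × 64-pixel
ROI per keyframe: 2520 temperature–ROI pairs per case. A 64-pixel window
cannot be centred symmetrically on one pixel; the half-open convention
`[c − 32, c + 32)` is used on both axes, with 0-based x = column /
y = row coordinates and origin at the top-left. Samples are split
4 : 1 : 1 by largest-remainder rounding. The default `per_sample` mode
shuffles individual samples, which mixes frames of one ablation across
splits and therefore yields optimistic test errors; `per_case` assigns
whole ablations to splits and is the mode to use for generalisation
claims. Both are provided because the frame-level split is what the
sample accounting (1680/420/420 from 2520) refers to.

**Features.** `extract_features()` computes the 104-feature IBSI battery:
first-order (19), 2-D shape (10), GLCM (24), GLRLM (16), GLSZM (16),
NGTDM (5), GLDM (14). Numerical choices, all configurable:

* Quantisation: fixed bin count, `Ng = 32`, per patch. This keeps matrix
  dimensions stable across patches with very different dynamic ranges
  (cold speckle spans most of the 8-bit range, coagulated tissue much
  less). Fixed bin width is available as an alternative.
* All matrix families use distance / neighbourhood radius 1; GLCM and
  GLRLM aggregate the four 2-D directions by averaging each feature over
  directions (not by merging matrices); GLSZM zones and the optional
  largest-component filter use 8-connectivity; GLDM uses similarity
  tolerance α = 0, with the dependence size defined as 1 + the number of
  matching neighbours so the small-dependence emphases never divide by
  zero.
* Degenerate patches never produce non-finite values: a constant patch
  has entropy 0, uniformity 1, skewness/kurtosis 0, GLCM correlation and
  MCC 1, IMC1/IMC2 0, and NGTDM coarseness capped at 1e6.
* Shape features of a square ROI are constants. They are computed anyway
  so the battery honours its 104-feature contract, and the forest is
  expected to assign them ~zero importance — a built-in sanity check on
  the ranking rather than dead weight.

**Model.** Features are z-score normalised with training-split statistics
(standard deviations floored at 1e-12, so constant features map to 0).
`rank_importance()` ranks all 104 features by random-forest impurity
importance — for regression, the total variance decrease over all splits,
summed across trees (the regression analogue of Gini importance). Ties
are broken by the canonical battery order for reproducibility. The top 10
features feed the final regression forest. Forest defaults (500 trees,
mtry = p/3, minimum node size 5) follow common regression-forest
practice; because the validation set's role is "model optimisation", a
small explicit grid (trees ∈ {200, 500} × min leaf ∈ {1, 5}) is scored by
validation MAE and the winner kept. All fits are single-threaded and
seeded, so rankings, selections and predictions are bit-reproducible. The
forests themselves are fitted by `ranger`; the package's contribution is
the pipeline around them, and an independent forest implementation
(`randomForest`) is used in the test suite to cross-check the importance
ranking, never to fit the model.

**Thermal maps and areas.** `predict_heatmap()` slides the 64 × 64 window
across a target region (reflect padding at the frame borders, so the map
covers the full region), extracts only the families that contain selected
features, and predicts every pixel (stride 1 by default; larger strides
predict a subgrid and upsample by nearest neighbour). `threshold_area()`
counts pixels at or above 54 °C — the comparison is `≥`, a documented
choice since boundary inclusion is otherwise ambiguous — and converts to
mm². No connected-component filtering is applied by default: spurious hot
islands away from the ablation zone are a known failure mode of the
method and are deliberately preserved in the area estimate; an optional
largest-component mode exists for sensitivity analyses. The hyperechoic
comparison area uses the caliper convention `S_v = ½·a·b·π` with `a` the
major diameter and `b` half the minor diameter, and both estimates are
scored by `ER = |x − S_r| / S_r`.

The same point-trained forest is reused for per-pixel prediction. An
alternative — retraining on pixel blocks of the target region — would
require per-pixel temperature ground truth, which thermocouples do not
provide; reusing the point model is the only option consistent with the
data actually collected.

## The synthetic ablation generator

`generate_case()` emulates the four inputs of a real case: the frame
sequence, the thermocouple log, the markup (probe coordinates, needle
axis, pixel spacing) and the ground-truth areas.

**Temperature field.** A separable elliptical Gaussian centred on the
antenna (5 mm from the needle tip along the shaft), elongated along the
needle — the fusiform zone typical of MWA in liver:
`T = baseline + (peak − baseline) · r(t) · exp(−u²/σ_a² − v²/σ_b²)`,
with ramp `r(t) = 1 − exp(−t/30 s)` and scales
`σ(t) = σ_0 (1 + 0.08 √t)` from σ_a0 = 4 mm, σ_b0 = 2.8 mm. Power
presets peak at 85 °C (15 W) and 100 °C (20 W) from a 37 °C bath
baseline. No bioheat PDE is solved; the closed form is the simplest
field with the right geometry, peak range and monotone growth, and it
makes ground truth exact and free.

**Speckle renderer.** Three ingredients, each tied to an observed
direction of texture drift in heated liver:

1. mean intensity `μ(θ) = 60 + 100(1 − e^{−6θ})` with
   `θ = (T − baseline)/(peak − baseline)`: coagulated tissue is brighter,
   saturating at high temperature;
2. additive zero-mean speckle built from a unit Rayleigh draw raised to
   an exponent that falls from 2 (cold) to 0.5 (hot) and standardised:
   heavy-tailed pre-Rayleigh statistics for sparse cold scatterers,
   tight post-Rayleigh statistics once coagulation densifies them. The
   amplitude falls linearly, `g(θ) = 45·(1 − 0.8θ)` gray levels × the
   Rayleigh sd.
3. Poisson-placed Gaussian bubble blobs (amplitude 8, σ 0.35 mm, up to
   2 per mm²) inside the hyperechoic ellipse once any tissue exceeds
   60 °C.

Two of these choices deserve their rationale spelled out. A purely
multiplicative speckle with a temperature-dependent scale cannot produce
the documented drift: the Rayleigh coefficient of variation is scale-free,
so per-patch fixed-bin-count quantisation erases a pure scale change and
co-occurrence statistics would not move at all. The *shape* sweep is what
moves cluster prominence; the shape change is also the physically
expected one (envelope statistics tighten as scatterer density rises).
Second, the mean map saturates quickly (rate 6) because a strong
brightness gradient inside a hot 64 × 64 patch inflates fourth-moment
statistics and would mask the noise-driven decrease of cluster
prominence. With these defaults, across a simulated ablation the patch
minimum correlates positively with temperature and variance, mean
absolute deviation and GLCM cluster prominence negatively — the
qualitative pattern the regression exploits. The test suite asserts the
signs only, never the magnitudes.

**Hyperechoic ellipse.** Concentric with the 54 °C isotherm and
`κ(t) = 1.15 + 0.45·e^{−t/60 s}` times larger, so the bubble cloud
overshoots the coagulation zone early and converges toward it — the
rendered hyperechoic area is never smaller than the isotherm area (an
asserted invariant). The final `(a, b)` caliper measurements and the
final-field isotherm pixel area are written as ground truth.

**Probe layout.** Probe 1 sits just left of the needle tip, the other six
spread below the shaft between 1.5 and 8 mm depth, all strictly below the
axis. Distances were chosen once so the seven channels span
near-baseline to near-peak temperatures; exact offsets are configurable
because no canonical layout exists. The log is sampled by bilinear
interpolation of the field at the probe coordinates plus N(0, 0.3 °C)
noise, on a clock that includes the 15 s thermometer warm-up, so the
standard trim window applies to synthetic logs verbatim.

All randomness of a case derives from a single seed; identical
configurations reproduce identical cases bit for bit.

**What the simulator does not emulate.** Acoustic wave propagation,
attenuation and shadowing; needle reverberation artefacts; tissue
inhomogeneity and vessels; respiration and perfusion (ex vivo setting);
3-D effects. Passing tests on synthetic cases therefore demonstrate that
the pipeline is implemented correctly and can invert its own generative
model — not that the learned forests transfer to clinical images.

## Problem sizes used in the tests

Unit tests run on small grids and short ablations. The end-to-end checks
use: one full-length case (180 s, 12 fps, 160 × 240 px at 0.2 mm/px) for
the keyframe/sample accounting; four 90 s, 240 × 320 px (0.1 mm/px) 15 W
cases (5040 samples) for training and held-out evaluation, with a
permuted-label negative control; and five further seeded cases for the
area comparison, with heat maps predicted at stride 4 over a
180 × 130 px region around the ablation centre. These sizes were chosen
as the smallest at which the field's geometry (a ~15 × 10 mm isotherm
inside the frame, ROIs inside the grid) and the statistical claims are
comfortably testable.

## Known limitations

* Feature values depend on the quantisation and aggregation conventions
  above; other radiomics implementations print different absolute values
  for the same names, so only ranking behaviour and correlation signs —
  not importance magnitudes — are comparable across implementations.
* The per-sample split leaks frames of one ablation across splits;
  held-out errors under it measure interpolation, not generalisation.
* Thermometry near the 54 °C contour is smoothed by the 6.4 mm window;
  area estimates inherit a bias wherever the temperature gradient is
  shallow.
* The 54 °C threshold is applied to predicted temperatures; prediction
  bias near the boundary translates directly into area error, and
  under-representation of mid-range temperatures in training data makes
  that region the weakest part of the regression.
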