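# echotherm

Ultrasound texture thermometry for microwave ablation.

During microwave ablation (MWA) of liver tissue, the temperature
distribution decides which tissue coagulates: isotherms near 54 °C mark
the lethal boundary. MRI thermometry is accurate but impractical in most
ablation suites, while plain B-mode ultrasound only shows a hyperechoic
bubble cloud that systematically overestimates the coagulation zone.
`echotherm` implements a texture-regression alternative for researchers
working with grayscale ultrasound of thermal ablation: it learns the
relationship between local speckle texture and tissue temperature from
thermocouple-annotated frames, and turns a single B-mode frame into a
per-pixel temperature map whose 54 °C contour estimates the coagulation
area.

## Method

For each thermocouple position, a 64 × 64-pixel region of interest (ROI)
is cut from every keyframe (the first and sixth frame of each second,
matching the 2 Hz thermocouple log) and paired with the simultaneous
temperature reading. Each ROI is summarised by the 104-feature IBSI
radiomics battery — first-order statistics (19), 2-D shape (10), GLCM
(24), GLRLM (16), GLSZM (16), NGTDM (5) and GLDM (14). After z-score
normalisation, features are ranked by random-forest Gini importance
(total variance decrease over all splits),

- the top **k = 10** features are kept,
- a regression forest maps them to temperature (°C),
- samples are split 4 : 1 : 1 into train/validation/test, with the
  validation set scoring a small hyperparameter grid.

Point predictions are scored by MAE and RMSE. For whole-image
thermometry, a sliding 64 × 64 window predicts the temperature of every
pixel in a target region; the area of the `T ≥ 54 °C` zone, `S_p`,
estimates the coagulation area. Against the gold-standard area `S_r`
(traced on the cut specimen), and the hyperechoic ellipse area
`S_v = ½·a·b·π` (major diameter `a`, half minor diameter `b`), accuracy
is scored by the error ratio

```
ER = |x − S_r| / S_r,    x ∈ {S_v, S_p}.
```

A seeded ablation simulator (`sim_config()`, `generate_case()`) produces
synthetic cases — an elliptical Gaussian temperature field with an
exponential heating ramp, Rayleigh-family speckle whose statistics drift
with temperature the way heated liver tissue's do, a growing hyperechoic
bubble ellipse, and a noisy 7-channel thermocouple log — so the whole
pipeline is testable without any imaging data.

## Worked example

```r
library(echotherm)

# one synthetic 90 s case per seed (15 W preset, 240 x 320 px, 0.1 mm/px)
cases <- lapply(1:4, function(i)
  generate_case(sim_config(grid_height_px = 240, grid_width_px = 320,
                           duration_s = 90, power_preset = "P15",
                           rng_seed = 1000 + i),
                out_dir = file.path(tempdir(), paste0("case", i))))

samples  <- do.call(c, lapply(cases, ingest_case))   # 5040 ROI pairs
samples  <- split_dataset(samples, seed = 7)         # 4:1:1
features <- feature_table(samples, mm_per_px = 0.1)  # 104 columns

fc <- feature_names()
tr <- features$split == "train"; va <- features$split == "val"
model <- fit_temperature_model(
  features[tr, fc], features$temperature_C[tr],
  validation = list(x = features[va, fc], y = features$temperature_C[va]),
  config = forest_config(seed = 11), power_label = "15W")

te <- features$split == "test"
pred <- predict(model, features[te, fc])
mae(features$temperature_C[te], pred)
#> [1] 0.3278486
rmse(features$temperature_C[te], pred)
#> [1] 0.4224028
```

A held-out MAE around 0.3 °C says the forest recovers the simulator's
probe temperatures almost exactly when samples of the same ablations are
split at random (the optimistic, frame-level split; use
`split_dataset(..., grouping = "per_case")` for a leakage-free split).
Thermometry of a whole frame and the area comparison:

```r
case  <- generate_case(sim_config(grid_height_px = 240, grid_width_px = 320,
                                  duration_s = 90, power_preset = "P15",
                                  rng_seed = 2001))
frame <- get_frame(case$frames, n_frames(case$frames))
hm    <- predict_heatmap(frame, model,
                         region = list(x0 = 60, y0 = 36,
                                       width = 180, height = 130),
                         mm_per_px = 0.1, stride = 4)
case_report(S_r = case$truth$isotherm_area_mm2,
            hyperechoic = c(a = case$truth$hyperechoic_a_mm,
                            b = case$truth$hyperechoic_b_mm),
            ml = hm)
#>   case_id    S_r      S_v    S_p ER_hyper     ER_ml
#> 1    case 107.35 167.9803 111.84 0.564791 0.0418258
```

The machine-learning area misses the true 54 °C isotherm area by ~4 %,
while the hyperechoic ellipse — still converging toward the coagulation
zone at 90 s — overshoots by ~56 %: the ordering the method is designed
to demonstrate. Published per-case area tables for
both power groups ship with the package:

```r
group_summary(area_reports_from_table(ablation_area_tables("15W")))
#> $mean_er_hyper [1] 0.4015835
#> $mean_er_ml    [1] 0.1592998
#> $n             [1] 5
```

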