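#' Configuration of a synthetic microwave-ablation case
#'
#' Describes the acquisition geometry and physics of one simulated ex vivo
#' ablation: grid size and pixel spacing of the B-mode image, ablation
#' duration and power preset, frame and thermocouple sampling rates, the
#' needle axis and the seven thermocouple positions, and the parameters of
#' the temperature field and speckle renderer.
#'
#' The temperature field is a separable elliptical Gaussian centred on the
#' microwave antenna (a point on the needle axis near the tip), with an
#' exponential time ramp `r(t) = 1 - exp(-t / tau_s)` and axis scales that
#' grow with the square root of time. Power presets follow the two study
#' arms: `P15` peaks at 85 degC and `P20` at 100 degC after 180 s.
#'
#' The seven probes sit below the needle axis (probe 1 just left of the
#' needle tip, the others spread under the shaft) at distances chosen so
#' that the recorded temperatures span from near-baseline to near-peak.
#'
#' @param grid_height_px,grid_width_px image grid size in pixels.
#' @param mm_per_px pixel spacing in mm.
#' @param duration_s ablation duration in seconds (default 180).
#' @param frame_rate_fps ultrasound frame rate (default 12).
#' @param temp_rate_hz thermocouple sampling rate (default 2).
#' @param power_preset `"P15"` or `"P20"`.
#' @param peak_temp_C asymptotic peak temperature; defaults to 85 (P15) or
#'   100 (P20).
#' @param baseline_temp_C water-bath baseline, default 37.
#' @param preheat_s thermometer warm-up before the ablation starts; the
#'   probe log includes this prefix (default 15 s).
#' @param probe_points 7 x 2 matrix of probe pixel coordinates, columns
#'   `x`, `y`, 0-based, origin top-left. Default layout is derived from
#'   the grid.
#' @param needle_axis 2 x 2 matrix, rows = the two axis endpoints (tip
#'   first), columns `x`, `y` in 0-based pixels.
#' @param rng_seed integer seed; all case randomness flows from it.
#' @param tau_s time constant of the heating ramp (default 30 s).
#' @param sigma_a0_mm,sigma_b0_mm initial Gaussian scales along/across the
#'   needle, in mm.
#' @param sigma_growth per-sqrt-second growth rate of both scales.
#' @param probe_noise_sd_C thermocouple noise, degC (default 0.3).
#' @param mean_floor,mean_gain,mean_rate mean-intensity model
#'   `mu(T) = mean_floor + mean_gain * (1 - exp(-mean_rate * theta))`,
#'   with `theta = (T - baseline) / (peak - baseline)` clipped to `[0, 1]`.
#' @param speckle_gain,speckle_decay speckle amplitude
#'   `g(theta) = speckle_gain * (1 - speckle_decay * theta)`; the speckle
#'   is additive, zero-mean, with sd `g(theta) * sd(Rayleigh(1))`.
#' @param speckle_shape_cold,speckle_shape_hot exponent applied to the
#'   unit Rayleigh draw at baseline and at peak temperature. Values above
#'   1 give pre-Rayleigh (heavy-tailed) envelope statistics, values below
#'   1 post-Rayleigh (tight) statistics; the sweep from 2 to 0.5 models
#'   the densification of scatterers as tissue coagulates.
#' @param bubble_temp_C temperature above which microbubbles appear
#'   (default 60).
#' @param bubble_amp,bubble_sigma_mm,bubble_rate_mm2 bubble blob amplitude
#'   (gray levels), Gaussian radius (mm), and asymptotic Poisson density
#'   (blobs per mm^2 of hyperechoic region).
#' @param kappa_start,kappa_end,kappa_tau_s ratio of the hyperechoic
#'   ellipse to the 54 degC isotherm: starts at `kappa_start`, converges to
#'   `kappa_end` with time constant `kappa_tau_s`.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(grid_height_px = 480L,
                       grid_width_px = 640L,
                       mm_per_px = 0.1,
                       duration_s = 180,
                       frame_rate_fps = 12,
                       temp_rate_hz = 2,
                       power_preset = c("P15", "P20"),
                       peak_temp_C = NULL,
                       baseline_temp_C = 37,
                       preheat_s = 15,
                       probe_points = NULL,
                       needle_axis = NULL,
                       rng_seed = 1L,
                       tau_s = 30,
                       sigma_a0_mm = 4,
                       sigma_b0_mm = 2.8,
                       sigma_growth = 0.08,
                       probe_noise_sd_C = 0.3,
                       mean_floor = 60,
                       mean_gain = 100,
                       mean_rate = 6,
                       speckle_gain = 45,
                       speckle_decay = 0.8,
                       speckle_shape_cold = 2,
                       speckle_shape_hot = 0.5,
                       bubble_temp_C = 60,
                       bubble_amp = 8,
                       bubble_sigma_mm = 0.35,
                       bubble_rate_mm2 = 2,
                       kappa_start = 1.6,
                       kappa_end = 1.15,
                       kappa_tau_s = 60) {
  power_preset <- match.arg(power_preset)
  if (is.null(peak_temp_C)) {
    peak_temp_C <- switch(power_preset, P15 = 85, P20 = 100)
  }
  stopifnot(grid_height_px > 0, grid_width_px > 0, mm_per_px > 0,
            duration_s > 0, frame_rate_fps > 0, temp_rate_hz > 0)
  if (baseline_temp_C >= peak_temp_C) {
    stop_domain("baseline temperature must be below peak temperature")
  }
  n_temp <- duration_s * temp_rate_hz
  if (abs(n_temp - round(n_temp)) > 1e-9) {
    stop_domain("duration_s * temp_rate_hz must be an integer")
  }

  if (is.null(needle_axis)) {
    y <- round(grid_height_px * 0.42)
    needle_axis <- rbind(c(round(grid_width_px * 0.25), y),
                         c(round(grid_width_px * 0.85), y))
  }
  needle_axis <- matrix(as.numeric(needle_axis), 2, 2,
                        dimnames = list(c("tip", "shaft"), c("x", "y")))

  if (is.null(probe_points)) {
    probe_points <- default_probe_points(needle_axis, mm_per_px)
  }
  probe_points <- matrix(as.numeric(probe_points), ncol = 2,
                         dimnames = list(NULL, c("x", "y")))
  if (nrow(probe_points) != 7L) {
    stop_domain("exactly 7 probe points are required")
  }
  if (any(probe_points[, 1] < 0 | probe_points[, 1] > grid_width_px - 1 |
          probe_points[, 2] < 0 | probe_points[, 2] > grid_height_px - 1)) {
    stop_domain("probe points must lie inside the grid")
  }
  # all thermocouple holes sit below the ablation needle
  axis_y <- stats::approx(needle_axis[, "x"], needle_axis[, "y"],
                          xout = pmin(pmax(probe_points[, 1],
                                           min(needle_axis[, "x"])),
                                      max(needle_axis[, "x"])))$y
  if (any(probe_points[, 2] <= axis_y)) {
    stop_domain("all probe points must lie below the needle axis")
  }

  cfg <- list(
    grid_height_px = as.integer(grid_height_px),
    grid_width_px = as.integer(grid_width_px),
    mm_per_px = mm_per_px,
    duration_s = duration_s,
    frame_rate_fps = frame_rate_fps,
    temp_rate_hz = temp_rate_hz,
    power_preset = power_preset,
    peak_temp_C = peak_temp_C,
    baseline_temp_C = baseline_temp_C,
    preheat_s = preheat_s,
    probe_points = probe_points,
    needle_axis = needle_axis,
    rng_seed = as.integer(rng_seed),
    tau_s = tau_s,
    sigma_a0_mm = sigma_a0_mm,
    sigma_b0_mm = sigma_b0_mm,
    sigma_growth = sigma_growth,
    probe_noise_sd_C = probe_noise_sd_C,
    mean_floor = mean_floor,
    mean_gain = mean_gain,
    mean_rate = mean_rate,
    speckle_gain = speckle_gain,
    speckle_decay = speckle_decay,
    speckle_shape_cold = speckle_shape_cold,
    speckle_shape_hot = speckle_shape_hot,
    bubble_temp_C = bubble_temp_C,
    bubble_amp = bubble_amp,
    bubble_sigma_mm = bubble_sigma_mm,
    bubble_rate_mm2 = bubble_rate_mm2,
    kappa_start = kappa_start,
    kappa_end = kappa_end,
    kappa_tau_s = kappa_tau_s
  )
  class(cfg) <- "sim_config"
  cfg
}

# Default probe layout, in mm offsets (u along axis from the tip, v below
# the axis), scaled into pixels. Probe 1 sits left of the needle tip, the
# rest spread below the shaft at increasing depth so the recorded
# temperatures cover the full baseline-to-peak range.
default_probe_points <- function(needle_axis, mm_per_px) {
  offsets_mm <- rbind(
    c(-1.0, 1.5),  # probe 1: left of the tip, close to the antenna
    c(5.0, 1.5),
    c(8.0, 3.0),
    c(2.0, 4.0),
    c(5.0, 5.5),
    c(9.0, 6.5),
    c(3.0, 8.0)
  )
  dirv <- needle_axis["shaft", ] - needle_axis["tip", ]
  dirv <- dirv / sqrt(sum(dirv^2))
  perp <- c(-dirv[2], dirv[1])
  if (perp[2] < 0) perp <- -perp  # point "down" (increasing row)
  tip <- needle_axis["tip", ]
  t(apply(offsets_mm, 1, function(o) {
    tip + (o[1] * dirv + o[2] * perp) / mm_per_px
  }))
}

# Centre of the temperature field: 5 mm from the tip along the shaft,
# where the antenna slot of the ablation needle radiates.
field_center_px <- function(cfg) {
  dirv <- cfg$needle_axis["shaft", ] - cfg$needle_axis["tip", ]
  dirv <- dirv / sqrt(sum(dirv^2))
  cfg$needle_axis["tip", ] + dirv * (5 / cfg$mm_per_px)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ablation configuration\n")
  cat(sprintf("  grid: %d x %d px at %.3g mm/px\n",
              x$grid_height_px, x$grid_width_px, x$mm_per_px))
  cat(sprintf("  %s: baseline %.1f degC, peak %.1f degC, %g s at %g fps, probes at %g Hz\n",
              x$power_preset, x$baseline_temp_C, x$peak_temp_C,
              x$duration_s, x$frame_rate_fps, x$temp_rate_hz))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}
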