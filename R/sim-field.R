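#' Ground-truth temperature field at a given time
#'
#' Evaluates the simulator's analytic tissue-temperature model
#' `T(x, y, t) = baseline + (peak - baseline) * r(t) *
#' exp(-(u^2 / sigma_a(t)^2 + v^2 / sigma_b(t)^2))`, where `(u, v)` are mm
#' coordinates along/across the needle axis measured from the antenna
#' centre, `r(t) = 1 - exp(-t / tau_s)`, and
#' `sigma_.(t) = sigma_.0 * (1 + sigma_growth * sqrt(t))`. The field is the
#' fusiform (elongated elliptical) heating zone typical of microwave
#' ablation in liver, and is fully deterministic given the configuration.
#'
#' @param cfg a [sim_config()].
#' @param time_s time since ablation start, in `[0, duration_s]`.
#' @return an object of class `temperature_field`: list with `values`
#'   (matrix, degC), `time_s`, and `mm_per_px`.
#' @export
simulate_field <- function(cfg, time_s) {
  stopifnot(inherits(cfg, "sim_config"))
  if (time_s < 0 || time_s > cfg$duration_s) {
    stop_domain("time_s must be within [0, duration_s]")
  }
  sig <- field_sigmas_mm(cfg, time_s)
  ramp <- 1 - exp(-time_s / cfg$tau_s)
  ctr <- field_center_px(cfg)
  dirv <- cfg$needle_axis["shaft", ] - cfg$needle_axis["tip", ]
  dirv <- dirv / sqrt(sum(dirv^2))

  x <- (seq_len(cfg$grid_width_px) - 1 - ctr["x"]) * cfg$mm_per_px
  y <- (seq_len(cfg$grid_height_px) - 1 - ctr["y"]) * cfg$mm_per_px
  xm <- matrix(x, cfg$grid_height_px, cfg$grid_width_px, byrow = TRUE)
  ym <- matrix(y, cfg$grid_height_px, cfg$grid_width_px)
  u <- xm * dirv[1] + ym * dirv[2]
  v <- -xm * dirv[2] + ym * dirv[1]

  amp <- (cfg$peak_temp_C - cfg$baseline_temp_C) * ramp
  values <- cfg$baseline_temp_C +
    amp * exp(-(u^2 / sig[1]^2 + v^2 / sig[2]^2))
  structure(list(values = values, time_s = time_s,
                 mm_per_px = cfg$mm_per_px),
            class = "temperature_field")
}

# Gaussian scales (mm) along (a) and across (b) the needle at time t.
field_sigmas_mm <- function(cfg, time_s) {
  g <- 1 + cfg$sigma_growth * sqrt(time_s)
  c(a = cfg$sigma_a0_mm * g, b = cfg$sigma_b0_mm * g)
}

# Analytic field value at arbitrary (fractional) 0-based pixel
# coordinates; vectorised over points. Matches simulate_field() exactly at
# integer coordinates.
field_value_analytic <- function(cfg, time_s, x_px, y_px) {
  sig <- field_sigmas_mm(cfg, time_s)
  ramp <- 1 - exp(-time_s / cfg$tau_s)
  ctr <- field_center_px(cfg)
  dirv <- cfg$needle_axis["shaft", ] - cfg$needle_axis["tip", ]
  dirv <- dirv / sqrt(sum(dirv^2))
  x <- (x_px - ctr["x"]) * cfg$mm_per_px
  y <- (y_px - ctr["y"]) * cfg$mm_per_px
  u <- x * dirv[1] + y * dirv[2]
  v <- -x * dirv[2] + y * dirv[1]
  amp <- (cfg$peak_temp_C - cfg$baseline_temp_C) * ramp
  cfg$baseline_temp_C + amp * exp(-(u^2 / sig[1]^2 + v^2 / sig[2]^2))
}

# Bilinear interpolation of the gridded field at probe coordinates,
# computed from the four surrounding pixel centres without materialising
# the whole grid.
field_bilinear_at <- function(cfg, time_s, x_px, y_px) {
  nc <- cfg$grid_width_px; nr <- cfg$grid_height_px
  if (any(x_px < 0 | x_px > nc - 1 | y_px < 0 | y_px > nr - 1)) {
    stop_domain("probe coordinates outside the grid")
  }
  x0 <- pmin(floor(x_px), nc - 2); y0 <- pmin(floor(y_px), nr - 2)
  fx <- x_px - x0; fy <- y_px - y0
  v00 <- field_value_analytic(cfg, time_s, x0, y0)
  v01 <- field_value_analytic(cfg, time_s, x0 + 1, y0)
  v10 <- field_value_analytic(cfg, time_s, x0, y0 + 1)
  v11 <- field_value_analytic(cfg, time_s, x0 + 1, y0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Semi-axes of an isotherm of the analytic field
#'
#' Solves the elliptical Gaussian for the contour `T = threshold_C`.
#'
#' @param cfg a [sim_config()].
#' @param time_s time since ablation start.
#' @param threshold_C isotherm temperature (default 54).
#' @return named vector `c(u = , v = )` of semi-axes in mm, or `c(0, 0)`
#'   if the field never reaches the threshold at that time.
#' @export
isotherm_semiaxes_mm <- function(cfg, time_s, threshold_C = 54) {
  amp <- (cfg$peak_temp_C - cfg$baseline_temp_C) * (1 - exp(-time_s / cfg$tau_s))
  excess <- threshold_C - cfg$baseline_temp_C
  if (amp <= excess) return(c(u = 0, v = 0))
  sig <- field_sigmas_mm(cfg, time_s)
  L <- sqrt(log(amp / excess))
  c(u = unname(sig[1]) * L, v = unname(sig[2]) * L)
}

#' Hyperechoic ellipse of the simulated case
#'
#' The renderer's microbubble cloud fills an ellipse concentric with the
#' 54 degC isotherm, `kappa(t)` times larger, with
#' `kappa(t) = kappa_end + (kappa_start - kappa_end) * exp(-t / kappa_tau_s)`.
#' This reproduces the clinical observation that the bright hyperechoic
#' region overshoots the coagulation zone early in the ablation and
#' converges toward it as heating continues.
#'
#' @param cfg a [sim_config()].
#' @param time_s time since ablation start.
#' @return list with `a` (major diameter, mm), `b` (half the minor
#'   diameter, mm), `semiaxes_mm` (u/v semi-axes), and `center_px`.
#'   `a` and `b` follow the caliper convention used when measuring the
#'   hyperechoic ellipse on frozen B-mode images, so the ellipse area is
#'   `pi * a * b / 2`.
#' @export
hyperechoic_ellipse <- function(cfg, time_s) {
  iso <- isotherm_semiaxes_mm(cfg, time_s, threshold_C = 54)
  kap <- cfg$kappa_end +
    (cfg$kappa_start - cfg$kappa_end) * exp(-time_s / cfg$kappa_tau_s)
  semi <- kap * iso
  list(a = 2 * unname(semi["u"]), b = unname(semi["v"]),
       semiaxes_mm = semi, center_px = field_center_px(cfg))
}

#' Pixel mask of the hyperechoic ellipse
#'
#' @inheritParams hyperechoic_ellipse
#' @return logical matrix of the grid; all-`FALSE` while the field is
#'   everywhere below 54 degC.
#' @export
hyperechoic_mask <- function(cfg, time_s) {
  ell <- hyperechoic_ellipse(cfg, time_s)
  mask_ellipse(cfg, ell$semiaxes_mm)
}

mask_ellipse <- function(cfg, semi_mm) {
  out <- matrix(FALSE, cfg$grid_height_px, cfg$grid_width_px)
  if (any(semi_mm <= 0)) return(out)
  ctr <- field_center_px(cfg)
  dirv <- cfg$needle_axis["shaft", ] - cfg$needle_axis["tip", ]
  dirv <- dirv / sqrt(sum(dirv^2))
  x <- (seq_len(cfg$grid_width_px) - 1 - ctr["x"]) * cfg$mm_per_px
  y <- (seq_len(cfg$grid_height_px) - 1 - ctr["y"]) * cfg$mm_per_px
  xm <- matrix(x, cfg$grid_height_px, cfg$grid_width_px, byrow = TRUE)
  ym <- matrix(y, cfg$grid_height_px, cfg$grid_width_px)
  u <- xm * dirv[1] + ym * dirv[2]
  v <- -xm * dirv[2] + ym * dirv[1]
  (u / semi_mm[1])^2 + (v / semi_mm[2])^2 <= 1
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("temperature_field: %d x %d px at t = %g s, range %.1f-%.1f degC\n",
              nrow(x$values), ncol(x$values), x$time_s,
              min(x$values), max(x$values)))
  invisible(x)
}
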