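#' Render one B-mode frame from a temperature field
#'
#' Produces an 8-bit grayscale speckle image whose texture drifts with
#' temperature in the directions observed during tissue heating:
#'
#' * the per-pixel mean intensity is a saturating increasing function of
#'   local temperature (coagulated tissue is brighter),
#' * zero-mean Rayleigh-derived speckle is added with a gain that falls
#'   linearly in the normalised temperature
#'   `theta = (T - baseline) / (peak - baseline)`, so patch variance, mean
#'   absolute deviation and co-occurrence cluster prominence fall while
#'   the patch minimum rises with temperature,
#' * once any tissue exceeds `bubble_temp_C` (60 degC), Poisson-placed
#'   Gaussian bright blobs (microbubbles) fill the hyperechoic ellipse,
#'   which strictly contains the 54 degC isotherm and converges toward it
#'   over time.
#'
#' The result is clipped to `[0, 255]` and rounded to integers.
#'
#' @param field a [simulate_field()] result (its `time_s` drives the
#'   bubble schedule).
#' @param cfg the [sim_config()] that produced the field.
#' @param seed optional integer; when supplied the frame is rendered under
#'   its own temporary RNG state, otherwise the current RNG stream is
#'   consumed (as [generate_case()] does for frame-to-frame independence).
#' @return integer matrix in `[0, 255]`, same shape as the field.
#' @export
render_frame <- function(field, cfg, seed = NULL) {
  stopifnot(inherits(field, "temperature_field"), inherits(cfg, "sim_config"))
  if (!all(dim(field$values) == c(cfg$grid_height_px, cfg$grid_width_px))) {
    stop_domain("field shape does not match the configured grid")
  }
  if (!is.null(seed)) {
    return(with_seed(seed, render_frame(field, cfg, seed = NULL)))
  }
  tv <- field$values
  theta <- pmin(pmax((tv - cfg$baseline_temp_C) /
                       (cfg$peak_temp_C - cfg$baseline_temp_C), 0), 1)
  mu <- cfg$mean_floor + cfg$mean_gain * (1 - exp(-cfg$mean_rate * theta))
  gain <- cfg$speckle_gain * (1 - cfg$speckle_decay * theta)
  img <- mu
  if (cfg$speckle_gain > 0) {
    # Rayleigh-family (Weibull) speckle: raising the unit Rayleigh draw to
    # the exponent e in (0.5, 2] sweeps the envelope statistics from
    # pre-Rayleigh (heavy-tailed, sparse scatterers: cold tissue) toward
    # post-Rayleigh (tight, dense scatterers: coagulated tissue). The
    # variate is standardised per pixel, so the speckle is zero-mean with
    # sd equal to `gain * sd(Rayleigh(1))` everywhere.
    e <- cfg$speckle_shape_cold -
      (cfg$speckle_shape_cold - cfg$speckle_shape_hot) * theta
    x <- rrayleigh(length(tv))^e
    m <- 2^(e / 2) * gamma(1 + e / 2)
    v <- 2^e * (gamma(1 + e) - gamma(1 + e / 2)^2)
    img <- img + gain * RAYLEIGH_SD * (x - m) / sqrt(v)
  }
  if (cfg$bubble_amp > 0 && any(tv >= cfg$bubble_temp_C)) {
    img <- img + bubble_layer(cfg, field$time_s)
  }
  m <- matrix(as.integer(round(pmin(pmax(img, 0), 255))),
              nrow(tv), ncol(tv))
  m
}

# Microbubble brightness layer: Poisson-placed Gaussian blobs uniformly
# covering the hyperechoic ellipse, with density ramping up over time.
bubble_layer <- function(cfg, time_s) {
  ell <- hyperechoic_ellipse(cfg, time_s)
  semi <- ell$semiaxes_mm
  out <- matrix(0, cfg$grid_height_px, cfg$grid_width_px)
  if (any(semi <= 0)) return(out)
  area_mm2 <- pi * semi[1] * semi[2]
  lambda <- cfg$bubble_rate_mm2 * area_mm2 * (1 - exp(-time_s / cfg$kappa_tau_s))
  n <- stats::rpois(1, lambda)
  if (n == 0) return(out)

  # uniform points in the unit disc, mapped onto the ellipse
  r <- sqrt(stats::runif(n)); phi <- stats::runif(n, 0, 2 * pi)
  eu <- r * cos(phi) * semi[1]; ev <- r * sin(phi) * semi[2]
  dirv <- cfg$needle_axis["shaft", ] - cfg$needle_axis["tip", ]
  dirv <- dirv / sqrt(sum(dirv^2))
  ctr <- ell$center_px
  bx <- ctr["x"] + (eu * dirv[1] - ev * dirv[2]) / cfg$mm_per_px
  by <- ctr["y"] + (eu * dirv[2] + ev * dirv[1]) / cfg$mm_per_px

  sig_px <- cfg$bubble_sigma_mm / cfg$mm_per_px
  half <- ceiling(3 * sig_px)
  nr <- nrow(out); nc <- ncol(out)
  ker_off <- -half:half
  ker <- exp(-outer(ker_off^2, ker_off^2, "+") / (2 * sig_px^2))
  for (k in seq_len(n)) {
    r0 <- round(by[k]) + 1; c0 <- round(bx[k]) + 1
    rr <- (r0 - half):(r0 + half); cc <- (c0 - half):(c0 + half)
    rok <- rr >= 1 & rr <= nr; cok <- cc >= 1 & cc <= nc
    out[rr[rok], cc[cok]] <- out[rr[rok], cc[cok]] +
      cfg$bubble_amp * ker[rok, cok]
  }
  out
}

#' Speckle variance of baseline (unheated) tissue
#'
#' The variance of the rendered intensity where `T = baseline`, i.e.
#' `(speckle_gain * sd(Rayleigh(1)))^2`. Useful for checking the renderer's
#' noise model.
#'
#' @param cfg a [sim_config()].
#' @return numeric scalar (gray-level^2).
#' @export
cold_speckle_variance <- function(cfg) {
  (cfg$speckle_gain^2) * (4 - pi) / 2
}

#' Sample the thermocouple probe log
#'
#' Generates the 7-channel temperature log at `temp_rate_hz`, on the
#' thermometer clock: the log starts `preheat_s` before the ablation does
#' (readings at baseline during warm-up) and covers
#' `[0, preheat_s + duration_s)`. Each reading is the bilinear
#' interpolation of the ground-truth field at the probe's pixel
#' coordinates plus zero-mean Gaussian noise of sd `probe_noise_sd_C`.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed; default uses the current RNG stream.
#' @return an object of class `temperature_log`: list with `times_s`,
#'   `values_C` (n x 7 matrix) and `channel_ids` (101:107, mapped to probe
#'   indices 1..7).
#' @export
sample_probes <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) {
    return(with_seed(seed, sample_probes(cfg, seed = NULL)))
  }
  dt <- 1 / cfg$temp_rate_hz
  times <- seq(0, cfg$preheat_s + cfg$duration_s - dt, by = dt)
  vals <- matrix(cfg$baseline_temp_C, length(times), 7)
  for (i in seq_along(times)) {
    t_abl <- times[i] - cfg$preheat_s
    if (t_abl >= 0) {
      vals[i, ] <- field_bilinear_at(cfg, min(t_abl, cfg$duration_s),
                                     cfg$probe_points[, "x"],
                                     cfg$probe_points[, "y"])
    }
  }
  if (cfg$probe_noise_sd_C > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), 0, cfg$probe_noise_sd_C),
                          nrow(vals), ncol(vals))
  }
  temperature_log(times, vals)
}

#' Construct a temperature log object
#'
#' @param times_s monotone increasing sampling times (s).
#' @param values_C numeric matrix, one column per channel.
#' @param channel_ids thermometer channel ids (default 101:107).
#' @return object of class `temperature_log`.
#' @export
temperature_log <- function(times_s, values_C, channel_ids = 101:107) {
  values_C <- as.matrix(values_C)
  stopifnot(length(times_s) == nrow(values_C),
            length(channel_ids) == ncol(values_C),
            !is.unsorted(times_s, strictly = TRUE))
  structure(list(times_s = as.numeric(times_s), values_C = values_C,
                 channel_ids = as.integer(channel_ids)),
            class = "temperature_log")
}

#' @export
print.temperature_log <- function(x, ...) {
  cat(sprintf("temperature_log: %d channels x %d readings, t in [%g, %g] s\n",
              ncol(x$values_C), nrow(x$values_C),
              min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' @export
as.data.frame.temperature_log <- function(x, ...) {
  d <- data.frame(time_s = x$times_s)
  for (j in seq_along(x$channel_ids)) {
    d[[paste0("ch", x$channel_ids[j])]] <- x$values_C[, j]
  }
  d
}
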