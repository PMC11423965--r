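test_that("temperature field follows the closed-form heating model", {
  cfg <- small_cfg(duration_s = 180, power_preset = "P20")

  f0 <- simulate_field(cfg, 0)
  expect_true(all(abs(f0$values - cfg$baseline_temp_C) < 0.1))

  # value at the antenna centre after 180 s, against the formula by hand
  f <- simulate_field(cfg, 180)
  r <- 1 - exp(-180 / cfg$tau_s)
  expected <- cfg$peak_temp_C * r + cfg$baseline_temp_C * (1 - r)
  ctr <- echotherm:::field_center_px(cfg)
  at_ctr <- f$values[round(ctr["y"]) + 1, round(ctr["x"]) + 1]
  expect_lt(abs(at_ctr - expected), 1)

  # far tail is at baseline: a corner pixel is > 10 sigma from the needle
  expect_lt(abs(f$values[1, ncol(f$values)] - cfg$baseline_temp_C), 0.5)

  # energy sanity over the whole ablation
  for (t in c(0, 20, 90, 180)) {
    ft <- simulate_field(cfg, t)
    expect_lte(max(ft$values), cfg$peak_temp_C)
    expect_gte(min(ft$values), cfg$baseline_temp_C - 1)
  }

  expect_error(simulate_field(cfg, -1), "time_s")
  expect_error(simulate_field(cfg, 181), "time_s")
})

test_that("renderer reproduces its speckle noise model on uniform tissue", {
  cfg <- small_cfg()
  f0 <- simulate_field(cfg, 0)
  vars <- vapply(1:10, function(k) {
    stats::var(as.numeric(render_frame(f0, cfg, seed = k)))
  }, numeric(1))
  expect_lt(abs(mean(vars) - cold_speckle_variance(cfg)) /
              cold_speckle_variance(cfg), 0.2)
})

test_that("hot tissue renders brighter, more uniform texture than cold", {
  cfg <- sim_config(grid_height_px = 64L, grid_width_px = 128L,
                    duration_s = 10, rng_seed = 1L,
                    probe_points = cbind(x = seq(35, 95, by = 10),
                                         y = rep(50, 7)),
                    needle_axis = rbind(c(10, 20), c(118, 20)))
  cold <- structure(list(values = matrix(37, 64, 128), time_s = 0,
                         mm_per_px = 0.1), class = "temperature_field")
  hotv <- matrix(37, 64, 128); hotv[, 65:128] <- 80
  hot <- structure(list(values = hotv, time_s = 0, mm_per_px = 0.1),
                   class = "temperature_field")
  wins <- 0L
  for (k in 1:100) {
    ic <- render_frame(cold, cfg, seed = k)[1:64, 65:128]
    ih <- render_frame(hot, cfg, seed = k)[1:64, 65:128]
    ok <- mean(ih) > mean(ic) && min(ih) > min(ic) &&
      stats::var(as.numeric(ih)) < stats::var(as.numeric(ic)) &&
      mean(abs(ih - mean(ih))) < mean(abs(ic - mean(ic)))
    wins <- wins + ok
  }
  expect_gte(wins, 95)
})

test_that("zero speckle gain gives the deterministic mean map", {
  cfg <- small_cfg()
  cfg$speckle_gain <- 0
  f <- simulate_field(cfg, 5)  # everywhere below bubble onset
  i1 <- render_frame(f, cfg, seed = 1)
  i2 <- render_frame(f, cfg, seed = 2)
  expect_identical(i1, i2)
  theta <- pmin(pmax((f$values - 37) / (85 - 37), 0), 1)
  mu <- cfg$mean_floor + cfg$mean_gain * (1 - exp(-cfg$mean_rate * theta))
  expect_true(all(abs(i1 - round(mu)) <= 1))
})

test_that("probe log matches the field and the acquisition clock", {
  cfg <- small_cfg(duration_s = 10)
  log <- sample_probes(cfg, seed = 3)
  expect_s3_class(log, "temperature_log")
  expect_equal(ncol(log$values_C), 7)
  expect_equal(nrow(log$values_C), (cfg$preheat_s + 10) * 2)
  expect_equal(log$channel_ids, 101:107)

  # noiseless log equals bilinear interpolation of the field exactly
  cfg0 <- small_cfg(duration_s = 10)
  cfg0$probe_noise_sd_C <- 0
  log0 <- sample_probes(cfg0, seed = 3)
  t_abl <- 5 - cfg0$preheat_s  # log row at t = 5 s is still preheat
  i <- which(abs(log0$times_s - (cfg0$preheat_s + 4)) < 1e-9)
  f <- simulate_field(cfg0, 4)
  expected <- echotherm:::bilinear_at(f$values, cfg0$probe_points[, "x"],
                                      cfg0$probe_points[, "y"])
  expect_equal(unname(log0$values_C[i, ]), unname(expected),
               tolerance = 1e-12)
  # preheat rows are at baseline
  expect_true(all(log0$values_C[log0$times_s < cfg0$preheat_s, ] == 37))
})

test_that("case generation is deterministic and obeys its contracts", {
  cfg <- small_cfg(duration_s = 2, rng_seed = 99L)
  c1 <- generate_case(cfg)
  c2 <- generate_case(cfg)
  expect_identical(c1$frames$frames, c2$frames$frames)
  expect_identical(c1$probe_log$values_C, c2$probe_log$values_C)
  expect_equal(n_frames(c1$frames), floor(2 * 12))

  # a 10 s case at 12 fps yields 120 frames
  c3 <- generate_case(small_cfg(duration_s = 10, rng_seed = 5L))
  expect_equal(n_frames(c3$frames), 120)

  # higher power burns a strictly larger 54 degC isotherm
  a15 <- generate_case(small_cfg(duration_s = 2, power_preset = "P15",
                                 rng_seed = 4L))
  a20 <- generate_case(small_cfg(duration_s = 2, power_preset = "P20",
                                 rng_seed = 4L))
  cfg15 <- small_cfg(duration_s = 180, power_preset = "P15")
  cfg20 <- small_cfg(duration_s = 180, power_preset = "P20")
  area <- function(cfg) sum(simulate_field(cfg, 180)$values >= 54) *
    cfg$mm_per_px^2
  expect_gt(area(cfg20), area(cfg15))
})

test_that("hyperechoic ellipse always contains the 54 degC isotherm", {
  cfg <- small_cfg(duration_s = 180, power_preset = "P20")
  for (t in c(5, 15, 40, 90, 180)) {
    iso_area <- sum(simulate_field(cfg, t)$values >= 54)
    hyper_area <- sum(hyperechoic_mask(cfg, t))
    expect_gte(hyper_area, iso_area)
  }
  # and it converges toward the isotherm over time
  ratio <- function(t) {
    semi <- hyperechoic_ellipse(cfg, t)$semiaxes_mm
    iso <- isotherm_semiaxes_mm(cfg, t)
    semi[["u"]] / iso[["u"]]
  }
  expect_gt(ratio(20), ratio(180))
})

test_that("on-disk case layout round-trips through read_case", {
  cfg <- small_cfg(duration_s = 2, rng_seed = 12L)
  dir <- withr::local_tempdir()
  case <- generate_case(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "frames.csv")))
  expect_true(file.exists(file.path(dir, "probe_log.csv")))
  expect_true(file.exists(file.path(dir, "markup.yaml")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  rc <- read_case(dir)
  expect_equal(n_frames(rc$frames), n_frames(case$frames))
  expect_equal(get_frame(rc$frames, 3), get_frame(case$frames, 3))
  expect_equal(rc$probe_log$values_C, case$probe_log$values_C,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rc$markup$probe_points, case$markup$probe_points,
               ignore_attr = TRUE)
  expect_equal(rc$truth$isotherm_area_mm2, case$truth$isotherm_area_mm2)
})

test_that("probe layout below the needle axis is enforced", {
  expect_error(sim_config(probe_points = cbind(x = rep(300, 7),
                                               y = rep(10, 7))),
               "below the needle")
  expect_error(sim_config(probe_points = cbind(x = rep(-5, 7),
                                               y = rep(300, 7))),
               "inside the grid")
  expect_error(sim_config(duration_s = 10.3), "integer")
  expect_error(sim_config(baseline_temp_C = 90, peak_temp_C = 85),
               "baseline")
})
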