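make_log <- function(from, to, rate = 2, nch = 7, base = 40) {
  times <- seq(from, to - 1 / rate, by = 1 / rate)
  temperature_log(times, matrix(base + seq_along(times), length(times),
                                nch))
}

dummy_frames <- function(n, fps = 12, val = 0) {
  frame_sequence((seq_len(n) - 1) / fps,
                 lapply(seq_len(n), function(i) matrix(val, 4, 4)))
}

test_that("preheat trimming keeps exactly the ablation window", {
  log <- make_log(0, 200)
  tr <- trim_preheat(log)
  expect_equal(nrow(tr$values_C), 360)
  expect_equal(tr$times_s[1], 0)
  expect_equal(max(tr$times_s), 179.5)
  # values are the original readings from t = 15 on
  expect_equal(tr$values_C[1, 1], log$values_C[which(log$times_s == 15), 1])

  # a log covering exactly [15, 195) trims to itself, re-zeroed
  log2 <- make_log(15, 195)
  tr2 <- trim_preheat(log2)
  expect_equal(nrow(tr2$values_C), nrow(log2$values_C))
  expect_equal(tr2$values_C, log2$values_C)
  expect_equal(tr2$times_s, log2$times_s - 15)

  # too-short log names the missing span
  expect_error(trim_preheat(make_log(0, 100)), "missing")
})

test_that("keyframe extraction keeps the first and sixth frame per second", {
  # 1 s at 12 fps: within-second indices 0 and 5
  kf <- extract_keyframes(dummy_frames(12), fps = 12)
  expect_equal(n_frames(kf), 2)
  expect_equal(kf$times_s, c(0, 5) / 12)

  # 2 s at 6 fps: 4 keyframes
  kf6 <- extract_keyframes(dummy_frames(12, fps = 6), fps = 6)
  expect_equal(n_frames(kf6), 4)
  expect_equal(kf6$times_s, c(0, 5, 6, 11) / 6)

  # 180 s at 12 fps: 360 keyframes at 2 per second
  kf180 <- extract_keyframes(dummy_frames(2160), fps = 12)
  expect_equal(n_frames(kf180), 360)

  # partial trailing second warns and contributes what it has
  expect_warning(kf_p <- extract_keyframes(dummy_frames(12 + 3), fps = 12),
                 "fewer than 6")
  expect_equal(n_frames(kf_p), 3)

  expect_error(extract_keyframes(dummy_frames(10, fps = 5), fps = 5),
               "fps >= 6")
})

test_that("ROI cutting uses the half-open centred window convention", {
  frame <- outer(0:127, 0:127, function(r, c) r * 1000 + c)
  roi <- cut_roi(frame, c(64, 64), 64)
  expect_equal(dim(roi), c(64, 64))
  # rows/cols [32, 96) in 0-based coordinates
  expect_equal(roi[1, 1], 32 * 1000 + 32)
  expect_equal(roi[64, 64], 95 * 1000 + 95)

  expect_error(cut_roi(frame, c(10, 10), 64), "exceeds")

  cst <- cut_roi(matrix(7, 70, 70), c(35, 35), 64)
  expect_true(all(cst == 7))

  # translation consistency: shifted frame, shifted centre, same patch
  big <- outer(0:199, 0:199, function(r, c) (r * 7 + c * 13) %% 251)
  p1 <- cut_roi(big, c(80, 90), 64)
  shifted <- big[11:200, 6:200]
  p2 <- cut_roi(shifted, c(80 - 5, 90 - 10), 64)
  expect_identical(p1, p2)
})

test_that("sample pairing matches frames to nearest readings", {
  mk <- list(probe_points = cbind(x = 32, y = 32))
  fr <- frame_sequence(0.41, list(matrix(1, 64, 64)))
  log <- temperature_log(seq(0, 5, by = 0.5), matrix(50 + 0:10, 11, 1),
                         channel_ids = 101)
  s <- pair_samples(fr, log, mk)
  expect_equal(length(s$patch), 1)
  expect_equal(s$temperature_C, 50 + 1)  # nearest reading is t = 0.5

  # a 0.5 s offset exceeds the 0.25 s tolerance
  log_off <- temperature_log(seq(0.91, 5, by = 1), matrix(1, 5, 1),
                             channel_ids = 101)
  expect_error(pair_samples(fr, log_off, mk), "no temperature reading")
})

test_that("simulated case ingest yields the full sample accounting", {
  cfg <- small_cfg(duration_s = 20, rng_seed = 21L)
  case <- generate_case(cfg)
  s <- ingest_case(case)
  expect_equal(length(s$patch), 20 * 2 * 7)
  expect_true(all(vapply(s$patch, function(p) all(dim(p) == 64), logical(1))))
  expect_true(all(is.finite(s$temperature_C)))

  # sample temperatures stay within 3 noise sd of the ground-truth field
  # at the matched reading instant (99% of samples)
  truth <- echotherm:::field_bilinear_at
  errs <- vapply(seq_along(s$patch), function(i) {
    p <- s$point_index[i]
    t_read <- s$time_s[i]  # frame time; reading within 0.25 s
    t_near <- round(t_read * 2) / 2
    gt <- truth(cfg, t_near, cfg$probe_points[p, "x"],
                cfg$probe_points[p, "y"])
    abs(s$temperature_C[i] - gt)
  }, numeric(1))
  expect_lte(stats::quantile(errs, 0.99), 3 * cfg$probe_noise_sd_C)
})

test_that("dataset splitting respects the 4:1:1 contract", {
  fake <- structure(list(patch = vector("list", 2520),
                         point_index = rep(1:7, 360),
                         time_s = rep(1:360, each = 7),
                         temperature_C = rnorm(2520),
                         case_id = rep(sprintf("c%d", 1:6), length.out = 2520)),
                    class = "roi_samples")
  d <- split_dataset(fake, seed = 3L)
  expect_equal(as.vector(table(d$split)), c(1680, 420, 420))

  # deterministic
  d2 <- split_dataset(fake, seed = 3L)
  expect_identical(d$split, d2$split)
  d3 <- split_dataset(fake, seed = 4L)
  expect_false(identical(d$split, d3$split))

  # union of splits is everything, no sample in two splits
  expect_false(anyNA(d$split))
  expect_equal(length(d$split), 2520)

  # minimal input
  tiny <- structure(list(patch = vector("list", 6), point_index = 1:6,
                         time_s = 1:6, temperature_C = 1:6,
                         case_id = rep("a", 6)),
                    class = "roi_samples")
  expect_equal(as.vector(table(split_dataset(tiny, seed = 1)$split)),
               c(4, 1, 1))
  expect_error(split_dataset(structure(list(patch = list()),
                                       class = "roi_samples")),
               "at least 6")

  # per-case mode never splits a case across sets
  dc <- split_dataset(fake, seed = 5L, grouping = "per_case")
  tab <- table(fake$case_id, dc$split)
  expect_true(all(rowSums(tab > 0) == 1))
})
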