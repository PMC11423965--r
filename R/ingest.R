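#' Trim a thermocouple log to the ablation window
#'
#' The thermometers start logging before the ablation does (warm-up of the
#' multi-channel acquisition); the ablation and the ultrasound recording
#' begin `start_s` seconds into the log. This keeps the readings with
#' `start_s <= t < end_s` and re-zeroes the clock so the ablation starts
#' at `t = 0`. With the standard window `[15, 195)` and a 2 Hz log this
#' retains 360 readings per channel.
#'
#' @param log a [temperature_log()].
#' @param start_s,end_s window bounds in log time (defaults 15 and 195).
#' @return a `temperature_log` on the ablation clock.
#' @export
trim_preheat <- function(log, start_s = 15, end_s = 195) {
  stopifnot(inherits(log, "temperature_log"), end_s > start_s)
  dt <- stats::median(diff(log$times_s))
  if (min(log$times_s) > start_s || max(log$times_s) < end_s - dt - 1e-9) {
    stop_domain(sprintf(
      "log covers [%g, %g] s but the window [%g, %g) s is required; missing [%g, %g) s",
      min(log$times_s), max(log$times_s), start_s, end_s,
      max(log$times_s) + dt, end_s))
  }
  keep <- log$times_s >= start_s - 1e-9 & log$times_s < end_s - 1e-9
  temperature_log(log$times_s[keep] - start_s,
                  log$values_C[keep, , drop = FALSE],
                  log$channel_ids)
}

#' Extract keyframes matched to the temperature sampling clock
#'
#' Keeps the first and the sixth frame of each whole second of video
#' (within-second indices 1 and 6, 1-based), giving two keyframes per
#' second to match the 2 Hz thermocouple log. A 180 s sequence at 12 fps
#' yields 360 keyframes. Timestamps are preserved, so at 12 fps keyframes
#' are spaced 5/12 s then 7/12 s apart; pairing with the log is done by
#' nearest timestamp, not by assuming uniform spacing.
#'
#' @param seq a [frame_sequence()].
#' @param fps integer frames per second of the source video (>= 6).
#' @return a `frame_sequence` containing only the keyframes.
#' @export
extract_keyframes <- function(seq, fps = 12L) {
  stopifnot(inherits(seq, "frame_sequence"))
  fps <- as.integer(fps)
  if (fps < 6L) stop_domain("keyframe extraction requires fps >= 6")
  idx0 <- seq_len(n_frames(seq)) - 1L
  within <- idx0 %% fps
  keep <- within == 0L | within == 5L
  # a trailing partial second may not reach its sixth frame
  last_sec <- max(idx0) %/% fps
  if (sum(keep & idx0 %/% fps == last_sec) < 2L) {
    warning("final second has fewer than 6 frames; it contributes only ",
            sum(keep & idx0 %/% fps == last_sec), " keyframe(s)")
  }
  frame_sequence(seq$times_s[keep],
                 if (is.character(seq$frames)) seq$frames[keep]
                 else seq$frames[keep])
}

#' Cut a square region of interest around a marked point
#'
#' Returns the `size` x `size` window centred on `center_xy` (0-based,
#' x = column, y = row, origin top-left). An even-sized window cannot be
#' symmetric about one pixel; the half-open convention
#' `[c - size/2, c + size/2)` is used on each axis. Windows that do not
#' fit inside the frame raise an error (no padding: training ROIs must be
#' genuine tissue).
#'
#' @param frame numeric/integer matrix.
#' @param center_xy numeric length-2 vector `c(x, y)`, 0-based.
#' @param size window side in pixels (default 64).
#' @return `size` x `size` matrix.
#' @export
cut_roi <- function(frame, center_xy, size = 64L) {
  size <- as.integer(size)
  h <- size %/% 2L
  cx <- round(center_xy[[1]]); cy <- round(center_xy[[2]])
  r0 <- cy - h; c0 <- cx - h  # 0-based window origin
  if (r0 < 0 || c0 < 0 || r0 + size > nrow(frame) || c0 + size > ncol(frame)) {
    stop_domain(sprintf(
      "ROI [%d, %d) x [%d, %d) exceeds the %d x %d frame",
      r0, r0 + size, c0, c0 + size, nrow(frame), ncol(frame)))
  }
  frame[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size)]
}

#' Pair keyframe ROIs with temperature readings
#'
#' For every keyframe and every one of the 7 marked points, cuts the
#' 64 x 64 ROI and attaches the temperature reading of the corresponding
#' channel whose timestamp is nearest to the frame's (within
#' `tolerance_s`). 360 keyframes x 7 points give 2520 temperature-ROI
#' sample pairs per case.
#'
#' @param keyframes a [frame_sequence()] of keyframes (ablation clock).
#' @param log a trimmed [temperature_log()] (ablation clock).
#' @param markup list with `probe_points` (7 x 2 matrix, x/y 0-based) as
#'   stored in an [generate_case()] case.
#' @param case_id identifier attached to every sample.
#' @param roi_size ROI side in pixels (default 64).
#' @param tolerance_s maximum |frame time - reading time| (default 0.25 s,
#'   half the 2 Hz period).
#' @return object of class `roi_samples`: list with `patch` (list of
#'   matrices), and vectors `point_index`, `time_s`, `temperature_C`,
#'   `case_id`, optionally `split`.
#' @export
pair_samples <- function(keyframes, log, markup, case_id = "case",
                         roi_size = 64L, tolerance_s = 0.25) {
  stopifnot(inherits(keyframes, "frame_sequence"),
            inherits(log, "temperature_log"))
  nk <- n_frames(keyframes)
  np <- nrow(markup$probe_points)
  nearest <- vapply(keyframes$times_s, function(t) {
    which.min(abs(log$times_s - t))
  }, integer(1))
  gap <- abs(log$times_s[nearest] - keyframes$times_s)
  if (any(gap > tolerance_s + 1e-9)) {
    orphans <- keyframes$times_s[gap > tolerance_s + 1e-9]
    stop_domain("no temperature reading within ", tolerance_s,
                " s of frame time(s): ",
                paste(utils::head(orphans, 5), collapse = ", "),
                if (length(orphans) > 5) " ...")
  }
  n <- nk * np
  patches <- vector("list", n)
  point_index <- integer(n); time_s <- numeric(n); temp <- numeric(n)
  k <- 0L
  for (i in seq_len(nk)) {
    fr <- get_frame(keyframes, i)
    for (p in seq_len(np)) {
      k <- k + 1L
      patches[[k]] <- cut_roi(fr, markup$probe_points[p, ], roi_size)
      point_index[k] <- p
      time_s[k] <- keyframes$times_s[i]
      temp[k] <- log$values_C[nearest[i], p]
    }
  }
  structure(list(patch = patches, point_index = point_index,
                 time_s = time_s, temperature_C = temp,
                 case_id = rep(case_id, n)),
            class = "roi_samples")
}

#' @export
print.roi_samples <- function(x, ...) {
  cat(sprintf("roi_samples: %d temperature-ROI pairs from %d case(s), %.1f-%.1f degC\n",
              length(x$patch), length(unique(x$case_id)),
              min(x$temperature_C), max(x$temperature_C)))
  if (!is.null(x$split)) print(table(x$split))
  invisible(x)
}

#' Combine roi_samples objects
#' @param ... `roi_samples` objects.
#' @export
c.roi_samples <- function(...) {
  parts <- list(...)
  structure(list(
    patch = do.call(c, lapply(parts, `[[`, "patch")),
    point_index = do.call(c, lapply(parts, `[[`, "point_index")),
    time_s = do.call(c, lapply(parts, `[[`, "time_s")),
    temperature_C = do.call(c, lapply(parts, `[[`, "temperature_C")),
    case_id = do.call(c, lapply(parts, `[[`, "case_id"))
  ), class = "roi_samples")
}

#' Split samples into training / validation / test sets
#'
#' Random 4:1:1 split (largest-remainder rounding, so sizes are within one
#' sample of the exact ratio), deterministic for a fixed seed.
#' `grouping = "per_sample"` shuffles individual samples — the procedure
#' used when all frames of an ablation may appear in any split.
#' `grouping = "per_case"` assigns whole cases to splits, which avoids
#' leaking frames of one ablation across splits and is the honest mode for
#' generalisation claims.
#'
#' @param samples a `roi_samples` object.
#' @param ratio integer ratio, default `c(4, 1, 1)`.
#' @param seed integer seed recorded in the result.
#' @param grouping `"per_sample"` (default) or `"per_case"`.
#' @return `samples` with a `split` factor (levels train/val/test) and
#'   attribute `split_seed`.
#' @export
split_dataset <- function(samples, ratio = c(4, 1, 1), seed = 1L,
                          grouping = c("per_sample", "per_case")) {
  grouping <- match.arg(grouping)
  n <- length(samples$patch)
  if (n < 6L) stop_domain("at least 6 samples are required for a 4:1:1 split")
  labels <- c("train", "val", "test")
  sizes <- largest_remainder(n, ratio)
  if (grouping == "per_sample") {
    lab <- rep(labels, times = sizes)
    ord <- with_seed(seed, sample.int(n))
    split <- factor(lab[order(ord)], levels = labels)
  } else {
    cases <- unique(samples$case_id)
    csz <- largest_remainder(length(cases), ratio)
    clab <- rep(labels, times = csz)
    cord <- with_seed(seed, sample(cases))
    case_split <- stats::setNames(clab, cord)
    split <- factor(case_split[samples$case_id], levels = labels)
  }
  samples$split <- split
  attr(samples, "split_seed") <- as.integer(seed)
  attr(samples, "grouping") <- grouping
  samples
}

largest_remainder <- function(n, ratio) {
  exact <- n * ratio / sum(ratio)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Ingest one case into temperature-ROI samples
#'
#' Convenience wrapper chaining [trim_preheat()], [extract_keyframes()]
#' and [pair_samples()] on a synthetic or on-disk case. The trim window is
#' derived from the case's preheat and duration (the standard acquisition
#' gives `[15, 195)`).
#'
#' @param case an `ablation_case`.
#' @param roi_size ROI side (default 64).
#' @return a `roi_samples` object.
#' @export
ingest_case <- function(case, roi_size = 64L) {
  cfg <- case$config
  preheat <- if (!is.null(cfg)) cfg$preheat_s else 15
  duration <- if (!is.null(cfg)) cfg$duration_s else 180
  fps <- if (!is.null(cfg)) cfg$frame_rate_fps else 12
  log <- trim_preheat(case$probe_log, preheat, preheat + duration)
  kf <- extract_keyframes(case$frames, fps)
  pair_samples(kf, log, case$markup, case_id = case$case_id,
               roi_size = roi_size)
}
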