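#' Frame sequences
#'
#' A frame sequence pairs per-frame timestamps with 8-bit grayscale
#' frames, held either in memory (list of integer matrices) or on disk
#' (vector of PNG paths, loaded on access).
#'
#' @param times_s strictly increasing frame timestamps (s).
#' @param frames list of integer matrices, or character vector of PNG
#'   paths of the same length.
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(times_s, frames) {
  stopifnot(length(times_s) == length(frames),
            !is.unsorted(times_s, strictly = TRUE))
  structure(list(times_s = as.numeric(times_s), frames = frames),
            class = "frame_sequence")
}

#' @rdname frame_sequence
#' @param seq a `frame_sequence`.
#' @export
n_frames <- function(seq) length(seq$times_s)

#' @rdname frame_sequence
#' @param i frame index (1-based).
#' @return `get_frame()`: numeric matrix with values in `[0, 255]`.
#' @export
get_frame <- function(seq, i) {
  f <- seq$frames[[i]]
  if (is.character(f)) {
    f <- round(png::readPNG(f) * 255)
    if (length(dim(f)) == 3L) f <- f[, , 1]
  }
  f
}

#' @export
print.frame_sequence <- function(x, ...) {
  where <- if (is.character(x$frames)) "file-backed" else "in-memory"
  cat(sprintf("frame_sequence: %d frames (%s), t in [%g, %g] s\n",
              n_frames(x), where, min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Generate a complete synthetic ablation case
#'
#' Runs the simulator end to end: renders `floor(duration_s *
#' frame_rate_fps)` speckle frames on the ablation clock, samples the
#' 7-channel thermocouple log on the thermometer clock (including the
#' warm-up prefix), and records the ground truth (final-field 54 degC
#' isotherm area and the hyperechoic ellipse diameters). All randomness
#' flows from `cfg$rng_seed`; the same configuration reproduces the case
#' bit for bit.
#'
#' When `out_dir` is given the case is also written to disk:
#' `frames/frame_%05d.png` plus `frames.csv` (frame_index, time_s),
#' `probe_log.csv` (time_s, ch101..ch107), `markup.yaml` (probe pixel
#' coordinates, needle axis, mm_per_px; 0-based x/y, origin top-left),
#' `truth.json` and `truth_final_field.tiff` (16-bit, degC x 100), and
#' frames are kept file-backed rather than in memory.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory to write the case to.
#' @param case_id identifier recorded in the case (default derived from
#'   preset and seed).
#' @return object of class `ablation_case`: list with `config`, `frames`
#'   (a [frame_sequence()]), `probe_log`, `markup`, `truth`, `case_id`,
#'   `dir`. Ground-truth fields are not materialised: use
#'   [simulate_field()] with the stored config.
#' @export
generate_case <- function(cfg, out_dir = NULL,
                          case_id = sprintf("%s_seed%d", cfg$power_preset,
                                            cfg$rng_seed)) {
  stopifnot(inherits(cfg, "sim_config"))
  n_fr <- floor(cfg$duration_s * cfg$frame_rate_fps)
  times <- (seq_len(n_fr) - 1) / cfg$frame_rate_fps

  to_disk <- !is.null(out_dir)
  if (to_disk) {
    frame_dir <- file.path(out_dir, "frames")
    if (!dir.exists(frame_dir) && !dir.create(frame_dir, recursive = TRUE)) {
      stop_domain("cannot create output directory: ", out_dir)
    }
  }

  frames <- vector(if (to_disk) "character" else "list", n_fr)
  log <- NULL
  with_seed(cfg$rng_seed, {
    for (i in seq_len(n_fr)) {
      fld <- simulate_field(cfg, times[i])
      img <- render_frame(fld, cfg)
      if (to_disk) {
        p <- file.path(out_dir, "frames", sprintf("frame_%05d.png", i - 1))
        png::writePNG(img / 255, p)
        frames[i] <- p
      } else {
        frames[[i]] <- img
      }
    }
    log <- sample_probes(cfg)
  })

  final <- simulate_field(cfg, cfg$duration_s)
  ell <- hyperechoic_ellipse(cfg, cfg$duration_s)
  truth <- list(
    isotherm_area_mm2 = sum(final$values >= 54) * cfg$mm_per_px^2,
    hyperechoic_a_mm = ell$a,
    hyperechoic_b_mm = ell$b,
    threshold_C = 54
  )
  markup <- list(
    probe_points = cfg$probe_points,
    needle_axis = cfg$needle_axis,
    mm_per_px = cfg$mm_per_px,
    channel_map = stats::setNames(1:7, paste0("ch", 101:107))
  )
  case <- structure(list(
    config = cfg,
    frames = frame_sequence(times, frames),
    probe_log = log,
    markup = markup,
    truth = truth,
    case_id = case_id,
    dir = out_dir
  ), class = "ablation_case")

  if (to_disk) write_case_metadata(case, out_dir, final)
  case
}

write_case_metadata <- function(case, out_dir, final_field) {
  utils::write.csv(
    data.frame(frame_index = seq_len(n_frames(case$frames)) - 1,
               time_s = case$frames$times_s),
    file.path(out_dir, "frames.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(case$probe_log),
                   file.path(out_dir, "probe_log.csv"), row.names = FALSE)
  mk <- case$markup
  yaml::write_yaml(list(
    case_id = case$case_id,
    mm_per_px = mk$mm_per_px,
    coordinate_convention = "0-based, x = column, y = row, origin top-left",
    probe_points = lapply(seq_len(nrow(mk$probe_points)), function(i) {
      list(point_index = i, channel = 100 + i,
           x = mk$probe_points[i, "x"], y = mk$probe_points[i, "y"])
    }),
    needle_axis = list(
      tip = as.list(mk$needle_axis["tip", ]),
      shaft = as.list(mk$needle_axis["shaft", ]))
  ), file.path(out_dir, "markup.yaml"))
  jsonlite::write_json(case$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  # 16-bit TIFF of the final temperature field, degC x 100
  tiff::writeTIFF(pmin(final_field$values * 100 / 65535, 1),
                  file.path(out_dir, "truth_final_field.tiff"),
                  bits.per.sample = 16L)
  invisible(NULL)
}

#' Read a synthetic case back from disk
#'
#' Reads the on-disk layout written by [generate_case()] (or any
#' directory with `frames/` + `frames.csv` + `probe_log.csv` +
#' `markup.yaml`, so exported real data can be dropped in). Frames stay
#' file-backed.
#'
#' @param dir case directory.
#' @return an `ablation_case` (with `config = NULL` and `truth` only if
#'   `truth.json` is present).
#' @export
read_case <- function(dir) {
  man <- utils::read.csv(file.path(dir, "frames.csv"))
  paths <- file.path(dir, "frames", sprintf("frame_%05d.png", man$frame_index))
  pl <- utils::read.csv(file.path(dir, "probe_log.csv"))
  chn <- grep("^ch", names(pl), value = TRUE)
  mk <- yaml::read_yaml(file.path(dir, "markup.yaml"))
  pp <- t(vapply(mk$probe_points, function(p) c(p$x, p$y), numeric(2)))
  colnames(pp) <- c("x", "y")
  na <- rbind(unlist(mk$needle_axis$tip), unlist(mk$needle_axis$shaft))
  dimnames(na) <- list(c("tip", "shaft"), c("x", "y"))
  truth_path <- file.path(dir, "truth.json")
  structure(list(
    config = NULL,
    frames = frame_sequence(man$time_s, paths),
    probe_log = temperature_log(pl$time_s, as.matrix(pl[chn]),
                                as.integer(sub("ch", "", chn))),
    markup = list(probe_points = pp, needle_axis = na,
                  mm_per_px = mk$mm_per_px,
                  channel_map = stats::setNames(1:7, paste0("ch", 101:107))),
    truth = if (file.exists(truth_path)) jsonlite::read_json(truth_path),
    case_id = if (!is.null(mk$case_id)) mk$case_id else basename(dir),
    dir = dir
  ), class = "ablation_case")
}

#' @export
print.ablation_case <- function(x, ...) {
  cat(sprintf("ablation_case '%s': %d frames, %d probe readings\n",
              x$case_id, n_frames(x$frames), nrow(x$probe_log$values_C)))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: 54 degC isotherm %.1f mm^2, hyperechoic a=%.1f b=%.1f mm\n",
                x$truth$isotherm_area_mm2, x$truth$hyperechoic_a_mm,
                x$truth$hyperechoic_b_mm))
  }
  invisible(x)
}
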