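#' Area of the hyperechoic ellipse from caliper measurements
#'
#' The hyperechoic region is measured on the frozen B-mode image as the
#' major diameter `a` and half the minor diameter `b` of its largest
#' cross-section; its area is `S_v = 1/2 * a * b * pi`.
#'
#' @param a major diameter (mm).
#' @param b half the minor diameter (mm).
#' @return area in mm^2.
#' @export
ellipse_area <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop_domain("diameters must be positive")
  0.5 * a * b * pi
}

#' Relative area error against the gold standard
#'
#' `ER = |x - S_r| / S_r`; the closer to 0, the smaller the error of the
#' area estimate `x` (hyperechoic `S_v` or predicted `S_p`) against the
#' gold-standard coagulation area `S_r`.
#'
#' @param x estimated area (mm^2); vectorised.
#' @param S_r gold-standard coagulation area (mm^2), > 0.
#' @return error ratio (dimensionless).
#' @export
error_ratio <- function(x, S_r) {
  if (any(S_r <= 0)) stop_domain("gold-standard area must be positive")
  abs(x - S_r) / S_r
}

#' Per-case coagulation-area report
#'
#' Assembles, for one ablation case, the gold-standard area `S_r`, the
#' hyperechoic estimate `S_v` (given directly in mm^2 or as caliper
#' measurements `c(a =, b =)`), the machine-learning estimate `S_p`
#' (given directly or as a `heat_map` to be thresholded), and both error
#' ratios.
#'
#' @param S_r gold-standard coagulation area (mm^2).
#' @param hyperechoic `S_v` in mm^2, or a named vector/list with `a` and
#'   `b` (mm) to be converted by [ellipse_area()].
#' @param ml `S_p` in mm^2, or a `heat_map` thresholded at `threshold_C`.
#' @param threshold_C isotherm for heat-map thresholding (default 54).
#' @param case_id case identifier.
#' @return one-row data frame of class `area_report`: `case_id`, `S_r`,
#'   `S_v`, `S_p`, `ER_hyper`, `ER_ml`.
#' @export
case_report <- function(S_r, hyperechoic, ml, threshold_C = 54,
                        case_id = "case") {
  S_v <- if (is.numeric(hyperechoic) && length(hyperechoic) == 1 &&
             is.null(names(hyperechoic))) {
    hyperechoic
  } else {
    ellipse_area(hyperechoic[["a"]], hyperechoic[["b"]])
  }
  S_p <- if (inherits(ml, "heat_map")) {
    threshold_area(ml, threshold_C)
  } else {
    ml
  }
  out <- data.frame(case_id = case_id, S_r = S_r, S_v = S_v, S_p = S_p,
                    ER_hyper = error_ratio(S_v, S_r),
                    ER_ml = error_ratio(S_p, S_r),
                    stringsAsFactors = FALSE)
  class(out) <- c("area_report", "data.frame")
  out
}

#' Group summary of error ratios
#'
#' Arithmetic mean of the per-case error ratios of both methods over a
#' power group.
#'
#' @param reports an `area_report` data frame (one or more rows, e.g.
#'   `rbind`ed [case_report()]s).
#' @return list with `mean_er_hyper`, `mean_er_ml` and `n`.
#' @export
group_summary <- function(reports) {
  if (NROW(reports) == 0) stop_domain("no case reports given")
  list(mean_er_hyper = mean(reports$ER_hyper),
       mean_er_ml = mean(reports$ER_ml),
       n = NROW(reports))
}

#' Build area reports from a measurement table
#'
#' Reads a CSV (or takes a data frame) with columns `gold_mm2`,
#' `hyperechoic_mm2`, `ml_mm2` — one row per case — and computes the
#' error ratios of both methods.
#'
#' @param table path to a CSV file, or a data frame.
#' @return an `area_report` data frame with one row per case.
#' @export
area_reports_from_table <- function(table) {
  d <- if (is.character(table)) utils::read.csv(table) else table
  need <- c("gold_mm2", "hyperechoic_mm2", "ml_mm2")
  if (!all(need %in% names(d))) {
    stop_domain("table must have columns: ", paste(need, collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    case_report(d$gold_mm2[i], d$hyperechoic_mm2[i], d$ml_mm2[i],
                case_id = if (!is.null(d$case_id)) d$case_id[i]
                          else sprintf("case%02d", i))
  }))
  out
}

#' Bundled coagulation-area measurements
#'
#' Reference per-case area measurements from an ex vivo porcine-liver
#' microwave-ablation study (five cases per power group, 180 s heating):
#' gold-standard coagulation area traced on the cut specimen, hyperechoic
#' area measured on the B-mode image, and the area predicted by the
#' texture-regression method at the 54 degC isotherm, all in mm^2. The
#' `er_*_printed` columns carry the error ratios as originally reported
#' (3 decimal places), for cross-checking.
#'
#' @param power `"15W"` or `"20W"`.
#' @return data frame with columns `gold_mm2`, `hyperechoic_mm2`,
#'   `ml_mm2`, `er_hyperechoic_printed`, `er_ml_printed`.
#' @export
ablation_area_tables <- function(power = c("15W", "20W")) {
  power <- match.arg(power)
  path <- system.file("extdata",
                      sprintf("coagulation_areas_%s.csv", power),
                      package = "echotherm", mustWork = TRUE)
  utils::read.csv(path)
}
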