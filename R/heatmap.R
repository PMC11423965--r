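#' Predict a per-pixel temperature heat map
#'
#' Slides a `window` x `window` block over the target region: for each
#' output pixel the block centred there is cut (the frame is
#' reflect-padded so the map covers the whole region), the model's
#' selected texture features are computed and normalised with the model's
#' training statistics, and the forest predicts the centre temperature.
#' With `stride > 1` predictions are computed on a subgrid and upsampled
#' by nearest neighbour to full region resolution. Only the feature
#' families containing selected features are computed, which keeps
#' per-pixel prediction tractable.
#'
#' @param frame grayscale frame (matrix, 0-255).
#' @param model a [fit_temperature_model()] result.
#' @param region target region `list(x0 = , y0 = , width = , height = )`
#'   in 0-based frame pixels.
#' @param mm_per_px pixel spacing recorded in the map.
#' @param window block side (default 64).
#' @param stride prediction grid step in pixels (default 1 = per-pixel).
#' @param Ng quantisation levels, matching training (default 32).
#' @return object of class `heat_map`: list with `values` (matrix, degC,
#'   `height` x `width`), `origin` (x0, y0), `mm_per_px`, `stride`.
#' @export
predict_heatmap <- function(frame, model, region, mm_per_px,
                            window = 64L, stride = 1L, Ng = 32L) {
  stopifnot(inherits(model, "temp_model"))
  frame <- as.matrix(frame)
  x0 <- region$x0; y0 <- region$y0
  w <- region$width; h <- region$height
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(frame) || y0 + h > nrow(frame)) {
    stop_domain("region exceeds the frame")
  }
  half <- window %/% 2L
  pad <- reflect_pad(frame, half)
  families <- unique(sub("_.*$", "", model$selected))

  gy <- seq(0L, h - 1L, by = stride)
  gx <- seq(0L, w - 1L, by = stride)
  feats <- matrix(NA_real_, length(gy) * length(gx),
                  length(feature_names(families)))
  k <- 0L
  for (iy in gy) {
    for (ix in gx) {
      k <- k + 1L
      # centre in padded coordinates (0-based): original + half
      cy <- y0 + iy + half; cx <- x0 + ix + half
      block <- pad[(cy - half + 1):(cy + half), (cx - half + 1):(cx + half)]
      feats[k, ] <- extract_features(block, mm_per_px, Ng,
                                     families = families)
    }
  }
  colnames(feats) <- feature_names(families)
  pred <- predict(model, feats)
  sub <- matrix(pred, length(gy), length(gx), byrow = TRUE)
  values <- sub[pmin(floor((seq_len(h) - 1) / stride) + 1, length(gy)),
                pmin(floor((seq_len(w) - 1) / stride) + 1, length(gx)),
                drop = FALSE]
  structure(list(values = values, origin = c(x0 = x0, y0 = y0),
                 mm_per_px = mm_per_px, stride = stride),
            class = "heat_map")
}

reflect_pad <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  m[ri, ci]
}

#' Area of the supra-threshold zone of a heat map
#'
#' Counts map pixels at or above `threshold_C` (the lethal 54 degC
#' isotherm by default) and converts to mm^2. All supra-threshold pixels
#' are summed by default — spurious hot islands away from the ablation
#' centre are deliberately kept, mirroring how the pixel area is defined;
#' `largest_component = TRUE` optionally restricts to the largest
#' 8-connected component.
#'
#' @param map a `heat_map`.
#' @param threshold_C isotherm threshold (default 54; comparison is `>=`).
#' @param largest_component keep only the largest connected component
#'   (default FALSE).
#' @return area in mm^2.
#' @export
threshold_area <- function(map, threshold_C = 54, largest_component = FALSE) {
  stopifnot(inherits(map, "heat_map"))
  mask <- map$values >= threshold_C
  if (!any(mask)) return(0)
  if (largest_component) {
    z <- label_zones(matrix(as.integer(mask), nrow(mask), ncol(mask)))
    lab <- matrix(z$labels, nrow(mask), ncol(mask))
    in_mask <- z$level == 1L
    sizes <- tabulate(z$labels)
    sizes[!in_mask] <- 0L
    mask <- lab == which.max(sizes)
  }
  sum(mask) * map$mm_per_px^2
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("heat_map: %d x %d px at %.3g mm/px (stride %d), %.1f-%.1f degC\n",
              nrow(x$values), ncol(x$values), x$mm_per_px, x$stride,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.heat_map <- function(x, threshold_C = NULL, ...) {
  v <- t(x$values)[, rev(seq_len(nrow(x$values))), drop = FALSE]
  graphics::image(v, col = grDevices::hcl.colors(64, "Inferno"),
                  axes = FALSE, asp = nrow(x$values) / ncol(x$values),
                  main = "Predicted temperature (degC)", ...)
  if (!is.null(threshold_C)) {
    graphics::contour(v, levels = threshold_C, add = TRUE, col = "white",
                      lwd = 2, drawlabels = TRUE)
  }
  invisible(x)
}

#' Write a heat map to disk
#'
#' Writes the predicted map as a 16-bit TIFF (degC x 100) and the
#' supra-threshold mask as a PNG.
#'
#' @param map a `heat_map`.
#' @param path base path (without extension).
#' @param threshold_C isotherm for the mask (default 54).
#' @return invisibly, the paths written.
#' @export
write_heatmap <- function(map, path, threshold_C = 54) {
  tif <- paste0(path, ".tiff")
  tiff::writeTIFF(pmin(pmax(map$values, 0) * 100 / 65535, 1), tif,
                  bits.per.sample = 16L)
  msk <- paste0(path, "_mask.png")
  png::writePNG((map$values >= threshold_C) * 1, msk)
  invisible(c(tif, msk))
}
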