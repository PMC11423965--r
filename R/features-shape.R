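#' 2-D shape features of a binary mask
#'
#' The 10 IBSI 2-D shape descriptors. Surface area and perimeter follow
#' the marching-squares mesh of the 0.5-isocontour (so a rasterised disc
#' scores a sphericity close to 1, while an axis-aligned square scores
#' `sqrt(pi)/2`); axis lengths derive from the eigenvalues of the
#' pixel-coordinate covariance (`4 * sqrt(lambda)`). On the full square
#' ROI used by the temperature pipeline these features are constant by
#' construction; they are computed anyway so the battery keeps its 104
#' entries, and they are expected to receive near-zero importance.
#'
#' @param mask logical (or 0/1) matrix; must contain at least one `TRUE`.
#' @param mm_per_px pixel spacing (default 1).
#' @return named numeric vector of length 10.
#' @export
shape2d_features <- function(mask, mm_per_px = 1) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop_domain("empty mask")
  s <- mm_per_px
  ms <- marching_squares(mask)
  area <- ms$area * s^2
  perim <- ms$perimeter * s

  idx <- which(mask, arr.ind = TRUE)
  # physical coordinates of pixel centres
  xy <- cbind(x = (idx[, "col"] - 1) * s, y = (idx[, "row"] - 1) * s)
  if (nrow(xy) > 1) {
    ev <- sort(eigen(stats::cov(xy), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0)
  }
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1

  bnd <- boundary_pixels(mask)
  bxy <- cbind((bnd[, "col"] - 1) * s, (bnd[, "row"] - 1) * s)
  hull <- grDevices::chull(bxy)
  hxy <- bxy[hull, , drop = FALSE]
  maxdiam <- if (nrow(hxy) > 1) max(stats::dist(hxy)) else 0

  sphericity <- if (perim > 0) 2 * sqrt(pi * area) / perim else 1

  c(shape2d_MeshSurface = area,
    shape2d_PixelSurface = sum(mask) * s^2,
    shape2d_Perimeter = perim,
    shape2d_PerimeterSurfaceRatio = if (area > 0) perim / area else 0,
    shape2d_Sphericity = sphericity,
    shape2d_SphericalDisproportion = if (sphericity > 0) 1 / sphericity else 0,
    shape2d_MaximumDiameter = maxdiam,
    shape2d_MajorAxisLength = major,
    shape2d_MinorAxisLength = minor,
    shape2d_Elongation = elong)
}

# Marching-squares area and contour length of the 0.5-isocontour of a
# binary mask (pixel units). Each 2x2 cell of the zero-padded mask
# contributes by its corner configuration; ambiguous diagonal cases are
# resolved as two separate corners.
marching_squares <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  tl <- m[-nr, -nc]; tr <- m[-nr, -1]; bl <- m[-1, -nc]; br <- m[-1, -1]
  code <- tl + 2L * tr + 4L * bl + 8L * br
  ncorn <- tl + tr + bl + br
  diagpair <- (code == 6L | code == 9L)
  area_tab <- c(0, 1 / 8, 1 / 2, 7 / 8, 1)          # by corner count 0..4
  area <- sum(area_tab[ncorn[!diagpair] + 1L]) + sum(diagpair) * (1 / 4)
  len1 <- sqrt(2) / 2
  per_tab <- c(0, len1, 1, len1, 0)
  perimeter <- sum(per_tab[ncorn[!diagpair] + 1L]) + sum(diagpair) * sqrt(2)
  list(area = area, perimeter = perimeter)
}

boundary_pixels <- function(mask) {
  interior <- shift_matrix(mask, 1, 0, FALSE) &
    shift_matrix(mask, -1, 0, FALSE) &
    shift_matrix(mask, 0, 1, FALSE) &
    shift_matrix(mask, 0, -1, FALSE)
  which(mask & !interior, arr.ind = TRUE)
}
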