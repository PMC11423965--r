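#' Gray-level size-zone matrix features
#'
#' Zones are maximal 8-connected sets of pixels sharing one gray level;
#' the 16 IBSI GLSZM statistics are computed from the (level, zone size)
#' counts. Rotation-invariant by construction (no directions).
#'
#' @param q a [quantize()]d patch.
#' @return named numeric vector of length 16.
#' @export
glszm_features <- function(q) {
  stopifnot(inherits(q, "quantized_patch"))
  z <- label_zones(q$levels)
  zsize <- tabulate(z$labels)
  zlev <- z$level
  np <- length(q$levels)
  nz <- length(zsize)
  p <- 1 / nz
  mu_i <- mean(zlev)
  mu_s <- mean(zsize)

  gi <- tabulate(zlev, q$Ng)          # zones per gray level
  sj <- tabulate(zsize)               # zones per size
  # joint counts for zone entropy
  joint <- table(factor(paste(zlev, zsize)))
  pj <- as.numeric(joint) / nz

  out <- c(
    SmallAreaEmphasis = mean(1 / zsize^2),
    LargeAreaEmphasis = mean(zsize^2),
    GrayLevelNonUniformity = sum(gi^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gi^2) / nz^2,
    SizeZoneNonUniformity = sum(sj^2) / nz,
    SizeZoneNonUniformityNormalized = sum(sj^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = mean((zlev - mu_i)^2),
    ZoneVariance = mean((zsize - mu_s)^2),
    ZoneEntropy = -sum(xlog2(pj) * pj),
    LowGrayLevelZoneEmphasis = mean(1 / zlev^2),
    HighGrayLevelZoneEmphasis = mean(zlev^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (zlev^2 * zsize^2)),
    SmallAreaHighGrayLevelEmphasis = mean(zlev^2 / zsize^2),
    LargeAreaLowGrayLevelEmphasis = mean(zsize^2 / zlev^2),
    LargeAreaHighGrayLevelEmphasis = mean(zlev^2 * zsize^2)
  )
  names(out) <- paste0("glszm_", names(out))
  out
}

# 8-connected same-level zone labelling by iterative minimum-label
# propagation: every pixel repeatedly takes the smallest label among its
# same-level neighbours until a fixed point; exact on convergence.
label_zones <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev)
  lab <- matrix(seq_along(lev), nr, nc)
  nbrs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
               c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    new <- lab
    for (d in nbrs) {
      ls <- shift_matrix(lab, d[1], d[2], NA)
      qs <- shift_matrix(lev, d[1], d[2], NA)
      ok <- !is.na(qs) & qs == lev & ls < new
      new[ok] <- ls[ok]
    }
    if (all(new == lab)) break
    lab <- new
  }
  ids <- sort(unique(as.vector(lab)))
  labels <- match(as.vector(lab), ids)
  list(labels = labels, level = lev[ids])
}
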