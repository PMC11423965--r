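#' Gray-level dependence matrix features
#'
#' A pixel's dependence is the number of its 8-neighbours (distance 1)
#' whose gray level differs by at most `alpha` (default 0, i.e. equal),
#' plus one for the pixel itself, so dependence sizes run from 1 to 9 and
#' the emphasis denominators never vanish. Every pixel contributes one
#' entry to the (gray level, dependence size) matrix; the 14 IBSI GLDM
#' statistics follow.
#'
#' @param q a [quantize()]d patch.
#' @param alpha similarity tolerance in quantised levels (default 0).
#' @return named numeric vector of length 14.
#' @export
gldm_features <- function(q, alpha = 0L) {
  stopifnot(inherits(q, "quantized_patch"))
  lev <- q$levels
  np <- length(lev)
  dep <- dependence_size(lev, alpha)
  jmax <- 9L
  D <- matrix(tabulate((as.vector(lev) - 1L) * jmax + as.vector(dep),
                       q$Ng * jmax),
              q$Ng, jmax, byrow = TRUE)
  i <- seq_len(q$Ng); j <- seq_len(jmax)
  gi <- rowSums(D); dj <- colSums(D)
  p <- D / np
  mu_i <- sum(i * gi) / np
  mu_j <- sum(j * dj) / np
  ii <- matrix(i, q$Ng, jmax)
  jj <- matrix(j, q$Ng, jmax, byrow = TRUE)

  out <- c(
    SmallDependenceEmphasis = sum(dj / j^2) / np,
    LargeDependenceEmphasis = sum(dj * j^2) / np,
    GrayLevelNonUniformity = sum(gi^2) / np,
    DependenceNonUniformity = sum(dj^2) / np,
    DependenceNonUniformityNormalized = sum(dj^2) / np^2,
    GrayLevelVariance = sum(p * (ii - mu_i)^2),
    DependenceVariance = sum(p * (jj - mu_j)^2),
    DependenceEntropy = -sum(xlog2(p) * p),
    LowGrayLevelEmphasis = sum(gi / i^2) / np,
    HighGrayLevelEmphasis = sum(gi * i^2) / np,
    SmallDependenceLowGrayLevelEmphasis = sum(D / (ii^2 * jj^2)) / np,
    SmallDependenceHighGrayLevelEmphasis = sum(D * ii^2 / jj^2) / np,
    LargeDependenceLowGrayLevelEmphasis = sum(D * jj^2 / ii^2) / np,
    LargeDependenceHighGrayLevelEmphasis = sum(D * ii^2 * jj^2) / np
  )
  names(out) <- paste0("gldm_", names(out))
  out
}

# Dependence size per pixel: 1 + number of 8-neighbours within alpha.
dependence_size <- function(lev, alpha = 0L) {
  nbrs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
               c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  dep <- matrix(1L, nrow(lev), ncol(lev))
  for (d in nbrs) {
    v <- shift_matrix(lev, d[1], d[2], NA)
    ok <- !is.na(v) & abs(v - lev) <= alpha
    dep <- dep + ok
  }
  dep
}
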