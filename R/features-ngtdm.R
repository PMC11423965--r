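#' Neighbouring gray-tone difference matrix features
#'
#' For each gray level i, `s_i` accumulates the absolute difference
#' between pixels of level i and the mean of their valid 8-neighbours
#' (radius 1; border pixels use the neighbours that exist). The five IBSI
#' statistics follow. Degenerate conventions: Coarseness is capped at 1e6
#' when its denominator vanishes; Contrast, Busyness and Strength are 0
#' when undefined.
#'
#' @param q a [quantize()]d patch.
#' @return named numeric vector of length 5.
#' @export
ngtdm_features <- function(q) {
  stopifnot(inherits(q, "quantized_patch"))
  lev <- q$levels
  nbr <- neighbour_mean(lev)
  np <- length(lev)
  dev <- abs(lev - nbr)
  s <- as.vector(rowsum(as.vector(dev), as.vector(lev)))
  present <- sort(unique(as.vector(lev)))
  n_i <- tabulate(lev, q$Ng)[present]
  p_i <- n_i / np
  i <- present
  ngp <- length(present)

  psum <- sum(p_i * s)
  coarseness <- if (psum > 0) 1 / psum else 1e6

  if (ngp > 1) {
    dif2 <- outer(i, i, function(a, b) (a - b)^2)
    pp <- outer(p_i, p_i)
    contrast <- sum(pp * dif2) / (ngp * (ngp - 1)) * sum(s) / np
    ipi <- i * p_i
    busy_den <- sum(abs(outer(ipi, ipi, "-")))
    busyness <- if (busy_den > 0) psum / busy_den else 0
    pis <- p_i * s
    complexity <- sum(abs(outer(i, i, "-")) *
                        outer(pis, pis, "+") / outer(p_i, p_i, "+")) / np
    strength <- if (sum(s) > 0) sum(outer(p_i, p_i, "+") * dif2) / sum(s) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }

  c(ngtdm_Coarseness = coarseness,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

# Mean of the valid 8-neighbours of every pixel.
neighbour_mean <- function(lev) {
  nbrs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
               c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  tot <- matrix(0, nrow(lev), ncol(lev))
  cnt <- matrix(0, nrow(lev), ncol(lev))
  for (d in nbrs) {
    v <- shift_matrix(lev, d[1], d[2], NA)
    ok <- !is.na(v)
    tot[ok] <- tot[ok] + v[ok]
    cnt <- cnt + ok
  }
  tot / cnt
}
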