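#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` after seeding R's RNG with `seed`, then restores whatever
#' global RNG state existed before the call, so package functions never
#' perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Rayleigh deviates with unit scale
#'
#' @param n number of draws.
#' @return numeric vector; mean sqrt(pi/2), sd sqrt((4-pi)/2).
#' @keywords internal
rrayleigh <- function(n) sqrt(-2 * log(runif(n)))

# Mean and sd of a unit-scale Rayleigh variate.
RAYLEIGH_MEAN <- sqrt(pi / 2)
RAYLEIGH_SD <- sqrt((4 - pi) / 2)

#' Bilinear interpolation of a matrix at fractional pixel coordinates
#'
#' Coordinates are 0-based with x = column, y = row, origin at the
#' top-left pixel centre (the convention used throughout the package).
#'
#' @param m numeric matrix.
#' @param x,y numeric vectors of equal length.
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_at <- function(m, x, y) {
  stopifnot(length(x) == length(y))
  nr <- nrow(m); nc <- ncol(m)
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1)) {
    stop("coordinates outside the grid", call. = FALSE)
  }
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1; j <- x0 + 1
  v00 <- m[cbind(i, j)];     v01 <- m[cbind(i, j + 1)]
  v10 <- m[cbind(i + 1, j)]; v11 <- m[cbind(i + 1, j + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Shift a matrix by (dr, dc), filling vacated cells
#' @keywords internal
shift_matrix <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r <- max(1, 1 + dr):min(nr, nr + dr)
  c <- max(1, 1 + dc):min(nc, nc + dc)
  out[r, c] <- m[r - dr, c - dc]
  out
}

# log2 with the 0 * log(0) = 0 convention used by entropy formulas
xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

stop_domain <- function(...) stop(..., call. = FALSE)
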