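#' Gray-level run-length matrix features
#'
#' Runs of identical gray level are counted along the four 2-D directions
#' (0, 45, 90, 135 degrees); the 16 IBSI GLRLM statistics are computed per
#' direction and averaged feature-wise.
#'
#' @param q a [quantize()]d patch.
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(q) {
  stopifnot(inherits(q, "quantized_patch"))
  lev <- q$levels
  np <- length(lev)
  maxlen <- max(dim(lev))
  per_dir <- lapply(run_directions(lev), function(lines) {
    rlm <- run_length_matrix(lines, q$Ng, maxlen)
    glrlm_stats_one(rlm, np)
  })
  out <- Reduce(`+`, per_dir) / length(per_dir)
  names(out) <- paste0("glrlm_", names(out))
  out
}

# The image decomposed into contiguous lines along each direction:
# rows (0 deg), anti-diagonals (45), columns (90), main diagonals (135).
run_directions <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev)
  rows <- split(t(lev), rep(seq_len(nr), each = nc))
  cols <- split(lev, rep(seq_len(nc), each = nr))
  rr <- matrix(seq_len(nr), nr, nc); cc <- matrix(seq_len(nc), nr, nc,
                                                  byrow = TRUE)
  anti <- split(lev, rr + cc)       # along (-1, +1)
  main <- split(lev, rr - cc)       # along (+1, +1)
  list(rows = rows, anti = anti, cols = cols, main = main)
}

# Ng x maxlen matrix of run counts from a list of lines.
run_length_matrix <- function(lines, Ng, maxlen) {
  joined <- unlist(lapply(lines, function(l) c(l, NA_integer_)),
                   use.names = FALSE)
  r <- rle(joined)
  keep <- !is.na(r$values)
  lv <- r$values[keep]; ln <- r$lengths[keep]
  matrix(tabulate((lv - 1L) * maxlen + ln, Ng * maxlen),
         Ng, maxlen, byrow = TRUE)
}

glrlm_stats_one <- function(R, np) {
  nr_tot <- sum(R)
  i <- seq_len(nrow(R)); r <- seq_len(ncol(R))
  gi <- rowSums(R)   # per gray level
  rj <- colSums(R)   # per run length
  p <- R / nr_tot
  mu_i <- sum(i * gi) / nr_tot
  mu_r <- sum(r * rj) / nr_tot
  ii <- matrix(i, length(i), length(r))
  rr <- matrix(r, length(i), length(r), byrow = TRUE)

  c(ShortRunEmphasis = sum(rj / r^2) / nr_tot,
    LongRunEmphasis = sum(rj * r^2) / nr_tot,
    GrayLevelNonUniformity = sum(gi^2) / nr_tot,
    GrayLevelNonUniformityNormalized = sum(gi^2) / nr_tot^2,
    RunLengthNonUniformity = sum(rj^2) / nr_tot,
    RunLengthNonUniformityNormalized = sum(rj^2) / nr_tot^2,
    RunPercentage = nr_tot / np,
    GrayLevelVariance = sum(p * (ii - mu_i)^2),
    RunVariance = sum(p * (rr - mu_r)^2),
    RunEntropy = -sum(xlog2(p) * p),
    LowGrayLevelRunEmphasis = sum(gi / i^2) / nr_tot,
    HighGrayLevelRunEmphasis = sum(gi * i^2) / nr_tot,
    ShortRunLowGrayLevelEmphasis = sum(R / (ii^2 * rr^2)) / nr_tot,
    ShortRunHighGrayLevelEmphasis = sum(R * ii^2 / rr^2) / nr_tot,
    LongRunLowGrayLevelEmphasis = sum(R * rr^2 / ii^2) / nr_tot,
    LongRunHighGrayLevelEmphasis = sum(R * ii^2 * rr^2) / nr_tot)
}
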