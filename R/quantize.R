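#' Quantize a grayscale patch into Ng discrete levels
#'
#' All texture-matrix features operate on discretised gray levels.
#' `fixed_bin_count` (default) maps the patch's own `[min, max]` range
#' into `Ng` equal-width bins, so matrix dimensions are stable across
#' patches with different dynamic ranges; a constant patch maps to a
#' single level 1. `fixed_bin_width` bins absolute intensities with the
#' given width (levels are offset so the minimum falls in level 1).
#'
#' @param patch numeric/integer matrix.
#' @param Ng number of gray levels for `fixed_bin_count` (default 32).
#' @param mode `"fixed_bin_count"` or `"fixed_bin_width"`.
#' @param bin_width bin width for `fixed_bin_width` (default 8 gray
#'   levels).
#' @return object of class `quantized_patch`: list with `levels` (integer
#'   matrix in `1..Ng`), `Ng`, and `original`.
#' @export
quantize <- function(patch, Ng = 32L,
                     mode = c("fixed_bin_count", "fixed_bin_width"),
                     bin_width = 8) {
  mode <- match.arg(mode)
  if (length(patch) == 0) stop_domain("empty patch")
  patch <- as.matrix(patch)
  if (mode == "fixed_bin_count") {
    Ng <- as.integer(Ng)
    if (Ng < 2L) stop_domain("Ng must be at least 2")
    rng <- range(patch)
    if (rng[1] == rng[2]) {
      lev <- matrix(1L, nrow(patch), ncol(patch))
    } else {
      lev <- pmin(Ng, floor((patch - rng[1]) / (rng[2] - rng[1]) * Ng) + 1L)
      lev <- matrix(as.integer(lev), nrow(patch), ncol(patch))
    }
  } else {
    if (bin_width <= 0) stop_domain("bin_width must be positive")
    lev <- floor(patch / bin_width) - floor(min(patch) / bin_width) + 1L
    lev <- matrix(as.integer(lev), nrow(patch), ncol(patch))
    Ng <- max(lev)
  }
  structure(list(levels = lev, Ng = as.integer(Ng), original = patch,
                 mode = mode),
            class = "quantized_patch")
}
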