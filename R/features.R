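#' Canonical feature names of the 104-feature battery
#'
#' The battery concatenates seven families in a fixed, documented order:
#' first-order (19), 2-D shape (10), GLCM (24), GLRLM (16), GLSZM (16),
#' NGTDM (5) and GLDM (14) — 104 features in total. Names are namespaced
#' `family_Feature`. This canonical order is also the tie-break order for
#' feature selection.
#'
#' @param families character vector of families to include (default all
#'   seven, in canonical order).
#' @return character vector of feature names.
#' @export
feature_names <- function(families = FEATURE_FAMILIES) {
  unlist(lapply(families, function(f) feature_name_list()[[f]]),
         use.names = FALSE)
}

#' @rdname feature_names
#' @format `FEATURE_FAMILIES`: the seven family labels in canonical order.
#' @export
FEATURE_FAMILIES <- c("firstorder", "shape2d", "glcm", "glrlm", "glszm",
                      "ngtdm", "gldm")

# Names are derived from the family implementations themselves (computed
# once on a tiny probe patch) so they can never drift out of sync.
feature_name_env <- new.env(parent = emptyenv())
feature_name_list <- function() {
  if (is.null(feature_name_env$names)) {
    blank <- matrix(c(0, 1, 2, 3), 2, 2)
    qb <- quantize(blank, Ng = 2L)
    feature_name_env$names <- list(
      firstorder = names(first_order_features(blank)),
      shape2d = names(shape2d_features(matrix(TRUE, 2, 2))),
      glcm = names(glcm_features(qb)),
      glrlm = names(glrlm_features(qb)),
      glszm = names(glszm_features(qb)),
      ngtdm = names(ngtdm_features(qb)),
      gldm = names(gldm_features(qb))
    )
  }
  feature_name_env$names
}

#' Extract the full texture-feature battery from one ROI
#'
#' Computes all 104 features (or a subset of families) of a grayscale
#' patch. Matrix families share one quantisation (`Ng` fixed-bin-count
#' levels, distance/radius 1). Shape features are computed on the full
#' rectangular ROI mask, where they are constant by design; they are kept
#' so the battery honours its 104-feature contract. All values are finite
#' for any input, including constant patches (see the family pages for
#' the degenerate conventions).
#'
#' @param patch numeric matrix (the 64 x 64 ROI in the standard pipeline).
#' @param mm_per_px pixel spacing (default 1) used by shape features and
#'   first-order TotalEnergy.
#' @param Ng gray levels for quantisation (default 32).
#' @param families families to compute (default all; order is canonical
#'   regardless of the order given).
#' @return named numeric vector (length 104 for the full battery).
#' @export
extract_features <- function(patch, mm_per_px = 1, Ng = 32L,
                             families = FEATURE_FAMILIES) {
  families <- FEATURE_FAMILIES[FEATURE_FAMILIES %in% families]
  if (length(families) == 0) stop_domain("no valid feature family requested")
  need_q <- any(families %in% c("glcm", "glrlm", "glszm", "ngtdm", "gldm"))
  q <- if (need_q) quantize(patch, Ng = Ng)
  parts <- lapply(families, function(f) {
    switch(f,
           firstorder = first_order_features(patch, mm_per_px, Ng),
           shape2d = shape2d_cached(dim(patch), mm_per_px),
           glcm = glcm_features(q),
           glrlm = glrlm_features(q),
           glszm = glszm_features(q),
           ngtdm = ngtdm_features(q),
           gldm = gldm_features(q))
  })
  out <- unlist(parts, use.names = TRUE)
  stopifnot(all(is.finite(out)))
  out
}

# Shape features of the full rectangular ROI depend only on its size and
# spacing; cache them per (dims, spacing).
shape2d_cache_env <- new.env(parent = emptyenv())
shape2d_cached <- function(dims, mm_per_px) {
  key <- paste(dims[1], dims[2], mm_per_px, sep = "_")
  if (is.null(shape2d_cache_env[[key]])) {
    shape2d_cache_env[[key]] <-
      shape2d_features(matrix(TRUE, dims[1], dims[2]), mm_per_px)
  }
  shape2d_cache_env[[key]]
}

#' Feature matrix for a set of ROI samples
#'
#' Applies [extract_features()] to every patch of a `roi_samples` object
#' and returns a data frame with sample metadata followed by the 104
#' feature columns.
#'
#' @param samples a `roi_samples` object (see [pair_samples()]).
#' @param mm_per_px pixel spacing (default 1).
#' @param Ng quantisation levels (default 32).
#' @return data frame: `case_id`, `point_index`, `time_s`,
#'   `temperature_C`, `split` (if present), then one column per feature.
#' @export
feature_table <- function(samples, mm_per_px = 1, Ng = 32L) {
  stopifnot(inherits(samples, "roi_samples"))
  feats <- t(vapply(samples$patch,
                    function(p) extract_features(p, mm_per_px, Ng),
                    numeric(length(feature_names()))))
  meta <- data.frame(case_id = samples$case_id,
                     point_index = samples$point_index,
                     time_s = samples$time_s,
                     temperature_C = samples$temperature_C,
                     stringsAsFactors = FALSE)
  if (!is.null(samples$split)) meta$split <- samples$split
  cbind(meta, as.data.frame(feats))
}

#' Z-score normalisation fitted on the training split
#'
#' @param x numeric matrix or data frame of feature vectors (rows =
#'   samples); only the training split should be passed.
#' @return object of class `feature_normalizer` with per-feature `mean`
#'   and `sd` (floored at 1e-12, so constant features normalise to 0).
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_domain("at least 2 training vectors are required")
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  structure(list(mean = mu, sd = pmax(sd, 1e-12)),
            class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @param stats a `feature_normalizer`.
#' @param newdata matrix/data frame (or single named vector) to normalise;
#'   columns are matched by name when named.
#' @return normalised numeric matrix.
#' @export
apply_normalizer <- function(stats, newdata) {
  stopifnot(inherits(stats, "feature_normalizer"))
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) && !is.null(names(stats$mean))) {
    miss <- setdiff(names(stats$mean), colnames(x))
    if (length(miss) > 0) {
      stop_domain("missing feature column(s): ",
                  paste(utils::head(miss, 5), collapse = ", "))
    }
    x <- x[, names(stats$mean), drop = FALSE]
  }
  sweep(sweep(x, 2, stats$mean, "-"), 2, stats$sd, "/")
}
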