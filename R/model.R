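#' Random-forest configuration for temperature regression
#'
#' @param n_trees number of trees (default 500).
#' @param max_features fraction of features tried at each split (default
#'   1/3, the regression-forest convention).
#' @param min_leaf minimum terminal-node size (default 5).
#' @param seed integer seed; fitting and ranking are deterministic given
#'   it (forests run single-threaded).
#' @return object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500L, max_features = 1 / 3,
                          min_leaf = 5L, seed = 1L) {
  stopifnot(n_trees >= 10, max_features > 0, max_features <= 1,
            min_leaf >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_features = max_features,
                 min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "forest_config")
}

ranger_fit <- function(x, y, cfg) {
  mtry <- max(1L, floor(cfg$max_features * ncol(x)))
  ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = cfg$n_trees, mtry = mtry,
    min.node.size = cfg$min_leaf,
    importance = "impurity",
    seed = cfg$seed, num.threads = 1L
  )
}

#' Rank features by Gini (impurity) importance
#'
#' Fits a regression forest on all features and ranks them by impurity
#' importance — the total variance decrease attributable to each feature
#' over all splits, accumulated across trees. Ties are broken by the
#' canonical feature order so the ranking is fully reproducible. A
#' constant target yields all-zero importances and a warning.
#'
#' @param x feature matrix or data frame (rows = samples), normalised
#'   with training statistics.
#' @param y numeric temperatures (degC).
#' @param config a [forest_config()].
#' @return object of class `importance_ranking`: data frame with columns
#'   `feature`, `importance`, `rank`, in non-increasing importance order.
#' @export
rank_importance <- function(x, y, config = forest_config()) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < 2) stop_domain("too few samples to rank features")
  if (stats::sd(y) == 0) {
    warning("constant target: all importances are zero")
    imp <- stats::setNames(rep(0, ncol(x)), colnames(x))
  } else {
    imp <- ranger_fit(x, y, config)$variable.importance
  }
  canon <- match(names(imp), feature_names())
  canon[is.na(canon)] <- length(feature_names()) + seq_len(sum(is.na(canon)))
  ord <- order(-imp, canon)
  out <- data.frame(feature = names(imp)[ord],
                    importance = unname(imp[ord]),
                    rank = seq_along(imp),
                    stringsAsFactors = FALSE)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Keep the k most important features
#'
#' @param ranking an `importance_ranking` from [rank_importance()].
#' @param k number of features to keep (default 10).
#' @return character vector of k feature names.
#' @export
select_top_k <- function(ranking, k = 10L) {
  stopifnot(inherits(ranking, "importance_ranking"))
  if (k > nrow(ranking)) stop_domain("k exceeds the number of ranked features")
  ranking$feature[seq_len(k)]
}

#' Fit the ultrasound texture temperature model
#'
#' The core estimator: normalises the training features (z-score with
#' training statistics), ranks all features by Gini importance, keeps the
#' top `k` (default 10), and fits a random-forest regression of
#' temperature on the selected features. When a validation set is given,
#' a small grid (`n_trees` in {200, 500} x `min_leaf` in {1, 5}) is
#' scored by validation MAE and the best configuration is kept — the
#' operational form of "model optimisation on the validation set".
#'
#' @param x training feature matrix/data frame (columns named as in
#'   [feature_names()]); raw, not yet normalised.
#' @param y training temperatures (degC).
#' @param k number of features to select (default 10).
#' @param config a [forest_config()] (used as-is when `validation` is
#'   NULL).
#' @param validation optional `list(x = , y = )` held-out set for the
#'   hyperparameter grid.
#' @param power_label optional label of the power group the model was
#'   trained for (e.g. "15W"), stored as metadata.
#' @return object of class `temp_model`: fitted forest, selected feature
#'   names, normalisation statistics, the full importance ranking, the
#'   winning configuration and training metadata.
#' @export
fit_temperature_model <- function(x, y, k = 10L, config = forest_config(),
                                  validation = NULL, power_label = NULL) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  norm <- fit_normalizer(x)
  xn <- as.data.frame(apply_normalizer(norm, x))
  ranking <- rank_importance(xn, y, config)
  selected <- select_top_k(ranking, k)
  xs <- xn[, selected, drop = FALSE]

  grid_results <- NULL
  best_cfg <- config
  if (!is.null(validation)) {
    vx <- as.data.frame(apply_normalizer(norm, validation$x))
    vx <- vx[, selected, drop = FALSE]
    grid <- expand.grid(n_trees = c(200L, 500L), min_leaf = c(1L, 5L))
    grid_results <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
      cfg_g <- forest_config(grid$n_trees[g], config$max_features,
                             grid$min_leaf[g], config$seed)
      fit_g <- ranger_fit(xs, y, cfg_g)
      pred <- stats::predict(fit_g, data = vx, num.threads = 1L)$predictions
      data.frame(n_trees = grid$n_trees[g], min_leaf = grid$min_leaf[g],
                 val_mae_C = mae(validation$y, pred))
    }))
    best <- which.min(grid_results$val_mae_C)
    best_cfg <- forest_config(grid_results$n_trees[best],
                              config$max_features,
                              grid_results$min_leaf[best], config$seed)
  }

  forest <- ranger_fit(xs, y, best_cfg)
  structure(list(
    forest = forest,
    selected = selected,
    normalizer = norm,
    ranking = ranking,
    config = best_cfg,
    grid_results = grid_results,
    power_label = power_label,
    n_train = nrow(x)
  ), class = "temp_model")
}

#' Predict temperatures from texture features
#'
#' @param object a `temp_model`.
#' @param newdata feature matrix/data frame containing at least the
#'   model's selected features (raw scale; normalisation is applied
#'   internally), or a single named feature vector.
#' @param ... unused.
#' @return numeric vector of predicted temperatures (degC).
#' @export
predict.temp_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) {
    stop_domain("newdata must have named feature columns")
  }
  miss <- setdiff(object$selected, colnames(x))
  if (length(miss) > 0) {
    stop_domain("newdata lacks selected feature(s): ",
                paste(miss, collapse = ", "))
  }
  x <- x[, object$selected, drop = FALSE]
  mu <- object$normalizer$mean[object$selected]
  sd <- object$normalizer$sd[object$selected]
  xn <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
  stats::predict(object$forest, data = as.data.frame(xn),
                 num.threads = 1L)$predictions
}

#' @export
print.temp_model <- function(x, ...) {
  cat("Ultrasound texture temperature model (random forest)\n")
  if (!is.null(x$power_label)) cat("  power group:", x$power_label, "\n")
  cat(sprintf("  trained on %d samples; %d trees, min leaf %d, seed %d\n",
              x$n_train, x$config$n_trees, x$config$min_leaf,
              x$config$seed))
  cat("  selected features:\n")
  sel <- x$ranking[x$ranking$feature %in% x$selected, ]
  for (i in seq_len(nrow(sel))) {
    cat(sprintf("    %2d. %-45s %.4f\n", sel$rank[i], sel$feature[i],
                sel$importance[i]))
  }
  invisible(x)
}

#' @export
summary.temp_model <- function(object, ...) {
  print(object)
  if (!is.null(object$grid_results)) {
    cat("  validation grid (MAE, degC):\n")
    print(object$grid_results, row.names = FALSE)
  }
  cat(sprintf("  OOB RMSE: %.3f degC\n",
              sqrt(object$forest$prediction.error)))
  invisible(object)
}

#' @export
plot.temp_model <- function(x, n = 20L, ...) {
  top <- utils::head(x$ranking, n)
  graphics::par(mar = c(4, 14, 2, 1))
  graphics::barplot(rev(top$importance), names.arg = rev(top$feature),
                    horiz = TRUE, las = 1, cex.names = 0.65,
                    xlab = "Gini importance (variance decrease)",
                    main = "Feature importance", ...)
  invisible(x)
}
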