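# Thin regressor interface over the built-in histogram gradient-boosted
# tree backend. The contract required of any backend: deterministic for a
# fixed seed (single thread), squared-error regression, per-feature gain
# importances.

#' Boosted-tree hyperparameters
#'
#' Documented reasonable defaults for libraries of a few thousand variants;
#' all values are plain knobs loadable from a config file.
#'
#' @param n_trees boosting rounds
#' @param max_depth tree depth
#' @param learning_rate shrinkage
#' @param min_child minimum rows per leaf
#' @param subsample row subsampling per tree
#' @param colsample column subsampling per tree
#' @param max_bin histogram bins per feature
#' @param min_gain minimum variance-reduction to split
#' @return named list of hyperparameters
#' @export
gbt_params <- function(n_trees = 300L, max_depth = 6L,
                       learning_rate = 0.06, min_child = 20L,
                       subsample = 0.8, colsample = 0.5,
                       max_bin = 64L, min_gain = 1e-10) {
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       learning_rate = learning_rate, min_child = as.integer(min_child),
       subsample = subsample, colsample = colsample,
       max_bin = as.integer(max_bin), min_gain = min_gain)
}

#' Fit a gradient-boosted tree regressor
#'
#' @param X numeric feature matrix
#' @param y numeric outcome
#' @param params list from [gbt_params()]
#' @param seed integer seed (subsampling)
#' @return object of class `gbt_model`
#' @export
gbt_fit <- function(X, y, params = gbt_params(), seed = 1L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y must align", call. = FALSE)
  if (any(!is.finite(y))) stop("outcomes must be finite", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("degenerate constant outcome", call. = FALSE)
  fit <- .gbt_train_cpp(X, as.numeric(y), params$n_trees, params$max_depth,
                        params$learning_rate, params$min_child,
                        params$subsample, params$colsample, params$max_bin,
                        params$min_gain, as.integer(seed))
  structure(list(base = fit$base, trees = fit$trees,
                 importance = setNames(fit$importance, colnames(X)),
                 params = params, seed = as.integer(seed),
                 feature_names = colnames(X)),
            class = "gbt_model")
}

#' @param object a `gbt_model`
#' @param newdata numeric matrix with the training feature columns
#' @param ... unused
#' @rdname gbt_fit
#' @export
predict.gbt_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  as.numeric(.gbt_predict_cpp(object$trees, object$base, newdata))
}

#' Normalized gain importance of a fitted model
#'
#' @param model a `gbt_model`
#' @return named numeric vector summing to 1 (all-zero if no splits)
#' @export
gbt_importance <- function(model) {
  imp <- model$importance
  tot <- sum(imp)
  if (tot > 0) imp / tot else imp
}
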