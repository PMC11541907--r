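# Staged modeling: five boosted-tree regressors of ln mRNA level (one per
# timepoint) trained on biophysical features, then a decay-rate model
# trained on the features augmented with the five model-PREDICTED ln
# levels (predictions, never measurements, for train and test alike).

#' Bundle features and outcomes into a modeling dataset
#'
#' @param X feature matrix (variants x schema features)
#' @param levels ln-level outcome matrix (variants x timepoints)
#' @param k decay-constant outcomes (1/min)
#' @param groups design-group labels
#' @param schema the [feature_schema()] the features follow
#' @return object of class `decay_dataset`
#' @export
build_dataset <- function(X, levels, k, groups, schema) {
  stopifnot(nrow(X) == nrow(levels), nrow(X) == length(k),
            nrow(X) == length(groups))
  structure(list(X = X, levels = as.matrix(levels), k = as.numeric(k),
                 groups = as.character(groups), schema = schema,
                 split = NULL, split_seed = NA_integer_),
            class = "decay_dataset")
}

#' Stratified train/test split by design group
#'
#' Within each design group, floor(f*n) or ceil(f*n) variants go to the
#' training split; largest-remainder rounding makes the global training
#' count equal round(f*N) deterministically, and a seeded shuffle picks the
#' members. Empty groups are skipped.
#'
#' @param dataset a `decay_dataset` (or a character vector of group labels)
#' @param train_fraction fraction in the training split (default 0.8)
#' @param seed integer seed
#' @return the dataset with `split` set (factor `train`/`test`), or the
#'   split factor when given labels directly
#' @export
split_by_group <- function(dataset, train_fraction = 0.8, seed = 1L) {
  groups <- if (inherits(dataset, "decay_dataset")) dataset$groups
            else as.character(dataset)
  n <- length(groups)
  tab <- table(groups)
  tab <- tab[tab > 0L]
  base <- floor(train_fraction * as.numeric(tab))
  remainder <- train_fraction * as.numeric(tab) - base
  extra_total <- round(train_fraction * n) - sum(base)
  take_extra <- rep(0L, length(tab))
  if (extra_total > 0L) {
    o <- order(-remainder, names(tab))
    take_extra[o[seq_len(min(extra_total, length(tab)))]] <- 1L
  }
  n_train <- setNames(base + take_extra, names(tab))
  split <- rep("test", n)
  with_seed(seed, {
    for (g in names(tab)) {
      idx <- which(groups == g)
      pick <- sample(idx, n_train[[g]])
      split[pick] <- "train"
    }
  })
  split <- factor(split, levels = c("train", "test"))
  if (inherits(dataset, "decay_dataset")) {
    dataset$split <- split
    dataset$split_seed <- as.integer(seed)
    dataset
  } else split
}

#' Train the five mRNA-level models
#'
#' One boosted-tree regressor per timepoint, outcome = ln mRNA level;
#' training touches only the training split.
#'
#' @param dataset a split `decay_dataset`
#' @param params hyperparameters from [gbt_params()]
#' @param seed integer seed
#' @return named list of `gbt_model`s (one per level column)
#' @export
train_level_models <- function(dataset, params = gbt_params(), seed = 1L) {
  .check_split(dataset)
  tr <- dataset$split == "train"
  models <- list()
  for (j in seq_len(ncol(dataset$levels))) {
    y <- dataset$levels[tr, j]
    models[[colnames(dataset$levels)[j]]] <-
      gbt_fit(dataset$X[tr, , drop = FALSE], y, params, seed + j)
  }
  models
}

#' Train the decay-rate model on augmented features
#'
#' Augments the schema features with the five predicted ln levels (model
#' predictions for every variant, train and test) and regresses the decay
#' constant k (1/min).
#'
#' @param dataset a split `decay_dataset`
#' @param level_models result of [train_level_models()] on the same schema
#' @param params hyperparameters
#' @param seed integer seed
#' @return a `gbt_model` whose input dimension is schema dimension + 5
#' @export
train_decay_model <- function(dataset, level_models, params = gbt_params(),
                              seed = 1L) {
  .check_split(dataset)
  Xa <- augment_features(dataset$X, level_models, dataset$schema)
  tr <- dataset$split == "train"
  gbt_fit(Xa[tr, , drop = FALSE], dataset$k[tr], params, seed + 99L)
}

#' Augment a feature matrix with predicted ln levels
#'
#' @param X schema feature matrix
#' @param level_models fitted level models
#' @param schema schema the models were trained on (hash-checked)
#' @return matrix with 5 extra `pred_<timepoint>` columns
#' @export
augment_features <- function(X, level_models, schema = NULL) {
  if (!is.null(schema)) {
    h <- attr(X, "schema_hash")
    if (!is.null(h) && !identical(h, schema$hash))
      stop("schema hash mismatch between features and models",
           call. = FALSE)
  }
  preds <- vapply(level_models, function(m) predict(m, X),
                  numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  colnames(preds) <- paste0("pred_", names(level_models))
  cbind(X, preds)
}

#' Train a full model bundle
#'
#' @param dataset a split `decay_dataset`
#' @param params hyperparameters
#' @param seed integer seed
#' @return object of class `decay_bundle`: level models, decay model,
#'   hyperparameters, schema hash and split seed
#' @export
train_bundle <- function(dataset, params = gbt_params(), seed = 1L) {
  lv <- train_level_models(dataset, params, seed)
  dm <- train_decay_model(dataset, lv, params, seed)
  structure(list(level_models = lv, decay_model = dm, params = params,
                 schema = dataset$schema, schema_hash = dataset$schema$hash,
                 split_seed = dataset$split_seed, seed = as.integer(seed)),
            class = "decay_bundle")
}

#' Predict ln levels and decay rates from a bundle
#'
#' @param bundle a `decay_bundle`
#' @param X schema feature matrix
#' @return matrix of predicted ln levels (columns per timepoint)
#' @export
predict_levels <- function(bundle, X) {
  sapply(bundle$level_models, function(m) predict(m, X))
}

#' @rdname predict_levels
#' @return numeric vector of predicted decay constants (1/min)
#' @export
predict_decay <- function(bundle, X) {
  Xa <- augment_features(X, bundle$level_models)
  predict(bundle$decay_model, Xa)
}

#' Evaluate a bundle on its dataset
#'
#' R^2 is the squared Pearson correlation of predicted vs observed values;
#' the decay model additionally reports the median relative error of k on
#' the test split.
#'
#' @param bundle a `decay_bundle`
#' @param dataset the split `decay_dataset`
#' @return list of metrics: per-level-model train/test R^2, decay train/
#'   test R^2, `median_rel_error_k`
#' @export
evaluate_bundle <- function(bundle, dataset) {
  .check_split(dataset)
  if (all(dataset$split != "test")) stop("empty test split", call. = FALSE)
  tr <- dataset$split == "train"
  lv_pred <- predict_levels(bundle, dataset$X)
  level_r2 <- lapply(seq_along(bundle$level_models), function(j) {
    list(train = .r2(lv_pred[tr, j], dataset$levels[tr, j]),
         test = .r2(lv_pred[!tr, j], dataset$levels[!tr, j]))
  })
  names(level_r2) <- names(bundle$level_models)
  k_pred <- predict_decay(bundle, dataset$X)
  list(levels = level_r2,
       decay = list(train = .r2(k_pred[tr], dataset$k[tr]),
                    test = .r2(k_pred[!tr], dataset$k[!tr])),
       median_rel_error_k = median(abs(k_pred[!tr] - dataset$k[!tr]) /
                                     dataset$k[!tr]))
}

#' @noRd
.r2 <- function(pred, obs) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  cor(pred, obs)^2
}

#' @noRd
.check_split <- function(dataset) {
  if (!inherits(dataset, "decay_dataset") || is.null(dataset$split))
    stop("dataset must carry a split (see split_by_group)", call. = FALSE)
}

#' Prune features by importance and refit
#'
#' Drops features whose normalized gain importance falls below `threshold`
#' in all six models (five level models + decay model), then refits the
#' bundle on the reduced feature set.
#'
#' @param bundle fitted `decay_bundle`
#' @param dataset the split dataset it was trained on
#' @param threshold normalized-importance cutoff (0 prunes nothing)
#' @return list: `bundle` (refit), `kept`, `dropped`
#' @export
feature_importance_prune <- function(bundle, dataset, threshold) {
  mods <- c(bundle$level_models, list(decay = bundle$decay_model))
  p <- ncol(dataset$X)
  imp <- sapply(mods, function(m) gbt_importance(m)[seq_len(p)])
  low <- apply(imp, 1L, function(v) all(v < threshold))
  if (all(low)) stop("all features pruned", call. = FALSE)
  kept <- colnames(dataset$X)[!low]
  ds2 <- dataset
  ds2$X <- dataset$X[, !low, drop = FALSE]
  attr(ds2$X, "schema_hash") <- NULL
  ds2$schema <- list(names = kept, hash = .fnv1a(paste(kept,
                                                       collapse = "|")))
  refit <- train_bundle(ds2, bundle$params, bundle$seed)
  list(bundle = refit, kept = kept,
       dropped = colnames(dataset$X)[low])
}

#' Isoform-tracking ablation
#'
#' Compares model accuracy when features track only the single most
#' predominant isoform against the top-5 isoform feature set, over several
#' split seeds, with a paired bootstrap over test variants for the
#' difference in test R^2.
#'
#' @param dataset_top1,dataset_top5 datasets built from the same library
#'   with 1- and 5-isoform schemas
#' @param seeds integer vector of split seeds
#' @param params hyperparameters
#' @param n_boot bootstrap resamples
#' @return list: per-seed test R^2 for both settings, median difference,
#'   bootstrap p-value for (top5 - top1) <= 0
#' @export
isoform_ablation <- function(dataset_top1, dataset_top5, seeds = 1:5,
                             params = gbt_params(), n_boot = 200L) {
  r2_1 <- r2_5 <- numeric(length(seeds))
  diffs <- numeric(0)
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    d1 <- split_by_group(dataset_top1, seed = s)
    d5 <- split_by_group(dataset_top5, seed = s)
    b1 <- train_bundle(d1, params, seed = s)
    b5 <- train_bundle(d5, params, seed = s)
    te <- d1$split == "test"
    p1 <- predict_decay(b1, d1$X)[te]
    p5 <- predict_decay(b5, d5$X)[te]
    obs <- d1$k[te]
    r2_1[i] <- .r2(p1, obs); r2_5[i] <- .r2(p5, obs)
    if (i == 1L) {
      boot <- with_seed(s + 1000L, {
        vapply(seq_len(n_boot), function(b) {
          idx <- sample.int(length(obs), replace = TRUE)
          .r2(p5[idx], obs[idx]) - .r2(p1[idx], obs[idx])
        }, numeric(1))
      })
      diffs <- boot
    }
  }
  list(test_r2_top1 = r2_1, test_r2_top5 = r2_5,
       median_diff = median(r2_5 - r2_1),
       p_boot = mean(diffs <= 0))
}
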