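# model module: stratified splitting, staged boosted models, evaluation,
# pruning, isoform ablation.

synth_dataset <- function(n = 5000L, p = 20L, outcome = c("linear", "noise",
                                                          "smooth",
                                                          "hard"),
                          seed = 1L, groups = 4L, lv_noise = 0.1) {
  outcome <- match.arg(outcome)
  set.seed(seed)
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  k <- switch(outcome,
              linear = 3 * X[, 1] - 2 * X[, 2] + rnorm(n, 0, 0.05),
              noise = rnorm(n),
              smooth = 0.1 + 0.3 * plogis(6 * (X[, 1] - 0.5)) +
                0.2 * X[, 2] * X[, 3] + rnorm(n, 0, 0.02),
              hard = 0.1 + 0.3 * plogis(6 * (X[, 1] - 0.5)) +
                0.2 * X[, 2] * X[, 3] +
                0.15 * plogis(8 * (X[, 4] - 0.3)) +
                0.1 * X[, 5] * X[, 6] + rnorm(n, 0, 0.02))
  lv <- sapply(1:5, function(j) -log(abs(k) + 0.1) + rnorm(n, 0, lv_noise))
  colnames(lv) <- paste0("t", c(0, 2, 4, 8, 16))
  sch <- list(names = colnames(X), hash = "synth")
  ds <- build_dataset(X, lv, k, rep(paste0("g", 1:groups), length.out = n),
                      sch)
  attr(ds$X, "schema_hash") <- "synth"
  ds
}

fast_hp <- gbt_params(n_trees = 80L, max_depth = 4L, learning_rate = 0.1,
                      colsample = 0.8)

test_that("group-stratified splits use largest-remainder rounding", {
  s <- split_by_group(rep("a", 10L), 0.8, seed = 1L)
  expect_equal(sum(s == "train"), 8L)
  s2 <- split_by_group(rep(c("a", "b"), c(10L, 5L)), 0.8, seed = 1L)
  expect_equal(unname(table(s2, rep(c("a", "b"), c(10L, 5L)))["train", ]),
               c(8L, 4L))
  expect_identical(split_by_group(rep(c("a", "b"), c(10L, 5L)), 0.8,
                                  seed = 1L), s2)
})

test_that("splits have no leakage and per-group fractions within 1 variant", {
  ds <- synth_dataset(n = 997L, groups = 5L)
  ds <- split_by_group(ds, 0.8, seed = 2L)
  expect_equal(sum(ds$split == "train"), round(0.8 * 997))
  for (g in unique(ds$groups)) {
    n_g <- sum(ds$groups == g)
    tr_g <- sum(ds$split == "train" & ds$groups == g)
    expect_lte(abs(tr_g - 0.8 * n_g), 1)
  }
})

test_that("level models recover known signal and reject degenerate input", {
  ds <- synth_dataset(outcome = "linear", seed = 3L)
  ds$levels[, 1L] <- ds$k  # exact linear function of two features
  ds <- split_by_group(ds, 0.8, seed = 3L)
  mods <- train_level_models(ds, fast_hp, seed = 3L)
  te <- ds$split == "test"
  pred <- predict(mods$t0, ds$X[te, ])
  expect_gt(cor(pred, ds$levels[te, 1L])^2, 0.95)
  # pure-noise outcome: test R^2 near zero
  dn <- synth_dataset(outcome = "noise", seed = 4L)
  dn <- split_by_group(dn, 0.8, seed = 4L)
  mn <- gbt_fit(dn$X[dn$split == "train", ], dn$k[dn$split == "train"],
                fast_hp, seed = 4L)
  r2 <- cor(predict(mn, dn$X[dn$split == "test", ]),
            dn$k[dn$split == "test"])^2
  expect_lt(abs(r2), 0.05)
  # determinism
  mods2 <- train_level_models(ds, fast_hp, seed = 3L)
  expect_identical(predict(mods$t0, ds$X[1:20, ]),
                   predict(mods2$t0, ds$X[1:20, ]))
  dc <- ds
  dc$levels[, 2L] <- 1
  expect_error(train_level_models(dc, fast_hp, seed = 1L), "constant")
})

test_that("decay model uses augmented features and recovers smooth truth", {
  ds <- synth_dataset(outcome = "smooth", seed = 5L)
  ds <- split_by_group(ds, 0.8, seed = 5L)
  lv <- train_level_models(ds, fast_hp, seed = 5L)
  dm <- train_decay_model(ds, lv, fast_hp, seed = 5L)
  expect_equal(length(dm$feature_names), ncol(ds$X) + 5L)
  Xa <- augment_features(ds$X, lv)
  te <- ds$split == "test"
  expect_gt(cor(predict(dm, Xa[te, ]), ds$k[te])^2, 0.8)
  # constant outcome errors
  dk <- ds; dk$k <- rep(1, length(dk$k))
  expect_error(train_decay_model(dk, lv, fast_hp, seed = 1L), "constant")
  # schema hash mismatch errors
  Xbad <- ds$X
  attr(Xbad, "schema_hash") <- "other"
  expect_error(augment_features(Xbad, lv, ds$schema), "hash")
})

test_that("augmentation does not hurt decay accuracy (paired seeds)", {
  diffs <- vapply(1:5, function(s) {
    ds <- synth_dataset(n = 2000L, outcome = "hard", seed = 10L + s,
                        lv_noise = 0.03)
    ds <- split_by_group(ds, 0.8, seed = s)
    te <- ds$split == "test"; tr <- !te
    lv <- train_level_models(ds, fast_hp, seed = s)
    dm_aug <- train_decay_model(ds, lv, fast_hp, seed = s)
    r2_aug <- cor(predict(dm_aug, augment_features(ds$X, lv)[te, ]),
                  ds$k[te])^2
    dm_plain <- gbt_fit(ds$X[tr, ], ds$k[tr], fast_hp, seed = s + 99L)
    r2_plain <- cor(predict(dm_plain, ds$X[te, ]), ds$k[te])^2
    r2_aug - r2_plain
  }, numeric(1))
  expect_gte(median(diffs), 0)
})

test_that("evaluation metrics match a hand-computed oracle", {
  ds <- synth_dataset(n = 1500L, outcome = "smooth", seed = 6L)
  ds <- split_by_group(ds, 0.8, seed = 6L)
  bun <- train_bundle(ds, fast_hp, seed = 6L)
  met <- evaluate_bundle(bun, ds)
  te <- ds$split == "test"
  k_pred <- predict_decay(bun, ds$X)
  expect_equal(met$decay$test, cor(k_pred[te], ds$k[te])^2)
  expect_equal(met$median_rel_error_k,
               median(abs(k_pred[te] - ds$k[te]) / ds$k[te]))
  lvp <- predict_levels(bun, ds$X)
  expect_equal(met$levels$t0$train,
               cor(lvp[!te, 1L], ds$levels[!te, 1L])^2)
})

test_that("importance pruning drops noise features and keeps signal", {
  hits <- vapply(1:3, function(s) {
    ds <- synth_dataset(n = 2000L, p = 10L, outcome = "smooth",
                        seed = 20L + s)
    ds <- split_by_group(ds, 0.8, seed = s)
    bun <- train_bundle(ds, fast_hp, seed = s)
    pr <- feature_importance_prune(bun, ds, threshold = 0.02)
    c(noise_pruned = "f9" %in% pr$dropped || "f10" %in% pr$dropped,
      signal_kept = "f1" %in% pr$kept)
  }, logical(2))
  expect_gte(median(hits["noise_pruned", ]), 1)
  expect_true(all(hits["signal_kept", ]))
  # threshold zero prunes nothing
  ds <- synth_dataset(n = 1500L, p = 8L, outcome = "smooth", seed = 30L)
  ds <- split_by_group(ds, 0.8, seed = 30L)
  bun <- train_bundle(ds, fast_hp, seed = 30L)
  pr0 <- feature_importance_prune(bun, ds, threshold = 0)
  expect_length(pr0$dropped, 0L)
})

test_that("isoform ablation detects truth carried by extra isoform blocks", {
  # construct: k depends on a feature present only in the top-5 set
  set.seed(40L)
  n <- 2000L
  shared <- matrix(runif(n * 6L), n, 6L,
                   dimnames = list(NULL, paste0("s", 1:6)))
  extra <- matrix(runif(n * 2L), n, 2L,
                  dimnames = list(NULL, paste0("x", 1:2)))
  k <- 0.1 + 0.5 * extra[, 1L] + 0.2 * shared[, 1L] + rnorm(n, 0, 0.02)
  lv <- sapply(1:5, function(j) -k + rnorm(n, 0, 0.05))
  colnames(lv) <- paste0("t", c(0, 2, 4, 8, 16))
  g <- rep(c("a", "b"), length.out = n)
  d1 <- build_dataset(shared, lv, k, g, list(names = colnames(shared),
                                             hash = "s1"))
  d5 <- build_dataset(cbind(shared, extra), lv, k, g,
                      list(names = c(colnames(shared), colnames(extra)),
                           hash = "s5"))
  res <- isoform_ablation(d1, d5, seeds = 1:3, params = fast_hp,
                          n_boot = 100L)
  expect_gt(res$median_diff, 0.1)
  expect_lt(res$p_boot, 0.05)
  # identical feature sets: difference exactly zero
  res0 <- isoform_ablation(d1, d1, seeds = 1L, params = fast_hp,
                           n_boot = 50L)
  expect_equal(res0$test_r2_top1, res0$test_r2_top5)
  expect_equal(res0$median_diff, 0)
})

test_that("generator-trained bundle meets the synthetic recovery bar (decay)", {
  ds <- fx_dataset()
  bun <- fx_bundle()
  met <- evaluate_bundle(bun, ds)
  expect_gt(met$decay$test, 0.6)
  # determinism of the full pipeline stage
  expect_identical(predict_decay(bun, ds$X[1:5, , drop = FALSE]),
                   predict_decay(fx_bundle(), ds$X[1:5, , drop = FALSE]))
})
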