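# kinetics module: spike-in normalization, exponential fitting, QC.

make_table <- function(N, C, dna = 1000L) {
  tp <- c(0, 2, 4, 8, 16)
  df <- data.frame(variant_id = c("v1", "SPIKEIN"),
                   dna_t0 = c(dna, 0L), stringsAsFactors = FALSE)
  for (i in seq_along(tp)) df[[paste0("rna_t", tp[i])]] <- c(N[i], C[i])
  df
}

test_that("normalization follows R_i = (N_i/N_0)/CR_i", {
  # constant spike-in: ratios mirror the raw decay
  n1 <- normalize_counts(make_table(c(1000, 500, 250, 125, 63),
                                    rep(100, 5)))
  expect_equal(n1$R[1, ], c(1, .5, .25, .125, .063), ignore_attr = TRUE)
  # flat counts with doubling spike-in: decay revealed by normalization
  n2 <- normalize_counts(make_table(rep(1000, 5),
                                    c(100, 200, 400, 800, 1600)))
  expect_equal(n2$R[1, ], c(1, .5, .25, .125, .0625), ignore_attr = TRUE)
  expect_equal(n2$cr, c(1, 2, 4, 8, 16))
})

test_that("zero T0 reads flag low_reads; zero T0 spike-in is fatal", {
  n <- normalize_counts(make_table(c(0, 10, 5, 2, 1), rep(100, 5)))
  expect_identical(n$status[1L], "low_reads")
  fits <- fit_decay_table(n)
  expect_identical(fits$status[1L], "low_reads")
  expect_error(normalize_counts(make_table(rep(10, 5),
                                           c(0, 10, 10, 10, 10))),
               "spike-in")
  expect_error(normalize_counts(make_table(rep(10, 5), rep(10, 5))[-2, ]),
               "SPIKEIN")
})

test_that("noiseless exponential series are recovered exactly", {
  tp <- c(0, 2, 4, 8, 16)
  f <- fit_decay(exp(-0.3 * tp), tp)
  expect_equal(f$k, 0.3, tolerance = 1e-7)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$half_life_min, log(2) / 0.3, tolerance = 1e-6)
  expect_identical(f$status, "ok")
  # the slowest observed decay class: half-life 25.4 min
  k_slow <- log(2) / 25.4
  f2 <- fit_decay(exp(-k_slow * tp), tp)
  expect_equal(f2$half_life_min, 25.4, tolerance = 1e-4)
})

test_that("degenerate no-decay series hit the k = 0 bound", {
  tp <- c(0, 2, 4, 8, 16)
  f <- fit_decay(rep(1, 5), tp)
  expect_equal(f$k, 0)
  expect_identical(f$half_life_min, Inf)
})

test_that("fits satisfy k * half-life = ln 2 and match a grid oracle", {
  ct <- fx_small_counts()
  norm <- normalize_counts(ct)
  fits <- fit_decay_table(norm)
  ok <- fits$status == "ok" & is.finite(fits$half_life_min)
  expect_gt(sum(ok), 100L)
  expect_equal(fits$k[ok] * fits$half_life_min[ok],
               rep(log(2), sum(ok)), tolerance = 1e-9)
  # dense grid oracle on a subsample
  grid <- seq(1e-4, 10, length.out = 1e5)
  E <- exp(-outer(grid, norm$timepoints))
  for (i in seq(1L, nrow(norm$R), by = 37L)) {
    sse <- rowSums(sweep(E, 2L, norm$R[i, ])^2)
    expect_lt(abs(fits$k[i] - grid[which.min(sse)]), 2e-4)
  }
})

test_that("normalization is invariant to per-sample scaling", {
  ct <- fx_small_counts()
  # restrict to strictly positive counts: the 0.5 pseudocount substituted
  # for zero counts is (intentionally) not scale-covariant
  cols <- grep("^rna_t", colnames(ct), value = TRUE)
  pos <- rowSums(ct[, cols] == 0) == 0
  ct <- ct[pos | ct$variant_id == "SPIKEIN", ]
  scaled <- ct
  cols <- grep("^rna_t", colnames(ct), value = TRUE)
  for (j in seq_along(cols)) scaled[[cols[j]]] <- ct[[cols[j]]] * (j + 1L)
  r1 <- normalize_counts(ct)$R
  r2 <- normalize_counts(scaled)$R
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("QC filters by read depth and fit quality", {
  ct <- fx_small_counts()
  fits <- fit_decay_table(normalize_counts(ct))
  qc <- apply_qc(fits, ct)
  vt <- ct[ct$variant_id != "SPIKEIN", ]
  keep_manual <- vt$dna_t0 >= 100 & vt$rna_t0 >= 100 &
    !is.na(fits$r_squared) & fits$r_squared > 0.75 & fits$status == "ok"
  expect_equal(qc$report$n_pass, sum(keep_manual))
  expect_setequal(qc$fits$variant_id, fits$variant_id[keep_manual])
  # medians agree with an independent computation
  expect_equal(unname(qc$report$medians[["rna_t0"]]), median(vt$rna_t0))
  expect_equal(unname(qc$report$medians[["dna_t0"]]), median(vt$dna_t0))
  # a variant one read short of the DNA threshold is excluded
  ct2 <- ct
  ct2$dna_t0[1L] <- 99L
  qc2 <- apply_qc(fits, ct2)
  expect_false(ct2$variant_id[1L] %in% qc2$fits$variant_id)
  # noiseless expected counts retain every variant
  tr <- fx_small_truth()
  cte <- expected_counts(tr, depth = 1000)
  fe <- fit_decay_table(normalize_counts(cte))
  qce <- apply_qc(fe, cte)
  expect_equal(qce$report$n_pass, nrow(tr))
})

test_that("steady-state levels use the natural log with 0.5 pseudocounts", {
  ct <- make_table(c(100, 1, 1, 1, 1), rep(10, 5), dna = 100L)
  expect_equal(unname(steady_state_level(ct)["v1"]), 0)
  ct$rna_t0[1L] <- round(exp(1) * 100)
  expect_equal(unname(steady_state_level(ct)["v1"]), 1, tolerance = 0.01)
  ct$rna_t0[1L] <- 0L
  expect_equal(unname(steady_state_level(ct)["v1"]), log(0.5 / 100))
  lv <- level_outcomes(ct)
  expect_equal(dim(lv), c(1L, 5L))
  expect_equal(unname(lv[1L, "t0"]), log(0.5 / 100))
})

test_that("fitted k recovers the generator truth within stated error", {
  tr <- fx_small_truth()
  ct <- fx_small_counts()  # depth 1e3
  fits <- fit_decay_table(normalize_counts(ct))
  rel <- abs(fits$k - tr$k_true) / tr$k_true
  expect_lt(median(rel, na.rm = TRUE), 0.10)
  ct5 <- simulate_counts(tr, depth = 1e5, seed = 104L)
  fits5 <- fit_decay_table(normalize_counts(ct5))
  rel5 <- abs(fits5$k - tr$k_true) / tr$k_true
  expect_lt(median(rel5, na.rm = TRUE), 0.02)
})
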