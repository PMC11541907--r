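# Shared fixtures, built once per test run and memoized. The "world" is the
# standard recovery simulation (n = 5000 variants, depth 1e4) used by the
# model property suite and the acceptance criteria; building it (and
# training its model bundle) dominates suite runtime, so every test shares
# one instance.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, builder(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# small mixed library for cheap unit tests
fx_small_lib <- function() fx_memo("small_lib", function() {
  generate_design_library(library_config(groups = list(
    structure_series = list(n = 120L),
    g_quadruplex = list(n = 60L),
    i_motif = list(n = 30L),
    motif_insertion = list(n = 30L))), seed = 101L)
})

fx_small_truth <- function() fx_memo("small_truth", function() {
  generate_truth(fx_small_lib(), seed = 102L)
})

fx_small_counts <- function() fx_memo("small_counts", function() {
  simulate_counts(fx_small_truth(), depth = 1000, seed = 103L)
})

# the full recovery world (spec-scale: n = 5000, depth 1e4)
fx_world <- function() fx_memo("world", function() {
  lib <- generate_design_library(seed = 11L)
  truth <- generate_truth(lib, seed = 12L)
  counts <- simulate_counts(truth, depth = 10000, seed = 13L)
  norm <- normalize_counts(counts)
  fits <- fit_decay_table(norm)
  schema <- feature_schema()
  X <- featurize_library(lib, schema = schema)
  levels <- level_outcomes(counts)
  list(lib = lib, truth = truth, counts = counts, fits = fits,
       X = X, levels = levels, schema = schema)
})

fx_dataset <- function() fx_memo("dataset", function() {
  w <- fx_world()
  ds <- build_dataset(w$X, w$levels, w$fits$k, w$lib$design_group,
                      w$schema)
  attr(ds$X, "schema_hash") <- w$schema$hash
  split_by_group(ds, 0.8, seed = 14L)
})

fx_bundle <- function() fx_memo("bundle", function() {
  train_bundle(fx_dataset(), gbt_params(), seed = 15L)
})

# brute-force Hamming distance oracle
oracle_min_pairwise_distance <- function(codes) {
  chars <- do.call(rbind, strsplit(codes, "", fixed = TRUE))
  n <- nrow(chars)
  best <- ncol(chars)
  for (i in seq_len(n - 1L)) {
    d <- rowSums(chars[(i + 1L):n, , drop = FALSE] !=
                   matrix(chars[i, ], n - i, ncol(chars), byrow = TRUE))
    best <- min(best, d)
  }
  best
}
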