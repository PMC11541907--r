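# synthetic_data module: design libraries, barcodes, ground truth,
# count simulation and read emission.

test_that("full-factorial groups enumerate every RppH site x RBS variant", {
  lib <- generate_design_library(library_config(groups = list(
    full_factorial_polyA = list(rbs_variants = c(2L, 5L, 8L, 10L, 12L)))),
    seed = 3L)
  expect_equal(nrow(lib), 4^4 * 5)
  expect_equal(length(unique(lib$variant_id)), nrow(lib))
  expect_setequal(unique(lib$rpph_site), decaylab:::.all_4mers())
  expect_true(all(lib$rpph_site == substr(lib$utr_seq, 1L, 4L)))
  expect_true(all(nchar(lib$barcode) == 15L))
  expect_false(any(grepl("[^ACGU]", lib$utr_seq)))
})

test_that("unknown or empty design-group configs raise errors", {
  expect_error(generate_design_library(list(groups = list(bogus = list(n = 5))),
                                       seed = 1L), "unknown design group")
  expect_error(generate_design_library(list(groups = list()), seed = 1L),
               "no design groups")
})

test_that("tertiary design groups match their construction patterns", {
  lib <- fx_small_lib()
  g4 <- lib$utr_seq[lib$design_group == "g_quadruplex"]
  expect_true(all(grepl("GGG(?:[ACU]{6}GGG){3}", g4, perl = TRUE)))
  im <- lib$utr_seq[lib$design_group == "i_motif"]
  expect_true(all(grepl("CCC(?:[AGU]{6}CCC){3}", im, perl = TRUE)))
})

test_that("barcode sets respect the minimum pairwise Hamming distance", {
  b2 <- generate_barcodes(2L, seed = 5L)
  expect_gte(oracle_min_pairwise_distance(b2), 3L)
  b <- generate_barcodes(200L, seed = 6L)
  expect_equal(length(b), 200L)
  expect_gte(oracle_min_pairwise_distance(b), 3L)
  expect_identical(b, generate_barcodes(200L, seed = 6L))
  expect_error(generate_barcodes(5L, length = 1L, seed = 1L), "capacity")
})

test_that("ground-truth decay constants follow the stated effect rules", {
  mk <- function(ss, g4 = FALSE, im = FALSE, tir = 2, site = "AACG",
                 spacer = strrep("AGCU", 8L)) {
    data.frame(variant_id = "v", rpph_site = site,
               spacer_seq = substr(spacer, 1L, ss), ssrna_design_nt = ss,
               has_g4 = g4, has_imotif = im, tir_au = tir,
               stringsAsFactors = FALSE)
  }
  p0 <- truth_params(sigma_k = 0, sigma_m0 = 0)
  # unprotected peak ~0.4 1/min at the 33-nt ssRNA saturation
  k_peak <- generate_truth(mk(33L, spacer = strrep("AGCU", 9L)), p0, 1L)$k_true
  expect_lt(abs(k_peak - 0.4), 0.05)
  # G4 replaces the ssRNA term: flat ~0.2 1/min
  k_g4 <- generate_truth(mk(33L, g4 = TRUE, spacer = strrep("AGCU", 9L)),
                         p0, 1L)$k_true
  expect_lt(abs(k_g4 - 0.2), 0.05)
  # i-motif pushes decay toward ~0.5 1/min
  k_im <- generate_truth(mk(6L, im = TRUE), p0, 1L)$k_true
  expect_lt(abs(k_im - 0.5), 0.06)
  # all effect weights zero -> k = baseline everywhere
  pz <- truth_params(sigma_k = 0, sigma_m0 = 0, ssrna_slope = 0,
                     g4_level = 0, imotif_target = 0, protection_max = 0,
                     rpph_fold = 1)
  lib <- fx_small_lib()
  tz <- generate_truth(lib, pz, 1L)
  expect_true(all(abs(tz$k_true - pz$baseline) < 1e-12))
  # component decomposition: k_det = clamped sum of components
  tr <- generate_truth(lib, truth_params(sigma_k = 0, sigma_m0 = 0), 2L)
  s <- with(tr, baseline + rpph + ssrna + translation + g4 + imotif)
  expect_equal(tr$k_det, pmin(pmax(s, 0.027), 2.24), tolerance = 1e-12)
  expect_equal(tr$k_true, tr$k_det, tolerance = 1e-12)
})

test_that("k_true is monotone in ssRNA length up to saturation", {
  p0 <- truth_params(sigma_k = 0, sigma_m0 = 0)
  sp <- strrep("A", 48L)  # constant composition at every length
  ks <- vapply(0:40, function(ss) {
    lib <- data.frame(variant_id = "v", rpph_site = "AACG",
                      spacer_seq = substr(sp, 1L, ss),
                      ssrna_design_nt = ss, has_g4 = FALSE,
                      has_imotif = FALSE, tir_au = 2,
                      stringsAsFactors = FALSE)
    generate_truth(lib, p0, 1L)$k_true
  }, numeric(1))
  expect_true(all(diff(ks[1:34]) >= -1e-12))
  expect_equal(ks[34], ks[41], tolerance = 1e-12)  # saturated beyond 33
})

test_that("invalid generator configurations are rejected", {
  expect_error(truth_params(ssrna_slope = -1), "configuration error")
  expect_error(truth_params(sigma_k = -0.1), "configuration error")
  expect_error(truth_params(nonsense = 1), "configuration error")
  tr <- fx_small_truth()
  expect_error(simulate_counts(tr, depth = -5, seed = 1L),
               "configuration error")
  expect_error(simulate_counts(tr, spike_frac = -1, seed = 1L),
               "configuration error")
})

test_that("expected counts reproduce exp(-k t) ratios exactly", {
  tr <- fx_small_truth()
  ct <- expected_counts(tr)
  norm <- normalize_counts(ct)
  for (i in c(1L, 50L, nrow(norm$R))) {
    expect_equal(norm$R[i, ], exp(-tr$k_true[i] * norm$timepoints),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("read emission round-trips through barcode counting", {
  tr <- head(fx_small_truth(), 40L)
  lib <- head(fx_small_lib(), 40L)
  ct <- simulate_counts(tr, depth = 50, seed = 7L)
  outdir <- withr::local_tempdir()
  paths <- emit_reads(ct, lib, outdir, error_rate = 0, seed = 8L)
  idx <- build_index(c(lib$barcode, decaylab:::SPIKE_BARCODE),
                     c(lib$variant_id, "SPIKEIN"))
  counted <- count_reads(paths, idx)
  m <- match(ct$variant_id, counted$counts$variant_id)
  for (s in setdiff(colnames(ct), "variant_id")) {
    expect_equal(counted$counts[[s]][m], ct[[s]], ignore_attr = TRUE)
  }
  expect_true(all(counted$unmapped == 0L))
})

test_that("substitution errors produce the binomial unmapped fraction", {
  er <- 0.02
  lib <- head(fx_small_lib(), 30L)
  ct <- data.frame(variant_id = lib$variant_id, rna_t0 = 700L)
  outdir <- withr::local_tempdir()
  paths <- emit_reads(ct, lib, outdir, error_rate = er, seed = 9L)
  idx <- build_index(lib$barcode, lib$variant_id)
  counted <- count_reads(paths, idx)
  n_reads <- sum(ct$rna_t0)
  frac <- counted$unmapped[["rna_t0"]] / n_reads
  expected <- 1 - pbinom(1, 15, er)  # >= 2 errors within the barcode
  expect_lt(abs(frac - expected) / expected, 0.35)
  expect_equal(sum(counted$counts$rna_t0) + counted$unmapped[["rna_t0"]],
               n_reads, ignore_attr = TRUE)
})

test_that("empty count tables emit empty FASTQ files", {
  lib <- head(fx_small_lib(), 3L)
  ct <- data.frame(variant_id = lib$variant_id, rna_t0 = 0L)
  outdir <- withr::local_tempdir()
  paths <- emit_reads(ct, lib, outdir, seed = 1L)
  expect_identical(read_fastq(paths[["rna_t0"]]), character(0))
})
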