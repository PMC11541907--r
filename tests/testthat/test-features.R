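# features module: providers, folding anatomy, tertiary detection, motif
# counting, schema assembly.

test_that("quadruplex detection matches the printed patterns", {
  g4 <- paste0("GGG", "AACCUA", "GGG", "CUAACU", "GGG", "AUACCA", "GGG")
  hit <- detect_quadruplex(g4)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$width, 30L)
  expect_equal(hit$start0, 0L)
  # the same arrangement of C-runs is an i-motif, not a G4
  im <- chartr("G", "C", g4)
  expect_equal(nrow(detect_quadruplex(im)), 0L)
  expect_equal(nrow(detect_quadruplex(im, base = "C")), 1L)
  # fewer than four runs never match
  expect_equal(nrow(detect_quadruplex("GGGGGG")), 0L)
})

test_that("quadruplex detection agrees with a brute-force oracle", {
  # leftmost non-overlapping placements of the fixed-length 30-nt pattern:
  # base runs at offsets 0, 9, 18, 27; loops unconstrained
  brute <- function(seq, base) {
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    spans <- integer(0)
    i <- 1L
    while (i + 29L <= n) {
      run_at <- function(s) all(ch[s:(s + 2L)] == base)
      if (run_at(i) && run_at(i + 9L) && run_at(i + 18L) &&
          run_at(i + 27L)) {
        spans <- c(spans, i - 1L)
        i <- i + 30L
      } else i <- i + 1L
    }
    spans
  }
  set.seed(31L)
  for (rep in 1:20) {
    seq <- paste0(sample(c("A", "C", "G", "U"), 200, replace = TRUE,
                         prob = c(.2, .2, .4, .2)), collapse = "")
    got <- detect_quadruplex(seq)$start0
    expect_identical(got, brute(seq, "G"), label = seq)
  }
})

test_that("motif counting is overlapping and validates IUPAC input", {
  expect_equal(unname(count_motifs("AGGAGGA", c(m = "AGGA"))[["m"]]), 2L)
  expect_length(count_motifs("ACGU", character(0)), 0L)
  expect_equal(unname(count_motifs("ACGU", c(m = "AGGA"))[["m"]]), 0L)
  expect_equal(unname(count_motifs("AAUUA", c(m = "RAUUW"))[["m"]]), 1L)
  expect_error(count_motifs("ACGU", c(m = "AXGU")), "IUPAC")
})

test_that("structure anatomy annotates hairpins, loops and ssRNA", {
  # fully unpaired A/C-only UTR
  a <- fold_and_annotate("ACACACAAAACACACAAAAC")
  expect_equal(a$ssrna_total_nt, 20L, ignore_attr = TRUE)
  expect_equal(a$hairpin_count, 0L, ignore_attr = TRUE)
  # perfect 8-bp hairpin with a 4-nt loop
  stem <- "GCGCGCGC"
  hp <- paste0(stem, "GAAA", "GCGCGCGC")  # palindromic stem pairs itself
  ann <- fold_and_annotate(hp)
  expect_equal(ann$hairpin_count, 1L, ignore_attr = TRUE)
  expect_equal(ann$duplex_max_len, 8L, ignore_attr = TRUE)
  expect_equal(ann$loop_max_len, 4L, ignore_attr = TRUE)
  expect_equal(ann$bulge_count, 0L, ignore_attr = TRUE)
  expect_equal(ann$dotbracket, "((((((((....))))))))")
})

test_that("tertiary modes control the ssRNA tally of G4 spans", {
  utr <- paste0("AAAACAC", "GGG", "AACCUA", "GGG", "CUAACU", "GGG",
                "AUACCA", "GGG", "ACACA")
  aware <- fold_and_annotate(utr, tertiary_mode = "g4_aware")
  sec <- fold_and_annotate(utr, tertiary_mode = "secondary_only")
  expect_equal(aware$g4_present, 1, ignore_attr = TRUE)
  expect_equal(aware$g4_span_nt, 30, ignore_attr = TRUE)
  expect_lt(aware$ssrna_total_nt, sec$ssrna_total_nt + 1e-9)
  expect_equal(aware$ssrna_total_nt, nchar(utr) - 30L, ignore_attr = TRUE)
})

test_that("anatomy conserves nucleotides over a fuzz suite", {
  set.seed(33L)
  for (i in 1:300) {
    len <- sample(20:80, 1L)
    seq <- paste0(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                  collapse = "")
    a <- fold_and_annotate(seq, tertiary_mode = "g4_aware")
    expect_equal(a$ssrna_total_nt + a$paired_nt + a$tertiary_nt, len,
                 ignore_attr = TRUE, label = seq)
  }
})

test_that("transcription provider is deterministic and ITR-sensitive", {
  con <- paste0(decaylab:::PROMOTER_DNA, "ACGTACGTACGTACGTACGTACGT")
  s1 <- surrogate_tx_provider(con)
  s2 <- surrogate_tx_provider(con)
  expect_identical(s1, s2)
  expect_gt(nrow(s1), 0L)
  # a single-nt change inside the first 20 transcribed nt changes the rate
  con2 <- paste0(decaylab:::PROMOTER_DNA, "CCGTACGTACGTACGTACGTACGT")
  r1 <- s1$tx_rate[s1$tss_offset == nchar(decaylab:::PROMOTER_DNA)]
  r2 <- surrogate_tx_provider(con2)
  r2 <- r2$tx_rate[r2$tss_offset == nchar(decaylab:::PROMOTER_DNA)]
  expect_false(isTRUE(all.equal(r1, r2)))
})

test_that("translation provider responds to SD strength and occlusion", {
  cds <- decaylab:::dna_to_rna(decaylab:::CDS_DNA)
  strong <- paste0("ACGUCAAACAAA", "AGGAGGAAAAAA", cds)
  tir_strong <- surrogate_tir_provider(strong, 24L)
  expect_gt(tir_strong, 1e4)
  weak <- paste0("ACGUCAAACAAA", "CUCUCUCAAACA", cds)
  expect_lt(surrogate_tir_provider(weak, 24L), 10)
  # a hairpin sequestering the SD lowers TIR relative to the open control
  anti <- "CCUCCU"
  occluded <- paste0("ACGUCA", anti, "GAAA", "AGGAGGAAAAAA", cds)
  tir_occ <- surrogate_tir_provider(occluded, nchar(occluded) - nchar(cds))
  expect_lt(tir_occ, tir_strong)
})

test_that("isoform enumeration ranks by rate with offset tie-breaks", {
  stub <- function(construct, ...) {
    data.frame(tss_offset = c(40L, 20L, 30L), tx_rate = c(5, 9, 9))
  }
  pv <- default_providers(tx_provider = stub)
  iso <- enumerate_isoforms(strrep("ACGT", 30L), pv, n = 5L,
                            cds_offset = 100L)
  expect_equal(iso$tss_offset, c(20L, 30L, 40L))  # tie: lower offset first
  expect_equal(iso$rank, 1:3)
  expect_equal(iso$rpph_site[1L], substr(decaylab:::dna_to_rna(
    substring(strrep("ACGT", 30L), 21L)), 1L, 4L))
})

test_that("the default schema has 496 named features; exclusions shrink it", {
  sch <- feature_schema()
  expect_length(sch$names, 496L)
  expect_false(anyDuplicated(sch$names) > 0L)
  red <- feature_schema(exclude = c("duplex", "bulge", "internal_loop"))
  expect_lt(length(red$names), 496L)
  expect_false(any(grepl("duplex|bulge|internal_loop", red$names)))
  expect_false(identical(sch$hash, red$hash))
})

test_that("featurization is deterministic and pads missing isoforms", {
  lib <- head(fx_small_lib(), 12L)
  X1 <- featurize_library(lib)
  X2 <- featurize_library(lib)
  expect_identical(X1, X2)
  expect_false(any(is.na(X1)))
  # single-isoform provider: blocks 2..5 keep the pad sentinel
  one_site <- function(construct, ...) {
    surrogate_tx_provider(construct)[1L, , drop = FALSE]
  }
  X3 <- featurize_library(lib[1L, , drop = FALSE],
                          default_providers(tx_provider = one_site))
  expect_true(all(X3[1L, grep("^iso[2-5]_", colnames(X3))] == -1))
  expect_false(any(X3[1L, grep("^iso1_", colnames(X3))] == -1))
})
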