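# Design-library generation: enumerates 5' UTR variants organised into
# design groups (full-factorial RppH-site x RBS crosses, structure series,
# G-quadruplex / i-motif cassettes, motif insertions, RBS sweeps) and
# assigns minimum-Hamming-distance barcodes.

#' Generate a barcode set with a minimum pairwise Hamming distance
#'
#' Draws random DNA barcodes and rejects candidates closer than
#' `min_distance` to an accepted barcode, so that single-substitution
#' sequencing errors remain uniquely correctable (Hamming-1 balls of a
#' distance-3 code are disjoint). Deterministic for a fixed seed.
#'
#' Candidate collisions are found with a wildcard-key hash (all
#' `choose(length, min_distance - 1)` position-deleted keys) instead of an
#' all-pairs scan, so thousands of barcodes are generated quickly; tests
#' verify the result against a brute-force O(n^2) distance scan.
#'
#' @param n number of barcodes
#' @param length barcode length in nucleotides (default 15)
#' @param min_distance minimum pairwise Hamming distance (default 3)
#' @param seed integer seed
#' @param max_rounds iteration budget before a capacity error is raised
#' @return character vector of `n` distinct DNA barcodes
#' @export
generate_barcodes <- function(n, length = 15L, min_distance = 3L, seed,
                              max_rounds = 50L) {
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (n > 1L && min_distance > length)
    stop("capacity error: minimum distance exceeds barcode length",
         call. = FALSE)
  if (4^length < 4 * n)
    stop("capacity error: barcode space too small for n codes",
         call. = FALSE)
  with_seed(seed, {
    kept <- character(0)
    round <- 0L
    while (length(kept) < n) {
      round <- round + 1L
      if (round > max_rounds)
        stop("capacity error: could not place ", n,
             " barcodes within the iteration budget", call. = FALSE)
      need <- n - length(kept)
      cand <- unique(random_seq(ceiling(need * 1.3) + 8L, length))
      pool <- c(kept, setdiff(cand, kept))
      pool <- .prune_close_barcodes(pool, length, min_distance,
                                    n_protected = length(kept))
      kept <- pool[seq_len(min(length(pool), n))]
    }
    kept
  })
}

# Remove barcodes violating the minimum distance, preferring to keep the
# first `n_protected` entries (already accepted in earlier rounds).
#' @noRd
.prune_close_barcodes <- function(pool, len, min_distance, n_protected = 0L) {
  d <- min_distance - 1L  # positions deleted per wildcard key
  if (d <= 0L) return(unique(pool))
  del_sets <- utils::combn(len, d, simplify = FALSE)
  n <- length(pool)
  chars <- do.call(rbind, strsplit(pool, "", fixed = TRUE))
  bad_pairs <- list()
  for (ds in del_sets) {
    keys <- apply(chars[, -ds, drop = FALSE], 1L, paste0, collapse = "")
    dup <- which(duplicated(keys) | duplicated(keys, fromLast = TRUE))
    if (length(dup) > 0L) {
      for (grp in split(dup, keys[dup])) {
        if (length(grp) > 1L) bad_pairs[[length(bad_pairs) + 1L]] <- grp
      }
    }
  }
  if (length(bad_pairs) == 0L) return(pool)
  drop <- logical(n)
  for (grp in bad_pairs) {
    grp <- grp[!drop[grp]]
    if (length(grp) < 2L) next
    # verify true distances for every pair, then drop the later member
    for (i in seq_len(length(grp) - 1L)) {
      for (j in seq(i + 1L, length(grp))) {
        a <- grp[i]; b <- grp[j]
        if (drop[a] || drop[b]) next
        if (sum(chars[a, ] != chars[b, ]) < min_distance)
          drop[max(a, b)] <- TRUE
      }
    }
  }
  if (any(drop[seq_len(n_protected)]))
    drop[seq_len(n_protected)] <- FALSE  # never drop accepted codes
  pool[!drop]
}

#' Default design-library configuration
#'
#' Group sizes chosen to exercise every design family at desk scale; the
#' full-factorial group is exhaustive by construction (256 RppH sites x
#' configured RBS variants).
#'
#' @param groups named list overriding per-group settings
#' @return configuration list for [generate_design_library()]
#' @export
library_config <- function(groups = NULL) {
  default <- list(
    full_factorial_polyA = list(rbs_variants = FULL_FACTORIAL_RBS),
    structure_series = list(n = 1500L),
    g_quadruplex = list(n = 800L),
    i_motif = list(n = 600L),
    motif_insertion = list(n = 400L),
    rbs_sweep = list(n = 420L)
  )
  if (!is.null(groups)) default <- groups
  list(groups = default)
}

#' Generate a designed 5' UTR variant library
#'
#' Enumerates UTR variants for each configured design group and attaches
#' barcodes, designed single-stranded-region annotations, and surrogate
#' translation initiation rates (computed with the package's own TIR
#' calculator on the designed transcript, mirroring how the constructs
#' would be designed with the same model used for featurization).
#'
#' @param config list from [library_config()]; group names must be drawn
#'   from the known design-group vocabulary
#' @param seed integer seed
#' @return data.frame, one row per variant: `variant_id`, `design_group`,
#'   `utr_seq` (RNA), `rpph_site`, `barcode`, `rbs_variant_index`, plus
#'   generator annotations (`ssrna_design_nt`, `spacer_seq`, `has_g4`,
#'   `has_imotif`, `tir_au`)
#' @export
generate_design_library <- function(config = library_config(), seed = 1L) {
  groups <- config$groups
  if (length(groups) == 0L)
    stop("configuration error: no design groups configured", call. = FALSE)
  unknown <- setdiff(names(groups), DESIGN_GROUPS)
  if (length(unknown) > 0L)
    stop("configuration error: unknown design group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  rbs_tab <- rbs_variant_table()
  parts <- with_seed(seed, {
    lapply(names(groups), function(g) {
      spec <- groups[[g]]
      if (startsWith(g, "full_factorial")) {
        .gen_full_factorial(g, spec, rbs_tab)
      } else {
        switch(g,
               structure_series = .gen_structure_series(spec$n, rbs_tab),
               g_quadruplex = .gen_tertiary(spec$n, rbs_tab, "G"),
               i_motif = .gen_tertiary(spec$n, rbs_tab, "C"),
               motif_insertion = .gen_motif_insertion(spec$n, rbs_tab),
               rbs_sweep = .gen_rbs_sweep(spec$n, rbs_tab))
      }
    })
  })
  lib <- do.call(rbind, parts)
  lib$variant_id <- sprintf("%s_%05d", lib$design_group,
                            stats::ave(seq_len(nrow(lib)), lib$design_group,
                                       FUN = seq_along))
  lib$rpph_site <- substr(lib$utr_seq, 1L, 4L)
  lib$barcode <- generate_barcodes(nrow(lib), seed = seed + 7777L)
  # surrogate TIR of the designed (nominal) transcript
  lib$tir_au <- vapply(lib$utr_seq, function(u) {
    surrogate_tir_provider(paste0(u, dna_to_rna(CDS_DNA)), nchar(u))
  }, numeric(1), USE.NAMES = FALSE)
  rownames(lib) <- NULL
  lib[, c("variant_id", "design_group", "utr_seq", "rpph_site", "barcode",
          "rbs_variant_index", "ssrna_design_nt", "spacer_seq", "has_g4",
          "has_imotif", "tir_au")]
}

#' @noRd
.all_4mers <- function() {
  g <- expand.grid(RNA_ALPHABET, RNA_ALPHABET, RNA_ALPHABET, RNA_ALPHABET,
                   stringsAsFactors = FALSE)
  apply(g[, 4:1], 1L, paste0, collapse = "")
}

#' @noRd
.row <- function(group, utr, rbs_idx, ssrna_nt, spacer, g4 = FALSE,
                 im = FALSE) {
  data.frame(design_group = group, utr_seq = utr,
             rbs_variant_index = rbs_idx, ssrna_design_nt = ssrna_nt,
             spacer_seq = spacer, has_g4 = g4, has_imotif = im,
             stringsAsFactors = FALSE)
}

#' @noRd
.gen_full_factorial <- function(group, spec, rbs_tab) {
  spacer <- FF_SPACERS[[group]]
  rbs_idx <- spec$rbs_variants
  if (is.null(rbs_idx)) rbs_idx <- FULL_FACTORIAL_RBS
  sites <- .all_4mers()
  grid <- expand.grid(site = sites, rbs = rbs_idx, stringsAsFactors = FALSE)
  utr <- paste0(grid$site, spacer, rbs_tab$rbs_seq[grid$rbs])
  .row(group, utr, grid$rbs, nchar(spacer), spacer)
}

# Designed-unstructured spacers: A/C-biased with scarce G/U so that the
# region stays single-stranded when folded (complementary 3-runs are rare),
# matching the design intent that these regions ARE the ssRNA amount.
#' @noRd
.random_spacer <- function(len, alphabet = RNA_ALPHABET,
                           prob = c(A = 0.45, C = 0.30, G = 0.10,
                                    U = 0.15)) {
  if (len == 0L) return("")
  random_seq(1L, len, alphabet = alphabet, prob = prob[alphabet])
}

#' @noRd
.gen_structure_series <- function(n, rbs_tab) {
  sites <- random_seq(n, 4L, alphabet = RNA_ALPHABET)
  rbs_idx <- rep_len(seq_len(nrow(rbs_tab)), n)
  lens <- rep_len(0:40, n)
  stems <- rep_len(c(0L, 2L, 8L, 16L), n)
  utr <- character(n); spacer <- character(n)
  for (i in seq_len(n)) {
    spacer[i] <- .random_spacer(lens[i])
    hp <- ""
    if (stems[i] > 0L) {
      stem <- random_seq(1L, stems[i], alphabet = RNA_ALPHABET)
      hp <- paste0(stem, "GAAA", .rna_revcomp(stem))
    }
    utr[i] <- paste0(sites[i], spacer[i], hp, rbs_tab$rbs_seq[rbs_idx[i]])
  }
  .row("structure_series", utr, rbs_idx, lens, spacer)
}

#' @noRd
.rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA", paste(rev(seq_chars(x)), collapse = ""))
}

#' @noRd
.gen_tertiary <- function(n, rbs_tab, base = "G") {
  run <- strrep(base, 3L)
  loop_alpha <- setdiff(RNA_ALPHABET, base)
  sites <- random_seq(n, 4L, alphabet = RNA_ALPHABET)
  rbs_idx <- rep_len(seq_len(nrow(rbs_tab)), n)
  lens <- rep_len(0:40, n)
  utr <- character(n); spacer <- character(n)
  for (i in seq_len(n)) {
    spacer[i] <- .random_spacer(lens[i], alphabet = loop_alpha)
    loops <- vapply(1:3, function(j) .random_spacer(6L, loop_alpha),
                    character(1))
    cassette <- paste0(run, loops[1L], run, loops[2L], run, loops[3L], run)
    utr[i] <- paste0(sites[i], spacer[i], cassette,
                     rbs_tab$rbs_seq[rbs_idx[i]])
  }
  .row(if (base == "G") "g_quadruplex" else "i_motif", utr, rbs_idx, lens,
       spacer, g4 = base == "G", im = base == "C")
}

#' @noRd
.gen_motif_insertion <- function(n, rbs_tab) {
  # concrete RNA instantiations of the default IUPAC motif set
  inst <- c("AAUUA", "AUUUA", "UAUUU", "AGGAU", "AGGGA", "AAGGA")
  sites <- random_seq(n, 4L, alphabet = RNA_ALPHABET)
  rbs_idx <- rep_len(seq_len(nrow(rbs_tab)), n)
  copies <- rep_len(1:5, n)
  utr <- character(n); spacer <- character(n)
  for (i in seq_len(n)) {
    ms <- paste0(sample(inst, copies[i], replace = TRUE), collapse = "")
    spacer[i] <- paste0(.random_spacer(6L), ms, .random_spacer(4L))
    utr[i] <- paste0(sites[i], spacer[i], rbs_tab$rbs_seq[rbs_idx[i]])
  }
  .row("motif_insertion", utr, rbs_idx, nchar(spacer), spacer)
}

#' @noRd
.gen_rbs_sweep <- function(n, rbs_tab) {
  sites <- random_seq(n, 4L, alphabet = RNA_ALPHABET)
  rbs_idx <- rep_len(seq_len(nrow(rbs_tab)), n)
  spacer <- vapply(seq_len(n), function(i) .random_spacer(10L), character(1))
  utr <- paste0(sites, spacer, rbs_tab$rbs_seq[rbs_idx])
  .row("rbs_sweep", utr, rbs_idx, 10L, spacer)
}
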