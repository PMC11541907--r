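# Pluggable biophysical providers. The built-in surrogates are deliberately
# simple, deterministic stand-ins for full thermodynamic calculators: a
# -10-element PWM plus initial-transcribed-region composition for
# transcription initiation, and Shine-Dalgarno complementarity with
# structure occlusion of the ribosome footprint for translation initiation.

MINUS10_CONSENSUS <- "TATAAT"

#' Surrogate site-specific transcription initiation provider
#'
#' Scores every candidate transcription start offset of a construct:
#' matches of the upstream hexamer (positions -12..-7 relative to the
#' start) to the -10 consensus, plus a position-weighted composition term
#' over the first 20 transcribed nucleotides (the ITR), so any single-nt
#' change within the ITR changes the rate. Rates are positive and
#' deterministic.
#'
#' @param construct DNA string (coding strand)
#' @param min_offset smallest candidate start offset (0-based; needs 12 nt
#'   of upstream context)
#' @return data.frame `tss_offset` (0-based), `tx_rate` (au), sorted by
#'   decreasing rate with ties broken by smaller offset
#' @export
surrogate_tx_provider <- function(construct, min_offset = 13L) {
  len <- nchar(construct)
  offs <- seq.int(min_offset, len - 5L)
  if (length(offs) == 0L)
    stop("provider error: construct too short for any start site",
         call. = FALSE)
  cons <- seq_chars(MINUS10_CONSENSUS)
  itr_w <- c(A = 0.30, C = 0.10, G = 0.15, T = 0.25)
  ch <- seq_chars(construct)
  rate <- vapply(offs, function(o) {
    hex <- ch[(o - 11L):(o - 6L)]
    m <- sum(hex == cons)
    itr <- ch[(o + 1L):min(len, o + 20L)]
    comp <- sum(itr_w[itr] * 0.92^(seq_along(itr) - 1L), na.rm = TRUE)
    exp(1.5 * m + 0.3 * comp)
  }, numeric(1))
  out <- data.frame(tss_offset = offs, tx_rate = rate)
  out[order(-out$tx_rate, out$tss_offset), , drop = FALSE]
}

#' Surrogate translation initiation rate provider
#'
#' Scans the 18 nt upstream of the start codon for the best ungapped
#' Shine-Dalgarno consensus match (with a spacing penalty away from the
#' canonical ~6.5 nt), folds a local window, and penalizes pairing within
#' the ribosome footprint (-12..+4 around the start). The result is mapped
#' to 10^[0, 5] au, matching the dynamic range of thermodynamic RBS models.
#'
#' @param mrna RNA string
#' @param cds_start 0-based offset of the start codon within `mrna`
#' @param fold_provider folding function used for the occlusion term
#' @return translation initiation rate in au (scalar, positive)
#' @export
surrogate_tir_provider <- function(mrna, cds_start,
                                   fold_provider = fold_rna) {
  len <- nchar(mrna)
  if (cds_start < 0L || cds_start > len)
    stop("cds_start outside sequence", call. = FALSE)
  ch <- seq_chars(mrna)
  cons <- seq_chars(SD_CONSENSUS)
  sd_score <- 0
  if (cds_start >= 9L) {
    w0s <- seq.int(max(0L, cds_start - 18L), cds_start - 9L)
    sd_score <- max(vapply(w0s, function(w0) {
      win <- ch[(w0 + 1L):(w0 + 6L)]
      spacing <- cds_start - (w0 + 6L)
      sum(win == cons) - 0.25 * abs(spacing - 6.5)
    }, numeric(1)))
  }
  # occlusion: fraction of the ribosome footprint that is base-paired
  w_lo <- max(0L, cds_start - 20L)
  w_hi <- min(len, cds_start + 15L)
  sub <- substr(mrna, w_lo + 1L, w_hi)
  pt <- fold_provider(sub)
  fp <- seq.int(max(0L, cds_start - 12L), min(len, cds_start + 4L) - 1L)
  fp_local <- fp - w_lo + 1L
  fp_local <- fp_local[fp_local >= 1L & fp_local <= nchar(sub)]
  pf <- if (length(fp_local) > 0L) mean(pt[fp_local] > 0L) else 0
  log10_tir <- min(max(0.85 * sd_score - 4 * pf, 0), 5)
  10^log10_tir
}

#' Fold an RNA sequence (built-in provider)
#'
#' Self-contained weighted base-pair-maximization folder (GC=3, AU=2, GU=1,
#' minimum hairpin loop 3, isolated pairs removed). A Vienna-class MFE
#' provider with the same signature can be plugged in anywhere a
#' `fold_provider` argument appears.
#'
#' @param seq RNA string
#' @param blocked optional logical vector marking positions excluded from
#'   pairing (e.g. a tertiary-structure span)
#' @return integer pair table, 1-based partner index per position (0 =
#'   unpaired)
#' @export
fold_rna <- function(seq, blocked = NULL) {
  ch <- seq_chars(toupper(dna_to_rna(seq)))
  code <- match(ch, RNA_ALPHABET) - 1L
  if (anyNA(code))
    stop("fold error: sequence contains non-ACGU characters", call. = FALSE)
  if (is.null(blocked)) blocked <- rep(FALSE, length(code))
  .fold_cpp(code, blocked)
}

#' Dot-bracket rendering of a pair table
#' @param pair_table integer vector from [fold_rna()]
#' @return dot-bracket string
#' @export
pairs_to_dotbracket <- function(pair_table) {
  n <- length(pair_table)
  out <- rep(".", n)
  out[pair_table > seq_len(n)] <- "("
  out[pair_table > 0L & pair_table < seq_len(n)] <- ")"
  paste0(out, collapse = "")
}

#' Default provider set
#'
#' @param tx_provider transcription-site provider
#' @param tir_provider translation-rate provider
#' @param fold_provider folding provider
#' @return named list of providers
#' @export
default_providers <- function(tx_provider = surrogate_tx_provider,
                              tir_provider = surrogate_tir_provider,
                              fold_provider = fold_rna) {
  list(tx = tx_provider, tir = tir_provider, fold = fold_provider)
}
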