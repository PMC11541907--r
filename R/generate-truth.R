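# Ground-truth decay constants. Effects are additive in 1/min on top of a
# baseline, with the RppH-site contribution implemented as a multiplicative
# factor on the baseline (4-fold span across 4-mers) converted to an
# additive component, so every component is separable for recovery tests.

#' Default ground-truth effect parameters
#'
#' The defaults encode the stated world the generator emulates:
#' decay rises by ~0.01 (1/min) per single-stranded nucleotide up to a
#' 33-nt saturation (peak ~0.4 1/min for an unprotected transcript), a
#' G-quadruplex renders decay flat at ~0.2 1/min independent of ssRNA
#' length, an i-motif pushes decay up toward ~0.5 1/min, the RppH 4-mer
#' spans a 4-fold multiplicative range (homopolymeric sites fastest),
#' ribosome protection is a decreasing sigmoid of log-TIR saturating near
#' 5e4 au, and decay constants are clamped to [0.027, 2.24] 1/min
#' (half-lives 25.4 to 0.31 min).
#'
#' @param ... overrides of individual parameters
#' @return named list of effect parameters
#' @export
truth_params <- function(...) {
  p <- list(
    baseline = 0.07,        # 1/min, neutral-site unprotected floor term
    rpph_fold = 4,          # multiplicative span of the RppH-site factor
    ssrna_slope = 0.01,     # 1/min per ssRNA nt
    ssrna_sat = 33,         # nt, saturation of the ssRNA term
    comp_amp = 0.3,         # A/C-rich vs G/U-rich steepness modulation
    g4_level = 0.13,        # 1/min, replaces the ssRNA term when G4 present
    imotif_target = 0.5,    # 1/min, level i-motifs push decay toward
    protection_max = 0.06,  # 1/min, maximal ribosome protection
    tir_mid = 3000,         # au, protection sigmoid midpoint
    tir_width = 0.4,        # decades, protection sigmoid width
    k_floor = 0.027,        # 1/min (half-life 25.4 min)
    k_cap = 2.24,           # 1/min (half-life 0.31 min)
    sigma_k = 0.15,         # log-normal sd of biological noise on k
    sigma_m0 = 0.2,         # log-normal sd of initial-abundance noise
    m_scale = 100,          # synthesis rate: m0 = m_scale / (k + growth)
    growth_rate = 0.028     # 1/min dilution by exponential growth
                            # (~25-min doubling), caps steady-state levels
                            # of very stable mRNAs
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad) > 0L)
    stop("configuration error: unknown truth parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  p[names(ov)] <- ov
  chk <- c("rpph_fold", "ssrna_slope", "ssrna_sat", "g4_level",
           "imotif_target", "protection_max", "sigma_k", "sigma_m0",
           "comp_amp")
  for (nm in chk) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("configuration error: `", nm, "` must be non-negative",
           call. = FALSE)
  }
  if (p$rpph_fold == 0 || p$k_floor <= 0 || p$k_cap <= p$k_floor)
    stop("configuration error: invalid rpph_fold / k bounds", call. = FALSE)
  p
}

#' Multiplicative RppH-site factor for a 4-mer
#'
#' Composition skew (how homopolymeric the site is) maps to the factor:
#' a perfectly balanced 4-mer (all four bases distinct) gets
#' `fold^-0.5` (most stable) and a homopolymer gets `fold^0.5` (fastest
#' decay), giving a `fold`-span across all 256 sites.
#'
#' @param site 4-nt RNA string(s)
#' @param fold span of the factor (default 4)
#' @return numeric factor(s)
#' @export
rpph_site_factor <- function(site, fold = 4) {
  vapply(site, function(s) {
    ch <- seq_chars(s)
    if (length(ch) != 4L) stop("RppH site must be 4 nt", call. = FALSE)
    imbalance <- (max(table(ch)) - 1) / 3
    fold^(imbalance - 0.5)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Composition modulation of the ssRNA slope
#'
#' A/C-rich single-stranded regions (stiff, accessible) decay faster per
#' nucleotide than G/U-rich regions.
#' @noRd
.comp_factor <- function(spacer, amp) {
  vapply(spacer, function(s) {
    if (nchar(s) == 0L) return(1)
    fr <- base_fractions(s)
    1 + amp * ((fr[["A"]] + fr[["C"]]) - (fr[["G"]] + fr[["U"]]))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate ground-truth decay parameters for a design library
#'
#' @param library data.frame from [generate_design_library()]
#' @param params list from [truth_params()]
#' @param seed integer seed (biological noise)
#' @return data.frame with `variant_id`, `k_true` (1/min), `m0_true`,
#'   additive effect components (`baseline`, `rpph`, `ssrna`, `translation`,
#'   `g4`, `imotif`), `k_det` (noise-free clamped sum) and the applied
#'   `noise_mult`; `k_true = clamp(sum(components)) * noise_mult`, reclamped
#' @export
generate_truth <- function(library, params = truth_params(), seed = 1L) {
  if (nrow(library) == 0L) stop("library is empty", call. = FALSE)
  p <- params
  mult <- rpph_site_factor(library$rpph_site, p$rpph_fold)
  rpph <- p$baseline * (mult - 1)
  cf <- .comp_factor(library$spacer_seq, p$comp_amp)
  ssrna <- p$ssrna_slope * cf * pmin(library$ssrna_design_nt, p$ssrna_sat)
  g4 <- ifelse(library$has_g4, p$g4_level - ssrna, 0)
  pre <- p$baseline + rpph + ssrna + g4
  imotif <- ifelse(library$has_imotif, pmax(0, p$imotif_target - pre), 0)
  translation <- -p$protection_max *
    plogis((log10(pmax(library$tir_au, 1)) - log10(p$tir_mid)) / p$tir_width)
  k_det <- pmin(pmax(pre + imotif + translation, p$k_floor), p$k_cap)
  with_seed(seed, {
    noise <- if (p$sigma_k > 0)
      rlnorm(nrow(library), -p$sigma_k^2 / 2, p$sigma_k) else
        rep(1, nrow(library))
    k_true <- pmin(pmax(k_det * noise, p$k_floor), p$k_cap)
    m0_noise <- if (p$sigma_m0 > 0)
      rlnorm(nrow(library), -p$sigma_m0^2 / 2, p$sigma_m0) else
        rep(1, nrow(library))
    data.frame(variant_id = library$variant_id,
               k_true = k_true,
               m0_true = p$m_scale / (k_true + p$growth_rate) * m0_noise,
               baseline = p$baseline, rpph = rpph, ssrna = ssrna,
               translation = translation, g4 = g4, imotif = imotif,
               k_det = k_det, noise_mult = noise,
               stringsAsFactors = FALSE)
  })
}
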