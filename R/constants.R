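# Fixed genetic-context constants for the simulated expression system.
#
# The reporter architecture mirrors a plasmid library driven by one
# constitutive sigma70 promoter: every construct is
#   [promoter][designed 5' UTR][constant CDS prefix]
# with transcription nominally starting right after the promoter, so the
# first four transcribed nucleotides (the RppH binding site) are the first
# four UTR nucleotides.

# Constitutive promoter with a consensus -10 element (TATAAT) placed so the
# nominal transcription start site sits at offset nchar(PROMOTER_DNA)
# (0-based) with a 6-nt discriminator. Derived from the J23100 layout.
PROMOTER_DNA <- "TTGACGGCTAGCTCAGTCCTAGGTATAATGCTAGC"

# Constant CDS prefix (synthetic reporter N-terminus, coding strand).
# Deliberately T/U-free and without G/C runs so the start-codon region
# forms essentially no structure on its own and cannot pair with A-rich
# UTR elements; designed RBS strength is then not confounded by the
# constant context.
CDS_DNA <- "ATGGCAAAAGCAGAAGCAAAAGCAGCAGAA"

# Reserved barcode for the fixed-mass spike-in RNA control.
SPIKE_BARCODE <- "ATATCGCGAGCTCGA"
SPIKEIN_ID <- "SPIKEIN"

# Default amplicon layout for simulated reads: anchor + barcode + anchor.
READ_ANCHOR_UP <- "CGCTGAGG"
READ_ANCHOR_DOWN <- "TCCTAGGA"

# Shine-Dalgarno consensus used by the surrogate translation model.
SD_CONSENSUS <- "AGGAGG"

#' Designed ribosome binding site variants
#'
#' Twelve RBS variants graded in strength: `m` consensus Shine-Dalgarno
#' nucleotides (remainder replaced with non-complementary filler) at a
#' spacing of 6 or 8 nt from the start codon. Indices are ordered by
#' increasing surrogate-predicted translation initiation rate, spanning
#' roughly 1e0 to 1e5 au. The 5-variant subset used by full-factorial design
#' groups spans a ~10,000-fold range.
#'
#' @return data.frame with columns `rbs_variant_index`, `sd_match`,
#'   `spacing`, `rbs_seq` (RNA: SD region + spacer, start codon excluded),
#'   `ref_tir_au` (surrogate TIR in the reference context); rows ordered by
#'   increasing reference TIR
#' @export
rbs_variant_table <- function() {
  filler <- "UCUCUC"           # zero positional matches to the SD consensus
  spacer_src <- strrep("A", 8L)  # inert against the U-free CDS prefix
  grid <- expand.grid(spacing = c(8L, 6L), sd_match = 1:6)
  seqs <- mapply(function(m, sp) {
    sd_region <- paste0(substr(SD_CONSENSUS, 1L, m),
                        substr(filler, 1L, 6L - m))
    paste0(sd_region, substr(spacer_src, 1L, sp))
  }, grid$sd_match, grid$spacing)
  cds <- dna_to_rna(CDS_DNA)
  ref_tir <- vapply(seqs, function(rbs) {
    utr <- paste0("ACGU", "CAAACAAA", rbs)
    surrogate_tir_provider(paste0(utr, cds), nchar(utr))
  }, numeric(1), USE.NAMES = FALSE)
  o <- order(ref_tir, grid$sd_match, -grid$spacing)
  data.frame(rbs_variant_index = seq_len(nrow(grid)),
             sd_match = grid$sd_match[o],
             spacing = grid$spacing[o],
             rbs_seq = as.character(seqs)[o],
             ref_tir_au = ref_tir[o],
             stringsAsFactors = FALSE)
}

# Indices of the 5 RBS variants used by full-factorial groups (weak ->
# strong, ~10,000-fold span of surrogate TIR).
FULL_FACTORIAL_RBS <- c(2L, 5L, 8L, 10L, 12L)

DESIGN_GROUPS <- c("full_factorial_polyA", "full_factorial_polyU",
                   "full_factorial_AAACAAA", "full_factorial_AAAGAAA",
                   "full_factorial_UUUGUUU", "structure_series",
                   "g_quadruplex", "i_motif", "motif_insertion", "rbs_sweep")

# Single-stranded spacer motifs of the full-factorial design groups.
FF_SPACERS <- c(full_factorial_polyA = strrep("A", 16L),
                full_factorial_polyU = strrep("U", 16L),
                full_factorial_AAACAAA = strrep("AAACAAA", 2L),
                full_factorial_AAAGAAA = strrep("AAAGAAA", 2L),
                full_factorial_UUUGUUU = strrep("UUUGUUU", 2L))
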