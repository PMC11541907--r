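# Sequence utilities shared across the generator, barcode and feature modules.
# RNA strings use A/C/G/U; DNA strings (barcodes, constructs on the coding
# strand) use A/C/G/T. Coordinates are 0-based half-open unless a function
# documents otherwise.

RNA_ALPHABET <- c("A", "C", "G", "U")
DNA_ALPHABET <- c("A", "C", "G", "T")

dna_to_rna <- function(x) chartr("Tt", "Uu", x)
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Split sequences into character matrices / vectors
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Random DNA/RNA strings under the current RNG state
#' @noRd
random_seq <- function(n, len, alphabet = DNA_ALPHABET, prob = NULL) {
  m <- matrix(sample(alphabet, n * len, replace = TRUE, prob = prob),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

#' Hamming distance between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  sum(seq_chars(a) != seq_chars(b))
}

#' GC fraction of a sequence (RNA or DNA)
#' @noRd
gc_fraction <- function(x) {
  ch <- seq_chars(x)
  if (length(ch) == 0L) return(0)
  mean(ch %in% c("G", "C"))
}

#' Base composition fractions (A, C, G, U) of an RNA string
#' @noRd
base_fractions <- function(x) {
  ch <- seq_chars(x)
  if (length(ch) == 0L) return(setNames(rep(0, 4), RNA_ALPHABET))
  tab <- table(factor(ch, levels = RNA_ALPHABET))
  setNames(as.numeric(tab) / length(ch), RNA_ALPHABET)
}

#' Expand an IUPAC nucleotide code string into a regex character pattern
#'
#' Operates on RNA alphabet (T is accepted and treated as U).
#' @noRd
iupac_to_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", U = "U", T = "U",
           R = "[AG]", Y = "[CU]", S = "[CG]", W = "[AU]",
           K = "[GU]", M = "[AC]", B = "[CGU]", D = "[AGU]",
           H = "[ACU]", V = "[ACG]", N = "[ACGU]")
  ch <- seq_chars(toupper(motif))
  bad <- setdiff(ch, names(map))
  if (length(bad) > 0L)
    stop("invalid IUPAC character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  paste0(map[ch], collapse = "")
}

#' All single-substitution (Hamming-1) neighbours of a sequence
#' @noRd
hamming1_neighbours <- function(x, alphabet = DNA_ALPHABET) {
  ch <- seq_chars(x)
  out <- character(0)
  for (i in seq_along(ch)) {
    for (alt in setdiff(alphabet, ch[i])) {
      y <- ch
      y[i] <- alt
      out <- c(out, paste0(y, collapse = ""))
    }
  }
  out
}
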