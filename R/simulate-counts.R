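# Sequencing-count simulation. Reads at each RNA timepoint are multinomial
# over {variants + spike-in}: the spike-in is a constant absolute RNA mass
# mixed into the declining mRNA pool before sampling, so its read share
# rises as the library decays (about tenfold by 16 min under defaults).
# DNA T0 reads are multinomial over abundance-independent library
# frequencies.

DEFAULT_TIMEPOINTS <- c(0, 2, 4, 8, 16)

#' Simulate barcode count tables for a rifampicin chase
#'
#' @param truth data.frame from [generate_truth()]
#' @param depth expected reads per variant per timepoint (total sample reads
#'   = `depth * n_variants`)
#' @param timepoints minutes post rifampicin; must start at 0
#' @param spike_frac spike-in mass as a fraction of total T0 mRNA mass
#'   (the absolute spike mass is constant across timepoints; default 0.02,
#'   i.e. a ~2% read share at T0)
#' @param replicates number of replicate multinomial draws summed per sample
#' @param seed integer seed
#' @return count-table data.frame: `variant_id`, `dna_t0`, `rna_t<t>` for
#'   each timepoint, plus one reserved `SPIKEIN` row holding spike reads
#' @export
simulate_counts <- function(truth, depth = 1000,
                            timepoints = DEFAULT_TIMEPOINTS,
                            spike_frac = 0.02, replicates = 1L, seed = 1L) {
  .check_sim_args(depth, spike_frac, timepoints)
  n <- nrow(truth)
  total <- round(depth * n)
  spike_mass <- spike_frac * sum(truth$m0_true)
  with_seed(seed, {
    rna <- sapply(timepoints, function(t) {
      mass <- truth$m0_true * exp(-truth$k_true * t)
      prob <- c(mass, spike_mass)
      prob <- prob / sum(prob)
      cnt <- rep(0L, n + 1L)
      for (r in seq_len(replicates))
        cnt <- cnt + as.integer(rmultinom(1L, total, prob))
      cnt
    })
    dna <- rep(0L, n + 1L)
    dna[seq_len(n)] <- as.integer(rmultinom(1L, total, rep(1 / n, n)))
    out <- data.frame(variant_id = c(truth$variant_id, SPIKEIN_ID),
                      dna_t0 = dna, stringsAsFactors = FALSE)
    for (i in seq_along(timepoints))
      out[[paste0("rna_t", timepoints[i])]] <- rna[, i]
    out
  })
}

#' Expected (noise-free, infinite-depth) counts
#'
#' Real-valued expectation of [simulate_counts()]; plugging these into the
#' kinetics module returns normalized ratios equal to `exp(-k t)` exactly.
#'
#' @inheritParams simulate_counts
#' @return count-table data.frame with real-valued counts
#' @export
expected_counts <- function(truth, depth = 1000,
                            timepoints = DEFAULT_TIMEPOINTS,
                            spike_frac = 0.02) {
  .check_sim_args(depth, spike_frac, timepoints)
  n <- nrow(truth)
  total <- depth * n
  spike_mass <- spike_frac * sum(truth$m0_true)
  rna <- sapply(timepoints, function(t) {
    mass <- truth$m0_true * exp(-truth$k_true * t)
    tot_mass <- sum(mass) + spike_mass
    total * c(mass, spike_mass) / tot_mass
  })
  out <- data.frame(variant_id = c(truth$variant_id, SPIKEIN_ID),
                    dna_t0 = c(rep(total / n, n), 0),
                    stringsAsFactors = FALSE)
  for (i in seq_along(timepoints))
    out[[paste0("rna_t", timepoints[i])]] <- rna[, i]
  out
}

#' @noRd
.check_sim_args <- function(depth, spike_frac, timepoints) {
  if (!is.finite(depth) || depth <= 0)
    stop("configuration error: `depth` must be positive", call. = FALSE)
  if (!is.finite(spike_frac) || spike_frac < 0)
    stop("configuration error: `spike_frac` must be non-negative",
         call. = FALSE)
  if (length(timepoints) < 2L || timepoints[1L] != 0 ||
      any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing and start at 0",
         call. = FALSE)
}

#' Emit simulated FASTQ files from a count table
#'
#' Each read is `anchor_up + barcode + anchor_down` with independent
#' per-base substitution errors; read totals per sample match the counts.
#'
#' @param counts count table from [simulate_counts()]
#' @param library design library (for variant -> barcode mapping)
#' @param outdir output directory; one FASTQ per sample column
#' @param error_rate per-base substitution probability, in [0, 0.25)
#' @param seed integer seed
#' @return invisible named vector of written file paths
#' @export
emit_reads <- function(counts, library, outdir, error_rate = 0, seed = 1L) {
  if (error_rate < 0 || error_rate >= 0.25)
    stop("`error_rate` must be in [0, 0.25)", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bc <- setNames(c(library$barcode, SPIKE_BARCODE),
                 c(library$variant_id, SPIKEIN_ID))
  samples <- setdiff(colnames(counts), "variant_id")
  paths <- setNames(file.path(outdir, paste0(samples, ".fastq")), samples)
  with_seed(seed, {
    for (s in samples) {
      cnt <- counts[[s]]
      keep <- which(cnt > 0)
      reads <- if (length(keep) > 0L)
        rep(paste0(READ_ANCHOR_UP, bc[counts$variant_id[keep]],
                   READ_ANCHOR_DOWN), cnt[keep]) else character(0)
      if (length(reads) > 0L && error_rate > 0) {
        reads <- .mutate_reads(reads, error_rate)
      }
      con <- file(paths[[s]], "w")
      if (length(reads) > 0L) {
        ids <- sprintf("@%s_read%d", s, seq_along(reads))
        qual <- strrep("I", nchar(reads[1L]))
        writeLines(rbind(ids, reads, "+", qual), con)
      }
      close(con)
    }
  })
  invisible(paths)
}

#' @noRd
.mutate_reads <- function(reads, error_rate) {
  len <- nchar(reads[1L])
  n_mut <- rbinom(length(reads), len, error_rate)
  hit <- which(n_mut > 0L)
  for (i in hit) {
    ch <- seq_chars(reads[i])
    pos <- sample.int(len, n_mut[i])
    for (p in pos) ch[p] <- sample(setdiff(DNA_ALPHABET, ch[p]), 1L)
    reads[i] <- paste0(ch, collapse = "")
  }
  reads
}
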