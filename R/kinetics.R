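# Spike-in normalization and first-order decay fitting.
#
# For variant counts N_i at timepoints t_i and spike-in counts C_i, the
# normalized ratio is R_i = (N_i / N_0) / CR_i with CR_i = C_i / C_0.
# The ratio series is fit to M(t) = e^(-k t) (M0 fixed at 1 in ratio space,
# so k is the single free parameter), minimizing squared error over k >= 0;
# goodness of fit is the squared Pearson correlation of observed vs fitted
# ratios on the linear scale. Half-life t1/2 = ln(2) / k.

#' Normalize a count table with the spike-in control
#'
#' @param table count-table data.frame (see [simulate_counts()]), one
#'   `SPIKEIN` row required
#' @param pseudo replacement for zero RNA counts at t > 0 (keeps ratios
#'   finite; T0 zeros instead flag the variant `low_reads`)
#' @return object of class `normalized_series`: ratio matrix `R`
#'   (variants x timepoints), spike ratios `cr`, timepoints, per-variant
#'   status, and the variant table without the spike row
#' @export
normalize_counts <- function(table, pseudo = 0.5) {
  rna_cols <- grep("^rna_t", colnames(table), value = TRUE)
  timepoints <- as.numeric(sub("^rna_t", "", rna_cols))
  o <- order(timepoints)
  rna_cols <- rna_cols[o]; timepoints <- timepoints[o]
  spike_row <- which(table$variant_id == SPIKEIN_ID)
  if (length(spike_row) != 1L)
    stop("data error: count table must contain one SPIKEIN row",
         call. = FALSE)
  C <- as.numeric(table[spike_row, rna_cols])
  if (C[1L] <= 0)
    stop("data error: spike-in has zero reads at T0", call. = FALSE)
  cr <- C / C[1L]
  vt <- table[-spike_row, , drop = FALSE]
  N <- as.matrix(vt[, rna_cols, drop = FALSE])
  status <- ifelse(N[, 1L] > 0, "ok", "low_reads")
  Nadj <- N
  Nadj[, -1L][Nadj[, -1L] == 0] <- pseudo
  R <- sweep(Nadj / Nadj[, 1L], 2L, cr, "/")
  R[status == "low_reads", ] <- NA_real_
  structure(list(R = R, cr = cr, timepoints = timepoints,
                 status = status, variant_id = vt$variant_id,
                 table = vt),
            class = "normalized_series")
}

#' Fit a single exponential decay curve
#'
#' @param r numeric vector of normalized ratios (R_0 = 1 first)
#' @param timepoints minutes, aligned with `r`
#' @param k_max upper bound of the decay-constant search (1/min)
#' @param r2_threshold fits with Pearson R^2 at or below this are flagged
#'   `nonexponential`
#' @return one-row data.frame: `k` (1/min), `half_life_min`, `r_squared`,
#'   `status` (`ok`, `low_reads`, `nonexponential`, `fit_failed`);
#'   `half_life_min` is `Inf` when k hits the zero bound
#' @export
fit_decay <- function(r, timepoints, k_max = 20, r2_threshold = 0.75) {
  out <- data.frame(k = NA_real_, half_life_min = NA_real_,
                    r_squared = NA_real_, status = "fit_failed",
                    stringsAsFactors = FALSE)
  ok <- is.finite(r)
  if (sum(ok) < 3L) {
    out$status <- if (all(is.na(r))) "low_reads" else "fit_failed"
    return(out)
  }
  r <- r[ok]; tp <- timepoints[ok]
  sse <- function(k) sum((r - exp(-k * tp))^2)
  opt <- tryCatch(optimize(sse, c(0, k_max), tol = 1e-10),
                  error = function(e) NULL)
  if (is.null(opt)) return(out)
  k <- opt$minimum
  # golden search can stall at an interior point when the optimum is at the
  # boundary; snap to 0 when flat
  if (sse(0) <= opt$objective + 1e-12) k <- 0
  fitted <- exp(-k * tp)
  r2 <- if (stats::sd(fitted) > 0 && stats::sd(r) > 0)
    suppressWarnings(cor(r, fitted)^2) else NA_real_
  status <- "ok"
  if (is.finite(r2) && r2 <= r2_threshold) status <- "nonexponential"
  out$k <- k
  out$half_life_min <- if (k < 1e-9) Inf else log(2) / k
  out$r_squared <- r2
  out$status <- status
  out
}

#' Fit decay curves for every variant of a normalized series
#'
#' @param norm a [normalize_counts()] result
#' @inheritParams fit_decay
#' @return data.frame: `variant_id`, `k`, `half_life_min`, `r_squared`,
#'   `status`
#' @export
fit_decay_table <- function(norm, k_max = 20, r2_threshold = 0.75) {
  n <- nrow(norm$R)
  tp <- norm$timepoints
  ks <- .fit_decay_cpp(norm$R, tp, k_max)
  r2 <- rep(NA_real_, n)
  status <- rep("fit_failed", n)
  status[norm$status == "low_reads"] <- "low_reads"
  for (i in which(is.finite(ks) & norm$status != "low_reads")) {
    fitted <- exp(-ks[i] * tp)
    obs <- norm$R[i, ]
    r2[i] <- if (stats::sd(fitted) > 0 && stats::sd(obs) > 0)
      suppressWarnings(cor(obs, fitted)^2) else NA_real_
    status[i] <- if (is.finite(r2[i]) && r2[i] <= r2_threshold)
      "nonexponential" else "ok"
  }
  ks[norm$status == "low_reads"] <- NA_real_
  data.frame(variant_id = norm$variant_id, k = ks,
             half_life_min = ifelse(is.finite(ks) & ks >= 1e-9,
                                    log(2) / ks,
                                    ifelse(is.finite(ks), Inf, NA_real_)),
             r_squared = r2, status = status, stringsAsFactors = FALSE)
}

#' Apply read-depth and fit-quality filters
#'
#' Retains variants with at least `min_reads` DNA T0 reads, at least
#' `min_reads` RNA T0 reads, and fit R^2 above `r2_threshold`.
#'
#' @param fits data.frame from [fit_decay_table()]
#' @param table the count table the fits came from
#' @param min_reads minimum T0 read count (default 100)
#' @param r2_threshold minimum exponential-fit R^2 (exclusive, default 0.75)
#' @return list with `fits` (retained rows) and `report` (tallies, medians
#'   per count column, per-timepoint coverage at `min_reads`, and the
#'   half-life range of retained fits)
#' @export
apply_qc <- function(fits, table, min_reads = 100, r2_threshold = 0.75) {
  vt <- table[table$variant_id != SPIKEIN_ID, , drop = FALSE]
  m <- match(fits$variant_id, vt$variant_id)
  if (anyNA(m))
    stop("fits and count table are not aligned by variant_id", call. = FALSE)
  vt <- vt[m, , drop = FALSE]
  cnt_cols <- c("dna_t0", grep("^rna_t", colnames(vt), value = TRUE))
  dna_ok <- vt$dna_t0 >= min_reads
  rna_ok <- vt$rna_t0 >= min_reads
  r2_ok <- !is.na(fits$r_squared) & fits$r_squared > r2_threshold &
    fits$status %in% c("ok")
  keep <- dna_ok & rna_ok & r2_ok
  hl <- fits$half_life_min[keep]
  report <- list(
    n_variants = nrow(fits),
    n_dna_pass = sum(dna_ok),
    n_rna_pass = sum(rna_ok),
    n_r2_pass = sum(r2_ok & dna_ok & rna_ok),
    n_pass = sum(keep),
    frac_dna_detected = mean(vt$dna_t0 >= 1),
    medians = vapply(cnt_cols, function(cc) median(vt[[cc]]), numeric(1)),
    coverage_ge_min = vapply(cnt_cols, function(cc)
      mean(vt[[cc]] >= min_reads), numeric(1)),
    half_life_range = if (length(hl) > 0L)
      range(hl[is.finite(hl)]) else c(NA_real_, NA_real_)
  )
  list(fits = fits[keep, , drop = FALSE], report = report)
}

#' Steady-state mRNA level outcome
#'
#' Natural log of the RNA/DNA T0 read-count ratio, with a 0.5 pseudocount
#' substituted for zero counts.
#'
#' @param table count table
#' @param pseudocount value replacing zeros (default 0.5)
#' @return named numeric vector of ln(N_0 / DNA_0) per variant
#' @export
steady_state_level <- function(table, pseudocount = 0.5) {
  vt <- table[table$variant_id != SPIKEIN_ID, , drop = FALSE]
  n0 <- ifelse(vt$rna_t0 == 0, pseudocount, vt$rna_t0)
  d0 <- ifelse(vt$dna_t0 == 0, pseudocount, vt$dna_t0)
  setNames(log(n0 / d0), vt$variant_id)
}

#' ln-level outcomes for every timepoint
#'
#' ln(N_i / DNA_0) per variant and timepoint (DNA denominators always use
#' T0 plasmid counts), with the same pseudocount policy as
#' [steady_state_level()].
#'
#' @inheritParams steady_state_level
#' @return matrix variants x timepoints (column names `t<minutes>`)
#' @export
level_outcomes <- function(table, pseudocount = 0.5) {
  vt <- table[table$variant_id != SPIKEIN_ID, , drop = FALSE]
  rna_cols <- grep("^rna_t", colnames(vt), value = TRUE)
  tp <- as.numeric(sub("^rna_t", "", rna_cols))
  rna_cols <- rna_cols[order(tp)]
  d0 <- ifelse(vt$dna_t0 == 0, pseudocount, vt$dna_t0)
  out <- vapply(rna_cols, function(cc) {
    n <- ifelse(vt[[cc]] == 0, pseudocount, vt[[cc]])
    log(n / d0)
  }, numeric(nrow(vt)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  rownames(out) <- vt$variant_id
  colnames(out) <- paste0("t", sort(tp))
  out
}
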