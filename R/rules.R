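# Design-rule extraction: systematic single-feature queries of a trained
# bundle (sweeps) and multi-factor stratification of measured decay rates.
# Sweeps follow the convention that all five predominant isoforms are
# treated as having identical features, so a queried change applies to
# every isoform block at once.

#' Copy the rank-1 isoform block onto all other blocks
#'
#' @param fv named feature vector
#' @param schema the schema it follows
#' @return feature vector with identical isoform blocks
#' @export
unify_isoform_blocks <- function(fv, schema) {
  iso1 <- grep("^iso1_", names(fv), value = TRUE)
  for (r in seq.int(2L, schema$n_isoforms)) {
    tgt <- sub("^iso1_", paste0("iso", r, "_"), iso1)
    ok <- tgt %in% names(fv)
    fv[tgt[ok]] <- fv[iso1[ok]]
  }
  fv
}

#' Baseline mRNA specification for model sweeps
#'
#' The documented high-stability baseline that sweeps perturb: a balanced
#' RppH site, a short designed-unstructured spacer, the strongest RBS, no
#' tertiary structure.
#'
#' @param site RppH 4-mer (default balanced `ACGU`)
#' @param spacer single-stranded spacer sequence
#' @param rbs_variant_index RBS variant (default strongest)
#' @return baseline specification list
#' @export
baseline_spec <- function(site = "ACGU", spacer = "CAAA",
                          rbs_variant_index = 12L) {
  list(site = site, spacer = spacer,
       rbs_variant_index = as.integer(rbs_variant_index))
}

# Build library-shaped rows for a set of query variants
#' @noRd
.spec_rows <- function(site, spacer, rbs_idx, extra_utr = "") {
  rbs_tab <- rbs_variant_table()
  utr <- paste0(site, spacer, extra_utr, rbs_tab$rbs_seq[rbs_idx])
  data.frame(variant_id = sprintf("query_%04d", seq_along(utr)),
             design_group = "rbs_sweep", utr_seq = utr, rpph_site = site,
             barcode = strrep("A", 15L), rbs_variant_index = rbs_idx,
             ssrna_design_nt = nchar(spacer), spacer_seq = spacer,
             has_g4 = FALSE, has_imotif = FALSE, tir_au = NA_real_,
             stringsAsFactors = FALSE)
}

# Featurize query variants. Queries are featurized exactly like training
# constructs (the printed convention of assigning all five isoforms
# identical features is available via unify_isoform_blocks(), but pushes
# queries outside the training distribution of this surrogate world and is
# therefore not applied by default; see the methods vignette).
#' @noRd
.featurize_queries <- function(rows, providers, schema, unify = FALSE) {
  M <- featurize_library(rows, providers, schema)
  if (unify) {
    for (i in seq_len(nrow(M)))
      M[i, ] <- unify_isoform_blocks(M[i, ], schema)
  }
  M
}

#' Baseline feature vector of a sweep specification
#'
#' @param baseline a [baseline_spec()]
#' @param schema feature schema
#' @param providers provider set
#' @return named feature vector with unified isoform blocks
#' @export
baseline_features <- function(baseline = baseline_spec(),
                              schema = feature_schema(),
                              providers = default_providers()) {
  rows <- .spec_rows(baseline$site, baseline$spacer,
                     baseline$rbs_variant_index)
  .featurize_queries(rows, providers, schema)[1L, ]
}

#' One prediction pass for a matrix of queried feature vectors
#' @noRd
.predict_queries <- function(bundle, M) {
  lv <- predict_levels(bundle, M)
  if (is.null(dim(lv))) lv <- matrix(lv, nrow = 1L)
  list(level0 = lv[, 1L], k = predict_decay(bundle, M))
}

# Average model predictions over n_reps seeded spacer draws per grid point.
# Single-construct predictions carry tree-model noise; averaging over
# equivalent baseline realisations isolates the queried knob's effect.
#' @noRd
.averaged_queries <- function(bundle, providers, schema, baseline,
                              n_reps, sites = NULL, rbs_idx = NULL,
                              spacer_lens = NULL, composition = "designed",
                              extras = NULL) {
  site <- if (is.null(sites)) baseline$site else sites
  rbs <- if (is.null(rbs_idx)) baseline$rbs_variant_index else rbs_idx
  n_grid <- max(length(site), length(rbs),
                length(spacer_lens), length(extras), 1L)
  lvl <- numeric(n_grid)
  kk <- numeric(n_grid)
  tir <- numeric(n_grid)
  with_seed(1L, {
    for (r in seq_len(n_reps)) {
      spacer <- if (is.null(spacer_lens)) {
        .random_spacer(nchar(baseline$spacer))
      } else {
        vapply(spacer_lens, function(len) .sweep_spacer(len, composition),
               character(1))
      }
      rows <- .spec_rows(site, spacer, rbs,
                         extra_utr = if (is.null(extras)) "" else extras)
      M <- .featurize_queries(rows, providers, schema)
      pred <- .predict_queries(bundle, M)
      lvl <- lvl + pred$level0 / n_reps
      kk <- kk + pred$k / n_reps
      tir <- tir + 10^M[, "iso1_log_tir"] / n_reps
    }
  })
  list(level0 = lvl, k = kk, tir = tir)
}

#' Sweep all 256 RppH binding sites through a trained bundle
#'
#' Rebuilds the baseline mRNA with each of the 256 possible 4-mer RppH
#' sites, re-featurizes it (so every sequence-determined feature moves
#' coherently), unifies the isoform blocks, and reports the predicted
#' change in steady-state ln mRNA level and the predicted decay rate,
#' ranked by level change.
#'
#' @param bundle trained `decay_bundle`
#' @param baseline a [baseline_spec()]
#' @param providers provider set used for featurization
#' @return object of class `sweep_result`: data.frame with `site`,
#'   `delta_ln_level`, `pred_k`, ranked; plus top/bottom-10 site lists
#' @export
sweep_rpph <- function(bundle, baseline = baseline_spec(),
                       providers = default_providers(), n_reps = 8L) {
  schema <- bundle$schema
  sites <- .all_4mers()
  agg <- .averaged_queries(bundle, providers, schema, sites = sites,
                           baseline = baseline, n_reps = n_reps)
  base_i <- which(sites == baseline$site)
  out <- data.frame(site = sites,
                    delta_ln_level = agg$level0 - agg$level0[base_i],
                    pred_k = agg$k, stringsAsFactors = FALSE)
  out <- out[order(-out$delta_ln_level), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(table = out,
                 top10 = head(out$site, 10L),
                 bottom10 = utils::tail(out$site, 10L),
                 swept_feature = "rpph_site"),
            class = "sweep_result")
}

#' Sweep a scalar design knob through a trained bundle
#'
#' Each knob is applied at the sequence level — the baseline mRNA is
#' rebuilt with the knob changed, re-featurized, and isoform blocks are
#' unified — so every feature the knob determines moves coherently:
#' * `tir`: sweeps the designed RBS-variant ladder (grid ignored; the
#'   reported grid is each query's featurized TIR in au) and detects the
#'   plateau onset, the first grid point within `plateau_tol` of the
#'   response range from the asymptote;
#' * `ssrna`: sweeps the spacer length over `grid` (nt) with the requested
#'   `composition`;
#' * `dsrna`: inserts a hairpin of `grid` base pairs (4-nt loop) after the
#'   spacer, leaving the designed ssRNA amount fixed.
#'
#' @param bundle trained `decay_bundle`
#' @param feature `"tir"`, `"ssrna"` or `"dsrna"`
#' @param grid strictly increasing numeric grid (lengths or base pairs;
#'   unused for `tir`)
#' @param baseline a [baseline_spec()]
#' @param composition spacer composition for ssRNA sweeps: `"designed"`
#'   (the generator's designed-unstructured distribution), `"polyA"`,
#'   `"polyC"`, `"polyG"` or `"polyU"`
#' @param providers provider set
#' @param plateau_tol fraction of the response range defining the plateau
#' @return `sweep_result` with `grid`, `pred_ln_level`, `pred_k`, and for
#'   TIR sweeps `plateau_onset`
#' @export
sweep_scalar <- function(bundle, feature = c("tir", "ssrna", "dsrna"),
                         grid = NULL, baseline = baseline_spec(),
                         composition = "designed",
                         providers = default_providers(),
                         plateau_tol = 0.05, n_reps = 8L) {
  feature <- match.arg(feature)
  schema <- bundle$schema
  if (feature == "tir") {
    rbs_idx <- seq_len(nrow(rbs_variant_table()))
    agg <- .averaged_queries(bundle, providers, schema, baseline,
                             n_reps = max(n_reps, 16L), rbs_idx = rbs_idx)
    grid <- agg$tir
  } else if (feature == "ssrna") {
    if (is.null(grid)) grid <- 0:33
    if (any(diff(grid) <= 0) || any(grid < 0))
      stop("grid must be strictly ordered and non-negative", call. = FALSE)
    agg <- .averaged_queries(bundle, providers, schema, baseline, n_reps,
                             spacer_lens = grid, composition = composition)
  } else {
    if (is.null(grid)) grid <- seq(0, 16, by = 2)
    if (any(diff(grid) <= 0) || any(grid < 0))
      stop("grid must be strictly ordered and non-negative", call. = FALSE)
    stems <- vapply(grid, function(bp) {
      if (bp == 0) return("")
      stem <- paste0(rep_len(c("G", "C"), bp), collapse = "")
      paste0(stem, "GAAA", .rna_revcomp(stem))
    }, character(1))
    agg <- .averaged_queries(bundle, providers, schema, baseline, n_reps,
                             extras = stems)
  }
  o <- order(grid)
  grid <- grid[o]
  level0 <- agg$level0[o]
  k <- agg$k[o]
  plateau <- NA_real_
  if (feature == "tir") {
    asym <- level0[length(grid)]
    rng <- diff(range(level0))
    if (rng > 0) {
      onset_idx <- which(abs(level0 - asym) <= plateau_tol * rng)
      plateau <- grid[min(onset_idx)]
    }
  }
  structure(list(table = data.frame(grid = grid, pred_ln_level = level0,
                                    pred_k = k),
                 swept_feature = feature, composition = composition,
                 plateau_onset = plateau),
            class = "sweep_result")
}

#' @noRd
.sweep_spacer <- function(len, composition) {
  if (len == 0L) return("")
  switch(composition,
         designed = .random_spacer(len),
         polyA = strrep("A", len), polyC = strrep("C", len),
         polyG = strrep("G", len), polyU = strrep("U", len),
         stop("unknown composition", call. = FALSE))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep of", x$swept_feature, "over", nrow(x$table), "points\n")
  if (!is.null(x$plateau_onset) && is.finite(x$plateau_onset))
    cat("  plateau onset:", format(x$plateau_onset), "\n")
  invisible(x)
}

#' Rank RppH sites by measured stability
#'
#' @param df data.frame with `rpph_site` and `k` columns
#' @param m number of most-stable sites to return (default 20)
#' @return character vector of the m sites with lowest median k
#' @export
stable_rpph_sites <- function(df, m = 20L) {
  med <- tapply(df$k, df$rpph_site, median)
  names(sort(med))[seq_len(min(m, length(med)))]
}

#' Multi-factor stratification of measured decay rates
#'
#' Applies the configured filters (data-derived stable-RppH class, TIR
#' bound, moderate ssRNA range), then reports the Pearson correlation of k
#' with the stratifying variable (two-tailed t-distribution p-value),
#' quartiles of k and Tukey outlier count.
#'
#' @param df data.frame with columns `k`, `rpph_site`, `tir_au`, `ssrna`
#' @param var name of the stratifying variable column; `log_tir` uses
#'   log10(`tir_au`)
#' @param rpph_top_m stable-RppH class size (NULL disables the filter)
#' @param tir_bound,tir_side TIR filter: keep `tir_au < bound` (side `"<"`)
#'   or `> bound` (side `">"`); NULL disables
#' @param ssrna_range inclusive nt interval (default moderate, 11-40 nt);
#'   NULL disables
#' @return object of class `stratum_summary`
#' @export
stratify_decay <- function(df, var = "log_tir", rpph_top_m = 20L,
                           tir_bound = NULL, tir_side = "<",
                           ssrna_range = c(11, 40)) {
  filt <- rep(TRUE, nrow(df))
  desc <- character(0)
  if (!is.null(rpph_top_m)) {
    stable <- stable_rpph_sites(df, rpph_top_m)
    filt <- filt & df$rpph_site %in% stable
    desc <- c(desc, sprintf("stable RppH class (top %d)", rpph_top_m))
  }
  if (!is.null(tir_bound)) {
    filt <- filt & if (tir_side == "<") df$tir_au < tir_bound else
      df$tir_au > tir_bound
    desc <- c(desc, sprintf("TIR %s %g au", tir_side, tir_bound))
  }
  if (!is.null(ssrna_range)) {
    filt <- filt & df$ssrna >= ssrna_range[1L] & df$ssrna <= ssrna_range[2L]
    desc <- c(desc, sprintf("ssRNA in [%g, %g] nt", ssrna_range[1L],
                            ssrna_range[2L]))
  }
  sub <- df[filt, , drop = FALSE]
  n <- nrow(sub)
  x <- if (var == "log_tir") log10(pmax(sub$tir_au, 1)) else sub[[var]]
  if (n >= 3L && stats::sd(x) > 0 && stats::sd(sub$k) > 0) {
    r <- cor(x, sub$k)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  } else {
    r <- NA_real_; p <- NA_real_
  }
  q <- if (n > 0L) quantile(sub$k, c(0.25, 0.5, 0.75)) else
    rep(NA_real_, 3L)
  iqr <- q[3L] - q[1L]
  outliers <- if (n > 0L)
    sum(sub$k < q[1L] - 1.5 * iqr | sub$k > q[3L] + 1.5 * iqr) else NA
  structure(list(filter = paste(desc, collapse = " & "), n = n,
                 pearson_r = r, p_value = p, quartiles = q,
                 n_outliers = outliers, variable = var),
            class = "stratum_summary")
}

#' @export
print.stratum_summary <- function(x, ...) {
  cat("stratum:", x$filter, "\n  n =", x$n,
      sprintf("| Pearson R = %.3f (p = %.3g) vs %s\n",
              x$pearson_r, x$p_value, x$variable))
  invisible(x)
}

#' Tertiary-structure comparison of decay-rate profiles
#'
#' Bins variants by their secondary-only ssRNA amount and compares per-bin
#' median decay rates of a tertiary-structure arm (G-quadruplex or i-motif
#' design group) against the secondary-structure-only control arm; the
#' control arm's linear decay-vs-ssRNA slope is fit up to the saturation
#' length.
#'
#' @param df data.frame with `k`, `design_group`, `ssrna` columns
#' @param tertiary_group `"g_quadruplex"` or `"i_motif"`
#' @param control_group control design group (default structure series)
#' @param breaks ssRNA bin breaks (nt)
#' @param slope_max_nt ssRNA range used for the control slope fit
#' @return list: `slope` (1/min per nt, control arm), `bins` (per-bin
#'   medians and n for both arms), `tertiary_median_range`
#' @export
tertiary_comparison <- function(df, tertiary_group = "g_quadruplex",
                                control_group = "structure_series",
                                breaks = seq(0, 40, by = 5),
                                slope_max_nt = 33) {
  for (g in c(tertiary_group, control_group)) {
    if (!any(df$design_group == g))
      stop("missing design group: ", g, call. = FALSE)
  }
  tert <- df[df$design_group == tertiary_group, , drop = FALSE]
  ctrl <- df[df$design_group == control_group, , drop = FALSE]
  cut_bins <- function(d) cut(d$ssrna, breaks, include.lowest = TRUE)
  bin_stats <- function(d) {
    b <- cut_bins(d)
    data.frame(bin = levels(b),
               median_k = as.numeric(tapply(d$k, b, median)),
               n = as.integer(table(b)), stringsAsFactors = FALSE)
  }
  tb <- bin_stats(tert); cb <- bin_stats(ctrl)
  fit_sub <- ctrl[ctrl$ssrna <= slope_max_nt, , drop = FALSE]
  slope <- unname(stats::coef(stats::lm(k ~ ssrna, data = fit_sub))[2L])
  med_t <- tb$median_k[!is.na(tb$median_k)]
  list(slope = slope,
       bins = merge(cb, tb, by = "bin", suffixes = c("_control",
                                                     "_tertiary")),
       tertiary_median_range = if (length(med_t) > 0L)
         max(med_t) - min(med_t) else NA_real_,
       tertiary_median = median(tert$k))
}
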