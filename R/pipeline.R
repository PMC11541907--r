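# Orchestration: a single JSON-style config drives
# simulate -> count -> fit -> featurize -> train -> sweep, with explicit
# per-stage seeds derived from one root seed and a manifest recording
# config hash, seeds and per-stage row counts.

#' Default pipeline configuration
#'
#' @param seed root seed; per-stage seeds are derived as fixed offsets
#' @param outdir run directory
#' @return nested configuration list
#' @export
default_config <- function(seed = 1L, outdir = tempfile("decaylab_run_")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = list(simulate = TRUE, reads = FALSE, fit = TRUE,
                  featurize = TRUE, train = TRUE, sweep = TRUE),
    library = library_config(),
    truth = truth_params(),
    sim = list(depth = 1000, spike_frac = 0.02,
               timepoints = DEFAULT_TIMEPOINTS, error_rate = 0),
    qc = list(min_reads = 100, r2_threshold = 0.75),
    model = gbt_params(),
    train_fraction = 0.8,
    sweep = list(ssrna_grid = 0:33)
  )
}

#' Load a pipeline configuration from a JSON file
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_config()] values.
#'
#' @param path JSON config path
#' @return configuration list
#' @export
load_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad) > 0L)
    stop("configuration error: unknown config key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  utils::modifyList(cfg, user)
}

#' Write / read tab-separated tables
#'
#' Plain-text TSV interchange used by every stage.
#' @param x data.frame
#' @param path file path
#' @return `read_tsv()` returns a data.frame; `write_tsv()` its path,
#'   invisibly
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Load an external barcode-count table
#'
#' Reads a supplementary-style TSV through a column mapping and validates
#' it against the count-table schema (timepoint columns present, one
#' spike-in row).
#'
#' @param path TSV path
#' @param mapping optional named character vector `internal = external`
#'   renaming columns of a foreign dialect
#' @param spike_id value of `variant_id` marking the spike-in row (renamed
#'   to the reserved id)
#' @return validated count-table data.frame
#' @export
load_external_counts <- function(path, mapping = NULL,
                                 spike_id = SPIKEIN_ID) {
  df <- read_tsv(path)
  if (!is.null(mapping)) {
    m <- match(unname(mapping), colnames(df))
    if (anyNA(m))
      stop("schema error: mapped column(s) absent: ",
           paste(mapping[is.na(m)], collapse = ", "), call. = FALSE)
    colnames(df)[m] <- names(mapping)
  }
  needed <- c("variant_id", "dna_t0")
  missing <- setdiff(needed, colnames(df))
  if (length(missing) > 0L)
    stop("schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  rna_cols <- grep("^rna_t", colnames(df), value = TRUE)
  if (length(rna_cols) < 2L)
    stop("schema error: need at least two rna_t<min> columns",
         call. = FALSE)
  if (spike_id != SPIKEIN_ID)
    df$variant_id[df$variant_id == spike_id] <- SPIKEIN_ID
  if (sum(df$variant_id == SPIKEIN_ID) != 1L)
    stop("schema error: count table must contain one spike-in row",
         call. = FALSE)
  df
}

#' Run the pipeline end to end
#'
#' Executes the toggled stages, writes per-stage TSV artifacts plus a
#' `manifest.json` (config hash, derived seeds, per-stage row counts) to
#' the run directory, and returns the in-memory results. Reruns with the
#' same config produce identical artifacts.
#'
#' @param config configuration list (see [default_config()])
#' @return invisible list of stage results (`library`, `truth`, `counts`,
#'   `fits`, `qc`, `features`, `dataset`, `bundle`, `metrics`, `sweeps`,
#'   `manifest`)
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(library = cfg$seed, truth = cfg$seed + 1L,
                counts = cfg$seed + 2L, reads = cfg$seed + 3L,
                split = cfg$seed + 4L, model = cfg$seed + 5L)
  res <- list()
  manifest <- list(config_hash = .fnv1a(jsonlite::toJSON(cfg[
    setdiff(names(cfg), "outdir")], auto_unbox = TRUE, digits = NA)),
    seeds = seeds, rows = list())

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res$library <- stage("simulate",
                       generate_design_library(cfg$library,
                                               seed = seeds$library))
  res$truth <- stage("simulate",
                     generate_truth(res$library,
                                    do.call(truth_params, cfg$truth),
                                    seed = seeds$truth))
  res$counts <- stage("simulate",
                      simulate_counts(res$truth, depth = cfg$sim$depth,
                                      timepoints = cfg$sim$timepoints,
                                      spike_frac = cfg$sim$spike_frac,
                                      seed = seeds$counts))
  write_tsv(res$library, file.path(cfg$outdir, "library.tsv"))
  write_tsv(res$truth, file.path(cfg$outdir, "truth.tsv"))
  write_tsv(res$counts, file.path(cfg$outdir, "counts.tsv"))
  manifest$rows$library <- nrow(res$library)
  manifest$rows$counts <- nrow(res$counts)

  if (isTRUE(cfg$stages$reads)) {
    rd <- file.path(cfg$outdir, "reads")
    paths <- stage("reads", emit_reads(res$counts, res$library, rd,
                                       error_rate = cfg$sim$error_rate,
                                       seed = seeds$reads))
    idx <- build_index(c(res$library$barcode, SPIKE_BARCODE),
                       c(res$library$variant_id, SPIKEIN_ID))
    counted <- stage("count", count_reads(paths, idx))
    res$counts <- counted$counts
    res$read_report <- list(unmapped = counted$unmapped,
                            n_reads = counted$n_reads)
    jsonlite::write_json(res$read_report,
                         file.path(cfg$outdir, "read_report.json"),
                         auto_unbox = TRUE)
  }

  if (isTRUE(cfg$stages$fit)) {
    norm <- stage("fit", normalize_counts(res$counts))
    res$fits <- stage("fit", fit_decay_table(
      norm, r2_threshold = cfg$qc$r2_threshold))
    res$qc <- stage("fit", apply_qc(res$fits, res$counts,
                                    min_reads = cfg$qc$min_reads,
                                    r2_threshold = cfg$qc$r2_threshold))
    write_tsv(res$fits, file.path(cfg$outdir, "fits.tsv"))
    jsonlite::write_json(res$qc$report,
                         file.path(cfg$outdir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$rows$fits <- nrow(res$fits)
  }

  if (isTRUE(cfg$stages$featurize)) {
    schema <- feature_schema()
    res$features <- stage("featurize",
                          featurize_library(res$library, schema = schema))
    manifest$rows$features <- nrow(res$features)
    if (isTRUE(cfg$stages$train)) {
      lv <- level_outcomes(res$counts)
      keep <- res$fits$status == "ok" & !is.na(res$fits$k)
      ds <- build_dataset(res$features[keep, , drop = FALSE],
                          lv[keep, , drop = FALSE],
                          res$fits$k[keep],
                          res$library$design_group[keep], schema)
      attr(ds$X, "schema_hash") <- schema$hash
      ds <- split_by_group(ds, cfg$train_fraction, seed = seeds$split)
      res$dataset <- ds
      res$bundle <- stage("train",
                          train_bundle(ds, do.call(gbt_params, cfg$model),
                                       seed = seeds$model))
      res$metrics <- evaluate_bundle(res$bundle, ds)
      jsonlite::write_json(res$metrics,
                           file.path(cfg$outdir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      if (isTRUE(cfg$stages$sweep)) {
        res$sweeps <- stage("sweep", list(
          rpph = sweep_rpph(res$bundle),
          tir = sweep_scalar(res$bundle, "tir"),
          ssrna = sweep_scalar(res$bundle, "ssrna",
                               grid = cfg$sweep$ssrna_grid)))
        write_tsv(res$sweeps$rpph$table,
                  file.path(cfg$outdir, "sweep_rpph.tsv"))
        write_tsv(res$sweeps$tir$table,
                  file.path(cfg$outdir, "sweep_tir.tsv"))
      }
    }
  }

  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `fit`, `run-all` (full pipeline). Flags:
#' `--config <path>`, `--seed <int>`, `--outdir <path>`.
#'
#' @param args character vector (defaults to the command line)
#' @return invisible result of the executed stage
#' @export
decaylab_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: decaylab <simulate|fit|run-all> [--config path] ",
         "[--seed int] [--outdir path]", call. = FALSE)
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  cfg <- if (!is.null(opt("--config"))) load_config(opt("--config")) else
    default_config()
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
  if (!is.null(opt("--outdir"))) cfg$outdir <- opt("--outdir")
  switch(cmd,
         "simulate" = {
           cfg$stages[c("fit", "featurize", "train", "sweep")] <- FALSE
           run_pipeline(cfg)
         },
         "fit" = {
           cfg$stages[c("featurize", "train", "sweep")] <- FALSE
           run_pipeline(cfg)
         },
         "run-all" = run_pipeline(cfg),
         stop("unknown subcommand: ", cmd, call. = FALSE))
}
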