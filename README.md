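# decaylab

Massively parallel measurement of bacterial mRNA decay kinetics produces
tens of thousands of five-point time courses: barcoded 5′ UTR variants are
expressed from a common promoter, transcription is halted with rifampicin,
and barcode read counts at 0, 2, 4, 8 and 16 minutes — normalized by a
fixed-mass RNA spike-in — trace each variant's degradation. `decaylab` is
an R package for scientists running or modeling such experiments. It
covers the full loop:

* **Simulation** — design libraries (full-factorial RppH-site × RBS
  crosses, structure series, G-quadruplex / i-motif cassettes, motif
  insertions), ground-truth decay constants built from interpretable
  effect rules, multinomial sequencing counts with a constant-mass
  spike-in, and FASTQ reads.
* **Counting** — hash-based barcode mapping with single-mismatch
  tolerance (designed barcodes are pairwise Hamming distance ≥ 3, so
  Hamming-1 balls are disjoint).
* **Kinetics** — spike-in normalization
  `R_i = (N_i / N_0) / (C_i / C_0)` and a one-parameter exponential fit
  `M(t) = e^(−k t)`, with half-life `t_1/2 = ln 2 / k`, Pearson-R²
  goodness of fit, and read-depth / fit-quality QC.
* **Featurization** — the five most predominant transcription-start
  isoforms per construct, each described by RppH-site one-hots, surrogate
  transcription/translation rates, secondary-structure anatomy (ssRNA
  segments, duplexes, loops, bulges), G-quadruplex / i-motif spans and
  motif counts — a 496-feature schema.
* **Modeling** — five gradient-boosted tree regressors of log mRNA level
  (one per timepoint) and a decay-rate model on features augmented with
  the predicted levels, with group-stratified splits, importances,
  pruning and isoform ablations (self-contained C++ boosting backend).
* **Design rules** — systematic model queries (RppH-site sweeps, TIR /
  ssRNA / dsRNA sweeps with plateau detection) and multi-factor
  stratification of measured decay rates.

See `vignettes/decaylab-methods.Rmd` for the model, the synthetic world's
assumptions, and the reasoning behind every numerical default.

## Worked example

```r
library(decaylab)

lib    <- generate_design_library(library_config(groups = list(
            structure_series = list(n = 300))), seed = 42)
truth  <- generate_truth(lib, seed = 43)
counts <- simulate_counts(truth, depth = 2000, seed = 44)
fits   <- fit_decay_table(normalize_counts(counts))
qc     <- apply_qc(fits, counts)
head(fits[, c("variant_id", "k", "half_life_min", "r_squared")], 5)
```

```
              variant_id      k half_life_min r_squared
1 structure_series_00001 0.0596         11.63     0.996
2 structure_series_00002 0.0512         13.54     0.999
3 structure_series_00003 0.0719          9.64     0.998
4 structure_series_00004 0.0976          7.10     0.997
5 structure_series_00005 0.0825          8.40     0.998
```

Each row is one UTR variant: `k` is the fitted first-order decay constant
(1/min), `half_life_min = ln 2 / k`, and `r_squared` the Pearson R² of
the exponential fit. Here all 300 variants pass QC (≥ 100 DNA and RNA
reads at T0, R² > 0.75) with half-lives spanning 1.1–25.1 min, and the
fitted `k` recovers the generator's ground truth with a median relative
error of 3.6% at 2000 reads/variant.

The full pipeline (simulate → fit → featurize → train → sweep) runs from
one config:

```r
res <- run_pipeline(default_config(seed = 1))
res$metrics$decay$test          # held-out R^2 of the decay model
res$sweeps$tir$plateau_onset    # TIR (au) where stability saturates
```

or from the command line via `inst/scripts/decaylab`
(`simulate | fit | run-all`, flags `--config --seed --outdir`).

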