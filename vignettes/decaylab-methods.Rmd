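---
title: "decaylab: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{decaylab: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

`decaylab` analyzes massively parallel rifampicin-chase experiments in
bacteria. After transcription is halted, each barcoded mRNA variant decays
approximately first-order,

$$M(t) = M_0\, e^{-k t}, \qquad t_{1/2} = \ln 2 / k,$$

with $k$ in 1/min. Sequencing read counts are compositional, and the total
mRNA mass of the library falls severalfold during the chase, so raw read
fractions cannot be compared across timepoints. A fixed mass of exogenous
spike-in RNA added to each sample anchors the scale: with variant counts
$N_i$ and spike-in counts $C_i$ at timepoint $i$,

$$CR_i = C_i / C_0, \qquad R_i = \frac{N_i / N_0}{CR_i},$$

and the ratio series $R_0 \dots R_{16}$ is fit to $e^{-kt}$ with $k$ the
single free parameter ($M_0 \equiv 1$ in ratio space, and the $t = 0$
point is included in the fit). Goodness of fit is the squared Pearson
correlation between observed and fitted ratios on the linear scale;
curves with $R^2 \le 0.75$ are flagged non-exponential, and variants
need at least 100 DNA and 100 RNA reads at $t = 0$ to pass QC.

Numerical choices: $k$ is minimized over $[0, 20]$ 1/min by golden-section
search (tolerance $10^{-10}$; a dense-grid oracle is part of the test
suite); boundary solutions snap to $k = 0$ and report an infinite
half-life rather than a negative one; zero RNA counts at $t > 0$ are
replaced by 0.5 reads to keep ratios finite, and zero counts in log-level
outcomes use the same 0.5 pseudocount. This pseudocount intentionally
breaks exact scale-invariance of the normalization at zero counts.

## The synthetic world

The generator emulates the statistical structure the analysis assumes, so
every stage is testable without downloads. Its defaults are the stated
world, chosen once:

* **Decay truth.** $k$ is additive in 1/min over a baseline of 0.07:
  the first four transcribed nucleotides (the RppH binding site)
  contribute multiplicatively with a 4-fold span — homopolymeric
  (composition-skewed) sites decay fastest, balanced sites slowest;
  unstructured (ssRNA) nucleotides add 0.01 per nt up to a 33-nt
  saturation (peak ~0.4 for unprotected transcripts), modulated ±30% by
  A/C- vs G/U-richness; a G-quadruplex replaces the ssRNA term with a
  constant 0.13 (decay flat near 0.2 at every length — a pure cap would
  leave short-UTR length dependence the flat arm excludes); an i-motif
  pushes $k$ up toward 0.5; ribosome protection subtracts up to 0.06 as
  an increasing logistic of $\log_{10}$ TIR with midpoint 3000 au and
  width 0.4 decades, within 5% of saturation near $5\times10^4$ au.
  $k$ is clamped to $[0.027, 2.24]$ (half-lives 25.4 to 0.31 min) and
  multiplied by log-normal biological noise ($\sigma = 0.15$).
* **Abundance.** Steady state in exponentially growing cells:
  $m_0 = s/(k + \mu)$ with growth dilution $\mu = 0.028$ 1/min
  (~25-min doubling), times log-normal noise ($\sigma = 0.2$).
* **Counts.** Reads per RNA sample are multinomial over variants plus the
  spike-in, whose absolute mass is constant (default 2% of the T0 mRNA
  mass, emulating light doping). Because the library's mass-weighted
  16-min survival is ~0.11, the spike-in read share rises ~7-8x by
  16 min, inside the stated band around the observed tenfold rise; the
  maximum achievable rise in this world is ~8.7x. DNA T0 reads are
  multinomial over abundance-independent frequencies.
* **Designs.** Full-factorial groups cross all 256 RppH 4-mers with RBS
  variants spanning ~1e0-1e5 au (the 5-variant factorial subset spans
  ~10^4-fold); structure series vary designed-unstructured spacer lengths
  0-40 nt and optional hairpins; G-quadruplex and i-motif groups insert
  `(G3-N6)x4` / `(C3-N6)x4` cassettes with non-run-base loops; motif
  insertion and RBS sweep groups complete the vocabulary. Spacer
  sequences are drawn A/C-biased with scarce G/U so regions designed as
  single-stranded genuinely stay unpaired when folded — mirroring the
  rational design of unstructured regions in real libraries.

What the generator does **not** emulate: PCR and adapter bias, indels,
quality-score error models, rRNA contamination, replicate-level
biological variance structure (replicates are summed), or operon context.
A green recovery test therefore establishes correctness of the estimators
under multinomial sampling and the stated truth model — not robustness to
real library artifacts.

## Surrogate biophysical providers

The featurization pipeline is provider-based. The built-in surrogates are
deliberately simple, deterministic stand-ins for full thermodynamic
calculators, and any function with the same signature can be plugged in:

* **Transcription**: a -10-element consensus (TATAAT) positional match
  12-7 nt upstream of each candidate start, plus a position-weighted
  composition term over the first 20 transcribed nt, so start sites and
  rates respond to the initial transcribed region. The five top-rate
  sites become isoforms 1-5 (ties broken toward smaller offsets).
* **Translation**: best Shine-Dalgarno consensus match in the 18 nt
  upstream of the start codon with a spacing penalty, minus a structure
  occlusion term (fraction of the -12..+4 ribosome footprint paired),
  mapped to $10^{[0,5]}$ au. The scale coefficient (0.85) was set so the
  designed 12-variant RBS ladder covers the top decade with two distinct
  levels rather than clamping twice at 1e5 — without support points
  between 2.5e4 and 1e5 the protection ceiling would be unresolvable from
  data by any model.
* **Folding**: a self-contained weighted base-pair-maximization dynamic
  program (GC = 3, AU = 2, GU = 1; minimum hairpin loop 3). Helices
  shorter than 3 stacked pairs are removed: pure pair maximization
  otherwise litters random sequence with 1-2-bp "helices" that are not
  stable structure and corrupt both the occlusion term and the ssRNA
  anatomy. Detected G-quadruplex/i-motif spans are excluded from pairing
  in `g4_aware` mode and counted as tertiary nucleotides.

Designed RBS variants have their ground-truth TIR computed by the same
surrogate on the designed transcript — as in studies where the same
thermodynamic model both designs and featurizes the library — keeping
truth and features in a single unit system.

The 496-feature schema is a documented reconstruction: one global feature
(construct length) plus, per isoform (5), an RppH-site one-hot (16),
log rates (2), UTR length and GC (2), 23 structure-anatomy scalars, 16
motif counts (RNase E-proposed and CsrA motifs, supplied as IUPAC config
and replaceable), and a 40-entry one-hot of transcript positions 5-14.
Padded isoform blocks use a -1 sentinel.

## Staged models

Five gradient-boosted tree regressors predict $\ln(\mathrm{RNA}_i /
\mathrm{DNA}_0)$ (one per timepoint; DNA denominators always use T0
plasmid counts, the only timepoint at which plasmid is extracted), then a
decay model regresses $k$ on the schema features augmented with the five
model-*predicted* log levels (predictions, never measurements, for train
and test alike). Splits are stratified by design group with
largest-remainder rounding so every group contributes the same train
fraction (±1 variant).

No gradient-boosted tree backend exists in the supported R stack, so the
package ships a self-contained histogram-based learner (quantile binning,
level-wise growth, squared loss, gain importances, single-threaded and
seeded — determinism is part of the regressor contract). Default
hyperparameters (300 trees, depth 6, learning rate 0.06, min 20 rows per
leaf, 80% row / 50% column subsampling, 64 bins) were chosen by held-out
comparison on the development world and live in the run config.

**Known limitation (kept red in the acceptance suite).** On the standard
recovery world (5000 variants, depth $10^4$) the decay model reaches test
$R^2 \approx 0.66$ (threshold 0.6) with ~16% median relative error, but
the steady-state level model reaches only $\approx 0.53$ against its 0.7
threshold. This is structural, not a tuning miss: the level outcome's
irreducible noise ($\sigma_{m_0} = 0.2$, $\sigma_k = 0.15$, count noise)
caps attainable $R^2$ near 0.78, and boosted trees capture ~70% of the
feature-explainable signal at this sample size (an oracle regression
using the exact truth functional forms reaches ~0.77). Halving
$\sigma_{m_0}$ would still leave the bar unreached, so the criterion is
asserted faithfully and left failing rather than weakened.

## Design-rule extraction

Model sweeps are *sequence-level*: the baseline mRNA (balanced `ACGU`
site, short designed-unstructured spacer, strongest RBS) is rebuilt with
one design knob changed — each of the 256 RppH 4-mers, spacer length and
composition, hairpin size, or the RBS ladder for TIR — re-featurized, and
predicted. This keeps every feature the knob determines coherent. The
printed convention of assigning all five isoforms identical features is
implemented (`unify_isoform_blocks()`) but not applied by default: with
these surrogate providers the trained trees use minor-isoform
transcription rates as sequence-composition proxies, and unified blocks
fall far outside the training distribution, inverting sweep responses.
Each grid point is averaged over seeded spacer re-draws (`n_reps`) to
suppress single-construct tree noise; sweeps remain pure functions of
their arguments. TIR sweeps report the plateau onset as the first grid
point within 5% of the response range from the asymptote.

Stratified analyses (stable-RppH classes, TIR bounds, moderate ssRNA
ranges) recompute the RppH stability ranking from the data (median fitted
$k$ per 4-mer, class size default 20), use two-tailed t-distribution
p-values for Pearson correlations, and Tukey (1.5 IQR) outlier
conventions. The tertiary comparison bins fitted decay rates by
secondary-only ssRNA amount and contrasts G-quadruplex / i-motif arms
against the structure-series control arm, whose linear slope recovers
the ~0.01 (1/min)/nt rule.

## Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state; the pipeline derives per-stage seeds from one root
seed and writes a manifest (config hash, seeds, row counts) alongside
TSV/JSON artifacts. Re-running a config reproduces identical files.
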