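---
title: "Methods: quantifying grooming syntax, stereotypy, and variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying grooming syntax, stereotypy, and variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groomsyntax)
```

This vignette is the package's account of its methods: the behavioral model
it assumes, every tunable parameter that matters, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## The behavioral model

An **ethogram** is a categorical time series: one label per video frame
over a seven-action alphabet — five grooming actions (front leg cleaning
`F`, head grooming `H`, abdomen grooming `A`, back leg cleaning `B`, wing
grooming `W`) and two non-grooming actions (walking `Wk`, standing `S`).
The grooming actions form two motifs: anterior (`F`, `H`, performed with
the front legs) and posterior (`A`, `B`, `W`). The standard recording is
50,000 frames at 30 Hz (27.78 min).

The analysis treats behavior at the **bout** level: a bout is a maximal
run of frames sharing one label, so run-length encoding tiles the
recording and makes self-transitions impossible by construction. All
sequence statistics (syntax, entropy) are therefore first-order statistics
of the bout chain, not of frames — computing them at frame level would be
dominated by self-transitions and the frame rate. This is an assumption:
the bout chain is modeled as approximately Markov, which the entropy-rate
and comparison machinery inherits.

## Denoising

Automated frame classifiers produce isolated spurious labels. Grooming
bouts shorter than one complete leg sweep are eliminated before any
analysis.

- **Cutoff**: `min_duration_s = 0.150` s. At 30 Hz a 4-frame bout (133 ms)
  is removed, a 5-frame bout (167 ms) is kept — the rule keeps bouts with
  duration ≥ cutoff.
- **Relabeling**: an eliminated bout's frames are absorbed by the
  *preceding* bout (merge-left); a short first bout merges right. Adjacent
  same-action bouts are then re-merged, and the pass repeats to a fixed
  point, so the operation is idempotent and never changes the frame count.
  Merge-left was chosen over alternatives (merge-larger-neighbor, delete)
  because it is deterministic, local, and preserves total duration.
- **Scope**: the rule applies to grooming actions only. Short walking or
  standing bouts are kept, because the one-leg-sweep rationale is specific
  to grooming movements. The alternative (applying the cutoff to all seven
  actions) is a one-line change but alters walking/standing duration
  histograms; it is deliberately not the default.

## Feature families

- **Action proportions** (7-dim): fraction of frames per action, plus the
  grooming/walking/standing triplet for ternary plots.
- **Progression vectors** (70-dim): proportions within 10 equal,
  contiguous, non-overlapping windows (2.78 min each at full length).
  When the frame count is not divisible by 10, the remainder goes to the
  last window — deterministic and documented rather than interpolated.
- **Syntax** (42-dim): bout-level first-order transition probabilities,
  normalized per source action. Sources never observed as transition
  origins get an all-zero row and a missing flag. For classification,
  missing entries are imputed with 0 (uniform 1/6 imputation is available
  via `syntax_to_vector(impute = "uniform")`); for hypothesis testing,
  missing-source flies are *excluded per transition* instead, because
  imputing would manufacture identical zeros and distort both location and
  variance tests.
- **Duration histograms** (140-dim): per action, 20 equal-width bins of
  bout duration, normalized to sum 1 per occurring action. Bin width is set
  independently for grooming and non-grooming actions, since walking and
  standing are much longer-tailed. Grooming bins span `[0.15 s, max]`
  (durations below the cutoff cannot survive denoising); non-grooming bins
  span `[0 s, max]` because the cutoff does not apply there. The upper
  edges default to the cohort-pooled maximum per category
  (`cohort_features()`), recorded so histograms are comparable across
  flies and runs are bit-reproducible.
- **Grooming half-time**: the time at which cumulative grooming frames
  reach 50% of the fly's total — a longitudinal summary of how
  front-loaded the grooming response is.

## Stereotypy metrics

**Entropy rate** of the syntax chain:
$H = -\sum_i w_i \sum_{j \ne i} p_{ij} \ln p_{ij}$, with $0 \ln 0 = 0$.

- **Log base**: natural. This is forced by the calibration that one unit of
  entropy corresponds to $e^{-1} \approx 37\%$ predictability of the next
  action; `predictability = exp(-H)` is reported alongside.
- **Bounds**: $0 \le H \le \ln 6$ for 7 states without self-transitions;
  $H = 0$ iff every observed row is deterministic, $H = \ln 6$ iff every
  observed row is uniform over its 6 allowed targets.
- **Row weights** $w_i$: the empirical outgoing-transition frequency of
  each source (default). Weighting by the stationary distribution of the
  fitted chain is available (`weighting = "stationary"`) but requires all
  sources observed; the two agree when the chain is well sampled. The
  empirical weighting is the default because it stays defined for flies
  that never exhibit some action.

**Edit distance** between anterior motif runs. The protocol extracts each
session's *first* continuous run of anterior frames (`F`/`H`) lasting at
least 30 s — anterior runs are chosen because the two-action motif with
high mutual transition probabilities is the best candidate for repeated
sequences, and the 30 s minimum ensures sequences long enough to exhibit
stereotypy if present. Distances are Levenshtein (unit-cost substitutions,
insertions, deletions; implemented as a C++ dynamic program), computed on
**frame-resolution** symbols (a 30 s run is 900 symbols at 30 Hz) and
normalized by the longer sequence's length, reported as percent
difference. Design choices: sessions without a qualifying run are skipped
and counted, not imputed; runs are not truncated to a common length
(normalization handles unequal lengths); between-fly comparisons use all
pairs of first-session runs (a matched-pairs protocol would need an
explicit pairing criterion the design does not provide). Bout-resolution
comparison is available by passing bout-level symbol sequences directly to
`edit_distance()`.

## Group statistics

Each comparison table tests every feature (42 transitions, or 7 actions
for durations) for every unordered group pair, and applies **Holm's
step-down correction over the entire table as one family** — the most
conservative reading consistent with counting "420 pairwise comparisons"
for 5 groups × 42 transitions. Per-transition families would be less
stringent; the table layout makes re-adjustment trivial if wanted.

- **Location**: two-sided Wilcoxon rank-sum on per-fly transition
  probabilities; exact when both groups have ≤ 10 usable flies, otherwise
  the normal approximation with tie correction.
- **Variance (variability)**: Levene's test with the median as center —
  the Brown–Forsythe variant — chosen for robustness on bounded, skewed
  probability data. Transitions constant everywhere return statistic 0 and
  p = 1 rather than a numerical failure.
- **Durations**: two-sample Kolmogorov–Smirnov on pooled per-action bout
  durations per group.

A caveat found during calibration and worth stating: with very short
recordings (a few hundred frames per fly), per-fly transition estimates
become coarse and tie-heavy, and the Brown–Forsythe test loses its nominal
level. The null-calibration test therefore runs at ≥ 15,000 frames per fly
(≈ 330 bouts), where both test families hold family-wise error at or below
the nominal 0.05 across 200 replicate cohorts. Users analyzing very short
recordings should treat variance p-values with caution.

## Classification and embedding

- **Model**: multinomial logistic regression (`nnet::multinom`) with a
  small ridge (weight-decay) penalty, default `decay = 0.05`, for
  numerical stability with 42–140 features and tens of flies.
- **Cross-validation**: stratified 5-fold, 10 repeats by default (3 in the
  heavier tests), reported accuracy is the mean over repeats; folds are
  re-drawn per repeat under the run seed, so results are exactly
  reproducible.
- **Standardization**: per-feature z-scoring fit on training folds only
  (default on). This makes accuracy invariant to feature scaling without
  leaking test-fold statistics.
- **Chance level**: the mean cross-validated accuracy over label
  permutations (default 100), with a 2.5–97.5 percentile band. For
  balanced cohorts this sits near 1/k — slightly below for small cohorts,
  because held-out and training class proportions anti-correlate under
  permutation; the band quantifies this.
- **Embedding**: `embed_2d()` is visualization glue around standard
  methods — deterministic principal components by default, or Sammon's
  nonlinear distance-preserving mapping (`MASS::sammon`). Both preserve
  the property the plots are used for (similar syntax vectors land near
  each other); neither is claimed as a novel computation.

## The synthetic generator

`simulate_ethogram()` draws a **semi-Markov** bout sequence: bout actions
follow a 7×7 zero-diagonal row-stochastic transition matrix evaluated at
each bout's onset time, and each bout's dwell time is drawn from a
per-action distribution. It exists so that every downstream stage has
inputs with known ground truth.

What it emulates, and the defaults that define the simulated conditions:

- **Motif structure**: the default matrices couple `F↔H` and `A↔B↔W`
  strongly (within-motif probabilities 0.4–0.72).
- **Progression**: a logistic interpolation in bout-onset time between an
  early anterior-biased matrix and a late posterior/activity-biased one.
  The default midpoint sits at 24% of the recording with steepness 7.2%
  (400 s and 120 s for a 50,000-frame recording), scaled with recording
  length so short test fixtures express the same relative progression.
- **Dwell times**: truncated log-normals per action. Grooming actions use
  `meanlog = log(0.62) + 0.25`, `sdlog = 0.5`, giving a modal bout
  duration of ≈ 620 ms — inside the characteristic 500–750 ms band;
  walking and standing are heavier-tailed (`sdlog` 0.9–1.0, modes 1.0–1.2
  s). All dwells are truncated below at the 150 ms denoising cutoff so
  simulated bouts survive denoising. The log-normal family is a modeling
  choice: only the histogram peak location is constrained by what grooming
  duration distributions look like, so the family and scales live in the
  config (`duration_params`) rather than in code.
- **Individual variability**: per-fly matrices are resampled around the
  group template row-wise from a Dirichlet with concentration
  `jitter_kappa × row` (default 150 — mild jitter, per-transition SD
  ≈ 0.03 on a 0.7 transition). Zero entries stay zero; rows renormalize.
- **Group variation**: templates apply additive per-transition offsets to
  the base matrices and renormalize. The shipped presets
  (`preset_templates()`) diverge across many transitions — within-motif
  offsets of 0.10–0.25 for the species-like preset, activity-related
  transitions *and* walking/standing dwell scales for the stock-like
  preset — mirroring the observation that species-level differences are
  broad across syntax elements while stock-level differences concentrate
  in activity. These divergences are illustrative of direction and rough
  magnitude, not fitted to any dataset.
- **Optogenetic paradigm**: three 3-min stimulation windows (default
  onsets 120, 660, 1200 s). Inside a window the transition matrix is
  replaced by a near-deterministic anterior-dominant matrix (0.98 of each
  row's mass on the anterior motif) and light onset truncates the ongoing
  bout; outside, the baseline applies. The within-individual preset uses
  a tighter early anterior coupling (0.93) so that the ≥ 30 s anterior
  runs the edit-distance protocol selects on actually occur, as they do in
  dusted flies.

What it does **not** emulate: video classifier error structure (label
noise is only the short-bout kind removed by denoising), body-size or
kinematic differences between groups, longitudinal habituation across
sessions, latent dust-level dynamics, and any dependence beyond first
order in the bout chain. Passing tests therefore demonstrate that the
pipeline measures what it claims on data satisfying its own model
assumptions — not that real ethograms satisfy them.

## Numerical choices and degenerate inputs

- Seeded determinism everywhere: every stochastic entry point takes a
  `seed`, restores the caller's RNG state, and derives child seeds
  reproducibly; identical config + seed reproduces outputs bit-identically.
- `0 · ln 0 ≡ 0` in entropy; observed-row normalization guards against
  division by zero for missing sources.
- Degenerate transition matrices (a row with no off-diagonal mass) are
  rejected at config validation.
- Dwell-time rejection sampling falls back to the truncation bound after
  100 attempts, so pathological parameter choices terminate.
- Fewer than 2 bouts yields an all-missing syntax vector with a warning;
  no grooming frames yields `NA` half-time with a warning; comparisons
  with insufficient per-group data yield untestable rows (`NA` p-values)
  that are excluded from the Holm family but kept in the table so row
  counts always equal `comparison_count()`.

## Problem sizes used by the test suite and scripts

Full-scale simulated conditions are 50,000 frames per fly and 10–13 flies
per group. The suite exercises the full scale where the property demands
it (progression, species-level classification at 13 flies × 50,000
frames) and documented scaled-down cohorts elsewhere: parameter recovery
uses a balanced matrix at ~70,000 bouts (max-abs recovery error below
0.02); chance-level recovery uses 13 flies per group at 6,000–10,000
frames with 100 permutations; null calibration uses 200 replicate
two-group cohorts of 10 flies × 15,000 frames; the optogenetic stereotypy
contrast uses 8 sessions of 1,000 s with three 3-min windows. These sizes
are stated here so that every reported quantity can be tied to the
conditions that produced it.

## Known limitations

- The bout chain is assumed first-order Markov; higher-order structure
  (n-gram syntax) is out of scope.
- Syntax is computed at bout level by construction; if a frame-level
  convention with bridged short interruptions were wanted, it would change
  transition counts near walking/standing boundaries. No bridging is
  applied.
- The Brown–Forsythe variance test needs adequately sampled per-fly
  transition estimates (see above).
- Preset divergences are qualitative emulations; classification
  accuracies on synthetic cohorts characterize the pipeline, not any real
  species or stock.
- `stereotypy_comparison()` between-fly design uses all pairs; minimum
  percent differences shrink mechanically as the number of pairs grows,
  so compare minima only across designs with similar pair counts (the
  median is the more stable summary).
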