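---
title: "Lick microstructure analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lick microstructure analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickstruct)
```

## The assay and the measures

Anhedonia — a blunted response to normally rewarding stimuli — is assayed in
mice with single-bottle sucrose drinking tests. Two complementary readouts
come out of a 15-minute session on a contact lickometer:

* **Consumption**: the mass of solution drunk (g), a gross intake measure.
* **Lick cluster size**: rodents lick in rhythmic runs (~8 Hz) separated by
  pauses. A *cluster* (bout) ends whenever the gap between two licks reaches
  the interbout interval; the number of licks per cluster scales with the
  palatability of the solution, so mean cluster size indexes the hedonic
  response rather than just intake.

This package implements the full analysis path for a two-group
(tail-handled vs tunnel-handled), two-concentration (4 % vs 16 % w/w
sucrose) counterbalanced crossover with five daily sessions per phase and
16 mice per handling group, plus the surrounding anxiety-test battery on
pre-scored tabular data.

## Segmentation rule

`segment_clusters()` implements the literal bout rule: a gap of
`interbout_interval` seconds **or longer** ends a cluster, so a gap exactly
at the threshold (default 0.250 s) splits. Lickometers report contact times
to the nearest 0.01 s; gaps are therefore rounded to that resolution before
comparison, so that floating-point noise of order 1e-12 around the
threshold can never flip a boundary decision. Duplicate timestamps (two
contacts in one tick) are kept as two licks — the sensor reports discrete
contacts, and merging them would bias cluster sizes downward.

Two conventions were genuinely open and are exposed as arguments rather
than hard-coded:

* **Singleton clusters** count toward the mean (`min_cluster_size = 1`).
  The gap rule alone defines a cluster, and no exclusion is part of the
  rule; the common "clusters are ≥ 3 licks" variant is available via
  `min_cluster_size = 3` for sensitivity analysis.
* **Per-animal aggregation** is the mean of session means
  (`subject_means()`), not a pooled-licks mean: each of the five daily
  sessions contributes equally, matching how per-animal values are usually
  built in this assay. Pooling is available (`pooled = TRUE`) but off by
  default.

The robustness sweep (`sweep_thresholds()`, default grid 0.25 / 0.5 / 1.0 s)
re-runs the segmentation and the downstream ANOVA per threshold. The grid
brackets the 250 ms convention from above; total licks are invariant under
the threshold, the number of clusters is non-increasing and the mean
cluster size non-decreasing as the threshold grows, and both properties are
asserted in the test suite against a deliberately naive quadratic
re-segmentation oracle.

The engagement criterion (strictly more than 100 licks,
`engagement_filter()`) belongs to the training phase; the filter flags and
reports sessions, and never silently drops them, because whether such a
criterion excluded animals or merely extended training cannot be decided
from the data file alone.

## Statistical battery

`mixed_anova()` is a from-scratch univariate decomposition for balanced
mixed designs with one two-level between-subject factor and up to two fully
crossed within-subject factors, one observation per unit per within-cell.
Sums of squares are obtained by Möbius inversion over marginal cell means,
which is exact for balanced data; the between effect is tested against
subjects-within-groups, and each within effect (and its interaction with
the between factor) against the matching effect-by-subjects-within-groups
stratum. Unbalanced or incomplete designs are rejected with the offending
cell named, not approximated — for balanced data Type I/II/III sums of
squares coincide, so no type option exists. The test suite verifies the
decomposition against an independent projection oracle (base R `aov()` with
an `Error()` stratum) to 1e-8 on seeded random datasets for both the
2 × (2) drinking design (denominator df 30) and the 2 × (6 × 2)
voluntary-interaction design on cage means (df 14).

Design choices that deserve a note:

* **Sphericity**: uncorrected univariate F and df are the default, so
  reported df match the design directly; a Greenhouse–Geisser option
  (`gg_correction = TRUE`) exists for within factors with more than two
  levels (it matters only for the 6-level day factor, never for 2-level
  factors, whose epsilon is 1).
* **Zero-variance edge cases**: an effect with zero sum of squares reports
  F = 0 and p = 1 (no evidence), even when the matching error stratum is
  also degenerate; this keeps "all observations equal" and "identical
  within-subject differences" well-defined.
* **Bonferroni family** (`bonferroni_pairwise()`): the family is the set of
  comparisons requested together — for the cluster-size analysis, the two
  simple effects of handling at each concentration — and the adjustment is
  `min(1, m·p)`. Between-subject contrasts use the pooled-variance t,
  within-subject contrasts a paired t on unit differences.
* **Mann–Whitney U** (`mann_whitney_u()`): U is computed from rank sums
  with midranks; the exact two-sided p value is obtained by enumerating all
  `choose(n, n1)` rank configurations when `n ≤ 20` without ties, otherwise
  a normal approximation with tie and continuity corrections — the same
  switch as standard packages, so 14-vs-15 comparisons use the
  approximation. The two paths agree within |Δp| ≤ 0.02 at n = 10 + 10.
* **Logistic regression** (`binary_logistic()`): IRLS with the indicator on
  the first group level, so the slope is exactly the 2 × 2 table's log odds
  ratio; complete separation is flagged and no finite estimate reported.
* **Assumption checks** (`check_assumptions()`): Shapiro–Wilk per group and
  a Brown–Forsythe test warn but never auto-switch the analysis, since
  per-dataset test choices should stay explicit in the configuration.
* Lick cluster sizes are analysed on the natural-log scale
  (`transform = "log"`), the conventional variance-stabilising choice for
  this right-skewed measure; `log_transform()` refuses non-positive values
  by name rather than producing `-Inf`.

## The synthetic generator

`simulate_lick_train()` draws an alternating renewal process: cluster size
`K` from a shifted negative binomial (`1 + NB`; minimum one lick, matching
the long right tail of empirical cluster-size distributions), `K − 1`
within-cluster intervals from a truncated normal around 0.125 s (the ~8 Hz
rodent lick rhythm; this default is biology-motivated, not estimated from
any particular dataset), then a pause `0.25 s + Exp(2 s)`; the process runs
until the session's drinking-time budget
(`drinking_fraction × session_duration`) is spent. Setting
`cluster_size_dispersion = 0` degenerates to fixed-size clusters, which is
how the tests verify that segmentation exactly inverts generation.

Quantization is handled at the interval level: intervals are rounded to the
0.01 s grid *before* accumulation, and the within-cluster truncation upper
bound is `interbout_interval − 0.01` (one tick below the threshold) rather
than the open interval below the threshold itself. Without that one-tick
guard, an interval just under 0.25 s could round up to 0.25 s and split a
generated cluster; with it, segmentation at the configured threshold
recovers the generator's cluster count exactly, for every feasible
configuration — an invariant the test suite asserts. Configurations that
cannot satisfy it (mean interval at or above the threshold, pause shift
below it) are rejected at construction.

`simulate_experiment()` assembles the full study: cage-level group
assignment (both mice of a cage share handling), counterbalanced
concentration order (half of each handling group starts on 4 %), phase 1 on
study days 22–26 and phase 2 on days 29–33, and per-session consumption
`total licks × volume_per_lick + N(0, σ)` truncated at zero (0.0015 g per
lick and σ = 0.08 g are documented placeholders — per-lick volume is not
identifiable from event times). A single master seed expands into
per-subject substreams, so enlarging the cohort never perturbs existing
animals' data.

Two generator features deserve justification:

* **Between-animal variability** (`subject_cv`, default 0.08): each animal
  carries stable lognormal multipliers (mean 1) on its cluster-size mean
  and drinking fraction. Real cohorts show persistent animal-level
  differences in palatability response and task engagement; because the
  multiplier is constant across conditions it acts as a pure subject
  effect, is absorbed by the subject stratum of the mixed ANOVA, and leaves
  condition means unbiased. The generator does **not** model
  animal-by-concentration heterogeneity, satiation within sessions, or
  post-ingestive feedback — so within-subject F statistics run much larger
  on synthetic data than on real recordings, and passing tests demonstrate
  correctness of the pipeline, not realism of every variance component.
* **The effect-pattern preset** (`paper_pattern_preset()`): condition means
  are calibrated once to reproduce the qualitative published pattern —
  consumption increasing with concentration and higher under tunnel
  handling; cluster size higher at 16 %; a handling gap in cluster size at
  4 % only, i.e. a ceiling at the higher concentration. Cluster-size means
  are 4.0 (tail) vs 5.5 (tunnel) at 4 % and 7.0 for both at 16 %; drinking
  fractions 0.325 / 0.350 (4 %) and 0.380 / 0.450 (16 %), chosen so the
  tail-handled consumption deficit at 4 % is about 27 %, which serves as a
  calibration check rather than a fitted quantity.

## Problem sizes for simulation studies

Power and parameter-recovery runs use the study scale: 16 mice per group,
five 900 s sessions per phase, 200 replicates. Type-I-error calibration is
pivotal — the null distribution of the interaction F does not depend on the
session scale — so the 1000 null replicates use single-session phases of
180 s, which keeps a thousand full pipeline passes cheap while testing
exactly the same code path.

## Worked example

```{r example, eval = FALSE}
cfg <- paper_pattern_preset(seed = 1)
report <- run_pipeline(list(simulate = cfg))
report            # consumption + cluster-size ANOVAs, simple effects, sweep
write_report(report, "results/")
```

On file input, the pipeline expects a per-lick CSV (`subject_id,
session_day, concentration, time_s`), a metadata CSV and a consumption CSV;
`read_medpc_file()` ingests MED-PC text data files directly, with the
timestamp array letter and tick size as options, since neither is knowable
from the file itself.

## Known limitations

* Only balanced complete designs are supported; missing sessions propagate
  as flagged exclusions and unbalanced ANOVAs are refused rather than
  REML-approximated.
* The behavioural battery operates on pre-scored tables; video tracking and
  scoring are out of scope.
* The generator's pause distribution is a single shifted exponential; real
  inter-bout pauses are better described by mixtures (short pauses vs long
  disengagements). This affects realism of total-lick counts, not the
  cluster-size machinery.
* Exact Mann–Whitney enumeration is limited to n ≤ 20 without ties; beyond
  that the corrected normal approximation is used.
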