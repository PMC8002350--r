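---
title: "Metabolic fingerprinting of methionine-restricted cell cultures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic fingerprinting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metfinger)
library(dplyr)
```

## The problem

Methionine restriction (MetR) is one of the most effective ways to push
cultured cells into a low-energy metabolism (LEM), the reduced-growth state
that caloric restriction induces. A practical screening system for
candidate caloric-restriction mimetics (CRMs) needs two things: a
quantitative *metabolic fingerprint* — the set of metabolites that are
differentially abundant between methionine-containing (Met+) and
methionine-free (Met−) culture at a reference time — and a cheap way to
compare a new compound's profile against it. `metfinger` implements the
complete value-generation pipeline for such a system, from integrated LC/MS
peak areas to fingerprint and footprint scores, together with a synthetic
data generator that emulates the study design so every stage can be tested
against known ground truth.

The pipeline operates on *integrated peak areas*. Raw spectra, peak picking
and integration are upstream instrument-software concerns and are
deliberately out of scope.

## The value-generation model

For metabolite $m$ in sample $s$, the measured area $A_{m,s}$ is first
normalized against the external standard (lamivudine, spiked at a constant
amount into every extraction):

$$v_{m,s} = \frac{A_{m,s}}{A_{\mathrm{std},s}}.$$

This ratio is invariant to any per-sample scale factor — injection volume,
ionization efficiency, extraction recovery — which is the property the
test suite checks as *scale invariance*.

Within each independent experiment, replicates (triplicates by design) are
averaged to $\bar v$ with the sample standard deviation ($n-1$
denominator). Percent conversion then differs by compartment:

* **Media (supernatant):** the fresh, unconditioned control medium of the
  same experiment defines 100%:
  $p = 100 \, \bar v / \bar v_{\mathrm{medium}}$. Values above 100 mean net
  secretion, below 100 net consumption. Metabolites absent from the medium
  reference (zero or missing) cannot be placed on this scale and are
  excluded with a warning.
* **Cell pellets:** there is no external anchor, so the highest replicate
  mean in the *test series* — one metabolite, both conditions, all
  timepoints, within one experiment — defines 100%. Met+ and Met− share
  the anchor, so their pellet percents are directly comparable.

Finally the per-experiment percents are averaged across the four
experiments. The unrounded means feed all statistics; rounding (half away
from zero, to integers) is applied only when a heat-map matrix is exported.

### Numerical choices

* Percents are computed as `100 * (value / divisor)`, dividing first, so a
  value equal to its own baseline is *exactly* 100 in floating point. The
  anchor invariants (control medium = 100, series maximum = 100) hold to
  equality, not to a tolerance.
* "Rounded to natural numbers" is implemented as half-away-from-zero
  (84.5 → 85), the everyday rounding convention, rather than R's default
  banker's rounding.
* A missing (metabolite, sample) peak is a zero area flagged "not
  detected", not an error: in MS data a dropout is an absence.
* Ties at a series maximum all map to 100; an all-zero series yields zero
  percents with a warning rather than a division error.

### Open design points, and what was chosen

* **Scope of the pellet test series.** The series could plausibly span one
  condition or both. Both conditions share the anchor here, because that
  is what makes a Met+/Met− heat map comparable row by row; the choice is
  isolated in one helper and documented.
* **Anchor before or after cross-experiment averaging.** Default is
  anchor-then-average (each experiment is percent-converted with its own
  baseline, then percents are averaged); `order = "average_then_anchor"`
  averages the standard-normalized values first and applies a common
  baseline once. Both keep the pellet anchor at exactly 100.
* **Where the media baseline lives in the data.** The fresh-medium
  measurement must itself travel through standard normalization, so it is
  represented as ordinary samples with condition `medium_control` at
  timepoint 0, rather than as a side table. `normalize_series()` also
  accepts an explicit `media_reference` table for data sets that ship the
  baseline separately.

## Aggregation

The summed relative mass of a pathway or class (TCA cycle, amino acids,
purines, ...) is computed by summing member abundances on the
standard-normalized scale per sample and then percent-converting the sum
with the same dual-baseline rule as single metabolites. Sums are additive
by construction (the test suite checks additivity at machine precision),
and a subgroup sum can never exceed its parent class sum on the pre-percent
scale. Methionine itself never contributes to an amino-acid aggregate
(`amino_acid`, `essential`, `branched`): it is the restricted variable, not
a readout. Metabolites belonging to several classes contribute to each;
classes are reported independently, with no cross-class double-count
correction. A `mean_of_percents` alternative (average the member percents
instead of percent-converting the sum) is available behind a flag.

## Differential testing and the fingerprint

Met+ and Met− are compared per metabolite by an unpaired two-sample
pooled-variance t test (Welch behind a flag), two-sided, on the *unrounded
replicate-level percents* pooled across experiments (n = 12 per group under
the default design) — not on experiment means, which would discard most of
the replication. No multiple-testing correction is applied by default, the
convention for this kind of screening profile; Benjamini–Hochberg is
available via `adjust = "BH"`. Zero-variance degeneracies follow explicit
conventions: identical constant groups give p = 1 (no effect), perfectly
separated constant groups give p = 0.

The fingerprint at the reference timepoint (48 h, intracellular, by
default — the earliest time at which the profile is clearly defined)
collects every metabolite with p < α (default 0.05), its direction (up =
higher under Met−), and its magnitude as a *difference of percents*, the
same scale as the heat maps. Entries are ordered by |magnitude|.

`match_score()` compares a candidate compound's directional profile to the
fingerprint: the score is the fraction of evaluable fingerprint entries
whose direction the profile reproduces; metabolites the profile does not
cover shrink the denominator and are reported. No verdict threshold for
"is a CRM" is hard-coded; the score is the readout.

The small **footprint** is the five-component rapid panel: acetoacetate
(up), creatine (down), spermidine (down), GSSG (down) and the ADP/ATP
ratio. The ratio's expected direction is *up*: energy depletion lowers ATP
faster than ADP, and the rising ratio is the AMP-kinase input that shuts
down mTOR-driven proliferation. Because ratio kits are reported both ways
round, the expected-direction vector is a function argument, not a
constant. The score is concordant/evaluable components, so it takes values
in {0, 0.2, 0.4, 0.6, 0.8, 1} when all five are measurable.

## Proliferation readout

Crystal-violet OD-595 readings are summarized as relative cell number,
$\mathrm{RCN}\,(\%) = 100 \cdot \mathrm{CV_S} / \overline{\mathrm{CV_C}}$,
with inhibition $= 100 - \overline{\mathrm{RCN}}$. RCN is computed per
well against the control-group mean and then summarized — equivalent for
group means to normalizing the means directly, but it keeps per-well values
for the t test. Significance tiers map p ≤ 0.001 to `***`, p < 0.05 to
`*`; the intermediate `**` at p ≤ 0.01 is a conventional extension, not
part of the original two-tier convention.

## The synthetic-data generator

`simulate_experiment()` emulates the full study design: 2 conditions × 2
compartments × 5 timepoints (24–120 h) × 3 replicates × 4 independent
experiments — 12 samples per timepoint per experiment — for a catalog of
~90 metabolites plus the standard, with fresh-medium reference samples per
experiment. Its components:

* **Noise.** Multiplicative log-normal on areas, parameterized by a CV
  (default 0.1): areas are positive and MS intensity noise is
  CV-stable. The log-normal factors are mean-one, so configured effects
  are recovered in expectation. The standard has its own small CV
  (default 0.02). Measured CVs for this assay are not published; these
  defaults are fixtures chosen once as plausible for well-behaved
  HILIC-MS peak areas, not estimates.
* **Effects.** Per metabolite × condition × compartment, anchor relative
  levels (percent of control) at the first and last timepoints,
  interpolated log-linearly in between — the simplest smooth monotone
  trajectory, matching how restriction effects develop over days. Met+
  defaults to 100 throughout.
* **Experiment effect.** A per-(experiment, metabolite) log-normal factor
  (CV 0.05) perturbs baselines so cross-experiment averaging is
  non-trivial; it cancels within each experiment's percent conversion, as
  a real per-batch intensity shift would.
* **The MetR signature.** `metr_signature_config()` ships directions
  characteristic of methionine restriction in pellets: spermidine,
  creatine, carnitine, GSSG, homocysteine, homoserine, SAH and
  pantothenate down; acetoacetate, SAM, creatinine and UDP-glucose up; ATP
  and ADP both down by day 5 with ATP falling more steeply, so the ADP/ATP
  ratio rises. The *magnitudes* are package defaults, not measured values.
  They are sized by an a-priori power computation: at the default design
  (n = 12 per group) and 10% CV, every component separates at 48 h with
  per-component pooled-t power above 0.998, so the *joint* event — every
  signature direction recovered in one data set — holds in ≈99% of
  simulations. Down-anchors of 35% or less and up-anchors of 250% or more
  at 120 h achieve this (at 48 h the log-linear trajectories have covered
  only a quarter of their log-range).

### What the generator does and does not emulate

It reproduces the design structure, multiplicative noise, batch effects,
monotone condition trajectories and the two percent baselines. It does
**not** emulate retention-time drift, co-elution, saturation, censoring at
the detection limit, correlated metabolite networks, or non-monotone
trajectories (the NAD pool's rise-then-fall, for example). Passing tests
therefore demonstrate that the *pipeline arithmetic and inference* behave
as specified under the stated noise model — not that the signature would
be recovered from any particular real instrument run.

## Problem sizes in the test suite

The packaged checks use sizes chosen to make the Monte-Carlo statements
sharp but cheap: the null calibration uses six full-design simulations
(≈1,050 metabolite tests, binomial 3σ band around α = 0.05); direction
recovery uses 100 replicated signature data sets; convergence checks use
40 replicates × 4 experiments. All are fixed-seed.

## Known limitations

* The pellet percent scale is relative to a within-experiment maximum, so
  pellet percents are not comparable across data sets processed
  separately; media percents are, given the same medium lot.
* The built-in catalog covers the metabolites named in the main analyses
  (~90); a full profiling panel is larger. The annotation reader accepts
  user tables against the same controlled vocabulary.
* Pooling replicate percents across experiments for the t test treats
  experiments as exchangeable after percent conversion; a shared
  per-experiment baseline adds a small common variance component, which
  makes the test mildly conservative (the null simulation shows rejection
  rates slightly below the nominal 5%, inside the binomial band).
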