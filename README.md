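# metfinger

Metabolic fingerprinting of methionine-restricted cell cultures from
integrated LC/MS peak areas.

Methionine restriction (MetR) is one of the most effective ways to drive
cells into a low-energy metabolism (LEM), the state that makes caloric
restriction interesting for cancer biology. A cell-based MetR model yields
a *metabolic fingerprint*: the set of metabolites differentially abundant
between methionine-containing (Met+) and methionine-free (Met−) culture at
a reference timepoint, each with a direction and magnitude. Candidate
caloric-restriction mimetics can then be screened by counting directional
matches against that fingerprint, or by a rapid five-component *footprint*
(acetoacetate, creatine, spermidine, GSSG, ADP/ATP ratio) measurable with
plate kits instead of a mass spectrometer.

`metfinger` implements the complete analysis pipeline for such a system:

* **Value generation** — per-sample normalization against an external
  standard (lamivudine), triplicate mean ± SD per experiment, percent
  conversion with compartment-specific baselines (media: the fresh control
  medium defines 100%; cell pellets: the per-experiment test-series
  maximum defines 100%), averaging across independent experiments, and
  integer heat-map matrices (rounding only at presentation). For
  metabolite *m* in sample *s*:

  v(m,s) = area(m,s) / area(standard,s),  then
  media: p = 100 · v̄ / v̄(control medium);  cells: p = 100 · v̄ / max(series).

* **Aggregation** — summed relative masses per pathway class (amino acids
  excluding methionine, urea and TCA cycles, carbohydrates, pyrimidines,
  purines, ...) and subgroups (essential, branched, S-containing), with
  the same dual-baseline percent rule.
* **Fingerprinting** — per-metabolite unpaired pooled-variance t tests
  (Met+ vs Met−, p < 0.05) on unrounded replicate percents, fingerprint
  construction at 48 h, directional `match_score()` for candidate
  profiles, and the five-component LEM `footprint_score()`.
* **Proliferation** — crystal-violet relative cell number,
  RCN (%) = 100 · CVS / mean(CVC), inhibition and tiered significance.
* **Synthetic data** — a seeded generator emulating the full study design
  (2 conditions × 2 compartments × 5 timepoints × 3 replicates × 4
  experiments, log-normal multiplicative noise, per-experiment batch
  effects, log-linear effect trajectories) with ground truth attached, so
  the whole pipeline is testable without instrument data.

## Worked example

Simulate a four-experiment MetR study with the built-in restriction
signature at 10% measurement CV, run the pipeline, and build the 48 h
fingerprint:

```r
library(metfinger)

sim    <- simulate_experiment(metr_signature_config(noise_cv = 0.1, seed = 42))
series <- normalize_series(sim)
(fp    <- build_fingerprint(series, timepoint = 48, alpha = 0.05))
#> Metabolic fingerprint at 48 h (cells, alpha 0.05): 16 differential metabolite(s)
#> # A tibble: 16 × 6
#>   metabolite_id direction magnitude      p_value n_met_plus n_met_minus
#> 1 ATP           down          -35.7 0.0000000138         12          12
#> 2 spermidine    down          -30.8 0.0000000261         12          12
#> 3 pantothenate  down          -29.5 0.0000000164         12          12
#> 4 creatine      down          -25.3 0.00000541           12          12
#> 5 GSSG          down          -24.9 0.000000204          12          12
#> # i 11 more rows
```

Magnitudes are differences of percents (Met− minus Met+) on the heat-map
scale; `n` is replicate percents pooled over the four experiments. The
rounded intracellular heat-map rows show the trajectories:

```r
heatmap_matrix(series, "cells")[c("spermidine", "acetoacetate", "ATP"),
                                c("met_minus_24h", "met_minus_48h", "met_minus_120h")]
#>              met_minus_24h met_minus_48h met_minus_120h
#> spermidine              91            67             28
#> acetoacetate            35            45            100
#> ATP                     96            63             20
```

Spermidine and ATP fall toward their configured 120 h anchors while
acetoacetate rises to its own series maximum. The five-component footprint
is fully concordant with the LEM expectation:

```r
footprint_score(series)
#> LEM footprint score: 1.00 (5/5 components concordant)
```

And the crystal-violet readout, with the control anchored at 100% by
construction:

```r
plate <- simulate_plate(plate_config(c(untreated = 0.62, met_minus = 0.31),
                                     sd = 0.02, wells = 3, seed = 7))
proliferation_summary(plate, control = "untreated")
#> # A tibble: 2 × 9
#>   group     rcn_mean rcn_sd     n inhibition     t    df         p tier
#> 1 untreated    100     6.05     3        0    NA      NA NA        NA
#> 2 met_minus     47.3   1.01     3       52.7  14.9     4  0.000119 ***
```

A 52.7% proliferation inhibition at tier `***` — the kind of separation a
methionine-free medium produces within 48–72 h.

See `vignettes/metabolic-fingerprinting.Rmd` for the model, the percent
baselines, the power-based sizing of the default signature, and known
limitations.

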