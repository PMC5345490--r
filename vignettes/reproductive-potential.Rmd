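---
title: "Estimating the reproductive potential of sea urchin populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the reproductive potential of sea urchin populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urchingo)
```

## The model

`urchingo` estimates how much gamete mass a sea urchin population releases
per square metre of reef per year, and how that output is divided among
size classes. The chain of estimators is deliberately simple — each step is
an arithmetic definition — so that the scientific content lies in the data
and in two places where judgement is needed: deciding what counts as a
spawning event, and propagating values without premature rounding.

The unit of observation is one measured individual: test diameter (TD, mm
without spines), total wet weight and gonad wet weight (g). Its
gonadosomatic index is `GSI = 100 * gonad / total` (%), a mass-fraction
proxy for reproductive investment. Per calendar month and per
(zone, size class) stratum we take the plain mean and standard error over
individuals; sexes are pooled (the populations sampled are close to a 1:1
sex ratio, and gonads of both sexes count equally toward output). A
singleton month gets SE 0 rather than NA so downstream plotting and
detection never fail; the count `n` is carried so users can filter.

Size classes are half-open intervals of TD: the census is binned in 10-mm
bins (`0-10` … `60+`), and three named classes matter for reproduction:
Small-US `[30, 40)` (gonads present, effectively infertile), US `[40, 50)`
(fertile, below the legal landing size) and CS `[50, Inf)` (commercial
size). The CS lower bound equals the minimum landing size, 50 mm by
default; a TD exactly on a boundary belongs to the upper class.

A spawning event in a stratum's monthly series is a decline from a
pre-spawning peak to the subsequent post-spawning trough. Per event,

* `IGO = (pre - post) / 100` — gamete wet weight released per unit body
  weight (g g⁻¹ per spawning event);
* `magnitude = 100 * (pre - post) / pre` — the fraction of the peak gonad
  mass released (%);
* `GO = IGO * density` — output per m², using the class's natural density
  from the quadrat census;
* `TGO` / `MGO` — annual sum and mean of the class's GO; equal when the
  year had a single event;
* `popTGO` / `popMGO` — sums of class TGOs and of class MGOs over the
  fertile classes. Note popMGO is a *sum*, not a mean: each class
  contributes the average output of its own events, and the population
  total is the sum of contributions.

## Event detection

Field series are short (≈ 12 points), irregular (months can be missed) and
noisy (SE of a monthly mean around 0.3 GSI points at typical sampling
effort). The detector therefore works on the monthly means only, treats the
series as irregularly spaced, and uses three thresholds, all configurable
in `pipeline_config()`:

* `min_drop` (default 30%): the relative decline `100 * (pre - post)/pre`
  must reach this value. Observed spawning magnitudes in this species are
  roughly 50–80%, while ordinary month-to-month wiggles stay far below
  30%, so the default separates the two regimes with margin on both sides.
* `min_rise` (default = `min_drop`): a local maximum counts as a spawning
  peak only if the series rose at least this much above its running
  minimum since the previous peak. Without this, a one-month noise upturn
  inside a long decline (a 4% rebound halfway down an autumn spawning)
  would split one event into two. The first local maximum of the series is
  exempt — there is no preceding trough to measure a rise from, and a
  series that starts at its annual peak (common when sampling begins in
  early summer) must still open an event.
* `min_range_drop` (default 30%): the absolute drop must cover at least
  this share of the stratum's annual GSI range (max − min of the monthly
  means). Pre- and post-spawning months are, by definition, near the
  year's highest and lowest means, so a genuine event spans most of the
  annual excursion; a barely-over-threshold dip at a low GSI level early
  in the build-up does not.

Within each inter-peak segment the trough is the lowest subsequent mean;
runs of equal adjacent means collapse to their earliest month, making
tie-breaks deterministic. Events are disjoint and time-ordered by
construction. A monotone non-decreasing series yields no events, which is
a result, not an error.

Missing months are simply skipped: the optional linear interpolation of
single-month gaps (`interpolate_gaps`) is off by default because an
interpolated month can only move an event's endpoints, never create or
destroy one, and an endpoint taken from interpolated data would be
reported as if it had been observed.

## Densities and the census design

Density per bin is the ratio of totals — all individuals counted divided
by all area surveyed — which is unbiased when quadrat areas differ, unlike
the mean of per-quadrat ratios. Standard errors are computed across the
census design's replicate blocks (two replicate survey units per area by
default), the grain at which the sampling actually replicates;
`se_unit = "quadrat"` switches to per-quadrat SEs. We label the ± values
SE throughout. Frequencies are densities as percentages of the zone total;
an all-zero census reports zero frequencies with a warning rather than
NaN.

## Rounding

Every intermediate is kept at full double precision; presentation rounding
(half-up, 1 decimal for percentages, 2 for g g⁻¹ quantities) is applied
once, at the end, in the report's `value_rounded` column. This matters:
propagating a rounded IGO of 0.03 instead of 0.031 through the magnitude
formula yields 68.2% instead of the correct 70.5%. Half-up is used rather
than R's default round-half-even because the reported tables follow the
field's convention of rounding ties upward.

## The synthetic-data generator

The generator exists so that the full pipeline — file parsing through
population totals — can be exercised, and its estimators validated by
parameter recovery, without access to raw field data. It emulates:

* **GSI cycles** (`gsi_cycle_spec()`): the latent monthly mean follows a
  piecewise-linear build-up to each spawning window's peak and a linear
  decline to its trough, chaining across windows. A piecewise-linear shape
  (rather than a sinusoid) matches the gradual-ripening/abrupt-release
  pattern of real series and keeps the true pre/post months unambiguous,
  which makes recovery well-defined. Individual GSI is normal around the
  latent mean (sd 0.8% by default, the scale of observed within-month
  spread) and truncated at zero; at the signal-to-noise of interest
  (means ≥ 1%, sd ≤ 1%) the truncation bias is at most ~0.02 GSI points
  and is ignored. Gonad mass is back-derived from the simulated GSI and an
  allometric body weight (`TW = a * TD^b`, defaults a = 5e-4, b = 2.9,
  giving ~40 g at 50 mm), so the generator's ground truth is expressed in
  the same statistic the pipeline estimates.
* **Censuses** (`simulate_quadrats()`): per-quadrat, per-bin Poisson counts
  with mean density × area — complete spatial randomness. With
  `deterministic = TRUE` counts are replaced by their expectations, the
  zero-noise limit in which the pipeline must reproduce its inputs
  exactly.
* **Fertility assays** (`simulate_fertility()`): binomial egg and larva
  counts.

Two built-in scenarios bundle these: `"hp"`, a harvested zone (single
spring event per fertile class, total density 10 ind m⁻², commercial class
6% of the population) and `"lp"`, a protected zone (two events per year,
total density 5.4 ind m⁻², adult-dominated). Sampling effort defaults —
8 individuals per stratum per month, 200 quadrats of 0.25 m² per zone, 5
monthly assays of 400 eggs — mirror a realistic one-year field campaign
and keep simulation-based tests fast; these are the problem sizes used
throughout the test suite and the acceptance script.

What the generator does **not** emulate: individual growth and mortality
between months (every month is a fresh cross-section), within-zone spatial
structure beyond Poisson counts (no patchiness or overdispersion),
TD-dependence of GSI within a class, measurement error in weights, and
harvest dynamics. Passing recovery tests therefore demonstrates that the
estimators are consistent under the model's own assumptions — not that
real reefs satisfy those assumptions.

```{r recovery-example}
sim <- simulate_scenario("hp", seed = 7)
events <- detect_events(gsi_monthly_series(sim$urchins))
events[events$size_class %in% c("US", "CS"),
       c("size_class", "start_month", "end_month", "magnitude")]
sim$truth$classes[, c("size_class", "magnitude")]
```

## Degenerate inputs and numerical choices

* `compute_gsi()` rejects non-positive total weights and gonad weights
  exceeding the total; the result is bounded in [0, 100].
* Detection requires at least 3 months per stratum; fewer is an error
  (nothing can be said about a cycle from two points).
* Equal adjacent extrema resolve to the earliest month; a complete
  spawn-out (post = 0) has magnitude 100 regardless of the peak.
* A class whose year produced no events has no TGO/MGO (error rather than
  silent zero); a class with zero density has GO 0, which is a result.
* The magnitude–IGO identity `magnitude = 100 * (100 * IGO) / pre` holds to
  1e−12 for every detected event, and population TGO equals the direct
  event-level sum `Σ IGO × density` to 1e−12 — both are enforced in the
  test suite.
* Validation is total: every input row is either accepted or named in a
  located error (or, with `strict = FALSE`, returned in a `rejected`
  attribute); rows are never silently dropped.

## Fertility gating

Assays report the percentage of fertilized eggs; an assay succeeds when it
reaches the threshold (80% by default, inclusive — "at least 80%"). A
class with assay data stays in the population totals when the majority of
its assays succeed; a class without assays is taken as fertile on the
strength of its scheme flag alone (commercial-size adults are normally
assumed fertile without testing). The majority rule is a design choice:
assays are small binomial experiments, and one failed month should not
erase a class that succeeded in four others.

## Known limitations

* The event definition is descriptive, not inferential: no significance is
  attached to a detected event, and the thresholds, though defensible,
  are conventions. Histological confirmation of spawning is outside the
  package's scope.
* Monthly sampling cannot resolve events shorter than a month, and two
  events separated by a single month merge unless the rebound between them
  clears `min_rise`.
* Output units are gonad mass fraction per area (g g⁻¹ m⁻²), not absolute
  gamete mass: converting to grams per m² would require the body-weight
  distribution of each class, which the cascade deliberately avoids.
* Cochran's C is returned as a bare statistic with (k, n) for table
  lookup; its null distribution is not implemented.
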