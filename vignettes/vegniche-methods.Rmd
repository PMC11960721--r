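---
title: "Methods: niche-based understory community modelling with vegniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche-based understory community modelling with vegniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegniche)
```

## The model

`vegniche` simulates the composition of the forest herbaceous layer
(plants up to 1.8 m) as the outcome of fundamental-niche suitability
and competition for light. Each species is described by:

* four Gaussian niche responses, one per environmental axis
  (soil-solution pH, soil-solution N in mg/L, soil moisture as a
  saturation fraction, and light as a fraction of above-canopy
  radiation):

  $$\mathrm{Resp}(d, \mathrm{opt}, \mathrm{var}) =
    e^{-(d - \mathrm{opt})^2 / \mathrm{var}}$$

* a hard temperature window $[t_{min}, t_{max}]$,
* a rooting depth (m) selecting which soil layers the species
  experiences, and
* a shading height (m) placing it in the light-competition hierarchy.

Site suitability is the product of the four Gaussian responses and the
temperature indicator, evaluated on root-zone-aggregated drivers and on
the light left over after shading. The product form means every axis
can veto: suitability never exceeds its smallest factor.

Two representation choices deserve a note:

* **`var` is in squared driver units.** The exponent divides a squared
  difference by `var` directly, so `var` plays the role of $2\sigma^2$
  in a conventional Gaussian. Users who think in standard-deviation
  widths can set `var_is_sd = TRUE` (or
  `options(vegniche.var_is_sd = TRUE)`) and the value is squared
  internally. The literal reading is the default.
* **The temperature window is a hard 0/1 indicator on a closed
  interval.** Tolerance tails are a property of the four Gaussian axes
  only; a window has no stated tail shape, and the simplest reading —
  presence inside, absence outside, boundaries included — is the one
  implemented. Responses below $10^{-300}$ on any axis are clamped to 0,
  which is indistinguishable from exclusion and avoids denormalized
  arithmetic.

## Class keys

Field parameterization of this model family happens in ordered integer
*classes* per axis, not physical units. The mapping from class rank to
units is a `class_key`; the packaged default has five evenly spaced
optima per axis spanning plausible field ranges — pH 3–7, N 0–10 mg/L,
moisture 0.05–0.95, light 0.02–1.0 — with a constant per-axis tolerance
chosen so adjacent classes overlap but remain distinguishable (pH 0.8,
N 6, moisture 0.08, light 0.08, all in squared driver units). Shading
classes span 0.05–1.8 m and rooting classes 0.05–0.8 m. The key is
data, not structure: any strictly rank-monotone key can be supplied as
YAML (`read_class_key()`), and lookups are deliberately strict — a rank
between two defined ranks is an error, never an interpolation.

## Drivers

Driver series are monthly and layer-resolved: per (year, month, layer)
rows carry pH, N, moisture and soil temperature, plus the forest-floor
light fraction for the month. Root-zone aggregation is a
thickness-weighted mean over the layers intersecting
$[0, \text{rooting depth}]$; a partially reached layer contributes its
intersected thickness. This is the least committal reading of "roots
give access to soil layers"; a `method = "deepest"` switch returns the
deepest reached layer instead, for users whose biogeochemical model
already integrates over depth. Both layer-resolved input and
pre-aggregated use are therefore possible. Rooting depths below the
profile bottom are clamped with a warning.

### The synthetic generator

`generate_synthetic_drivers()` emulates what a monthly biogeochemical
simulation of an acidified northern hardwood soil would hand to the
vegetation model. Per driver the monthly value is

$$\text{baseline} + \text{amplitude}\cdot\sin\!\big(2\pi (m-4)/12\big)
  + \text{trend}_{\text{decade}}\cdot\text{decades} + \text{noise},$$

with the sine peaking in July. Defaults: pH 4.2 baseline rising 0.05
per decade (slow recovery from acidification) with a +0.6 pH/m depth
gradient; N 1.2 mg/L falling 0.1 per decade, lower at depth;
moisture 0.6 with a *negative* seasonal amplitude (late-summer dry
down); soil temperature 6 °C with an 8 °C seasonal cycle damped
exponentially with layer depth (e-folding 0.5 m); floor light 0.15
under a closed canopy. Noise is additive Gaussian except for the N
concentration, which is multiplicative lognormal (mean-corrected) so
concentrations stay non-negative and right-skewed, as concentration
records are. Fractions are clipped to [0, 1] after summing terms.
Identical configuration and seed give bit-identical output, and the
caller's RNG state is untouched.

What the generator does *not* emulate: month-to-month autocorrelation,
episodic events (droughts, frost, harvests), covariance between drivers
(e.g. wet months being cold months), and any feedback from vegetation
to soil. Tests passing on synthetic drivers therefore demonstrate the
*community machinery* — responses, competition, calibration — not
fidelity to any particular site's biogeochemistry.

## From suitability to cover

Competition works through two mechanisms:

* **Shading.** The light available to a species is
  `floor_light × (1 − s·C_taller)`, with `C_taller` the summed cover of
  strictly taller plants and shading efficiency `s = 0.75` by default.
  Linear occlusion was chosen over exponential extinction because no
  functional form is prescribed by the model family's description and
  the linear form has a single interpretable parameter; the result is
  clipped to `[floor_light·(1−s), floor_light]`. Species of equal
  shading height do not shade each other — the symmetric,
  order-independent tie convention.
* **Proportional cover.** Strength equals suitability (with an optional
  dominance exponent `gamma`, default 1: `strength = suitability^γ`),
  and covers are `strength / Σ strength`. Covers are normalized over
  the modeled species; there is no explicit bare-ground pool. If no
  species is viable (all strengths 0), the all-zero state is returned
  flagged rather than erroring.

The annual update averages monthly suitabilities over a configurable
growing season (default May–September) before the strength computation:
relevé observations are single-date summer inventories, and the model
is intended for annual rather than sub-annual dynamics. Because shading
depends on the covers being computed, each year is solved by damped
fixed-point iteration (damping 0.5, tolerance $10^{-6}$ on the maximum
cover change, at most 100 sweeps; non-convergence keeps the last
iterate and warns — in practice convergence takes 10–20 sweeps). An
inter-annual inertia `lambda` interpolates between the previous state
and the fixed point; `lambda = 1` (default) is instantaneous
replacement.

One structural caveat found while testing: the intuitive
competition-release property — removing a species never decreases any
survivor's cover — is exact under pure resource competition (`s = 0`)
and when the removed species tops the shading hierarchy, but with
shading on, removing a *short* species lets taller survivors grow and
can increase the shade on mid-height species by a few $10^{-4}$ cover.
The property tests assert release in the regimes where it is an exact
consequence of the model, and the suite samples light optima above the
floor-light level there (the light-limited regime; a shade specialist
sitting below its light optimum can legitimately decline when its
shader is removed).

## Calibration

`calibrate()` automates a three-step expert revision loop on species
whose simulated cover errs by more than 5 cover percentage points
("5 % error" is read as absolute cover points; relative error is
undefined at observed 0, which is common in relevés):

1. *false dominants* — observed sub-dominant (< 10 %) but simulated
   dominant (> 20 %) — are processed first,
2. then *suppressed dominants* — observed ≥ 20 % underestimated by
   more than 5 points,
3. then the remaining errors (canonically the 10–20 % sub-dominants;
   any other > 5-point error falls in this residual class so that every
   offender is eventually processed).

For the current worst offender the responsible axis is identified from
the per-axis response factors: the smallest factor for a suppressed
species, the largest exceedance over the community-mean factor for a
false dominant, with ties broken in the fixed order light, N, pH,
shading height, moisture (the order in which such revisions are
typically needed). Candidate moves shift that axis's class rank within
a per-species window (default ±2 classes around the starting rank,
standing in for literature constraints; never recentered, so total
drift stays bounded), and the community is re-simulated after every
candidate.

Three algorithmic choices matter, all found necessary on seeded
recovery experiments:

* **Candidate shifts up to two classes.** With a five-rank key the
  response ratio between adjacent classes can reach an order of
  magnitude, so a single-class step can overshoot the observed cover —
  the error flips sign and grows, and no admissible one-class path
  exists. Candidates of one *and* two classes are evaluated and the
  admissible candidate leaving the smallest residual error is kept, so
  small steps still win whenever they suffice.
* **A relaxed acceptance pass.** The primary acceptance rule protects
  species already within tolerance. In a normalized community that rule
  can deadlock: restoring a crashed dominant necessarily deflates every
  other cover and may push a borderline species just past tolerance.
  When no protected move exists, moves are accepted that still strictly
  decrease the community total error $\sum|P-O|$; displaced species
  become offenders and are repaired next, and the strict decrease rules
  out cycling. The community-level total error is non-increasing across
  accepted moves in both passes.
* **Tolerance edits as a last resort.** Only when no optimum shift is
  admissible is `var` widened or narrowed (factor 2, at most two steps
  either way per species and axis) — optimum-first editing mirrors how
  revisions are counted by class in expert practice.

Species for which no admissible move remains are flagged unresolved in
the report rather than raising an error, and a species stuck earlier is
retried whenever any accepted move changes the community. Calibrating
an already-calibrated table performs zero revisions.

The test suite validates recovery: a known six-species table's covers
serve as the observation, the niche optima of the 1–3 most dominant
species are displaced by two classes, and calibration must bring every
species back within 5 points. Across 20 seeded experiments the blind
(displaced) community similarity averages CzI ≈ 0.69 and the
calibrated one ≈ 0.98, with 100 % of runs recovering fully.

## Evaluation metrics

* `nae()` — $(\bar P - \bar O)/\bar O$, bias of the mean; usable with
  a handful of pairs. Note that between two normalized cover vectors
  NAE is structurally 0.
* `nrmse()` — $\sqrt{\sum_i (P_i-O_i)^2 / N}\,/\,\bar O$, a strict
  pairwise difference metric.
* `one_to_one()` — least-squares slope of $P = b\,O$ through the
  origin ($b = \sum PO / \sum O^2$; $b < 1$ flags underestimation),
  its standard error, and the Pearson correlation of the pairs.
  Pearson, not Spearman, because the slope itself is linear.
* `czekanowski()` — $1 - \sum|P-O| / \sum(P+O)$, the quantitative
  Sörensen / reverse Bray–Curtis similarity; symmetric, invariant to
  joint rescaling, and equal to 1 exactly at identity. Species present
  in only one vector count 0 in the other; unreported (`NA`) covers
  are treated as absent.
* `annual_median_pairs()` pairs yearly medians of monthly model output
  with yearly medians of dated observations (a mean-based mode is
  available via `fun = mean`); observation years outside the modeled
  span are dropped with a message.

All five are checked against independent brute-force re-implementations
on random data, and CzI additionally against `vegan`'s Bray–Curtis.

## Packaged fixtures

`load_cover_fixture()` exposes the published observed / blind /
calibrated relative covers for the HBEF (2013 relevé), EB and WB (1997)
sites, 45 species in total, as printed to two decimals (a species row
duplicated in the printed original is collapsed). Recomputing community
CzI values from these rounded covers reproduces the published values to
about ±0.01 for HBEF and WB; the EB columns round more aggressively
(the printed calibrated column sums to 0.82), so only ±0.06 agreement
is possible there — a property of the printed table, not of the index.

## Problem sizes and numerical settings used by the tests

The suite exercises 4–8-species tables over 1–3-year driver series
(100 random tables for the property suite, 20 seeded recovery
experiments, 1000 random series for the metric oracles), sizes at which
every behaviour of interest — convergence, competition release,
recovery — is already expressed while the whole suite stays fast.
Fixed-point settings ($10^{-6}$, damping 0.5, 100 sweeps) and the
calibration caps (200 candidate evaluations, ±2-class windows, 2-step
var budget) are the package defaults throughout; no test tunes them.

## Known limitations

* Cover is the only state: no phenology, biomass, age structure,
  dispersal, colonization from outside the species list, or spatial
  arrangement.
* Proportional cover assignment and linear shading are declared
  substitutes for the (unpublished) original competition equations of
  this model family, not reconstructions; `gamma` and `s` expose the
  main behavioural degrees of freedom.
* The default class key is a documented stand-in; real applications
  should supply the key their parameter tables were classed under.
* Normalized covers make community-level bias invisible to NAE; use
  CzI and the per-species errors instead.
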