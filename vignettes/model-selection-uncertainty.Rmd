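---
title: "Quantifying model-selection uncertainty in live-tree carbon with prediction envelopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying model-selection uncertainty in live-tree carbon with prediction envelopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomenv)
```

## The problem

Live-tree carbon is rarely measured; it is predicted. An analyst takes
inventory measurements -- species, diameter at breast height (DBH, cm),
sometimes height -- and runs them through published allometric regressions
for stem wood, bark, branches, foliage and roots, multiplies volume
predictions by a wood density, sums the components, and converts biomass to
carbon with a fraction near 50%. At every one of those steps there are
several published models that are plausibly applicable to the same tree, and
they disagree. Unlike sampling or measurement error, the error introduced by
*choosing* among them is systematic: picking a high-predicting stem equation
biases every tree in the region the same way, so it does not average out over
a large inventory. This package quantifies that model-selection uncertainty.

Rather than privileging any single model, the package computes, for each
species, tree component and 1-cm DBH class, the *prediction envelope*: the
interval between the lowest and highest predictions across all admissible
equations and conversion factors. Envelopes are aggregated to total-tree
carbon over a calculation roadmap, scaled to a region with per-tree expansion
factors, and summarised by the half-range uncertainty metric

$$ U = 100 \cdot \frac{(\mathrm{hi}-\mathrm{lo})/2}{(\mathrm{hi}+\mathrm{lo})/2}, $$

half the width of the range expressed as a percentage of its midpoint. The
midpoint is a point of comparison, not a claim about the most likely value:
the method deliberately discards central-tendency information in exchange for
making no assumptions about which model is right.

## The pipeline

### Equation catalogs

An `allom_catalog` holds one row per published regression:
a functional form (`power`, `log-log`, `linear-combination` or
`combined-variable` $y = a + b\,D^2H$), ordered coefficients, the response
kind (volume in m$^3$ or oven-dry biomass in kg), the predictors (DBH only,
or DBH and height), the *developmental DBH range* -- the diameter interval of
the trees the equation was fit to -- and stump-height / top-of-stem
conventions. Units are fixed package-wide (cm, m, m$^3$, kg) and are never
inferred.

`apply_inclusion_rules()` screens a catalog the way an analyst screens a
compilation: equations are excluded, with one machine-readable reason each,
if they (1) need predictors beyond DBH and height, (2) lack a developmental
range (waivable per record, for institutional equations that are used
operationally despite missing metadata), (3) use a stump height other than
the common 10/15/30 cm conventions, or (4) do not predict to the stem tip.

Log-log equations are exponentiated back to natural units as published.
Back-transformation from a log-scale fit biases predictions low; the standard
lognormal correction $\exp(\widehat{\sigma}^2/2)$ is available via
`correct_log_bias()` but is off by default, matching how such equations are
normally applied in practice. `additivity_error()` measures the related
nuisance that independently fitted component equations do not sum exactly to
an aggregate equation fit to the same trees.

### Heights

Volume equations almost always need height, but envelopes are indexed by DBH
alone, so heights come from an asymptotic height--diameter model

$$ h = b_0\,(1 - e^{b_1 d})^{b_2}, \qquad b_0 > 0,\; b_1 < 0,\; b_2 > 0, $$

with $b_0$ the asymptotic maximum height (m), $b_1$ the steepness (per cm)
and $b_2$ the curvature. The asymptote matters: polynomial height models
explode for large trees, and large trees carry much of the carbon. The form
is anchored at $h(0)=0$ with no breast-height offset. Published parameters
for the five northwest-Oregon target species ship in
`nwor_height_params()`; `fit_height_params()` refits the curve to (DBH
class, mean height) pairs by Levenberg--Marquardt least squares weighted by
$1/d$, from the fixed start $(1.05\max h,\ -0.02,\ 1)$ so fits are exactly
reproducible. The rendering of the curve is a design choice isolated behind
`predict_height()`: the parameter roles (asymptote, negative steepness,
curvature near 1) pin down this Chapman--Richards form, and the published
Douglas-fir parameters give 33.3 m at 50 cm under it, but any alternative
algebra would be a one-function change.

### Envelopes and extrapolation policy

`component_envelope()` takes, per class, the min and max over all admissible
candidate predictions. A volume equation contributes two candidates -- its
prediction times the lowest and the highest retained density for that species
and component -- so density uncertainty widens the envelope before the
min/max. Three extrapolation policies (`approach_policy()`) bracket how an
analyst might treat the developmental range:

* **approach 1** -- every equation over the whole grid, no corrections;
  negative extrapolated predictions are retained;
* **approach 2** -- each equation only inside its developmental range;
  classes with no admissible equation are undefined rather than silently
  extrapolated;
* **approach 3** -- extrapolation with an ordered list of modification
  rules, shipped as `clip-negative` followed by `crown-truncation` (crown
  mass plateaus at maturity, so branch/foliage predictions above a
  species-specific DBH -- 54 cm for red alder, `nwor_crown_truncation()` --
  are held at their value at that class).

Because approach 2 uses a subset of approach 1's admissible candidates, its
envelope nests inside approach 1's pointwise; the tests assert this as an
invariant.

Biomass envelopes convert to carbon by multiplying minima by 48% and maxima
by 52%, folding the carbon-fraction uncertainty into the interval. This puts
a floor of exactly $(0.52-0.48)/(0.52+0.48) = 4\%$ under the relative
half-width of any converted envelope, even a zero-width one. On classes where
uncorrected extrapolation left a negative bound, the conversion (and the
volume-to-biomass step) takes the proper interval product so bound ordering
is preserved; for non-negative envelopes this is exactly the min-times-low,
max-times-high rule.

### Aggregation and correlation

Few equations predict whole trees, so component envelopes are combined along
a directed acyclic roadmap (`default_roadmap()`): stem wood + stem bark form
the bole; bole + branches + foliage form one aboveground pathway, compared
(OR) against direct aboveground-total equations where those exist; aboveground
plus coarse roots gives total tree. Users may supply their own roadmap as
JSON; files are validated for acyclicity and a unique terminal node.

Summing *ranges* rather than points forces a choice about how components
co-vary within a tree. Two bracketing assumptions are provided at every
addition step:

* **positive** correlation -- extremes co-occur: $[l_a+l_b,\ u_a+u_b]$;
* **negative** correlation -- a tree that puts more into one component puts
  less into another, realised as cross-pairing:
  $[\min(l_a+u_b,\ u_a+l_b),\ \max(l_a+u_b,\ u_a+l_b)]$.

Negative-mode addition never widens the interval and roughly halves regional
uncertainty in practice. It is not associative, so the roadmap evaluates its
steps in their listed order, left to right, and that order is part of the
roadmap definition. The OR step is an envelope union: per class, the
outermost bounds across whichever alternatives are defined there. Whether a
comparison step should instead *select* one pathway is genuinely open; union
was chosen because the method's premise is to retain the outer bounds given
by all possible calculation combinations, and the positive-mode roadmap total
then equals an exhaustive enumeration over every pathway and equation choice
-- which the test suite verifies on small catalogs.

### Regional scaling and the experiments

`apply_envelope()` multiplies each tree's envelope bounds at its DBH class by
the tree's expansion factor (the number of population trees the record
represents) and sums by species; totals are exact sums of species bounds, in
Tg C ($10^9$ kg). Trees are binned to the class label nearest their DBH,
since the class label is the DBH at which envelopes are evaluated. Percents
are reported with round-half-away-from-zero at the presentation layer only
(`round_half_away()`); full precision is kept internally.

The auxiliary analyses mirror the strategies one would consider for reducing
model-selection uncertainty:

* `subdivision_experiment()` -- split each class interval into $k$
  equal-width sub-envelopes and partition trees equally among them
  (round-robin within species and class; remainders go to lower-indexed
  groups). With class counts divisible by $k$ and equal expansion factors
  the uncertainty ratio is exactly $1/k$: correct equation assignment pays
  off linearly.
* `dev_range_distance_experiment()` -- classify equations by whether their
  developmental range spans a target DBH, ends at half of it, or starts at
  twice it, and evaluate each category at the target; distant categories
  produce wider, shifted prediction ranges.
* `dbh_measurement_error()` -- the delta-method standard error of the
  regional total from a 2%-of-DBH measurement error, read as a 95%
  confidence interval ($\mathrm{sd} = 0.02\,D/1.96$; the 1.96 is exposed as
  a parameter), with independent per-tree errors aggregated in quadrature.
  The derivative is a central difference, exact for the polynomial forms.
* `single_source_estimate()` -- the point estimate from one internally
  consistent equation set at a flat 50% carbon fraction; by construction it
  lies inside the positive-correlation approach-1 envelope built from any
  catalog containing that set.
* `form_agreement()` -- relative spread of DBH-only versus DBH-and-height
  equations along $D$, $H$ and $D^2H$; the table is for inspection, and no
  convergence is asserted (adding height does not, by itself, make equations
  agree).

## The synthetic generators

Real equation compilations and the regional inventory are not shipped;
`generate_catalog()` and `generate_inventory()` emulate their statistical
structure so every pipeline stage is testable against a known truth.

A `true_allometry()` fixes, per species, leaf-component power laws
$m = a\,D^b$ (kg) with exponents in $[1.5, 3]$ and magnitudes plausible for
Pacific-Northwest conifers and hardwoods (e.g. stem wood $0.04\,D^{2.6}$,
about 1 t at 50 cm), a wood density per component, and height parameters.
Aggregates are sums of leaves, so the truth is additive by construction.
Each synthetic "published" equation is that truth *refit* on noisy
pseudodata over its own sampled developmental range, in a randomly drawn
functional form -- the three mechanisms by which real libraries disagree
(sampling noise, range truncation, form misspecification), reproduced
directly. Generator choices that matter:

* **Noise scale.** The log-scale pseudodata standard deviation defaults to
  0.3, i.e. roughly 30% relative disagreement among library members. That is
  the scale required for regional model-selection uncertainty in the
  20--40% band observed for real compilations; at 0.15 the synthetic
  libraries agree far better than published ones do.
* **Developmental ranges** are sub-intervals of $[3, 250]$ cm with lower
  ends drawn from $U(3, 30)$ -- saplings are easy to sample, so real ranges
  start small -- and widths of 20--150 cm. The first equation of every
  component spans the full range so approach-2 envelopes have no coverage
  gaps on the default 3--66 cm grid.
* **Forms.** The full-range equation is always log-log: the wide-range
  equations in real libraries are log-log or power, while linear
  combined-variable forms are only ever fit locally (a straight line in
  $D^2H$ over two orders of magnitude of biomass has a physically absurd
  intercept). Combined-variable equations are fit weighted by $1/(D^2H)^2$,
  the standard treatment of that family's strong heteroscedasticity; without
  it the intercepts are on the scale of a large tree's biomass and the
  class-3 envelope is dominated by fitting artifacts rather than by model
  disagreement.
* **Densities** are jittered within $\pm 10\%$ of the truth, matching the
  observed spread of the volume-to-carbon conversion about its midpoint.
  About 30% of stem-wood equations are expressed as volume so the density
  pathway is exercised.
* **Inventories** draw DBH from a Weibull (shape 1.3, scale 18) truncated to
  $[3, 66]$ cm -- right-skewed, most trees small, a long tail of large ones
  -- and lognormal expansion factors with median about 20. One seed fixes
  all draws.

What the generators do *not* emulate: spatial plot structure and sampling
design (so no sampling error), regression error within each equation,
species-level differences in allometric shape beyond scale, and correlated
disagreement among published equations that share source data. Passing tests
therefore demonstrate that the interval machinery is correct and that the
pipeline recovers a known truth; they do not certify the magnitude of
model-selection uncertainty in any real region, which depends on the real
library.

## Numerical choices and degenerate inputs

* Grid: integer 1-cm classes, default 3--66 cm; the class label is the DBH
  input (class midpoints are not modelled).
* Ties and crossings: where two equations cross, provenance switches and the
  envelope width is zero at the crossing; min/max ties resolve to the first
  candidate in catalog order.
* Approach 2 classes with no admissible equation are `NA` with a `defined`
  mask, and scaling an inventory against them is an error that lists the
  offending classes -- never a silent zero.
* Degenerate intervals (`lo == hi`) are legal everywhere; uncertainty is 0
  before carbon conversion and exactly 4% after.
* The height fit refuses fewer than 4 distinct classes or all-equal heights,
  and reports non-convergence rather than returning a silent fallback.
* All percent rounding is round-half-away-from-zero, applied only at the
  reporting layer.

## Problem sizes

The test suite and the reproduction script run on synthetic problems sized
for a laptop: libraries of 6--8 equations per component, inventories of
200--2,000 trees (10,000 for the distributional check of the DBH law),
envelope grids of 64 classes, 20 replicate seeds for the coverage study, and
exhaustive-enumeration oracles on catalogs of at most 4 equations per
component. These sizes are where the properties under test are already
decisive; nothing in the method scales worse than linearly in trees or
equations except the deliberately exhaustive test oracles.

## Reference values

`nwor_carbon_ranges()`, `nwor_height_table()`, `nwor_species()` and
`nwor_crown_truncation()` carry published northwest-Oregon values (regional
carbon bounds by approach and correlation mode, height parameters, the
five target species, the red-alder truncation class). They are inputs for
worked examples and regression tests of the uncertainty metrics; the
package does not claim to re-derive them, since doing so requires the
regional inventory database and the full published equation compilation.

```{r}
tb <- nwor_carbon_ranges()
tot <- tb[tb$species == "NWOR total" & tb$approach %in% 1:2, ]
tot$recomputed_pct <- round_half_away(uncertainty_percent(tot$min_tg, tot$max_tg))
tot[, c("correlation", "approach", "min_tg", "max_tg", "recomputed_pct")]
```
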