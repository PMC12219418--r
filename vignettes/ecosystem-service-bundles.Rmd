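---
title: "Scenario-based ecosystem service bundle analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scenario-based ecosystem service bundle analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esbundles)
```

# The problem

Regional ecosystems supply many services at once — food, raw materials,
climate and gas regulation, water retention, soil conservation, habitat.
Land-use change redistributes these services: converting grassland to
construction land removes nearly all of them from that parcel, converting
arable land to water multiplies its value manyfold. This package implements
a complete analysis chain for studying that redistribution under alternative
policy futures:

1. **Markov/CA land-use simulation** — estimate a 6-class transfer-probability
   matrix from two observed maps, edit it to express policy scenarios,
   project per-class area demand with a Markov step, and allocate the demand
   on the map with a cellular-automata patch grower.
2. **Dynamic ecosystem service valuation** — the equivalent-factor method
   (11 services × 6 land types, yuan/hm²) with a per-cell NDVI correction.
3. **Trade-off/synergy analysis** — Pearson correlations of service values
   across spatial units.
4. **Ecosystem service bundles** — K-means clustering of per-unit service
   profiles, with the elbow rule selecting the number of bundles.
5. **Trajectory typing** — positional coding of each cell's 4-date bundle
   sequence and classification into five stability types.
6. **Driver attribution** — the geographical detector's q statistic,
   two-factor interaction typing, and a VIF collinearity screen.

Because the original 30 m provincial rasters are not redistributable, the
package ships a synthetic-landscape generator with *known* ground truth
(target class shares, class-conditional NDVI, drivers with planted
associations), so every stage is exercised and tested end to end without any
external data.

# Land-use scenarios

## Transition matrices and scenario edits

A `transition_matrix` holds `p[i, j]`, the probability that land of class i
at one date is class j one interval later; rows sum to 1 (tolerance 1e-5,
which accepts tables printed at six decimals). The package ships the three
published Shanxi scenario matrices — natural development (NDS), farmland
protection (FPS) and accelerated economic development (AEDS) — as CSV, and
the documented multiplicative edit sets that generate FPS and AEDS from NDS
(e.g. the arable→construction probability cut by 70% under farmland
protection).

The source tables state only the multipliers, not how a row regains unit
mass after an edit. `apply_scenario_edits()` redistributes the freed (or
drawn) probability over the row's non-edited entries *in proportion to their
previous values*, then scales them so the row sums to exactly 1. This
convention was chosen because it is the unique simple rule that reproduces
every printed FPS and AEDS entry from the NDS matrix to better than 1e-6
(the alternative of preserving the printed row sum, which can differ from 1
by 1e-6 of rounding, does not):

```{r}
nds <- shanxi_transition_matrix("NDS")
fps_hat <- apply_scenario_edits(nds, shanxi_scenario_edits("FPS"))
max(abs(fps_hat - shanxi_transition_matrix("FPS")))
```

## Markov demand and the projection interval

`project_demand()` is the plain Markov step `areas' = areas %*% P^steps`.
The package treats the published matrices as a single-step 2020→2040 kernel:
one step applied to the published 2020 areas reproduces the published 2040
baseline arable, forest and grassland areas within 0.006% (the tests assert
0.1%). Water and construction are not expected to match, because the source
study imposes a water-conversion restriction inside its allocator that pure
Markov arithmetic cannot see.

## Patch allocation

`allocate()` converts surplus-class cells into deficit classes. A candidate
cell must have a positive transfer probability for its (from, to) pair and
must not be restricted (either via a mask or via "restrictive" origin
classes such as water). Candidates are scored by
`suitability × (1 + X_j × neighbourhood share of the target class)`, where
`X_j = (TA_j − TA_min)/(TA_max + TA_min)` is the expansion-intensity
neighbourhood weight. Cells above a per-class threshold are sampled with
probability proportional to score; the threshold decays by a configurable
factor (default 0.9) each iteration, so growth starts at the most suitable,
best-connected cells and relaxes. Defaults chosen where the source gives
none: demand tolerance 1% of total area, threshold decay 0.9, neighbourhood
radius 1. The allocator is deterministic given its seed; non-convergence
(e.g. demand unreachable under restrictions) is flagged on the returned
grid rather than raised, with per-class shortfalls attached.

Suitability surfaces come from a pluggable learner; the default
`learn_suitability()` fits one logistic regression per destination class on
the driver surfaces (a random-forest learner can be selected when available).
Map agreement is validated with Cohen's kappa, overall accuracy, and — when
the interval's initial map is supplied — the figure of merit over changed
cells.

# Valuation

`build_coefficients()` implements the equivalent-factor identities
`VC = E_a × V` and `E_a = Q × F / 7` (one seventh of the grain value per
hectare, the standard convention). The shipped Shanxi table uses
`E_a = 1031.93` yuan/hm²; its 11-service column sums reproduce the published
per-type totals (arable 4138.03, forest 23 827.26, grass 20 318.70, water
129 620.72, construction 0, unused 206.39 yuan/hm²) to the printed 0.01.

The dynamic correction divides each cell's NDVI by the study-area mean
(`ndvi_correction()`), so the factors average exactly 1 and reweight value
toward densely vegetated cells without changing the area-wide mean
coefficient. `compute_esv()` is linear in area and in the correction;
splitting a grid into tiles and summing reproduces the whole-grid value to
1e-9 relative — both are asserted as properties in the tests.

For conversion accounting, `transition_contribution()` values each changed
cell at `area × F_k × (VC_total_after − VC_total_before)`. The source's
single net-change denominator makes gain/loss percentages sign-ambiguous, so
three normalizations are reported: share of net change (the published
formula), share of total gains, and share of total losses; the latter two
mirror how "largest gains" and "largest reductions" are ranked separately.
Which date's NDVI enters the contribution is not specified at the source;
the package takes whatever correction the caller passes (the later date by
recommendation) and asserts the reconciliation identity
`ESV(t1) − ESV(t0) = ΔESV_total` only under a shared correction, where it is
exact.

# Trade-offs and synergies

`relation_matrix()` correlates every unordered service pair across spatial
units (block-aggregated cells; the aggregation factor is a configuration
knob because the source never states its unit) for each date or scenario
map. Classification: `r < 0` trade-off; `r ≥ 0` synergy (an exact zero
counts as synergy — documented tie rule); synergy with `|r| ≥ 0.8` strong
synergy. The 0.8 default is conventional; the source reports a 52.73% strong
share without defining "strong", so the threshold is exposed rather than
tuned. No significance filter is applied by default, since all pair-date
groups are reported at the source. With 11 services and 6 maps the
combinatorics give C(11,2) × 6 = 330 relations; 37 negative correlations
yield the published 11.21% / 88.79% split.

# Bundles

Per-unit service vectors are z-scored per service (required for Euclidean
K-means across services whose magnitudes differ by orders of magnitude) over
the *pooled* units of all dates, then clustered once in the pooled space so
bundle labels are directly comparable across dates — the cross-date
comparisons of bundle shares presuppose a shared label space. K-means runs
with 25 k-means++-style restarts under a fixed seed. `elbow_select()` scans
k = 1..k_max and takes the k of maximum curvature (largest second difference
of the WCSS curve); a numerically linear curve has no distinguished knee and
is flagged `flat`. Bundles are named by the services whose centroid z-score
exceeds 0.5 (configurable). On planted three-archetype landscapes
(crop-dominated, forest/grass-dominated, water-dominated bands) the
recovered bundles match the ground truth with adjusted Rand index above 0.9
and carry the expected dominant services: food production; regulation-type
services; hydrologic services.

# Trajectories

With three bundles and four dates there are 3⁴ = 81 possible sequences.
`encode_trajectory()` is the positional code
`c1·1000 + c2·100 + c3·10 + c4`. `classify_trajectory()` maps the metric
triple (changes, diversity, similarity) to: (0,1,4) stable, (1,2,3)
metastable, (1,2,2) gradual, (2,2,3) cyclic, and everything else "other".
Two rules deserve note. First, the published determination table lists only
examples for the residual class, and no class for three-change sequences;
"other" is therefore implemented as a strict catch-all, making the five
classes an exhaustive partition of all 81 sequences (asserted against an
independent brute-force classifier). Second, cyclic requires similarity 3,
so a two-step excursion-and-return such as 1221 (similarity 2) is "other"
even though prose alone ("changes cyclically between two time nodes") might
admit it; the metric rows of the determination table are taken as
authoritative. Classification is invariant under relabeling of bundle ids,
also asserted exhaustively.

# Driver attribution

`factor_q()` is the variance-decomposition statistic
`q = 1 − Σ N_h σ²_h / (N σ²)`, computed with population variances (a
documented convention — sample variances change q in small strata), equal to
1 − SSW/SST, with the noncentral-F significance test. Monotonicity under
partition refinement and agreement with a brute-force group-by oracle to
1e-12 are asserted in tests. `interaction_detect()` overlays two
stratifications and types the interaction by the standard inequalities
(nonlinear/two-factor enhancement, independence, single-factor/nonlinear
weakening); equalities are tested with tolerance 1e-6 and boundary ties
(e.g. a self-overlay, where q12 = max exactly) are reported as ties rather
than forced into an inequality class. `vif()` screens collinearity with the
usual `1/(1 − R²)` regressions; the risk and ecological detectors are out of
scope (named at the source but unused in its results).

The response for bundle attribution is a one-vs-rest bundle indicator per
unit (a continuous share once aggregated), with total ESV available as an
alternative — the source never states its response encoding.

# The synthetic generator

`gen_scene()` draws a stationary Gaussian random field (white noise smoothed
by FFT convolution with a Gaussian kernel; the kernel SD, in cells, is the
"patchiness"), then thresholds it at the cumulative target quantiles, so
class shares are exact up to cell discreteness and the mosaic is spatially
autocorrelated. NDVI is class-conditional normal clamped to [0, 1]; with
zero noise it equals the class means exactly, giving clean degenerate-case
tests. Drivers are trend surfaces (smooth field, gradients, radial distance)
plus noise plus `link ×` a standardized class level; the default set mirrors
the usual nine natural/socio-economic factors with slope and GDP carrying
planted associations, so driver detection has recoverable signal of known
location. All streams derive from one integer seed by fixed offsets; a
scene is bit-reproducible from its config.

`evolve_scene()` draws each cell's destination independently from its
class's matrix row. Spatial clustering of change is deliberately absent so
that binomial statistics for transfer frequencies hold exactly and
`estimate_transition_matrix()` recovery can be tested against 3-SD binomial
bands.

What the generator does *not* emulate: real geomorphology (valleys,
aspect-dependent vegetation), spatially correlated conversion (urban fringes),
class-dependent NDVI trends over time, or measurement error in the rasters.
Passing tests therefore demonstrate correctness of the algorithms and
recoverability of planted signal, not calibration to any real landscape.

# Problem sizes and numerical choices

The test suite uses grids from 16×16 to 256×256 for behavioural checks, one
512×512 scene for transition-recovery convergence (balanced class shares, so
the rarest row still has ~44 000 cells and the 3-SD binomial band is well
inside the 0.01 assertion), 2 000 units for correlation recovery, and a
48×48, 3-scenario, 4-date configuration for the end-to-end pipeline run.
These sizes were chosen so each statistical assertion has comfortable power
while the whole suite runs in seconds on a single core.

Other numeric choices: transition rows validated to 1e-5 (printed-table
rounding); scenario-edit renormalization restores row sums to exactly 1;
no-op edits leave rows bit-identical; WCSS curves are forced non-increasing
across k by taking the running minimum over restarts; interaction equalities
use tolerance 1e-6; q uses population variance; NODATA cells are excluded
from NDVI means and ESV totals.

# Limitations

- The allocator is a faithful but generic patch grower: it honours demand,
  transition gating, restrictions, neighbourhood weights and threshold
  decay, but makes no claim of bit-compatibility with any specific land-use
  simulator release.
- The published 2040 farmland-protection and accelerated-development maps
  depend on unpublished spatial constraint geometries; only their
  *directional* consequences (e.g. farmland protection retains more arable
  land than the baseline) are asserted, on synthetic scenes.
- Currency is kept in yuan with convenience reporting in 10⁹ yuan; no price
  deflation across dates is attempted, and the standard equivalent E_a is a
  configuration constant (its grain-statistics derivation inputs are not
  published).
- Trajectory typing requires exactly four dates; every other stage is
  date-count agnostic.
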