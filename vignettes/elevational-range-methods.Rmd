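---
title: "Methods: elevational range-size gradients, the mid-domain null, and their drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elevational range-size gradients, the mid-domain null, and their drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the statistic

Rapoport's rule predicts that species range sizes increase with elevation.
For a plot-based survey the standard test is Stevens' method: estimate each
species' elevational range as the difference between the highest and lowest
plot where it was recorded, average those range sizes over the species
present in each plot, and regress the per-plot mean on plot elevation. A
positive slope supports the rule; `elevrange` additionally gates the call on
a two-sided p-value below 0.05 by default (`rapoport_regression()`, the gate
is removable) so that sign noise in flat gradients is not scored as support.

Two properties of the Stevens statistic matter for interpretation and are
enforced throughout the package:

* a species recorded in a single plot has range size 0 m and still enters
  the average — the max-minus-min definition forces this;
* a plot containing no species of a group has an *undefined* mean, recorded
  as missing and dropped from regressions, never as zero. A zero would
  fabricate a small-range signal exactly where groups thin out, i.e. at the
  gradient ends.

Species are analysed overall and in four subgroups: life form (woody vs
herbaceous) and biogeographical affinity (temperate vs tropical, following
Wu's areal-type system; the mapping from areal-type labels to affinities is
shipped as a CSV lookup and matched case- and whitespace-insensitively).
Cosmopolitan and unclassified species never enter the affinity groups;
whether they enter the overall group is a config flag
(`include_unclassified_overall`, default `TRUE`, on the view that they are
recorded species).

## The mid-domain null model

Randomly placed ranges inside a hard-bounded domain overlap most near the
domain center, so mean range size shows a mid-domain peak with no ecology
involved. The null model (`simulate_mde()`) mirrors the field convention:
in each of `n_sims` simulations (default 1,000) every empirical range size
is placed exactly once — "sampled without replacement", so only midpoints
are random — with the midpoint drawn uniformly on the feasible interval
`[low + r/2, high - r/2]`. A plot is covered when it lies in the closed
placed interval; the per-plot statistic is the mean size of covering
ranges, undefined when none cover; the prediction averages over the
simulations with at least one covering range, and `n_effective_sims`
records the divisor.

`mde_expected_profile()` computes the same expectation exactly. With
independent coverage indicators `X_i ~ Bernoulli(p_i(e))` (the coverage
probability is the overlap of `[e - r/2, e + r/2]` with the feasible
midpoint interval divided by its length), the conditional mean uses the
identity

    E[ sum r_i X_i / N | N > 0 ] = sum_i r_i p_i E[ 1/(1 + N_-i) ] / P(N > 0),

where `N_-i` is Poisson-binomial over the other ranges. The full
Poisson-binomial polynomial is built once per elevation (O(k^2)) and each
leave-one-out distribution is recovered by synthetic division of one factor
(O(k)), dividing from whichever end of the polynomial has the larger factor
coefficient for stability. Two independent cross-checks are kept as
methods: brute-force enumeration of the `2^k` coverage outcomes (k <= 15)
and tensor quadrature over discretized midpoints (k <= 3), which is exact
when coverage boundaries align with the grid; the test suite drives all
three against each other and the simulator against the exact profile at 3
Monte-Carlo standard errors.

Numerical edge cases are resolved explicitly:

* coverage uses closed intervals, so boundary touching counts as covered;
* zero-size ranges are legal, placeable anywhere, and cover a plot only at
  exact elevation equality — they contribute essentially never;
* at the exact domain boundary every coverage probability vanishes, so a
  finite simulation never observes coverage there. The prediction is filled
  with the analytic limit of the conditional expectation (weights
  proportional to `1/(width - r)`, i.e. at most one covering range in the
  limit) and flagged in `boundary_fill`. This keeps the environmental table
  complete for the two plots that sit exactly on the domain bounds.

One caveat discovered while validating: the familiar "mid-peak" shape is
*not* universal for the mean-size statistic. If the multiset contains
ranges wider than about half the domain, every such range covers the center
with probability 1 (pulling the center value toward the plain average)
while boundary coverage is size-biased toward the widest ranges, and the
edge limit can exceed the center. Empirical plant communities — including
the one emulated here, where virtually all ranges are below half the
gradient — sit squarely in the regime where the mid-peak holds, and the
tests assert it there.

Whether the null should be run on the pooled ranges or per group is
underdetermined in the field literature; the pipeline runs it pooled (one
MDE predictor shared by all groups), and `simulate_mde()` accepts any range
subset for per-group runs.

## Environmental layers

Station monthly series are summarized per station-year and averaged across
years: MAT is the mean of the 12 monthly means, MAP the annual sum, TS the
standard deviation of the monthly means (population form, n = 12, in
degrees C — not the WorldClim x100 convention; a sample-SD variant is a
switch), and MATR the warmest-minus-coldest monthly mean. These summaries
are carried from the six stations to the plots by one-dimensional ordinary
kriging along the elevation axis. The reduction from the original 2-D GIS
interpolation is deliberate: with six stations strung along a valley, the
elevation axis carries the signal. The default variogram is linear,
`gamma(h) = c h`, because six support points cannot justify fitting a sill
and range, and the scale `c` cancels in the kriging weights (a spherical
model is available). The interpolator is exact at stations; plots outside
the 2,457-5,230 m station span are extrapolated (and reported) — with the
linear variogram this tends to the nearest station's value, so the outer
~650 m of the gradient carry flat climate profiles rather than invented
trends.

Human population is interpolated by inverse distance weighting (power 2,
along-elevation distance by default, x/y optional), exact at villages by
the limit convention; a target coincident with several villages takes the
first by input order. Glacial-interglacial deltas are
`TC = present MAT - LGM MAT` and `PC = present MAP - LGM MAP` (positive =
warmer/wetter now), with multiple LGM models averaged per plot before
differencing. `assemble_env_table()` joins the eight predictors (MAT, MAP,
MATR, TS, TC, PC, MDE, POP) into one complete row per plot and errors on
any missing plot-variable pair rather than carrying silent gaps.

## The inference layer

All regressions standardize variables to mean 0, sample SD 1, so
single-predictor OLS coefficients equal Pearson correlations and are
comparable across predictors and models.

Spatial autocorrelation is handled with a simultaneous autoregressive
*error* model, `y = X b + u`, `u = lambda W u + e` — the standard variant
when the goal is to account for autocorrelated residuals rather than a
diffusion process in `y` itself. The weights are a symmetric k-nearest-
neighbour graph (union rule, k = 5 by default, along-gradient distance,
deterministic tie-break by plot order) row-standardized; the neighbour
definition is this package's choice, reported in the output, since no
weights specification survives in the source literature. Estimation is
profile maximum likelihood: for a candidate lambda the filtered regression
of `(I - lambda W) y` on `(I - lambda W) X` gives `b` and `sigma^2`, the
Jacobian `log|I - lambda W|` is evaluated through the (real) eigenvalues of
`W` computed once, and lambda is optimized on `(1/min(eig), 1)`. AIC is
`2k - 2 logL` with `k = #b + 2` (lambda and sigma^2). A zero weights matrix
reproduces OLS exactly, and simulation tests verify lambda recovery
(planted 0.6 recovered within 0.1 in >= 90% of replicates at n = 400).

Variable importance uses repeated random forests. Forests themselves come
from the `randomForest` package; the importance statistic is authored here
from per-tree predictions because its exact normalization matters:
`%IncMSE_j = 100 (MSE_oob(permute j) - MSE_oob) / MSE_oob`, averaged over
`n_runs` independently seeded forests (field default 1,000; the bundled
analysis uses 200 and tests use 50 or fewer — the statistic stabilizes long
before that at these problem sizes). Out-of-bag status comes from the kept
in-bag counts; permuting a column and re-aggregating only out-of-bag trees
reproduces the reference implementation's convention, which the tests
confirm by rank agreement with `randomForest`'s own unscaled importance.
Explained variance is `100 (1 - MSE_oob / var(y))`. Note that with few
predictors the default `mtry = floor(p/3)` hits 1 and forces every split to
consider a single random variable, inflating the apparent importance of
uninformative columns; importance fixtures in the tests keep p >= 6 so
`mtry >= 2`.

Significance is reported with the conventional star thresholds (<.05,
<.01, <.001) alongside raw p-values; no multiple-testing correction is
applied, matching standard practice for these descriptive tables.

## The synthetic community generator

The generator exists so that every stage is testable without field data,
and its defaults are the study conditions used by the tests and the
acceptance script: 96 plots evenly spaced on 1,800-5,400 m (spacing about
37.9 m; jitter optional), a 545-species pool, six stations at 2,457, 2,792,
3,368, 3,740, 4,140 and 5,230 m with three years of monthly data, and
bimodal population centers at 2,700 and 4,200 m.

Species geometry is midpoint-parameterized: midpoint `m ~ Uniform(domain)`,
latent size `r = max(0, a + b (m - low) + eps)`, `eps ~ N(0, sd)`. Defaults
`a = 350` m, `b = 0.25` m/m, `sd = 150` m put mean range sizes near 800 m
with virtually all ranges below half the gradient — the regime real valley
floras occupy — and the planted slope is comfortably detectable over 96
plots. Detection is i.i.d. Bernoulli per species-plot (default 0.9,
reflecting exhaustive but imperfect single-visit inventories). When an
interval overhangs the domain it is *shifted* minimally inside rather than
clipped: sizes are preserved, so the planted slope remains interpretable,
and the placement geometry matches the feasible-midpoint convention of the
mid-domain null. Setting `truncate_ranges = FALSE` leaves intervals
overhanging, which makes the expected Stevens profile flat — the
calibration null for the support test. Group labels (life form, areal
type) are drawn independently of geometry by default; an optional per-group
slope map can plant group differences.

Climate follows a linear lapse (default 5.5 K/km from 20 C at sea level)
with a July-peaked cosine annual cycle (half-range 9 K) and small monthly
noise; precipitation declines linearly with elevation (1,500 mm at 0 m,
-0.2 mm/m) with a monsoon-peaked cycle, floored at zero. The
present-minus-LGM offset declines smoothly with elevation with a trough
near 2,700 m and is emitted for three synthetic stand-in models whose
shifts average to zero, so the downstream multi-model mean recovers the
curve exactly. The population table combines the two towns with six small
background villages: an inverse-distance surface interpolated from two
equal towns alone would be constant (IDW is a weighted average), so the
documented bimodal pattern requires the low-population background.

What the generator does *not* emulate: realistic floristics (taxonomy,
endemism structure), 2-D valley topography, elevation-dependent climate
variability (TS and MATR are flat in expectation unless the amplitude is
made elevation-dependent), and any coupling between species traits and
range geometry. Passing tests therefore demonstrate the correctness of the
estimators and the null model, not the ecological conclusions of any
particular survey.

## Calibration findings and known limitations

The package's own calibration study (part of the test suite) plants
`b = 0` with truncation disabled and measures how often the support call
fires at the nominal 0.05 gate. The measured false-support rate is about
13.5% over 200 replicates — well above the nominal 2.5% for a one-sided
call. This is the classic pseudoreplication of Stevens' method: adjacent
plots share most of their species, so the ~96 plot means carry perhaps a
tenth as many effective degrees of freedom as the OLS t-test assumes. The
package reports it as measured rather than recalibrating the generator
around it; it is precisely the motivation for fitting the SAR layer
alongside OLS, and a reason to treat marginal OLS significance on Stevens
profiles with suspicion in any real analysis.

Other limitations worth naming: kriging extrapolation beyond the station
span is honest but uninformative (near-constant); the SAR weights and the
original %IncMSE normalization cannot be recovered from the source
literature, so both are explicit, config-exposed choices here; and the
mid-domain mean-size profile is only mid-peaked in the small-range regime
described above.

## Problem sizes

Default test and analysis sizes, chosen as the package's own balance of
resolution against runtime: the bundled analysis and the acceptance script
run the full 96 x 545 community with 1,000 mid-domain simulations and 200
repeated forests; the null-model validation uses 10,000 simulations against
the exact profile; parameter-recovery suites use 100-200 replicates
(lambda at n = 400, support calls at the full community size). The complete
test suite runs in well under two minutes on one CPU.
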