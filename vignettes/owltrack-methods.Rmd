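---
title: "Models and methods behind owltrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind owltrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

owltrack analyses high-frequency (1 fix/min) GPS telemetry of
central-place-foraging owls: nightly space use and movement metrics,
availability data built from correlated random walks (CRWs), and
mixed-effects resource selection functions (RSFs). This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Fix cleaning and night segmentation

Raw fixes are filtered on two quality rules, applied literally: fixes with
fewer than 4 satellites are removed, and fixes with horizontal dilution of
precision (HDOP) above 5 are removed. Boundary values (exactly 4
satellites, HDOP exactly 5) are retained. Filtering is idempotent.

Fixes are then assigned to individual-nights. The recording window spans
midnight (default 21:00–04:00 local CEST; the package fixes the zone to
UTC+2 with no daylight-saving transitions because the study window is
mid-summer), so post-midnight fixes belong to the previous evening's
`night_date`. Two exclusion rules follow the study design:

* an individual's final night is dropped entirely when recording stops more
  than 10 minutes (configurable) before the window end — the
  battery-ran-out case;
* nights with fewer than 100 positions are excluded from the space-use
  (KDE) pathway but remain available to the distance and displacement
  models, which operate on all cleaned fixes.

## Nightly metrics

**Space use** is the area of the 95% isopleth of a bivariate Gaussian
kernel density estimate with the reference bandwidth
`h_ref = sqrt((var(x)+var(y))/2) * n^(-1/6)` applied to both coordinates.
Density is evaluated on a 200×200 grid extended three bandwidths beyond
the fix bounding box; the isopleth area is the summed area of the smallest
set of cells whose cumulative density reaches 95% of the total. Absolute
areas are mildly grid-sensitive, which is why both the resolution and the
margin are documented arguments; at the default resolution the area agrees
with a 1000×1000 oracle evaluation to well under 1% and is invariant under
translation and rotation to ~0.5%.

**Foraging trips** are maximal excursions containing at least one fix more
than 200 m from the nest, bounded by the last at-nest fix (≤25 m) before
and the first at-nest fix after; the duration runs between those bounds.
Excursions that exceed 200 m but lack an at-nest bound on either side
(recording started or ended mid-trip) are censored: counted and reported,
but excluded from duration statistics so they cannot bias durations
downward.

**Hourly displacement** sums straight-line distances between consecutive
fixes, assigning each step to the clock hour of its earlier fix. Steps
spanning a recording gap longer than 10 minutes are excluded (fix-dropout
protection); the number of fixes per hour is reported alongside because it
is a bias covariate for displacement models. **Nest visitation** is a
two-state machine: a fix beyond 50 m arms it, the first subsequent fix
within 25 m scores one visit (assigned to the arrival fix's hour) and
disarms it, so consecutive at-nest fixes collapse into one visit. The
**near-nest proportion** is the share of fixes within 25 m.

All four pointwise metrics are tested for exact agreement with independent
brute-force replays of their definitions on a thousand random synthetic
nights.

## The availability model: central-place correlated random walks

Comparing autocorrelated GPS positions against independently scattered
random points misstates availability. The pipeline instead simulates, per
individual, a central-place CRW with the same autocorrelation structure as
the observed trajectory:

* headings evolve by von Mises turns with concentration `kappa`
  (`kappa = 0` is an uncorrelated walk);
* step lengths are resampled with replacement from the individual's own
  observed steps — no parametric fit;
* with probability `(d/dmax)^gamma` (current nest distance `d`) the
  heading is instead redrawn around the bearing to the nest, a smooth
  movement restriction that strengthens with distance;
* positions beyond `dmax`, the individual's maximum observed nest
  distance, are rejected and redrawn (hard reflection).

Both mechanisms together reproduce bounded, nest-concentrated
availability. The turning model uses the von Mises concentration rather
than a [0,1] correlation scalar because it is standard, directly
samplable, and monotone in the mean resultant length
(`rho = I1(kappa)/I0(kappa)`, invertible via Fisher's approximation).

`(kappa, gamma)` are fitted by seeded simulation matching: a coarse grid
(`kappa` in {0, 0.5, 1, 2, 4, 8, 16}, `gamma` in {0, 0.5, 1, 2, 4}; 5
replicates per point) minimising

```
J = KS(nest distances) + KS(step lengths)
    + (1 - cosine similarity of turning-angle histograms)
```

followed by a local refinement pass around the optimum (multiplicative
neighbours for `kappa`, additive for `gamma`). Turning histograms use 10°
bins: concentrated distributions are not resolved by coarser binning. `J`
is non-negative and approaches its floor only in the self-match limit.
Fitting simulations are capped at 500 steps (about one recording night) by
default.

One identifiability caveat, which matters for validation: `gamma` is only
defined jointly with the radius. The study definition sets
`dmax = max(observed nest distance)`, which *undershoots* any true
movement boundary, so in simulation self-consistency checks the true
radius must be supplied (the `dmax` argument); otherwise the refit
compensates with a larger `gamma` by construction.

Availability sets contain exactly 10 random positions per used position
(configurable). When per-night fix counts are supplied, the availability
walks restart at the nest once per observed night with matching lengths,
mirroring the start-at-roost structure of the data; this measurably
improves the calibration of the used/available contrast.

## The synthetic generator and its ground truth

The generator exists so every stage can be validated against known truth.

**Landscape**: a square extent partitioned by jittered break lines into a
rectangular-field mosaic over nine land-cover classes; classes are
assigned by greedy largest-deficit so realised areal proportions track the
target mix; nest fields are forced to "built up" (owls nest in farm
buildings); roads run along a subset of interior borders and every field
border is a field edge. Reference conditions: 3 km extent, ~200 fields
(mean ~4.5 ha, matching the study regions' ~4.8 ha), cereal-dominated mix.

**Movement**: one position per minute inside the nightly window. A single
candidate step is proposed from the CRW kernel (von Mises turning from
`turn_correlation = 0.7`; gamma step lengths with mean `step_scale = 20` m
— chosen to reproduce the reported ~1.2 km mean hourly displacement) and
accepted with the Metropolis probability
`min(1, exp(beta_new - beta_old))` of the per-class log-selection
strengths; on rejection the owl perches in place for that minute. Two
details make the ground truth recoverable in principle:

* *Why Metropolis rather than weighted choice among candidates*: with
  ~20 m steps inside fields of 0.5–5 ha, most candidate sets fall in a
  single field, so choosing among them cannot express selection — the
  realised tilt saturates far below `exp(beta)`. The Metropolis rule's
  stationary distribution carries the `exp(beta)` tilt over the null
  walk's availability exactly (for a reversible proposal), at any field
  grain.
* *Heading reversal on rejection*: with persistent headings a
  position-only Metropolis rule is not reversible; reversing the heading
  on rejection (the standard momentum flip of underdamped samplers)
  restores the tilted stationary distribution. Without it the realised
  selection is attenuated by roughly a third.

With all coefficients zero, every proposal is accepted and the process is
exactly a null central-place CRW.

Central-place behaviour: proposals are re-centred on the nest bearing with
probability `min(d/home_scale, 1)^attraction` (defaults 800 m and 2,
giving ranges of several hundred metres), each night starts at the nest,
and end-of-night steps are forced nest-ward so the owl roosts within 25 m.
The assumption that owls start every night at the nest is a modelling
choice the study data cannot confirm.

**GPS degradation**: isotropic Gaussian noise (default sd 3 m, the
tag-class accuracy), nominal quality fields (nsats = 4 + Poisson(2), HDOP
log-normal with median 1.5), a `bad_fix_rate` fraction of fixes
overwritten to trigger the cleaning filter, and independent dropout. Under
the defaults a nominal fix essentially never trips the filter, so the
removal fraction estimates the injected rate.

**What the generator does not emulate**: prey, terrain, weather-dependent
behaviour, multi-animal interactions, day-time roosting, tag failure modes
beyond random dropout, or spatially structured land cover (classes are
exchangeable across fields). Passing tests therefore demonstrate the
*pipeline's* correctness and calibration under a faithful but idealised
movement model — not that real owl data meet the model's assumptions.

## Inference

All models use a single Gaussian random intercept for individual (the
study found nesting individuals within territory changed nothing). LMMs
are REML fits; GLMMs (binomial-logit, Poisson-log) use adaptive
Gauss–Hermite quadrature with 15 nodes by default — doubling the nodes
moves coefficients by far less than 1e-3 on test fixtures. The RSF front
end defaults to the Laplace approximation (one node), the standard choice
for large used/available designs. Wald 95% intervals are reported on the
link scale. Distances are z-scored before fitting. For Poisson fits with
more than one quadrature node the reported log-likelihood adds the
saturated-model constant that lme4 omits, so likelihoods are comparable
across node counts and with plain GLMs.

The RSF codes land cover against the "cereal" reference. Classes observed
on only one side of the used/available design are flagged unstable (their
coefficients diverge) and excluded from the default class set of the
relative-probability-of-use summary, which evaluates
`plogis(intercept + class effect)` at mean distance covariates and random
effect 0. Under a 1:R design with no selection this equals `1/(1+R)` —
the 0.1 reference line for R = 10.

Backward stepwise selection minimises AICc
(`AIC + 2k(k+1)/(n-k-1)`, `k` counting fixed effects and variance
components), respects marginality (main effects are not candidates while
their interaction remains), compares Gaussian models on ML fits, drops
the later term in formula order on exact ties, and skips candidates with
`n <= k+1` where the correction is undefined. Terms whose 95% interval
includes zero (boundary inclusive) are labelled uninformative. Nakagawa
marginal/conditional R² uses the fixed-predictor variance, the
random-intercept variance, and a distribution-specific residual variance:
the residual variance (Gaussian), `pi^2/3` (logit), or the trigamma of
the expected count at the model intercept (Poisson, trigamma method —
the lognormal approximation is the common alternative and differs
negligibly at the counts involved here).

## Calibration results and known limitations

Three calibration facts shape how the pipeline's output should be read;
all are measured by the test suite, none are asserted beyond what the
tests compute.

1. *The null is well calibrated.* With zero selection, six owls and five
   nights each, the class-averaged relative probability of use lands on
   the `1/(1+10)` line within ±0.02 across seeds, and thinned (10-minute
   lag) class use passes a goodness-of-fit test against areal
   availability. Thinning is essential: consecutive 1-minute fixes are so
   strongly autocorrelated that a raw chi-square has entirely the wrong
   size — the same point that motivates CRW availability in the first
   place.

2. *Selection-strength estimates are approximately unbiased but their
   Wald intervals are too narrow.* Across replicate synthetic studies
   (~2,500 used positions), estimates of a +1.5 / −1.0 ground truth
   centre near the truth, yet between-replicate spread exceeds the Wald
   halfwidth by a factor of 2–3. The residual variance comes from each
   owl's finite habitat exposure and from the single 10× availability
   draw, neither of which the GLMM's independence assumptions see. Wald
   CIs from used/available RSFs on high-frequency data should be read as
   optimistic; this is the residual form of the autocorrelation problem,
   mitigated but not removed by CRW availability.

3. *Two smaller attenuation sources*: GPS noise misclassifies points near
   field borders (relevant when fields are small), and the fitted
   availability absorbs the radial component of selection because the
   movement model is matched to the *observed* (selection-displaced)
   nest-distance distribution — the method estimates selection beyond
   movement, not the full marginal preference.

Backward AICc selection on null data retains any junk covariate whose
deletion statistic exceeds ≈2.13 (at n = 200), which happens for at least
one of three junk terms in roughly 38% of runs — matching the chi-square
arithmetic exactly. AICc-selected minimal models should not be read as
containing only real effects.

## Reference problem sizes

The shipped analysis scripts and tests use six owls × five nights
(~12,500 used positions, 10× availability), landscapes of ~200 fields over
3 km, 200×200 KDE grids, and 10-replicate recovery experiments; these
sizes were chosen so a full run completes on a laptop-class machine in
minutes while keeping Monte-Carlo error well inside every stated
tolerance.
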