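# owltrack

Movement analysis and habitat selection for high-frequency GPS telemetry
of central-place-foraging owls.

Nocturnal raptors such as the little owl (*Athene noctua*) can now be
tracked at one position per minute. Data at that rate are a mixed
blessing: they resolve individual foraging trips and nest visits, but
consecutive positions are so strongly autocorrelated that standard
habitat-selection analyses — which contrast *used* positions against
independently scattered *available* points — produce unreliable inference.
owltrack implements a complete, tested pipeline for this setting:

* **Cleaning and segmentation** — remove fixes with <4 satellites or
  HDOP >5; split fixes into individual-nights over a window that spans
  midnight (default 21:00–04:00 CEST); drop truncated final nights; keep
  nights with ≥100 positions for space-use estimation.
* **Nightly movement metrics** — 95% kernel density isopleth areas with
  the reference bandwidth `h_ref = sqrt((var(x)+var(y))/2) · n^(-1/6)`,
  straight-line nest distances, foraging trips >200 m from the nest
  (bounded by ≤25 m at-nest fixes), hourly displacement, and nest
  visitation (return within 25 m after exceeding 50 m).
* **Availability via correlated random walks** — for each individual, a
  central-place CRW (von Mises turning with concentration κ, step lengths
  resampled from the observed steps, nest-ward bias with probability
  `(d/dmax)^γ`, hard boundary at the maximum observed nest distance) is
  fitted by seeded simulation matching and used to generate 10 available
  positions per used position with the same autocorrelation structure.
* **Inference** — logistic resource selection functions (RSFs) and
  linear/Poisson/binomial mixed models with an individual random
  intercept (lme4 backend, adaptive Gauss–Hermite quadrature), backward
  stepwise selection on AICc, 95%-CI informativeness screening, Nakagawa
  marginal/conditional R², and per-class relative probability of use
  (null reference line `1/(1+R)` = 0.1 for the 1:10 design).
* **Synthetic data with known ground truth** — a landscape generator
  (nine land-cover classes on a rectangular-field mosaic), a
  habitat-biased central-place movement simulator whose stationary
  distribution carries an exact `exp(β)` selection tilt, and a GPS
  degradation model (2–4 m noise, quality flags, dropout), so every stage
  of the pipeline is validated against known parameters.

## Worked example

The `analysis/` scripts run a complete synthetic study — six owls, five
nights each, ground-truth selection of pasture (+1.5) and built-up areas
(+1.0) and avoidance of maize (−1.0) against a cereal reference:

```sh
Rscript analysis/01_simulate.R        # landscape, weather, owls, raw GPS
Rscript analysis/02_clean_segment.R   # quality filter + night segments
Rscript analysis/03_movement_metrics.R
Rscript analysis/04_availability.R    # CRW fits + used/available table
Rscript analysis/05_rsf_inference.R   # the RSF and its summaries
```

Each stage narrates what it found and writes tables under `results/`.
A run of the pipeline prints, among other things:

```
owl01: 2073 raw fixes over 5 nights
owl01: 2073 -> 1971 fixes (4.9% removed), 5 night segments
overall removal: 4.9% of 12404 fixes
nightly 95% KDE: 23.0 +- 7.6 ha over 30 nights
foraging trips >200 m: 63, duration 179 +- 113 min
hourly displacement: 1035 +- 392 m over 238 owl-hours
owl01: kappa 1.00, gamma 3.75, dmax 504 m (J = 0.210)
used/available table: 11799 used, 117990 available
territories: field size 4.3 +- 0.5 ha, Simpson D 0.84 +- 0.02
```

and the fitted RSF reports (truth in parentheses):

```
      land_coverpasture   1.5614  [ 1.4778,  1.6450]   (+1.5)
        land_covermaize  -0.7510  [-0.8758, -0.6262]   (-1.0)
     land_coverbuilt up   0.7680  [ 0.6912,  0.8448]   (+1.0)
relative probability of use (null line 0.091):
  pasture  0.209   maize  0.026   built up  0.107   cereal  0.053
```

Classes above the 0.1 reference line are selected, classes below it
avoided; the fitted RSF recovers the sign and ordering of the generator's
ground truth, with the neutral classes near the no-selection line. The
exact values above are from the shipped seed (2026) in
`analysis/01_simulate.R`.

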