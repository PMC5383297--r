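# foxhr

Home-range estimation and drivers of home-range size for red fox
(*Vulpes vulpes*) GPS telemetry along a gradient of landscape productivity
and human alteration.

Red foxes show enormous variation in home-range size, and separating the
landscape-level (latitude), local (elevation) and anthropogenic
(agriculture, settlement) contributions to that variation requires a full
chain of telemetry analysis steps, each with conventions that matter.
`foxhr` implements that chain as a tested R package plus a set of numbered
analysis drivers, for movement ecologists who want the whole workflow — or
any single step — reproducible from a seed:

* **Residency classification** from net squared displacement (NSD):
  constant / logistic / linear mean-NSD shapes fitted by bounded least
  squares and ranked by AICc, with the cohort filter (stationary animals,
  ≥ 90 days monitoring, explicit short-duration overrides).
* **Home-range estimation**: percent minimum convex polygon (MCP) and
  k-nearest-neighbour local convex hulls (LoCoH-k, `k = round(sqrt(n))`)
  at the 90/95/100% isopleths, with area-observation curves for
  monitoring-duration adequacy. Hull unions and all polygon overlay areas
  are computed *exactly* by an internal slab-decomposition geometry engine
  (no GIS dependency).
* **Landscape composition** of each home range: agriculture and settlement
  proportions by exact intersection (settlement precedence), mean elevation
  by zonal statistics or by contour-length weighting, centroid latitude,
  vegetation-zone assignment.
* **Inference**: paired t-tests comparing estimators, a |r| ≥ 0.6
  collinearity screen with full-model AICc arbitration, all 2^5 − 1 = 31
  additive candidate models (+ null) for
  `log(area) ~ elevation + agriculture + settlement + sex + age`,
  AICc = −2ℓ + 2K + 2K(K+1)/(n−K−1) with K = slopes + intercept + error
  variance, ΔAICc, Akaike weights and the ≤ 2-unit equivalence set.
* **A synthetic study generator**: 52 resident foxes (33 M / 19 F) split
  30/14/8 across three vegetation zones, zone-level covariate
  distributions, log areas following
  `log A = b0 + 0.003·elev − 1.37·agri + 0.34·male + e` with the residual
  variance calibrated to R² = 0.5, Ornstein–Uhlenbeck movement calibrated
  to each fox's true area, and a planar landscape (patch mosaics,
  elevation grid, zone bands) — the truth ledger every test recovers
  against.

See `vignettes/foxhr-methods.Rmd` for the models, calibrations and known
limitations.

## Worked example

The chain is split into narrative steps that write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R        # fixes, attributes, landscape, truth
Rscript analysis/02_classify_filter.R # NSD classification + cohort
Rscript analysis/03_homeranges.R      # MCP / LoCoH-k areas + AOC
Rscript analysis/04_composition.R     # proportions, elevation, zones
Rscript analysis/05_inference.R       # t-tests, screen, model selection
```

Transcript of a run at seed 1 (`FOXHR_SEED=1`, the default):

```
52 animals, 27369 fixes total, durations 84-257 days
latitude-elevation r = 0.886 (design calibration 0.89)
label agreement with truth: 94%
cohort: 49 residents kept, 3 excluded (movement_class)
LoCoH-k 90%: mean 6.9 km^2, range 0.47-43.8
MCP 100%:   mean 14.9 km^2, range 1.06-96.4
area-observation: day 90 holds 83% of the 180-day range (n = 23)
mean agriculture 27%, settlement 6%
86% of home ranges below 200 m elevation
paired t (MCP vs LoCoH-k):
  level    t df        p
1  0.90 5.34 48 2.47e-06
screen: dropped latitude (r = 0.88 with elevation, dAICc = 5.29)
top of the model-selection table:
                                model df logLik  AICc  delta  weight     R2
1       elevation + agriculture + sex  5 -54.16 119.7 0.0000 0.25841 0.5368
2                     elevation + sex  4 -55.54 120.0 0.2702 0.22575 0.5100
3 elevation + agriculture + sex + age  6 -53.89 121.8 2.0722 0.09169 0.5418
best-model coefficients:
                   term estimate       se
(Intercept) (Intercept)  0.68606 0.292756
elevation     elevation  0.00345 0.000595
agriculture agriculture -0.88830 0.550476
sex                 sex  0.58930 0.237438
measured vs true log area: r = 0.996
```

Reading: of 52 simulated animals the NSD filter keeps 49 residents (three
lost to chance logistic wins — the fit tables let you audit them); the
collinearity screen drops latitude (r = 0.88 with elevation, and the
elevation full model wins the AICc arbitration); the best model of log
home-range size is `elevation + agriculture + sex` with 26% of the Akaike
weight and R² = 0.54, its coefficients within sampling error of the
generating values (0.003 per m, −1.37 per unit agriculture, 0.34 for
males); MCP estimates are significantly larger than the matched LoCoH-k
estimates (paired t = 5.3 on 48 df); and the measured home ranges track the
planted truth at r = 0.996. The single-call equivalent of steps 2–5 is
`run_pipeline(simulate_study(generator_config(seed = 1)), pipeline_config())`.

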