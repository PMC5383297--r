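---
title: "Methods: home-range estimation and drivers of home-range size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: home-range estimation and drivers of home-range size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`foxhr` implements a complete analysis chain for GPS telemetry of red foxes
(*Vulpes vulpes*) sampled along a south-to-north gradient of landscape
productivity and human alteration: residency classification, home-range
estimation, landscape composition of home ranges, and log-linear modelling
of home-range size with AICc model selection. Because the raw field
telemetry is not redistributable, the package pairs the analysis chain with
a synthetic-data generator that emulates the study design, so every step can
be exercised, calibrated and tested end to end against a known truth. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the synthetic world does and does not capture.

## The movement model behind the generator

Resident (stationary) foxes are simulated as a discrete
Ornstein–Uhlenbeck (OU) process per coordinate axis: an AR(1) recursion

\[ x_{t+1} = \rho\, x_t + \varepsilon_t, \qquad
   \varepsilon_t \sim N\!\big(0,\; s^2 (1 - \rho^2)\big), \]

around a fixed home-range centre, whose stationary per-axis standard
deviation is `s = ou_position_sd` (metres). The autocorrelation is
parameterised by the correlation between consecutive fixes at 3 fixes/day,
default `ou_consec_cor = 0.7`, i.e. an OU time constant of about 0.93 days
— position decorrelates within a day or two, which is the scale reported
for resident mesocarnivore movement. The choice matters little for
home-range *area* (the stationary spread is `s` regardless) but matters for
how quickly the area–observation curve saturates.

The movement scale is tied to each fox's true home-range area by the
normal-ellipse calibration implemented in `derive_position_sd()`: an
isotropic bivariate normal cloud with per-axis SD `s` has a level-`q`
quantile ellipse of area \(A = \pi\, \chi^2_{2,q}\, s^2\), so
\(s = \sqrt{A / (\pi\, \chi^2_{2,q})}\) with the 90% isopleth as the
reference level. This is a first-order calibration: the LoCoH-k isopleth of
a *finite sample* is not the normal ellipse. Empirically, the 90% LoCoH-k
area of a simulated resident is about 0.8 of its nominal ellipse area — a
multiplicative factor common to all animals, which on the log scale is
absorbed entirely by the regression intercept and leaves every slope,
ranking and ratio untouched. We therefore did not chase the factor with a
Monte-Carlo refinement.

Dispersers run two stationary OU phases whose centres are 12 position-SDs
apart, joined by a short drifting leg; their net squared displacement (NSD)
therefore plateaus at roughly \(144\,s^2\), far above the resident plateau
of about \(4 s^2\). Transients are simulated as an *unbiased* random walk.
A directed (drifting) walk would give quadratically growing NSD, which
contradicts the linear-NSD nomadism shape the classifier fits; the unbiased
walk has exactly the linear expected NSD that candidate describes.

## Residency classification

`classify_movement()` fits three candidate mean-NSD shapes by least
squares — constant (resident), three-parameter logistic (disperser), and
linear through the origin (transient) — and ranks them by AICc under a
Gaussian residual likelihood with the maximum-likelihood error variance
(`K` = shape parameters + 1). Three numerical choices deserve mention:

* **Daily aggregation.** Sub-daily fixes are averaged into daily mean NSD,
  and the first day's bin is dropped. NSD is anchored at zero at the first
  fix and climbs away from it over the autocorrelation time; at 3 fixes/day
  that climb is movement noise, not strategy, and the logistic otherwise
  fits it as a spurious "dispersal" on day one.
* **Bounds.** The logistic is fitted with bounded Levenberg–Marquardt
  least squares (`minpack.lm::nlsLM`), with the transition midpoint
  constrained to the interior 5–95% of the monitoring window and the
  transition duration to at most an eighth of the window. The bounds encode
  what a dispersal *is* — a transition completed well inside the record —
  and keep the logistic from degenerating into a slow ramp that tracks
  chance drift.
* **Parsimony rule.** The label is the *simplest* candidate within 2 AICc
  units of the best, not the raw AICc argmin. Raw argmin selection
  over-picks the 4-parameter logistic on genuinely stationary animals at
  the classic AIC over-selection rate (roughly 5–15%); the 2-unit
  equivalence rule is the same convention the model-selection stage uses.
  With all three choices, simulated residents are labelled stationary in
  roughly 95% of runs (48/50 single-fox seeds; 49/52 in the seed-1 study).

Two limitations are worth stating plainly. First, a *single realization* of
an unbiased random walk often resembles a dispersal (the path wanders out
and happens to linger), so simulated transients are frequently labelled
"disperser"; both labels are non-resident and the analysis cohort is
unaffected. Second, the field workflow combined NSD with visual inspection
of the spatial data; inspection cannot be automated, so a small number of
true residents (typically 0–3 of 52) can be lost to chance logistic wins.
The full fit table is returned with every classification so a human can
audit exactly these cases.

The cohort filter keeps stationary animals monitored at least 90 days, a
threshold justified by the area–observation analysis below, plus an
explicit override list: the study design includes two females monitored 84
and 87 days, and the generator reproduces them.

## Home-range estimators

Both estimators work in projected planar metres on the raw fix coordinates
and report areas in km².

**Percent MCP.** `mcp(points, level)` retains the `ceiling(level * n)`
fixes nearest the arithmetic-mean centroid of *all* fixes (a single peel
from a fixed centroid, distance ties broken by fix order — the classical
percent-MCP) and returns their convex hull, built by the monotone-chain
construction with collinear boundary points dropped.

**LoCoH-k.** `locoh_k(points, k, level)` builds, for every fix, the convex
hull of the fix and its `k − 1` nearest neighbours (Euclidean metric, ties
by fix index), sorts the local hulls by ascending area (ties by root
index), and unions them in that order until the union contains at least
`ceiling(level * n)` fixes, boundary points counting as contained. The
per-animal `k` follows the square-root rule, `choose_k(n) = round(sqrt(n))`
rounded half-up and floored at 3 (a hull needs three points for positive
area); the rounding convention is the package's own choice, as only the
square-root rule itself is standard. All tie-breaks are by ascending index,
so the estimator is a deterministic function of the ordered fix table.

A consequence of the stopping rule worth knowing: on the four corners of
the unit square with `k = 3`, the union of the *first two* corner triangles
already contains all four points, so the 100% isopleth has area 0.75, not
the full square. The 100% isopleth is the union of *enough* hulls to cover
every point, not of all hulls.

Exact areas of hull unions and of intersections with landscape layers come
from a slab-decomposition overlay engine (in compiled code): all edge
endpoints and pairwise edge crossings cut the plane into vertical slabs
within which every boundary is linear and the interval structure of any
union/intersection of convex polygons is constant, so two-point
Gauss–Legendre quadrature per slab integrates areas and first moments
*exactly* (up to floating point). The engine is validated against
closed-form cases and an independent grid-counting oracle.

**Area–observation curves.** `area_observation_curve()` tracks the 100%
MCP of all fixes within the first 30, 60, 90, … days; nested point sets
make the curve non-decreasing. On simulated residents monitored 6 months,
the day-90 area is on average about 84% of the day-180 area — the package's
own version of the monitoring-adequacy argument for the 90-day inclusion
rule (the field value was 82%).

## Landscape composition

Land-class proportions are exact intersection areas divided by the
home-range area. Where agriculture and settlement would overlap, settlement
wins: agriculture is counted only outside settlement (the generator never
creates such overlaps; the rule matters for imported layers). Mean
elevation is computed two ways, mirroring the two field data sources:
`mean_elevation_zonal()` averages grid values whose cell centres fall
inside the range (the common GIS zonal-statistics rule,
boundary-inclusive), and `mean_elevation_contours()` length-weights contour
elevations over the clipped contour segments inside the range, with no
inter-contour interpolation. On smooth synthetic terrain the two methods
agree within a tolerance that shrinks with refinement; tests pin 5%.
Centroid latitude maps the area-weighted centroid of the (possibly
multi-part) region through the affine map `lat = lat0 + y / 111320`, which
is exact for the synthetic planar world and adequate at these latitudes for
any projected input. Zone assignment takes the zone polygon containing the
centroid, with shared boundaries resolved to the southernmost zone.

## The statistical model

The response is the natural log of the 90% LoCoH-k area in km² — the
conservative isopleth that excludes extraterritorial excursions. Natural
log is the package's reading of "log transformed": it makes the fitted
coefficients directly interpretable as proportional effects
(`exp(beta * dx)`) and matches the magnitudes of the reference analysis.

Covariates offered: centroid latitude, mean elevation (m), agriculture and
settlement proportions, sex (female = 0, male = 1) and age (subadult = 0,
adult = 1). The female reference for sex is the R factor-default reading of
a positive male offset; nothing in the zone-confounded summary tables
disambiguates it, and the choice only flips the sign of one coefficient.

`collinearity_screen()` computes all pairwise Pearson correlations and, for
every pair with |r| ≥ 0.6, fits the two full models that each exclude one
member; the member whose exclusion leaves the lower-AICc full model is
dropped. In the synthetic world latitude and elevation are correlated at
r ≈ 0.89 by design and elevation always survives the arbitration, because
elevation is the causal variable in the generator.

The candidate set is every non-empty additive subset of the five retained
covariates — \(2^5 - 1 = 31\) models — with the intercept-only null
appended separately for reference, exactly the structure of the reference
model table. `fit_ols()` uses ordinary least squares with the
maximum-likelihood error variance \(\hat\sigma^2 = RSS/n\), log-likelihood
\(-(n/2)(\log(2\pi\hat\sigma^2) + 1)\), and `K = |terms| + 2` (slopes +
intercept + residual variance). This `K` convention reproduces the printed
degrees-of-freedom column of the reference table (best model df 5, null
df 2) and is the decisive check that the likelihood bookkeeping matches.
`aicc()` applies the small-sample correction
\(-2\ell + 2K + 2K(K+1)/(n-K-1)\); `rank_models()` computes ΔAICc and
Akaike weights and flags the ≤ 2-unit equivalence set. No model averaging
is done; the best model is reported, with the equivalence set flagged.
Estimator comparisons use two-sided paired t-tests; the printed reference
statistics (t = 3.13 on 51 df, p = 0.003) are consistent with the
two-sided value, which settles the reading of "one-way".

## Generator calibration choices

The generator's defaults *are* the study conditions; they were fixed once,
from the design, and the package's acceptance checks run against them.

* **Cohort structure**: 52 foxes, 33 male; 30/14/8 across
  boreonemoral/southern-boreal/northern-boreal; per-zone sex splits 21/9,
  9/5, 3/5 (M/F). Age is Bernoulli(0.6) adult — the field split is not
  reported, and age carries no effect in the truth model, so the value only
  exercises the covariate plumbing.
* **Zone covariates**: truncated normals with the reported zone means and
  SDs — elevation 54 ± 22, 106 ± 40, 605 ± 164 m; agriculture 28 ± 21,
  25 ± 21, 2 ± 2%; settlement 1 ± 4, 7 ± 15, 0 ± 0%. Proportions are
  truncated to [0, 1] and jointly rejected if agriculture + settlement
  exceeds 1.
* **Latitude**: zone centres 58.7°, 59.6°, 61.9° with SDs 0.25°, 0.30°,
  0.25°, truncated so each fox's whole landscape window stays inside its
  zone band. Centres and SDs were calibrated analytically — once, before
  any end-to-end run — so that the fox-level latitude–elevation
  correlation is 0.89, the value the screening step is designed around;
  this pulls the southern-boreal centre slightly south of the midpoint of
  its two real study areas.
* **Response**: `true_log_area = b0 + 0.003 * elevation − 1.37 *
  agriculture + 0.34 * male + e`, with `sd(e)` set per cohort so that
  `Var(Xb) / (Var(Xb) + sigma^2)` equals `r2_target = 0.5` on the realized
  covariates. The intercept default anchors the *expected arithmetic mean*
  area of the boreonemoral zone (the best-sampled zone) at its reported
  4.7 km², via the lognormal mean formula.
* **Monitoring**: durations from Normal(170, 78) truncated to [90, 270]
  days, two designated females fixed at 84 and 87 days; 3 fixes/day
  (6/day supported).
* **Landscape**: per-fox patch mosaics on a grid of cell side `s/2` over a
  window of radius `5s`, agriculture as left-anchored strips of width
  fraction `p_agri` and settlement right-anchored — coverage near the
  centre equals the drawn proportions by construction and the classes
  cannot overlap. Elevation is a per-zone background with a plateau at the
  fox's drawn value over its window plus a ±2 m smooth ripple; the
  default grid cell is 250 m.

**What the synthetic world does not capture.** Covariates affect area only
through the additive log-linear model; there is no covariate–residual
structure, no habitat selection, no interaction between neighbouring
foxes, no GPS error or fix failure, and land-class patches exist only
around fox centres. One visible consequence: with the reported
coefficients and the reported zone covariate distributions, the implied
northern-boreal vs pooled-southern contrast in *mean* area is
\(\exp(\Delta X\beta) \approx e^{1.84} \approx 6.3\) (larger still in
arithmetic means, and noisy with only 8 northern foxes) — the generative
model cannot simultaneously match the reported regression coefficients and
the reported zone-mean ratio of about 4, because in the field data those
two summaries are reconciled by covariate–residual correlations the model
does not carry. The package reports the measured ratio as what the stated
model implies; passing tests on synthetic data demonstrate that the
*machinery* measures what was planted, not that the planted world is the
field.

## Problem sizes and reproducibility

Default study size is 52 foxes at 3 fixes/day for 84–270 days (roughly
26,000 fixes); the full chain — classification, six home ranges per fox,
composition against ~20,000 landscape patches and a ~2.8-million-cell
elevation grid, and 32 model fits — runs in a few minutes on one core.
Module tests use a 13-fox reduced design with shorter durations and a
coarser grid. Every random quantity descends from a single integer seed;
re-running any script with the same seed reproduces every output file
byte for byte. Stochastic test assertions (classification rates, recovery
experiments) fix their seeds and state the replicate counts they use:
200 replicate cohorts for coefficient recovery, 50 seeds for the
classification rate, 20 for the area–observation summary.
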