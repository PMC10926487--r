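---
title: "Methods: camera-trap monitoring and flight orientation of alpine aestivating moths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: camera-trap monitoring and flight orientation of alpine aestivating moths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpinemoth)
```

## The monitoring problem

Bogong moths (*Agrotis infusa*) migrate each spring to aestivation sites in
the Australian Alps, where a fraction of the aestivating population emerges
shortly after sunset on most evenings and flies in the open air. Upward-facing
wildlife cameras on a 5–10 minute timelapse can detect these flying moths in
sky images, and the nightly intensity of the evening flights is a usable index
of the relative abundance of moths aestivating nearby. `alpinemoth` implements
the analysis chain from raw per-detection tables to seasonal abundance
modelling and, for video deployments, flight-track orientation statistics.

The package deliberately starts downstream of image analysis: detections,
their prediction scores, and wingbeat measurements are inputs produced by an
upstream detector. Everything from quality screening onwards is implemented
and tested here.

## Study 1: seasonal abundance

### Quality filtering

Automated annotations are screened on three fields, all with closed
(inclusive) intervals: prediction score at least 0.8, wingbeat
signal-to-noise ratio within [1, 50], and wingbeat frequency within
[27, 78] Hz. Two conventions needed fixing where the screen alone does not
determine them:

* the score cut retains 0.8 exactly, because the rule excludes scores
  *less than* 0.8;
* records with a missing SNR or wingbeat frequency are excluded — a missing
  value cannot be shown to lie inside an accepted range. Both are
  configurable through `filter_thresholds()`.

### Twilight windows and exposure

Counting is restricted to evening twilight. `solar_events()` computes
sunset and the civil (−6°), nautical (−12°) and astronomical (−18°) dusks
from a compact low-precision solar ephemeris (Meeus-style series for solar
declination and the equation of time, with 0.833° of refraction at the
horizon). Agreement with an independently implemented reference is well
under two minutes, which is an order of magnitude finer than the image
cadence. The counting window defaults to `[sunset, astronomical dusk)` —
in the single-night video data the activity peak collapses just before
nautical dusk and over 90 % of detections precede astronomical dusk, so
this window captures essentially the whole evening flight. The window is
half-open so that every instant belongs to at most one window. Each
evening is keyed by the local calendar date of its sunset; dusk may fall
past local midnight without changing the key. A fixed UTC offset is used
throughout (AEDT = UTC+11 for the motivating deployment) so results do
not depend on a platform timezone database.

The number of images the camera actually took inside the window is the
*exposure*. Evenings with zero exposure (camera off, flooded, fallen) are
omitted entirely rather than recorded as zero counts: exposure enters the
Poisson model as a log offset, and log(0) is undefined. For the same
reason missing-weather evenings are dropped, not interpolated — the daily
weather is the object of inference, not a nuisance to be smoothed.

### Covariates, lapse rate, and collinearity pruning

Each retained site-evening carries: site elevation and latitude, daily
maximum/minimum temperature and their range, maximum wind gust, evening
twilight duration, an integer study-year index, 9 am relative humidity,
and rainfall. Station temperatures are projected from station elevation to
camera elevation with an adiabatic lapse rate of 9.1 °C per 1000 m
(configurable); whether the regression inputs are adjusted is itself a
switch (`adjust_temperatures`), since the projection is a deterministic
linear shift for a fixed site–station pair and does not change the fitted
temperature *effects*, only their intercept bookkeeping. Sites map to
stations by explicit configuration, never by inferred proximity.

Correlated covariates are pruned before fitting with a greedy rule:
repeatedly find the covariate pair with the highest pairwise Pearson R²;
while it exceeds 0.3, drop the member whose absolute correlation with the
per-evening detection *rate* (count/exposure) is smaller, and repeat. The
response is the rate rather than the raw count because exposure varies by
design. Zero-variance covariates are removed first (their correlations are
undefined), and all ties are broken lexicographically by covariate name so
the procedure is deterministic. The removal log records every step.

### The abundance model

`fit_poisson_exposure()` fits the maximum-likelihood Poisson log-link
regression

$$\log E[\,\text{count}_i\,] = \log(\text{exposure}_i) + \beta_0 + x_i^\top \beta$$

via `stats::glm`. The published description of this analysis is a plain
Poisson regression of jointly entered factors, although one figure caption
calls the model "mixed-effect"; this package implements the described
fixed-effects model (site identity can be entered as a covariate if
desired) and notes the discrepancy here rather than guessing at an
unstated random-effects structure. No overdispersion correction is applied
by default; `quasi = TRUE` inflates standard errors by the Pearson
dispersion without moving the estimates. Confidence intervals are
symmetric Wald intervals (±1.96 SE). `scaled_effects()` reports, per
covariate, the coefficient times the covariate's sample SD over the fitted
rows (a one-SD effect on the log rate) alongside the unscaled Wald bounds
in the covariate's own units.

### Arrival/departure phenology

The occupancy model is deliberately heuristic. With $r_t$ the detections
per image on evening $t$, the arrival curve is the running maximum of
$r_t$ up to the date of the seasonal absolute maximum, and the departure
curve is the reverse running maximum from that date onward. The median
arrival date $A_{1/2}$ is the earliest date whose arrival level reaches
half the peak rate, and the median departure date $D_{1/2}$ the latest
date whose departure level still does. Conventions fixed here: a tied
absolute maximum resolves to the earliest date (shortest arrival phase);
"at least half" (not strictly greater) defines both crossings; calendar
gaps are bridged by the running maxima without interpolating rates. Rain
can produce false-positive detections before first arrival; an optional
minimum-rate floor can suppress them but is off by default so the model
is exactly as stated. `phenology_temperatures()` summarises the thermal
lead-up to each event as the 3-day average of daily maxima ending on the
event date (inclusive), lapse-adjusted to any requested elevation.

## Study 2: flight-track orientation

### From pixels to bearings

Video tracking yields a net displacement (dx, dy) in image coordinates
(x rightward, y downward) for each flying insect. With the camera's top
edge pointing at compass azimuth $a$, the track bearing is
$a + \operatorname{atan2}(dx, -dy)$, wrapped to [0°, 360°). Net
displacement from first to last tracked position is used — the quantity
of interest is displacement over ground, not instantaneous heading.
Day-mode clips (before the camera switches to infrared) are excluded via
a configurable first-valid local time, since daytime detection is
unreliable.

### Uniformity and homogeneity tests

Moore's modified Rayleigh test weights each unit direction vector by the
rank of its track magnitude and normalises the resultant by $n^{3/2}$.
P-values come from a seeded Monte-Carlo null (uniform directions,
magnitude ranks held fixed; 10,000 draws by default) rather than the
published critical-value table, which makes the test exact at any sample
size and reproducible under a seed. With no magnitudes all ranks tie and
average-rank handling reduces the statistic to a scaled classical Rayleigh
resultant. Pairs of locations are compared with the Mardia–Watson–Wheeler
uniform-scores test using the chi-square (2 df) large-sample reference,
with a seeded permutation alternative for small samples; cross-sample ties
are broken by a tiny seeded jitter with a warning. Both tests hold their
nominal size in the package's calibration suite (type-I error within
±0.01 and ±0.015 of 0.05 over 1000 seeded null repetitions).

### Orientation-model family and AIC selection

Track directions are modelled with the classical orientation-model family
built from von Mises components: uniform; unimodal; unimodal with uniform
contamination; axial bimodal (modes 180° apart, shared concentration);
and general bimodal with shared or free concentrations — the two-mode
models each in a fixed-weight (λ = ½) and free-weight variant. The exact
family membership is configurable, since published selection frameworks
enumerate about ten variants. Each member is fitted by maximum likelihood
with multi-start bounded L-BFGS-B (mean-direction starts on a coarse
angular grid plus the moment estimate; κ bounded away from overflow) and
members are ranked by AIC = 2k − 2 log L. A non-converged member is
flagged and excluded from the ranking, never silently reported as best.
In a bimodal fit the "first" component is the one with the larger weight.
Component dispersion is reported as the circular SD,
$\sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}$, in degrees. The fitted
log-likelihood is required (and tested) to dominate a brute-force grid
scan, which guards against optimiser failure independently of the
optimiser itself.

### Summit-relative directions and elevation timing

Directions relative to a summit subtract the great-circle forward azimuth
from site to summit (via `geosphere::bearing`) and wrap to (−180°, 180°]:
0° is straight toward the summit and |relative| > 90° is motion away from
it. At sub-kilometre ranges the spherical bearing and a flat-earth bearing
differ by well under 0.01°. Detection time is regressed on site elevation
by ordinary least squares with a Wald test of zero slope; a slope of
$b$ s/m implies a delay of $b\,\Delta h/60$ minutes between two
elevations. Activity is summarised in half-open 2-minute bins, and sky
illuminance is interpolated log-linearly between measurements (twilight
illuminance decays roughly geometrically, so the midpoint of 10 lx and
0.1 lx is 1 lx); extrapolation outside the measured span is refused.

## The synthetic-data generator

Real deployments produce multi-gigabyte image sets; the generator
reproduces the *statistical* structure the analyses rely on so that every
stage can be tested end-to-end in code:

* a trapezoidal seasonal occupancy envelope per site (onset, linear rise,
  plateau, linear fall) — the simplest shape with well-defined half-rise
  and half-fall dates for phenology recovery tests;
* daily station weather as seasonal sinusoids plus independent Gaussian
  noise (an AR(1) switch is out of scope; independence is the default and
  the GLM tests assume it);
* per-evening counts Poisson-distributed with mean
  envelope × exp(β·(weather − centre)) × images-in-window, exposure taken
  from a generated capture log at the configured cadence;
* detection timestamps placed in the twilight window by a von Mises
  kernel centred mid-window;
* quality fields drawn from pass/fail mixtures with exactly computable
  pass rates, and rain-triggered false positives before onset;
* a truth ledger recording every intermediate (per-evening rate,
  envelope, Poisson mean, counts), so downstream stages are tested
  against exact bookkeeping, not just end-to-end statistics.

Defaults emulate the motivating deployment: two alpine sites at 2152 m
and 1839 m followed from mid-September to early April, 10-minute cadence,
envelope plateaus of 10 and 5 detections per image (on the order of a
hundred detections per evening at peak, matching the magnitude of the
field counts), a positive maximum-temperature effect and a negative gust
effect. Same seed, same output, byte for byte.

What the generator does *not* emulate: detector error structure beyond
the three quality fields, weather autocorrelation, within-evening
non-stationarity beyond the twilight kernel, and repeat detections of
individuals. Passing tests therefore demonstrate correctness of the
analysis chain under the stated generative assumptions, not robustness to
every property of real camera data.

## Numerical choices and test problem sizes

* Solar events: ±2 min accuracy target, verified against an independent
  10 site-date reference table; iterative hour-angle solution (3
  iterations) on the low-precision ephemeris.
* GLM: convergence tightened to 1e-10; coefficient recovery checked over
  100 seeded tables of 500 evenings (95 % Wald coverage ≥ 90 % per
  coefficient); the exposure-offset contract (multiplying exposure by c
  shifts only the intercept, by −log c) holds to 1e-6.
* Phenology: recovery of half-rise/half-fall dates within ±3 days in
  ≥ 90 of 100 seeded trapezoid seasons at peak expected counts well above
  20 per evening. The running-maximum construction biases the half level
  slightly upward (the observed peak is the maximum of many noisy
  evenings), which is why adequate counts matter; at realistic count
  magnitudes the bias is within the ±3-day tolerance.
* Circular tests: 1000-repetition seeded calibration of both tests; power
  ≥ 0.99 at κ = 2 with n = 100 (Moore) and n = 200 per sample, means 90°
  apart (MWW).
* Orientation fits: recovery of a bimodal mixture (μ = 60°/200°, κ = 4,
  λ = 0.6, n = 2000) to within 5° per mean and 0.05 in weight, with the
  fitted likelihood dominating 5° (unimodal) and 10° (bimodal) grid
  scans.

These sizes were chosen so the full suite exercises every statistical
claim while remaining a routine desk-scale run.

## Known limitations

* The abundance model treats evenings as independent; temporal
  autocorrelation in moth activity is not modelled.
* The phenology model cannot separate departure from mortality, and its
  median dates are defined relative to the observed seasonal peak, so
  they inherit the peak's sampling noise.
* The orientation analysis measures track over ground; wind drift is not
  corrected.
* Polar-latitude twilight (events that never occur) is reported as an
  explicit missing value, not handled by alternative window definitions.
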