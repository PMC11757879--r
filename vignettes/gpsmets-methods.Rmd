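---
title: "Estimating oxygen consumption from GPS tracks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating oxygen consumption from GPS tracks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsmets)
```

## The problem

A wrist GPS device records latitude, longitude and time at roughly one-second
intervals while someone walks or runs; elevation comes either from the device
or from map data. From speed and gradient alone, how much oxygen did the
athlete consume — and hence how much energy did they expend?

The classical tool is the pair of ACSM metabolic equations, linear in speed
$v$ (m/min) and decimal grade $g$:

$$\dot VO_2^{walk} = 0.1\,v + 1.8\,v\,g + 3.5, \qquad
  \dot VO_2^{run} = 0.2\,v + 0.9\,v\,g + 3.5 \quad \text{(ml/kg/min)},$$

the first intended below 8 km/h, the second at or above. Applied as a
speed-switched pair they jump from 16.8 to 30.2 ml/kg/min at exactly 8 km/h
on the flat — right in the speed band where a large share of recreational
marathoners run. `gpsmets` implements a continuous alternative built on the
metabolic-equivalent (MET) scale, alongside the ACSM equations as reference
methods and an agreement-statistics suite to compare any two methods.

## The model

**Horizontal METs from speed.** Exercise intensity for level walking and
running is piecewise log-linear in speed $v$ (km/h):

$$\ln(\mathrm{METs}) = \begin{cases}
  0.224528\,v + 0.254354 & v < 8.69 \\
  0.065439\,v + 1.636715 & v \ge 8.69
\end{cases}$$

The two lines intersect at the 8.69 km/h threshold: the branch disagreement
there is about 0.001 METs, so in contrast to the ACSM pair the model is
effectively continuous in speed.

**Gradient cost.** The ratio of VO₂ on a gradient to VO₂ for level travel at
the same speed is a quadratic in slope $s$ (percent, rise/run × 100) with a
Y-intercept fixed at 1:

$$\mathrm{Cost}(s) = 13.6524\times10^{-4}\,s^2 + 5.1921\times10^{-2}\,s + 1.$$

Its vertex sits near $s = -19\%$ (gentle downhills are cheaper than level
running; steep descents cost again), and it is strictly positive over its
±45% validity range — the gradient range of the source measurements. Inputs
beyond ±45% are clipped, never extrapolated, and clips are reported.

**Per-segment accumulation.** Adjacent track points define segments with
horizontal (great-circle, R = 6 371 km) and 3-D distance, duration, speed
and slope. Per segment,
$\mathrm{METs}_{slope} = \mathrm{METs}_{horiz}(v)\times\mathrm{Cost}(s)$,
MET·h = METs × hours, and cumulative VO₂ uses the standard 3.5 ml/kg/min per
MET (so 210 ml/kg per MET·h). Body mass (as worn, gear included) converts
ml/kg to litres, and 5 kcal per litre of O₂ converts to energy.

```{r}
mets_on_slope(10, 10)                    # 10 km/h on a 10% climb
b <- generate_track(leg_spec(10, 0, 3600))
kin <- segment_track(b$track)
accumulate_energy(kin, "mets", athlete_profile(60))
```

## Unit conventions

Two slope conventions coexist in this field and mixing them is the classic
100× bug. Throughout the package: segments and the METs-model functions use
**percent** slope; the ACSM equations use **decimal grade** (0.05 = 5%). The
accumulator converts at the boundary; every function documents which
convention it takes.

Cumulative VO₂ is reported in ml/kg (and L / kcal given a mass). The
embedded validation dataset's magnitudes (≈1,100 per 5-km bout) are only
consistent with cumulative ml/kg, so that is the unit used for all its
statistics.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `speed_threshold_kmh` | 8.69 | km/h | intersection of the two METs regression lines |
| `slope_clip_pct` | 45 | % | validity range of the gradient-cost fit |
| `outlier_speed_max_kmh` | 40 | km/h | above any human running speed: GPS "teleport" filter |
| `smooth_window` | 1 (off) | points | moving-median elevation smoothing; off by default — the reference configuration applies none |
| `met_vo2_ml_kg_min` | 3.5 | ml/kg/min | conventional resting VO₂ of 1 MET |
| `kcal_per_l_o2` | 5 | kcal/L | standard aerobic energy equivalent of oxygen |

Speeds above 20 km/h warn rather than error: the METs fit extrapolates
exponentially beyond the intensity tabulations it was built from.

## Kinematic design choices

* **Which distance feeds speed.** Segment speed uses the 3-D distance
  actually travelled (horizontal ⊕ vertical); slope uses the horizontal
  distance as denominator, exactly matching the rise/run definition. The
  source description of "Euclidean distance" does not resolve this; the
  choice is stated prominently because it is a genuine degree of freedom.
* **Spherical horizontal distance.** Haversine on R = 6 371 000 m; at
  sub-10 m 1 Hz hops the planar-vs-spherical discrepancy is orders of
  magnitude below GPS noise.
* **Degenerate segments.** Zero-duration segments (duplicate device
  timestamps) are dropped and counted, not errors. Pure vertical steps get
  the clipped ±45% slope instead of an infinite one, so elevator-like
  artifacts cannot produce unbounded cost.
* **Branch boundary guard.** Speeds reconstructed from coordinates written
  at 1e-7 degrees can land a few ULPs below a nominally exact 8 km/h, which
  would silently flip the speed-switched ACSM method onto the walking
  branch. Speeds within 1e-6 km/h of the threshold — far below GPS
  resolution — are treated as at-threshold.

## Elevation

Device elevations in the input file are authoritative by default
(`fill_missing` only completes absent values); `override_all` replaces them
from a provider. The provider contract is just a deterministic
`function(lat, lon)` returning metres or `NA` for not-covered, so a web
altitude API can be wrapped without the core ever needing a network; the
shipped implementation is an in-memory raster grid with bilinear
interpolation (nearest-neighbour available for exactness checks). Bilinear
was chosen because it reproduces linear terrain exactly and is the common
default for point queries on elevation rasters.

## Agreement statistics

`relative_errors()` computes per-pair $(\text{method}-\text{ref})/\text{ref}$,
its mean and sample ($n-1$) SD, a one-sample $t$ test against 0 and the
95% $t$ interval — the $t$ interval, not a normal one, because the embedded
ten-participant dataset reproduces its published interval only with
$t_{0.975,9}$. `bland_altman()` uses differences fixed as method − reference
(stated in every output) with limits of agreement at bias ± 1.96 sample SD.

```{r}
d <- fivek_validation()
relative_errors(paired_measurements(d$k5, d$mets, d$id))
bland_altman(paired_measurements(d$k5, d$mets, d$id))
```

The dataset's per-minute agreement biases cannot be recomputed from the
cumulative columns without each participant's finish time, which the table
does not carry; only cumulative-unit statistics are therefore asserted
anywhere in the package.

The speed-switched reference method is `"acsm_rw"`; `"acsm_run"` applies the
running equation at *all* speeds, including walking ones. That reading is
the one consistent with the embedded dataset (slow mixed-pace participants
show `acsm_run` above `acsm_rw`, which only the all-speeds application
produces) and with the observation that the running equation overestimates
when walking is included.

## The synthetic generator

`generate_track()` lays points along a meridian (so metres→degrees is
latitude-independent) at a fixed sampling interval, one constant-speed,
constant-slope leg at a time. The horizontal step is sized so the **3-D**
speed equals the specified speed — consistent with the kinematics convention
— and elevation integrates the vertical component. Optional Gaussian noise
(one seeded generator per bundle) perturbs positions in metres before
conversion to degrees, and elevations in metres. Leg durations are snapped
to whole sampling intervals, which makes the bundled closed-form
expectations exact rather than approximate: on noise-free input the full
read → segment → accumulate pipeline agrees with them to ~1e-13 relative,
and the test suite requires 0.1% over a speed × slope grid spanning both
model branches.

What the generator does *not* emulate: multipath and autocorrelated GPS
drift, pauses, curved paths, barometric elevation artifacts, and
physiological lag between mechanical and metabolic intensity. Passing the
synthetic round-trip therefore demonstrates internal consistency of the
implementation, not field accuracy of the model; field accuracy is what the
embedded validation dataset and its agreement statistics speak to.

Default study conditions used by the tests: 1 Hz sampling, zero noise,
walking and running legs between 4 and 17.4 km/h on slopes within ±10%, and
multi-leg courses of a few hundred seconds per leg (minutes-scale problems
keep the whole suite in seconds while exercising every branch of the model).

## Known limitations

* The METs and gradient-cost coefficients are taken as published; the
  package does not refit them from the underlying compendium/treadmill
  tables.
* The gradient-cost multiplier is speed-independent by construction; at
  extreme combinations (fast downhill) this is a modelling simplification.
* Validation statistics embedded here come from ten participants on one
  5-km course; they characterise that study, not every population.
* Anaerobic components (e.g. excess post-exercise oxygen consumption) are
  outside the model: estimates are aerobic steady-state costs.
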