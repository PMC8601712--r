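---
title: "Flight-altitude dynamics from multisensor biologgers: methods"
author: "nightflight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flight-altitude dynamics from multisensor biologgers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightflight)
```

## The measurement problem

Small nocturnal migrants such as European nightjars cannot carry GPS tags
with high-rate altimetry. The multisensor loggers this package targets
record two coarse streams every five minutes: an accelerometer *activity
score* (the number of 100-ms sub-measurements registering movement, 0-10
on pre-2018 loggers, 0-5 on later ones) and barometric pressure from a
sensor with an absolute accuracy of about one hectopascal. Daily positions
come separately from light-level geolocation and are only approximate.
Everything the pipeline infers - when a bird was flying, at what altitude,
how its altitude varied, whether it explored other strata, how it climbed
and descended - must come from these two coarse streams.

## Barometric altimetry

Pressure is converted to altitude with the hypsometric formula for a
standard atmosphere with a linear temperature lapse,

$$h = \frac{T_0}{L}\left(1 - \left(\frac{P}{P_0}\right)^{R_0 L / g}\right),$$

with sea-level temperature $T_0 = 288.15$ K, lapse rate $L = 0.0065$
K m$^{-1}$, sea-level pressure $P_0 = 1013.25$ hPa, $g = 9.8$ m s$^{-2}$
and the specific gas constant of air $R_0 = 287.058$ J kg$^{-1}$ K$^{-1}$
(`atmosphere_constants()`). The conversion is strictly decreasing in $P$
and has the exact algebraic inverse `altitude_to_pressure()`, which the
synthetic generator uses, so the round trip is exact to floating-point
precision. Weather-induced deviations from the standard atmosphere bias
absolute altitudes; within-flight *changes* over minutes to hours, which
almost all downstream statistics use, are far less affected.

Propagating the sensor's $\pm 1$ hPa accuracy bound through the formula
moves altitude by about 8.3 m at sea level, growing to about 13.9 m at
5000 m as the air thins. Five-minute altitude *differences* therefore
carry noise well under the 30 m near-level threshold, which is what makes
the interval classification below workable.

Descent extraction and the vertical-displacement metrics run on a
three-point centred rolling mean of the altitude series
(`rolling_mean3()`); a brief pressure blip or updraft then no longer
splits a descent in two. At the two endpoints the mean of the two
available samples is used so the smoothed series keeps its length and
sample counts remain comparable. Near-level classification, in contrast,
uses the raw series: its definition is the change from the preceding
record, not a property of a smoothed path. Both bases are switchable in
`pipeline_config()` (`level_basis`, `dz_basis`).

## Flight segmentation from activity

A 5-min sample indicates sustained flapping when its duty cycle
(score divided by the scale maximum) reaches 0.6 - score 6 of 10, or 3 of
5. The 0.6 fraction generalises the 11-grade rule to the 6-grade loggers
by preserving the fraction of active sub-measurements, since the
instrument semantics (5 or 10 sub-measurements per sample) are otherwise
identical. A UTC clock-hour with at least 7 of its 12 samples at flight
level is a *core hour*; maximal runs of consecutive core hours form the
core of a flight episode; and the episode is extended by 300 s for every
flight-level sample in the single hour on each side. Episodes strictly
longer than 3 h (roughly 100 km of nocturnal travel) are *migratory*;
shorter ones are kept as *short flights* because terminated exploratory
movements live there. All qualifying samples in the adjacent hour count
towards the extension whether or not they touch the core
(`contiguous_precore = FALSE` by default); the contiguous variant is a
config flag. Because an hour adjacent to a core run can hold at most six
qualifying samples, extensions from neighbouring episodes can touch but
never overlap.

The 5-min registration stream is taken as the operational unit throughout;
hourly activity histograms stored by some logger generations are
derivable from it but are not consumed.

Episodes are stratified by latitude band - above 38°N Europe, 8-38°N the
Mediterranean/Sahara passage, below 8°N sub-Saharan Africa - using the
daily latitude nearest in time to the episode midpoint, and by season.
Season defaults to the calendar rule (July-December autumn, January-June
spring), which matches the migration phenology of this system; a
latitude-trajectory rule (net southbound movement over the surrounding
week = autumn) is available and falls back to the calendar when positions
are missing or the bird is stationary.

## Altitude variation within flights

Three per-episode statistics summarise vertical dynamics:

* **Near-level fraction.** Each 5-min interval is *level* when its
  absolute altitude change is strictly below 30 m (mean vertical speed
  under 0.1 m s$^{-1}$), *large* at 300 m or more (at least 1 m
  s$^{-1}$), *intermediate* between. The three counts partition the
  intervals exactly. 30 m exactly is intermediate ("lower than 30 m" is
  strict).
* **Mean vertical speed**: the mean of $|\Delta z|/\Delta t$ over
  intervals. The absolute value matters - a signed mean telescopes to
  near zero on any out-and-back profile and would hide exactly the
  behaviour of interest.
* **Vertical tortuosity**: the number of shifts between ascent and
  descent divided by the number of altitude recordings minus one; 0 for a
  monotone profile, approaching 1 for a maximal zigzag. A level interval
  carries the previous direction, so a staircase climb counts its turns
  rather than its plateaus; this zero-carry rule is shared with the run
  decomposition that defines event legs, so "one displacement" means the
  same thing everywhere. The denominator is taken literally as $N - 1$
  even though the attainable maximum is $(N-2)/(N-1)$; no renormalisation
  is applied.

Because a long initial climb and final descent dominate these statistics,
each is also computed on the *presumed cruising phase*: the series with
the initial and terminal maximal stretch of constant non-zero direction
removed. A plateau ends such a stretch - trimming a
climb-plateau-descent profile keeps the plateau - and profiles that are
one monotone sweep are flagged untrimmable rather than reduced to
nothing.

## Exploratory movements, ascents, descents

A *terminated exploratory flight* is a short flight whose smoothed
profile decomposes into exactly one ascent run directly followed by one
descent run, with a climb of at least 500 m and a flight-wide mean
absolute vertical rate above 0.1 m s$^{-1}$: the bird climbs to sample
conditions aloft and lands. The displacement minimum applies to the
ascent leg by default (`terminated_leg_rule = "ascent"`); accepting
either leg is a config choice. *Mid-flight* exploratory movements are two
adjacent opposite-direction runs of at least 500 m each, at per-leg mean
rates above 0.1 m s$^{-1}$, embedded in a migratory flight; the run
holding the flight's first climb and the run holding its landing descent
are excluded, overlapping candidates are resolved greedily left to right,
and descent-first profiles are recorded as such.

*Maximum ascent rates* are taken over 5- and 20-min windows as the
largest net altitude gain achievable inside one window, divided by the
window length - operationally, the maximum over sample pairs lying no
further apart than the window. A series shorter than the window still
fits inside a single window and yields a value; only a single-sample
series does not. For between-stratum comparisons an episode enters the
ascent analysis only when its total climb exceeds what a bird climbing at
the theoretical maximum (1.16 m s$^{-1}$, below) would cover in one
window, so short flights cannot drag the distribution down.

*Descents* are maximal runs of non-increasing smoothed altitude with net
height loss that follow flight-level activity, lasting at least 10 min.
Level intervals inside a run are tolerated (`descent_monotone =
"strict"` disallows them) but stripped from its edges. The first and last
record of each run are dropped before the rate is computed, since they
can include time cruising or on the ground; the trimmed rate therefore
needs at least four samples, so the shortest ratable descent spans 15 min
on the 5-min grid. A descent is a *glide* when the mean duty cycle over
the run falls below the flight-level threshold (0.6), mirroring the
segmentation rule, else *active*.

## Flight-mechanics benchmarks

The observational statistics are compared against a classical
fixed-wing-theory power curve for flapping flight (induced + body
parasite + wing profile power; `power_curve()`, `flap_power()`) built on
the study population's mean biometrics: mass 0.0708 kg, wingspan 0.5747
m, wing area 0.04239 m$^2$. The induced-power factor (1.2), body drag
coefficient (0.1) and air density (1.225 kg m$^{-3}$) are textbook
values; the profile drag coefficient (0.0074) was set by calibrating the
curve's shape against published climb-rate estimates for this
morphology. The maximum sustainable climb rate is the power margin over
weight, $V_z(V) = (P_{max} - P(V))/(mg)$, and in the default calibrated
mode $P_{max}$ is solved so that $V_z(10) = 1.16$ m s$^{-1}$ exactly;
the curve then reproduces the published companion values at 8.65 and
7.02 m s$^{-1}$ (1.29 and 1.35 m s$^{-1}$) to within a few hundredths.
The glide polar is summarised by its best glide ratio, 11 for a
nightjar, giving a sink rate of $-V/(L/D) = -0.91$ m s$^{-1}$ at 10 m
s$^{-1}$ forward speed.

`exploratory_cot_penalty()` prices a to-and-fro vertical excursion
embedded in a level journey of fixed horizontal distance. The climb leg
flies the cruise airspeed along a slanted path and costs $P(V) + mgV_z$.
A gliding descent consumes only a gliding fuel rate while covering
ground at the polar's slope; an active descent keeps flapping at a
shallow sink rate, with a fraction of the potential-energy release
offsetting required power (floored at a configurable minimum). Scenario
defaults describe the study system - journey 108 km (the shortest
migratory flight, 3 h at 10 m s$^{-1}$), excursion 500 m (the
exploratory threshold), climb rate 1 m s$^{-1}$, active-descent rate 0.3
m s$^{-1}$ (the observed median glide-descent magnitude) - and the two
free bookkeeping constants (gliding fuel rate 0.306 W
mechanical-equivalent, roughly 2.8 times basal metabolism after muscle
efficiency; recovery efficiency 0.84) were calibrated once so the
penalties match published estimates for this morphology: about 7.9% for
a gliding descent and 1.4% for an active one. The qualitative result -
descending under power while recovering potential energy as thrust is
*cheaper* than gliding, because gliding sacrifices powered progress time
while still paying a metabolic rate - is robust across a wide band of
these constants; the exact percentages are not, which is why both are
plain config arguments.

## Group comparisons

Season-by-region contrasts are fitted as linear mixed models with the
metric as response, season and region (and their interaction, when both
vary) as fixed effects and a per-bird random intercept (`lme4`/
`lmerTest` via `compare_groups()`), with estimated marginal means and
95% confidence intervals from `emmeans`. Pairwise differences are
Tukey-adjusted, and compact letter displays are derived from the
resulting decision matrix with the insert-and-absorb algorithm: groups
sharing no letter differ at the chosen level (default $\alpha = 0.05$);
no additional correction is applied across responses. Designs that
cannot support a random intercept (a single bird) fall back to a
fixed-effects model with a logged warning, and a response with zero
variance yields a single shared letter rather than an error. The paired
seasonal test (`paired_seasonal_test()`) is a two-sided paired t-test on
per-bird spring-minus-autumn values with $n-1$ degrees of freedom; a
zero-variance non-zero difference reports a signed infinite statistic
flagged degenerate instead of `NaN`.

## The synthetic generator, and what passing tests mean

`generate_dataset()` emulates the instrument, not the bird: true
altitude is a piecewise-linear path assembled from constant-rate flight
phases over flat terrain (flights start and end at a configurable ground
elevation), sampled on the 5-min grid, pushed through the inverse
hypsometric formula and perturbed with Gaussian pressure noise (s.d.
0.5 hPa by default, treating the $\pm 1$ hPa accuracy bound as a
two-sigma envelope). Activity scores are Binomial(scale, duty) draws per
sample - duty 0.95 in flapping flight, 0.02 at rest by default - with an
optional dropout fraction forced to zero. Output is bit-reproducible
under a fixed seed, and every generated flight comes with ground truth
(boundaries, phase table, noiseless series and its metrics).

What the generator does *not* emulate bounds what green tests can show:
real flights have autocorrelated wind-driven altitude drift rather than
crisp constant-rate legs, pressure varies synoptically under a
non-standard atmosphere, terrain is not flat, activity dropout is not
independent across samples, and birds land and relaunch in ways no phase
table plans. Parameter-recovery results (level fractions within
$\pm 0.05$, planted-event precision and recall of 1, episode recall
above 0.9 under 10% dropout) therefore certify the *algorithms* against
the instrument model, not the field error rates of the study system.

Test problem sizes were chosen to exercise every code path while keeping
the default suite in the tens of seconds: 1000 random series for the
tortuosity oracle equivalence, 100 for the windowed-ascent oracle, 50
planted flights for the event-detection suite, single-night scenarios
elsewhere.

## Numerical and degenerate-input choices

* Rolling-mean endpoints: two-point means, preserving series length.
* Zero displacements: carry the previous direction in tortuosity and run
  decomposition; break the monotone stretch in cruise trimming (so
  plateaus survive trimming); are tolerated inside but stripped from the
  edges of descent runs.
* Ties at class boundaries: 30 m is intermediate, 300 m is large
  (strict "lower than", inclusive "or more").
* An all-level series has tortuosity 0; tortuosity needs three samples;
  displacement needs two; trimming needs four.
* Episodes with fewer than four altitude samples are skipped by the
  metrics stage with a logged warning rather than producing NaNs.
* Latitude missing at an episode's midpoint labels its region `unknown`;
  such episodes are excluded from regional comparisons but retained
  everywhere else.
* All timestamps are UTC on a 300-s grid; gaps are represented as absent
  rows and flagged, never as `NaN` rows.

## Known limitations

Absolute altitudes inherit standard-atmosphere bias; above-ground-level
comparisons would need a terrain model and are out of scope. The
flight-mechanics module is a benchmark family with calibrated constants,
not a wind-tunnel-grade aerodynamic model, and the cost-of-transport
percentages are only as sharp as the published calibration points.
Horizontal movement is invisible at this sampling scheme, so airspeeds,
ground speeds and horizontal tortuosity cannot be estimated. Wind is not
modelled anywhere; occasional 5-min climb rates above the theoretical
maximum are expected under thermal support and are reported, not
corrected.
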