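---
title: "Modelling set-point landing control from optical expansion rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling set-point landing control from optical expansion rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeland)
```

## The scientific problem

A flying insect approaching a vertical surface perceives an expanding
optical flow field. The relative rate of expansion

$$r(t) = \frac{V(t)}{y(t)}$$

— approach velocity over perpendicular distance, the inverse of the
time-to-contact $\tau$ — is available directly from vision, without any
explicit estimate of distance or speed. Holding $r$ constant produces
exponential deceleration toward the surface and a soft touchdown.
Bumblebees, however, do not hold a single $r$: they fly at a constant
set-point $r^*$ only briefly, then switch stepwise to a new, usually
higher, set-point. Each switch triggers a *transient*: an interval in
which $r$ rises (or occasionally falls) monotonically toward the new
set-point, during which the animal mostly accelerates toward the surface.

beeland implements the full analysis of such manoeuvres: state estimation
from 3-D tracks, detection of constant-$r$ segments and the transient
"entry" segments preceding them, identification of the closed-loop
dynamics that map the set-point input to the observed expansion rate,
characterisation of transients as motion at constant
expansion-acceleration $\dot{r}$, and the statistical models that relate
$\dot{r}$ and the mean acceleration $\bar{A}_e$ to the flight and
lighting conditions. A closed-loop simulator generates synthetic cohorts
with full ground truth, so every stage can be validated end to end.

## State estimation

Raw tracks are sampled at 175 Hz in a platform-centred frame ($y$ normal
to the surface, pointing into the arena). Positions are filtered with a
zero-phase (forward–backward) second-order Butterworth low-pass at 20 Hz;
the forward–backward pass squares the magnitude response and cancels the
phase. We implement the pass directly (odd-reflection padding of three
filter lengths, steady-state initial conditions) so that constant signals
pass through bit-exactly; `signal::butter` supplies the coefficients.
Velocities and accelerations come from second-order central differences
(one-sided second-order stencils at the ends), with $A$ differentiated
from $V$ so the two stay mutually consistent. Time is aligned so $t = 0$
at the sample of closest approach, ties broken to the latest sample.

Two algebraic identities tie the states together and are used as internal
cross-checks:

$$\dot{r} = \frac{y A + V^2}{y^2}, \qquad A = \dot{r}\,y - \frac{V^2}{y}.$$

Samples with $y \le 5$ mm are excluded: $r$ diverges at contact, and all
segment analyses operate away from the surface. Whether near-contact
samples were excluded before computing $r$ in the original analyses is
not stated; the clip threshold is this package's choice and matches the
simulator's touchdown floor. The segment analysis consumes the final
approach only — the last contiguous stretch of approach flight ending at
touchdown, where "receding" requires $V < -0.02$ m/s so that noise-driven
sign flips of the near-zero touchdown velocity do not truncate the
approach.

## Constant-r segment detection

The detector asks where $r(t)$ is *statistically constant*, governed by a
threshold factor $f$ (default 1.5, the smallest value found to give
robust results in this setting; a sweep utility covers
$f \in [0.25, 2.5]$). The full reference detector is published separately
by the original study group; `detect_constant_r()` is this package's own
operationalisation of the published criterion — six windowed
linear-regression statistics, each limited to $f$ scale parameters of a
t-distribution — and is exposed behind a plain interface so an external
detector can be substituted for exact replication.

Concretely, candidate windows (lengths 0.10–0.19 s, every starting
sample) are regressed on time, and a window is accepted when:

* its slope lies within $f$ slope-standard-errors of zero (the slope's
  sampling distribution is Student-t with that scale), **and** its net
  drift across the window is below $f \times 2\%$ of its level — the SE
  criterion alone goes blind where measurement noise in $r$ inflates
  close to the platform;
* its residual scale, slope SE, level SE and lag-1 residual
  autocorrelation each lie within $f$ scale parameters of a robust
  t-distribution (df = 4) location/scale fit to that statistic's
  distribution over all windows of the track — these statistics measure
  noise, which is homogeneous along a track, so excursions flag
  transient motion.

Accepted windows are merged into covered runs; runs are split where
consecutive accepted windows disagree in level by more than $f$ joint
scale parameters, gaps shorter than 0.05 s between level-consistent runs
are closed, and runs shorter than 0.1 s are dropped. Each surviving
segment is summarised by its mean states $(y^*, V^*, A^*, r^*)$. Window
lengths are deliberately kept short: windows much longer than the minimum
duration straddle brief transients, dilute their slope below the
acceptance bounds, and can bridge two distinct set-points into one
segment.

All scale-type thresholds scale with $f$, so coverage grows monotonically
with $f$ — small-$f$ detections are always contained in large-$f$
detections on the same track. With exactly constant (noise-free) input
the fitted scales collapse to a floor of $10^{-12}$ and only exact
plateau windows are accepted.

## Entry segments

For each constant-$r$ segment we look for a monotonic run of the
5 Hz-filtered $r$ immediately before it (tolerance 0.02 s$^{-1}$ per
step, minimum 5 samples), bounded by the end of the preceding segment.
The entry starts where that monotonic variation starts or — for
increasing runs beginning below 0.5 s$^{-1}$ — at the upward crossing of
$r = 0.5$ s$^{-1}$, whichever is later; it ends at the sample before the
constant-$r$ segment. Whether the 0.5 s$^{-1}$ rule also applies to
decreasing entries is not specified in the source analyses; we apply it
to increasing runs only. Two refinements are needed to make onset
detection robust: the direction of variation is read from the sign of
$r^*$ minus the filtered $r$ well before the segment (about 0.5 s), not
from a local difference, because the filtered signal immediately before a
segment lies in its flat settling zone; and a flat lead-in is trimmed
from the onset — variation has not started while the per-sample step
stays below half the run's mean step, capped at 20% of the run's total
change so a slow homogeneous rise is never eaten.

## Closed-loop system identification

For each linked (entry, constant-$r$) pair, the raw $r$ over both
segments is concatenated ($r_c$), low-pass filtered at 5 Hz ($r_f$), and
treated as the output of a dynamic system whose input is the constant
set-point signal $r^*(t)$. Candidate models are transfer functions of
orders 1–3 with unity-DC-gain-times-$K$ structure; the order-2 form is

$$\frac{r_f(s)}{r^*(s)} = \frac{K\,\omega^2}{s^2 + 2 D \omega s + \omega^2}$$

with gain $K$, damping ratio $D$ and natural frequency $\omega$. Because
the input is constant, frequency-domain excitation is degenerate, so
identification is done in the time domain: the model is simulated exactly
(eigendecomposition of the companion matrix; a Runge–Kutta fallback
covers defective cases) and the quadratic prediction error
$\sum (r_f - r_s)^2$ is minimised jointly over the parameters (log scale)
and the free initial state, initialised from $r_f(0)$ and its finite
difference. Eight deterministic starts on a Latin-style grid over
$K \in [0.5, 1.5]$, $D \in [0.2, 2]$, $\omega \in [2, 50]$ rad/s plus one
data-driven start guard against the local minima that step-response
identification is prone to; the winning start is polished with BFGS. Fits
are scored with the fit percentage

$$F = 100\left(1 - \frac{\lVert r_f - r_s \rVert}{\lVert r_f - \mathrm{mean}(r_f) \rVert}\right),$$

100 for a perfect fit, 0 for a model no better than the signal mean.
Identified parameter values are deliberately not interpreted — several
parameter combinations approximate the same low-frequency dynamics — and
cohort comparisons use $F$ only.

## Transients as constant expansion-acceleration

Within an entry segment the expansion rate is modelled as
$r(t) = \dot{r}_e t + c + \varepsilon$, fitted by ordinary least squares;
$R^2$ is defined as 0 when the total sum of squares vanishes. Motion at
constant $\dot{r}$ has the closed form

$$y(t) = y_0 \exp\!\left(-(r_0 t + \tfrac{1}{2}\dot{r} t^2)\right),$$

with $V = r y$ and $A = \dot{r} y - V^2/y$; the package exposes both this
closed form and a numerical ODE route (deSolve) as a cross-check. Three
summary quantities are computed per entry: the distance discrepancy
$\Delta d$ (actual minus model flight distance, positive when the animal
covered more distance than the constant-$\dot{r}$ model; the model's
$r_0$ is the regression line at the segment's first timestamp, for noise
robustness), the mean acceleration $\bar{A}_e = \Delta V / \Delta t$, and
the Pearson correlation between the model-trajectory acceleration
$A_e(t)$ and the instantaneous set-point error $r^* - r(t)$. The
model-trajectory acceleration is used in the correlation because
double-differentiated measured acceleration is noisy; the sign convention
for $\Delta d$ is fixed here since the source analyses report a signed
median without defining the sign.

## Statistical models

The expansion-accelerations of increasing entries are summarised by a
maximum-likelihood gamma fit (shape $a$, scale $b$, location fixed at 0)
with asymptotic 95% confidence intervals; fitting is done on
mean-standardised data, which conditions the optimisation and makes the
fit scale-equivariant by construction.

The two mixed-effects models regress $\log \dot{r}_e$ and
$\log \bar{A}_e$ (natural logarithms) on fixed effects $\log y_0$, light
condition (treatment-coded against twilight), landing type (against free
flight), $\log \Delta r_e$, $\log r^*$ and the
$\log y_0 \times \log \Delta r_e$ interaction, with random intercepts for
experimental day, approach number and landing side (crossed; the exact
nesting used originally is not stated, so the grouping is documented
here and kept simple). Estimation is REML via lme4. p-values are
large-sample normal approximations — degrees-of-freedom refinements are
out of scope by design. Singular random-effect factors are dropped with a
warning. Entries with negative $\Delta r_e$ are excluded from both models
by default, and the $\bar{A}_e$ model additionally keeps only entries
with positive mean acceleration. Estimated means at covariate settings
are computed from the fixed-effect linear combination (random intercepts
at their zero population mean) with delta-method intervals exponentiated
back to the response scale; pairwise light contrasts are
Bonferroni-adjusted over their family of 3, the landing-type contrast
over a family of 1.

## The synthetic-data generator

`simulate_landing()` integrates the hypothesized closed loop: the
expansion rate follows second-order dynamics toward the current set-point
($\ddot{r} = \omega^2 (K r^* - r) - 2 D \omega \dot{r}$) while position
follows the kinematic coupling $\mathrm{d}y/\mathrm{d}t = -r y$, at a
1 ms internal step with classical fourth-order (RK4) integration,
resampled to 175 Hz. Defaults, chosen once to emulate the study's
conditions:

* set-point schedule: first set-point lognormal with median 1.5 s$^{-1}$,
  multiplicative steps $\times U(1.3, 2.0)$, 2–4 set-points per landing —
  stepwise and mostly increasing;
* switching: a set-point counts as reached when
  $|r - r^*| < 0.05\,r^*$; after holding it for a dwell time
  $\sim U(0.15, 0.4)$ s the next set-point becomes active;
* controller: $K = 1$, $D \sim U(0.8, 1.05)$ (near-critically damped,
  so filtered transients are monotone), $\omega$ lognormal with median
  18 rad/s, per track;
* start: $y_0$ lognormal with median 0.4 m, initial
  $r \sim U(0.15, 0.35)$ s$^{-1}$ (below the 0.5 s$^{-1}$ entry-start
  threshold, as real approaches begin slowly);
* noise: white position noise of 0.5 mm added before filtering —
  sub-millimetre tracking-noise scale typical of laboratory videography —
  plus small smooth lateral ($x$, $z$) drift;
* condition effects: the controller natural frequency is scaled
  $\times 1.04$ under medium light, $\times 1.10$ under sunrise and
  $\times 0.97$ after take-off, mirroring the ~9–10% light and ~3%
  landing-type effects the method is meant to detect; day, landing-side
  and approach-number multipliers (log-SDs 0.05, 0.02, 0.03) induce the
  random-intercept structure;
* termination at $y \le 5$ mm.

Ground truth records every set-point, switch time, per-transient
$(r_0, y_0, \Delta r_e)$ and controller parameters. The per-transient
reference slope `rdot_true_eff` is the OLS slope of the *noise-free*
$r(t)$ over the transient window that the entry-start rule defines (from
the upward 0.5 s$^{-1}$ crossing where applicable, else from the switch,
to the first reach of the set-point band): the same functional the
pipeline estimates, evaluated on the clean signal, so that
estimator-vs-truth comparisons isolate noise and detection error from
the S-shape of the true transient.

What the generator does *not* emulate: wingbeat-scale oscillations of
$r$ around its mean variation, heteroscedastic tracking error from the
camera geometry, aborted or re-targeted approaches (set-points the animal
never reaches), body-orientation dynamics, and any aerodynamics. Passing
the synthetic round-trip therefore shows that the pipeline recovers the
parameters of the hypothesized control structure under realistic
sampling and noise — not that real bumblebee data are free of the above
complications.

## Numerical and design choices, in brief

* Zero-phase filtering rejects signals shorter than 19 samples; such
  tracks are skipped with a warning at cohort level rather than aborting.
* The t location/scale fits in the detector use fixed df = 4; scales are
  floored at $10^{-12}$.
* The touchdown tie-break takes the latest minimum (the final approach
  terminates the manoeuvre).
* `simulate_tf` perturbs nothing: repeated eigenvalues fall back to an
  RK4 path rather than jittered parameters.
* Identification refuses spans under 0.15 s; the multi-start loop stops
  early once a fit exceeds F = 99.9.
* The gamma CIs are asymptotic (normal) rather than profile: at the
  sample sizes involved (thousands) the difference is negligible.
* Problem sizes in the shipped tests are scaled to desk size: cohorts of
  12–96 tracks, 20 seeded replicates for calibration checks, 100
  replicates for the noisy identification benchmark. The headline
  full-dataset counts of the original study (about ten thousand
  manoeuvres) additionally require its archived raw data and its exact
  reference detector, and are out of scope here.

## Known limitations

* The constant-$r$ detector is an operationalisation, not the reference
  implementation; on identical data the two can disagree at segment
  boundaries, so absolute segment counts are detector-specific even
  though set-point values and transient parameters are robust.
* Set-points the animal never reaches are, by construction, invisible to
  both the detector and the entry extraction.
* The entry-boundary accuracy degrades near touchdown, where measurement
  noise in $r$ grows as $1/y$; late, high-$r$ transients carry the
  largest estimation errors.
* p-values and interval estimates use large-sample approximations
  throughout.
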