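# beeland

Analysis of visually guided landing manoeuvres from 3-D flight
trajectories, for researchers in insect sensorimotor control and
movement biomechanics.

A flying insect closing in on a surface can read the **relative rate of
optical expansion** r = V/y (approach velocity over perpendicular
distance; the inverse of the time-to-contact τ) directly from optic
flow. Flying at constant r yields exponential deceleration and a soft
touchdown — but bumblebees hold a given set-point r\* only briefly and
switch stepwise to new, usually higher, set-points as they approach.
Each switch opens a transient **entry segment** in which r varies
monotonically toward the new set-point and the animal mostly
*accelerates* toward the surface.

beeland implements the complete analysis chain for such data:

* **trajectory I/O and preprocessing** — canonical long-format CSV (or
  Feather), zero-phase 20 Hz Butterworth filtering, touchdown time
  alignment (`read_tracks`, `lowpass_track`, `align_touchdown`);
* **state estimation** — y, V, A and r = V/y by second-order finite
  differences, with the identity ṙ = (yA + V²)/y² as a cross-check
  (`compute_states`, `expansion_accel_identity`);
* **segmentation** — detection of statistically constant-r (set-point)
  segments under a threshold factor f, and extraction of the preceding
  monotonic entry segments with the r = 0.5 s⁻¹ start rule
  (`detect_constant_r`, `extract_entry_segment`, `sweep_f`);
* **closed-loop system identification** — transfer functions of order
  1–3 (order 2: K·w² / (s² + 2Dws + w²)) fitted in the time domain to
  the 5 Hz-filtered step response, scored by the fit percentage
  F = 100·(1 − ‖r_f − r_s‖/‖r_f − mean(r_f)‖)
  (`identify_tf`, `simulate_tf`, `fit_percentage`, `compare_orders`);
* **transient characterisation** — each entry as motion at constant
  expansion-acceleration ṙ, via the regression r(t) = ṙt + c + ε and
  the closed form y(t) = y₀·exp(−(r₀t + ṙt²/2)); distance discrepancy,
  mean acceleration ΔV/Δt, and the acceleration–error correlation
  (`fit_constant_rdot`, `simulate_constant_rdot`, `characterize_entry`);
* **statistics** — gamma fit to the expansion-accelerations and the two
  linear mixed-effects models
  log(M) ~ log(y₀) + light + landing type + log(Δr_e) + log(r\*) +
  log(y₀)×log(Δr_e) + (1|day) + (1|approach) + (1|side)
  for M ∈ {ṙ_e, Ā_e}, with estimated means and Bonferroni post-hoc
  contrasts (`fit_gamma`, `fit_lmm`, `predict_emm`,
  `condition_contrasts`);
* **a closed-loop landing simulator** with full ground truth
  (`simulate_landing`, `simulate_cohort`) and a pipeline orchestrator
  with a reproducible run manifest (`run_pipeline`).

The methods vignette (`vignettes/landing-control.Rmd`) documents the
model, every tunable parameter, the detector's operationalisation and
the simulator's scope.

## Worked example

Simulate a small cohort from the hypothesized r-based control loop,
run the segment pipeline on one track, and fit the cohort statistics:

```r
library(beeland)

cfg    <- generator_config(n_tracks = 24, seed = 7)
cohort <- simulate_cohort(cfg)

res <- analyze_track(cohort$tracks[[1]])
res$segments[, c("idx_start", "idx_end", "r_star", "y_star", "V_star")]
#>   idx_start idx_end r_star y_star V_star
#> 1        38      97   1.72 0.2114  0.362
#> 2       124     219   3.05 0.0517  0.158
```

The first track holds two set-points: r\* ≈ 1.7 s⁻¹ at about 21 cm from
the platform, then r\* ≈ 3.1 s⁻¹ at about 5 cm. Its entry segments:

```r
res$table[, c("y0", "r0", "r_star", "delta_re", "rdot_e", "R2", "Ae_mean")]
#>      y0    r0 r_star delta_re rdot_e    R2 Ae_mean
#> 1 0.344 0.508   1.72     1.21   7.12 0.919  1.5699
#> 2 0.156 1.975   3.05     1.07   6.47 0.833 -0.0485
```

Both transients raise r by ~1.1–1.2 s⁻¹ at an expansion-acceleration of
~7 s⁻², well described by a straight line in r(t) (R² 0.83–0.92); during
the first the bee accelerates toward the platform at 1.6 m/s².
Cohort-level distribution of the positive expansion-accelerations:

```r
tab <- entries_table(cohort$tracks)   # 51 entries from 24 tracks
fit_gamma(tab$rdot_e[tab$delta_re > 0 & tab$rdot_e > 0])
#> <gamma_fit> shape a = 3.759 [2.360, 5.158], scale b = 1.885 [1.134, 2.636]
#>   n = 51, sample median = 5.944
```

Closed-loop identification of the first (entry, constant-r) pair:

```r
inp <- build_sysid_input(res$states, res$entries[[1]],
                         res$segments[res$entries[[1]]$seg_index, ])
identify_tf(inp, order = 2)
#> <tf_fit> order 2 F = 90.41%
#>   params: K = 1.02, D = 1.029, w = 21.66
```

A second-order model with near-unity gain reproduces 90% of the
variation of the filtered expansion rate — the signature of a
sensorimotor loop regulating r toward its set-point.

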