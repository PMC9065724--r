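test_that("the expansion-acceleration regression recovers exact and noisy
           linear variation", {
  t <- seq(0, 0.4, by = 1 / FS)
  fit <- fit_constant_rdot(10 * t + 0.5, t)
  expect_equal(fit$rdot_e, 10, tolerance = 1e-10)
  expect_equal(fit$c, 0.5, tolerance = 1e-10)
  expect_equal(fit$R2, 1)

  set.seed(5)
  tn <- seq(0, by = 1 / FS, length.out = 100)
  r <- 8 * tn + 1 + rnorm(100, 0, 0.05)
  fitn <- fit_constant_rdot(r, tn)
  se <- 0.05 / sqrt(sum((tn - mean(tn))^2))
  expect_lt(abs(fitn$rdot_e - 8), 3 * se)

  fit0 <- fit_constant_rdot(rep(2, 10), tn[1:10])
  expect_equal(fit0$rdot_e, 0, tolerance = 1e-12)
  expect_equal(fit0$R2, 0)
  expect_error(fit_constant_rdot(c(1, 2), c(0, 1)), "3 samples")
})

test_that("constant-rdot motion has the closed form
           y = y0 exp(-(r0 t + rdot t^2/2))", {
  # constant-r limit: exponential distance decay
  sim0 <- simulate_constant_rdot(0.3, 2, 0, 0.5)
  expect_lt(max(abs(sim0$y - 0.3 * exp(-2 * sim0$t))), 1e-12)
  expect_lt(max(abs(sim0$r - 2)), 1e-12)

  sim <- simulate_constant_rdot(0.3, 1, 10, 0.2)
  y_end <- 0.3 * exp(-(1 * 0.2 + 10 * 0.2^2 / 2))
  expect_equal(sim$y[nrow(sim)], y_end, tolerance = 1e-9)
  expect_equal(y_end, 0.2010, tolerance = 1e-3)

  # initial velocity from the set-point decomposition: V(t0) = (r* - dre) y0
  r_star <- 3; dre <- 2; y0 <- 0.25
  sim2 <- simulate_constant_rdot(y0, r_star - dre, 8, 0.1)
  expect_equal(sim2$V[1], (r_star - dre) * y0, tolerance = 1e-12)

  # closed form against the numerical ODE route
  sim_ode <- simulate_constant_rdot(0.3, 1, 10, 0.2, method = "ode")
  expect_lt(max(abs(sim$y - sim_ode$y)), 1e-8)

  # clip-floor truncation is flagged
  sim3 <- simulate_constant_rdot(0.05, 3, 20, 1.5)
  expect_true(attr(sim3, "truncated"))
  expect_true(all(sim3$y > 0.005))
})

test_that("distance discrepancy vanishes for exact constant-rdot motion and
           stays bounded under bounded oscillation", {
  sim <- simulate_constant_rdot(0.35, 0.8, 12, 0.3)
  fit <- fit_constant_rdot(sim$r, sim$t)
  expect_lt(abs(distance_discrepancy(sim, fit)), 1e-9)

  osc <- sim
  osc$y <- osc$y + 0.002 * sin(2 * pi * 10 * osc$t)
  osc$r <- osc$V / osc$y
  fit2 <- fit_constant_rdot(osc$r, osc$t)
  expect_lte(abs(distance_discrepancy(osc, fit2)), 0.004)
})

test_that("mean acceleration is the net velocity change per unit time", {
  es <- data.frame(t = c(0, 0.15, 0.3), V = c(0.2, 0.4, 0.5))
  expect_equal(mean_acceleration(es), 1.0)
  es_dec <- data.frame(t = c(0, 0.1, 0.2), V = c(0.5, 0.4, 0.3))
  expect_lt(mean_acceleration(es_dec), 0)
  expect_error(mean_acceleration(data.frame(t = c(0, 0), V = c(1, 1))),
               "zero-duration")
})

test_that("decreasing entries always decelerate on noiseless data", {
  # falling r: the animal must shed approach speed faster than distance
  for (dre in c(-0.5, -1.5, -2.5)) {
    r0 <- 4; rdot <- 5 * dre
    sim <- simulate_constant_rdot(0.2, r0, rdot, abs(dre) / abs(rdot))
    expect_lt(mean_acceleration(sim), 0)
  }
})

test_that("model acceleration correlates with the set-point error on
           noiseless increasing entries and is undefined at steady state", {
  sim <- simulate_constant_rdot(0.3, 0.8, 10, 0.25)
  fit <- fit_constant_rdot(sim$r, sim$t)
  r_star <- sim$r[nrow(sim)]
  expect_gt(accel_error_correlation(sim, r_star, fit), 0.99)

  flat <- simulate_constant_rdot(0.3, 2, 0, 0.2)
  fitf <- fit_constant_rdot(flat$r, flat$t)
  expect_warning(out <- accel_error_correlation(flat, 2, fitf), "zero variance")
  expect_true(is.na(out))
})

test_that("entry characterisation bundles regression, discrepancy and
           correlation with the right signs", {
  r <- piecewise_r(c(0.2, 2.4, 70), c(2.4, 2.4, 100))
  st <- states_from_r(r)
  segs <- detect_constant_r(st)
  ent <- extract_entry_segment(st, segs[1, ])
  ch <- characterize_entry(st, ent)
  expect_s3_class(ch, "transient_characterization")
  expect_equal(sign(ch$rdot_e), sign(ent$delta_re))
  expect_gt(ch$R2, 0.95)
  expect_true(abs(ch$corr_Ae_dr) <= 1)
  expect_gt(ch$corr_Ae_dr, 0.9)
})
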