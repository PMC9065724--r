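test_that("the fit percentage satisfies its defining identities", {
  r_f <- c(1, 2, 3)
  expect_identical(fit_percentage(r_f, r_f), 100)
  expect_equal(fit_percentage(r_f, rep(mean(r_f), 3)), 0)
  expect_equal(fit_percentage(r_f, c(1, 2, 4)), 100 * (1 - 1 / sqrt(2)))
  # shift invariance: adding the same constant to both signals leaves F
  set.seed(7)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(fit_percentage(a + 3.7, b + 3.7), fit_percentage(a, b),
               tolerance = 1e-9)
  expect_error(fit_percentage(rep(2, 10), rep(2, 10)), "constant")
  expect_error(fit_percentage(1:3, 1:4), "equal length")
})

test_that("5 Hz filtering preserves slow content and strips fast content", {
  t <- (0:299) / FS
  expect_lt(max(abs(lowpass_r(rep(2.5, 300)) - 2.5)), 1e-12)
  # 30 Hz tone: squared second-order response at the prewarped ratio
  y <- lowpass_r(2 + 0.3 * sin(2 * pi * 30 * t))
  mid <- 80:220
  amp <- (max(y[mid]) - min(y[mid])) / 2
  ratio <- tan(pi * 30 / FS) / tan(pi * 5 / FS)
  expect_lt(amp, 0.3 * 2 / (1 + ratio^4))   # generous factor-2 headroom
  # ramp + ripple: ramp preserved within 1% away from the edges
  ramp <- 1 + 2 * t
  yr <- lowpass_r(ramp + 0.1 * sin(2 * pi * 30 * t))
  expect_lt(max(abs(yr[mid] - ramp[mid]) / ramp[mid]), 0.01)
})

test_that("transfer-function simulation honours equilibrium, overshoot and
           final value", {
  t <- seq(0, 3, by = 1 / FS)
  # equilibrium start stays at the set-point
  rs <- simulate_tf(list(K = 1, D = 0.8, w = 12), r_star = 2, t,
                    init_state = c(2, 0), order = 2)
  expect_lt(max(abs(rs - 2)), 1e-9)
  # underdamped unit step: peak overshoot exp(-pi D / sqrt(1 - D^2))
  D <- 0.5
  rs2 <- simulate_tf(list(K = 1, D = D, w = 10), 1, t, c(0, 0), 2)
  overshoot <- exp(-pi * D / sqrt(1 - D^2))
  expect_equal(max(rs2) - 1, overshoot, tolerance = 2e-3)
  # final value K * r_star once t >> 1/(D w)
  t_long <- seq(0, 8, by = 1 / FS)
  rs3 <- simulate_tf(list(K = 1.3, D = 0.4, w = 8), 2, t_long, c(0.5, 1), 2)
  expect_lt(abs(rs3[length(rs3)] - 1.3 * 2), 1e-6)
  expect_error(simulate_tf(list(K = NaN, D = 1, w = 1), 1, t, c(0, 0), 2),
               "non-finite")
})

test_that("eigendecomposition simulation agrees with an independent ODE
           solution across orders", {
  t <- seq(0, 1, by = 1 / FS)
  cases <- list(list(order = 1, params = list(K = 1.1, tau = 0.12), init = 0.3),
                list(order = 2, params = list(K = 0.9, D = 0.6, w = 14),
                     init = c(0.3, -1)),
                list(order = 3, params = list(K = 1, D = 0.7, w = 11, tau = 0.05),
                     init = c(0.2, 0.5, 0)))
  for (cs in cases) {
    rs <- simulate_tf(cs$params, r_star = 2, t, cs$init, cs$order)
    ss <- beeland:::.tf_ss(cs$order, cs$params)
    sol <- deSolve::lsoda(cs$init, t, function(tt, x, p)
      list(as.vector(ss$A %*% x + ss$B * 2)), rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(rs - sol[, 2])), 1e-6)
  }
})

test_that("noiseless second-order responses are identified to high
           accuracy and first-order models underfit them", {
  t <- seq(0, 0.8, by = 1 / FS)
  for (cs in list(c(D = 0.3, w = 10), c(D = 1.2, w = 20))) {
    rs <- simulate_tf(list(K = 1, D = cs["D"], w = cs["w"]), 2, t, c(0.4, 0), 2)
    fit <- identify_tf(list(t = t, r_f = rs, r_star = 2), order = 2)
    expect_lt(abs(fit$params$K - 1), 1e-3)
    expect_lt(abs(fit$params$D - cs["D"]) / cs["D"], 1e-3)
    expect_lt(abs(fit$params$w - cs["w"]) / cs["w"], 1e-3)
    expect_gt(fit$F, 99.99)
  }
  # strongly underdamped response: order 1 cannot match order 2
  rs_ud <- simulate_tf(list(K = 1, D = 0.25, w = 15), 2, t, c(0.2, 0), 2)
  inp <- list(t = t, r_f = rs_ud, r_star = 2)
  expect_lt(identify_tf(inp, 1)$F, identify_tf(inp, 2)$F)
})

test_that("order comparison summarises cohorts and degenerate inputs", {
  empty <- compare_orders(list())
  expect_equal(nrow(empty$per_input), 0)
  expect_equal(nrow(empty$summary), 0)

  t <- seq(0, 0.7, by = 1 / FS)
  rs <- simulate_tf(list(K = 1, D = 0.5, w = 12), 2, t, c(0.3, 0), 2)
  one <- compare_orders(list(list(t = t, r_f = rs, r_star = 2)), orders = 2)
  expect_equal(one$summary$median_F, one$per_input$F)
  expect_equal(one$summary$n, 1)
})

test_that("identification refuses spans that are too short", {
  t <- seq(0, 0.1, by = 1 / FS)
  expect_error(identify_tf(list(t = t, r_f = sin(t), r_star = 1), 2),
               "span too short")
})

test_that("sysid inputs built from linked segments share one grid and a
           constant set-point input", {
  r <- piecewise_r(c(0.2, 2, 80), c(2, 2, 100))
  st <- states_from_r(r)
  segs <- detect_constant_r(st)
  ent <- extract_entry_segment(st, segs[1, ])
  inp <- build_sysid_input(st, ent, segs[1, ])
  expect_s3_class(inp, "sysid_input")
  expect_equal(length(inp$t), length(inp$r_f))
  expect_equal(length(inp$t), length(inp$r_c))
  expect_equal(inp$r_star, segs$r_star[1])
  expect_equal(inp$t, st$t[ent$idx_start:segs$idx_end[1]])
})
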