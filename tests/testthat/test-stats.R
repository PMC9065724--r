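test_that("gamma fits are consistent at large n and handle the
           exponential special case", {
  set.seed(21)
  x <- rgamma(50000, shape = 4.8, scale = 2.5)
  gf <- fit_gamma(x)
  expect_gt(gf$a, 4.7); expect_lt(gf$a, 4.9)
  expect_gt(gf$b, 2.45); expect_lt(gf$b, 2.55)
  expect_true(gf$ci_a[1] < gf$a && gf$a < gf$ci_a[2])
  expect_true(gf$ci_b[1] < gf$b && gf$b < gf$ci_b[2])

  set.seed(22)
  e <- rexp(5000, rate = 0.5)
  gfe <- fit_gamma(e)
  expect_true(gfe$ci_a[1] < 1 && 1 < gfe$ci_a[2])

  expect_error(fit_gamma(c(1, 2, -1, 3)), "indices: 3")
})

test_that("gamma MLE is scale-equivariant", {
  set.seed(23)
  x <- rgamma(3000, shape = 3, scale = 1.5)
  f1 <- fit_gamma(x)
  f2 <- fit_gamma(10 * x)
  # equal up to optimizer tolerance
  expect_equal(f2$a, f1$a, tolerance = 1e-6)
  expect_equal(f2$b, 10 * f1$b, tolerance = 1e-6)
})

# shared synthetic design for the mixed-model tests
make_lmm_design <- function(n, seed) {
  set.seed(seed)
  data.frame(
    y0 = exp(rnorm(n, log(0.21), 0.4)),
    delta_re = exp(rnorm(n, log(1.68), 0.4)),
    r_star = exp(rnorm(n, log(2.78), 0.3)),
    light = sample(c("twilight", "medium", "sunrise"), n, TRUE),
    landing_type = sample(c("free_flight", "after_takeoff"), n, TRUE),
    day = sample(1:5, n, TRUE), approach_number = sample(1:8, n, TRUE),
    landing_side = sample(c("hive", "food"), n, TRUE))
}

BETA <- c(a = 1.35, b1 = -0.29, b2 = 0.03, b3 = 0.10, b4 = -0.02,
          b5 = -0.16, b6 = 0.32, b7 = -0.36)

lmm_linpred <- function(df, beta = BETA) {
  beta["a"] + beta["b1"] * log(df$y0) +
    beta["b2"] * (df$light == "medium") + beta["b3"] * (df$light == "sunrise") +
    beta["b4"] * (df$landing_type == "after_takeoff") +
    beta["b5"] * log(df$delta_re) + beta["b6"] * log(df$r_star) +
    beta["b7"] * log(df$y0) * log(df$delta_re)
}

test_that("with zero random variance the mixed model reduces to ordinary
           least squares", {
  df <- make_lmm_design(600, 31)
  set.seed(32)
  df$rdot_e <- exp(lmm_linpred(df) + rnorm(600, 0, 0.2))
  fit <- suppressWarnings(fit_lmm(df, "rdot_e"))
  ols <- lm(log(rdot_e) ~ log(y0) + factor(light, levels = c("twilight", "medium", "sunrise")) +
              factor(landing_type, levels = c("free_flight", "after_takeoff")) +
              log(delta_re) + log(r_star) + log(y0):log(delta_re), data = df)
  # REML variance estimates under a zero-variance generator sit near (not
  # exactly on) the boundary at finite n, so the GLS fixed effects agree
  # with OLS closely rather than identically
  expect_equal(unname(fit$fixed_effects$estimate), unname(coef(ols)),
               tolerance = 5e-3)
  expect_equal(nrow(fit$fixed_effects), 8)
  expect_true(all(fit$fixed_effects$p >= 0 & fit$fixed_effects$p <= 1))
  expect_true(all(fit$fixed_effects$SE > 0))
})

test_that("fixed effects are recovered across seeded replicates of the
           generating model", {
  n <- 800
  reps <- 20
  hits <- matrix(FALSE, reps, 8)
  for (k in seq_len(reps)) {
    df <- make_lmm_design(n, 100 + k)
    set.seed(200 + k)
    day_e <- rnorm(5, 0, 0.05); app_e <- rnorm(8, 0, 0.05); side_e <- rnorm(2, 0, 0.05)
    mu <- lmm_linpred(df) + day_e[df$day] + app_e[df$approach_number] +
      side_e[(df$landing_side == "food") + 1]
    df$rdot_e <- exp(mu + rnorm(n, 0, 0.2))
    fit <- suppressWarnings(fit_lmm(df, "rdot_e"))
    est <- fit$fixed_effects$estimate
    se <- fit$fixed_effects$SE
    hits[k, ] <- abs(est - unname(BETA)) <= qnorm(0.975) * se
  }
  # 95% CIs cover the truth for each coefficient in at least 90% of
  # replicates overall
  expect_gte(mean(hits), 0.9)
  expect_true(all(colMeans(hits) >= 0.75))
})

test_that("estimated means obey the model algebra and flag extrapolation", {
  df <- make_lmm_design(800, 41)
  set.seed(42)
  df$rdot_e <- exp(lmm_linpred(df) + rnorm(800, 0, 0.2))
  fit <- suppressWarnings(fit_lmm(df, "rdot_e"))
  beta <- lme4::fixef(fit$model)

  s0 <- data.frame(y0 = 0.2, delta_re = 1.5, r_star = 2.5,
                   light = "twilight", landing_type = "free_flight")
  em <- predict_emm(fit, s0)
  manual <- exp(beta["(Intercept)"] + beta["log_y0"] * log(0.2) +
                beta["log_dre"] * log(1.5) + beta["log_rstar"] * log(2.5) +
                beta["log_y0:log_dre"] * log(0.2) * log(1.5))
  expect_equal(em$emm, unname(manual), tolerance = 1e-9)
  expect_true(em$lwr < em$emm && em$emm < em$upr)

  # doubling delta_re multiplies the response by exp((b5 + b7 log y0) log 2)
  s1 <- s0; s1$delta_re <- 3.0
  em2 <- predict_emm(fit, rbind(s0, s1))
  ratio_pred <- exp((beta["log_dre"] + beta["log_y0:log_dre"] * log(0.2)) * log(2))
  expect_equal(em2$emm[2] / em2$emm[1], unname(ratio_pred), tolerance = 1e-9)

  expect_warning(predict_emm(fit, transform(s0, y0 = 99)), "extrapolates")
})

test_that("post-hoc contrasts use Bonferroni families of 3 and 1", {
  df <- make_lmm_design(600, 51)
  set.seed(52)
  df$rdot_e <- exp(lmm_linpred(df) + rnorm(600, 0, 0.2))
  fit <- suppressWarnings(fit_lmm(df, "rdot_e"))
  cc <- condition_contrasts(fit)
  expect_equal(nrow(cc), 4)
  light_rows <- cc$family == 3
  expect_equal(cc$p_adjusted[light_rows],
               pmin(1, 3 * cc$p_raw[light_rows]))
  expect_equal(cc$p_adjusted[!light_rows], pmin(1, cc$p_raw[!light_rows]))
  # the sunrise - twilight contrast equals the fixed effect itself
  b3 <- fit$fixed_effects$estimate[fit$fixed_effects$term == "lightsunrise"]
  expect_equal(cc$estimate[cc$contrast == "sunrise - twilight"], b3)
})

test_that("the entries table contract is enforced", {
  df <- make_lmm_design(100, 61)
  df$rdot_e <- 1
  df$rdot_e[5] <- -2
  expect_error(fit_lmm(df, "rdot_e"), "positive")
  expect_error(fit_lmm(df[, -1], "rdot_e"), "missing column")
})
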