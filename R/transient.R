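# Characterisation of entry segments as motion at a constant
# expansion-acceleration rdot: linear regression of r on t, the governing
# closed-form dynamics, distance discrepancy, mean approach acceleration,
# and the instantaneous acceleration-error correlation.

#' Fit a constant expansion-acceleration to an entry segment
#'
#' Ordinary least-squares fit of r(t) = rdot * t + c + eps. The slope is
#' the expansion-acceleration rdot_e that summarises how fast the animal
#' converges to its set-point.
#'
#' @param r expansion-rate samples over the entry (1/s).
#' @param t sample times (seconds).
#' @return a list with `rdot_e` (1/s^2), `c` (intercept at t = 0, 1/s) and
#'   `R2` (coefficient of determination; defined as 0 for a constant
#'   signal).
#' @export
fit_constant_rdot <- function(r, t) {
  if (length(r) < 3L) stop("need at least 3 samples")
  fit <- lm(r ~ t)
  tss <- sum((r - mean(r))^2)
  R2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 0
  list(rdot_e = unname(coef(fit)[2]), c = unname(coef(fit)[1]), R2 = R2)
}

#' Simulate motion at a constant expansion-acceleration
#'
#' For r(t) = r0 + rdot * t, the governing kinematics
#' dy/dt = -V, V = r y admit the closed form
#' y(t) = y0 exp(-(r0 t + rdot t^2 / 2)), with
#' V = r y and A = rdot y - V^2 / y. `method = "ode"` instead integrates
#' dy/dt = -r(t) y numerically (deSolve), as a cross-check of the closed
#' form.
#'
#' @param y0 initial distance in metres (> 0).
#' @param r0 initial expansion rate (1/s).
#' @param rdot constant expansion-acceleration (1/s^2).
#' @param t_span duration in seconds.
#' @param dt time step in seconds (default one 175 Hz frame).
#' @param method `"closed_form"` (exact) or `"ode"` (numerical).
#' @param y_floor truncate (with attribute `truncated = TRUE`) when y
#'   reaches this clip distance.
#' @return a data frame with `t, y, V, A, r` on the grid.
#' @export
simulate_constant_rdot <- function(y0, r0, rdot, t_span, dt = 1 / .BEELAND_FS,
                                   method = c("closed_form", "ode"),
                                   y_floor = 0.005) {
  if (y0 <= 0) stop("y0 must be positive")
  method <- match.arg(method)
  t <- seq(0, t_span, by = dt)
  r <- r0 + rdot * t
  if (method == "closed_form") {
    y <- y0 * exp(-(r0 * t + rdot * t^2 / 2))
  } else {
    sol <- deSolve::lsoda(c(y = y0), t,
                          function(tt, st, p) list(-(r0 + rdot * tt) * st[1]),
                          rtol = 1e-10, atol = 1e-12)
    y <- sol[, "y"]
  }
  V <- r * y
  A <- rdot * y - V^2 / y
  out <- data.frame(t = t, y = y, V = V, A = A, r = r)
  truncated <- FALSE
  if (any(y <= y_floor)) {
    out <- out[y > y_floor, , drop = FALSE]
    truncated <- TRUE
  }
  attr(out, "truncated") <- truncated
  out
}

#' Distance discrepancy between actual and constant-rdot model flight
#'
#' The difference between the actual flight distance covered over the entry
#' segment and the distance covered by the constant expansion-acceleration
#' model matched to the segment (r0 taken from the regression line at the
#' segment's first timestamp). Positive values mean the animal covered more
#' distance than the model.
#'
#' @param entry_states data frame with columns `t`, `y` over the entry
#'   segment.
#' @param fit output of [fit_constant_rdot()] on the same segment.
#' @return signed discrepancy in metres.
#' @export
distance_discrepancy <- function(entry_states, fit) {
  t <- entry_states$t
  y <- entry_states$y
  tau <- t - t[1]
  r0 <- fit$c + fit$rdot_e * t[1]          # regression line at segment start
  y_model_end <- y[1] * exp(-(r0 * tau[length(tau)] +
                              fit$rdot_e * tau[length(tau)]^2 / 2))
  actual <- y[1] - y[length(y)]
  model <- y[1] - y_model_end
  actual - model
}

#' Mean approach acceleration over an entry segment
#'
#' The net velocity change divided by the segment duration,
#' Ae_mean = dV / dt. Positive values mean the animal accelerated toward
#' the surface (or accelerated more than it decelerated) during the entry.
#'
#' @param entry_states data frame with columns `t`, `V` over the entry.
#' @return mean acceleration in m/s^2.
#' @export
mean_acceleration <- function(entry_states) {
  n <- nrow(entry_states)
  if (n < 2L) stop("need at least 2 samples")
  dt <- entry_states$t[n] - entry_states$t[1]
  if (dt <= 0) stop("zero-duration segment")
  (entry_states$V[n] - entry_states$V[1]) / dt
}

#' Correlation between model acceleration and set-point error
#'
#' Pearson correlation between the acceleration A_e(t) along the
#' constant-rdot model trajectory matched to the entry segment and the
#' instantaneous set-point error dr(t) = r_star - r(t). The model-trajectory
#' acceleration is used because the double-differentiated measured
#' acceleration is noisy.
#'
#' @param entry_states data frame with `t`, `y`, `r` over the entry.
#' @param r_star the target set-point (1/s).
#' @param fit output of [fit_constant_rdot()] on the same segment.
#' @return the Pearson coefficient, or `NA` (flagged with a warning) when
#'   either series has zero variance.
#' @export
accel_error_correlation <- function(entry_states, r_star, fit) {
  t <- entry_states$t
  if (length(t) < 3L) stop("need at least 3 samples")
  tau <- t - t[1]
  r0 <- fit$c + fit$rdot_e * t[1]
  y_m <- entry_states$y[1] * exp(-(r0 * tau + fit$rdot_e * tau^2 / 2))
  r_m <- r0 + fit$rdot_e * tau
  V_m <- r_m * y_m
  A_e <- fit$rdot_e * y_m - V_m^2 / y_m
  dr <- r_star - entry_states$r
  if (sd(A_e) == 0 || sd(dr) == 0) {
    warning("zero variance: acceleration-error correlation undefined")
    return(NA_real_)
  }
  cor(A_e, dr)
}

#' Characterise an entry segment
#'
#' Bundles the constant-rdot regression, distance discrepancy, mean
#' acceleration and acceleration-error correlation for one entry segment.
#'
#' @param states a `"state_series"`.
#' @param entry an `"entry_segment"` (see [extract_entry_segment()]).
#' @return a list of class `"transient_characterization"`: `rdot_e, c, R2,
#'   delta_d, Ae_mean, corr_Ae_dr`, plus the entry itself.
#' @export
characterize_entry <- function(states, entry) {
  idx <- entry$idx_start:entry$idx_end
  es <- states[idx, , drop = FALSE]
  fit <- fit_constant_rdot(es$r, es$t)
  corr <- suppressWarnings(accel_error_correlation(es, entry$r_star, fit))
  structure(list(rdot_e = fit$rdot_e, c = fit$c, R2 = fit$R2,
                 delta_d = distance_discrepancy(es, fit),
                 Ae_mean = mean_acceleration(es),
                 corr_Ae_dr = corr, entry = entry),
            class = "transient_characterization")
}
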