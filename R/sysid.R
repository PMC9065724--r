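# Transfer-function system identification of the closed-loop step response:
# constant set-point input r*(t), 5 Hz-filtered expansion rate r_f(t) as
# output. Orders 1-3, unity-DC-gain-times-K parameterisations:
#   order 1:  K / (tau s + 1)
#   order 2:  K w^2 / (s^2 + 2 D w s + w^2)
#   order 3:  K w^2 / ((tau s + 1)(s^2 + 2 D w s + w^2))
# Identification is done in the time domain (exact LTI simulation + least
# squares over parameters and initial state), since the constant input makes
# frequency-domain excitation degenerate.

#' Low-pass filter an expansion-rate signal at 5 Hz
#'
#' Zero-phase second-order Butterworth filter isolating the low-frequency
#' "mean variation" of r(t) used as the system-identification output; the
#' high-frequency content reflects tracking noise and r-control
#' oscillations.
#'
#' @param r_c raw expansion-rate signal (1/s) on the 175 Hz grid.
#' @param cutoff cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return filtered signal, same grid.
#' @export
lowpass_r <- function(r_c, cutoff = 5, fs = .BEELAND_FS) {
  filtfilt_lowpass(r_c, cutoff = cutoff, fs = fs)
}

#' Fit percentage of a simulated output against the filtered signal
#'
#' Normalised root-mean-square goodness metric:
#' F = 100 (1 - ||r_f - r_s|| / ||r_f - mean(r_f)||).
#' F = 100 is a perfect fit; F = 0 means the model does no better than a
#' constant equal to the signal mean; F is unbounded below.
#'
#' @param r_f filtered measured signal.
#' @param r_s simulated model output (same length).
#' @return fit percentage.
#' @export
fit_percentage <- function(r_f, r_s) {
  if (length(r_f) != length(r_s)) stop("signals must have equal length")
  if (length(r_f) < 2L) stop("need at least 2 samples")
  den <- sqrt(sum((r_f - mean(r_f))^2))
  if (den < .Machine$double.eps * length(r_f))
    stop("fit percentage undefined for a constant signal")
  100 * (1 - sqrt(sum((r_f - r_s)^2)) / den)
}

# Companion-form state-space (A, B) for each order; output is the first state.
.tf_ss <- function(order, params) {
  if (order == 1L) {
    tau <- params[["tau"]]
    list(A = matrix(-1 / tau, 1, 1), B = params[["K"]] / tau)
  } else if (order == 2L) {
    w <- params[["w"]]; D <- params[["D"]]
    list(A = matrix(c(0, -w^2, 1, -2 * D * w), 2, 2),
         B = c(0, params[["K"]] * w^2))
  } else {
    w <- params[["w"]]; D <- params[["D"]]; tau <- params[["tau"]]
    # (tau s + 1)(s^2 + 2 D w s + w^2) expanded, normalised to monic
    a2 <- (1 + 2 * D * w * tau) / tau
    a1 <- (2 * D * w + w^2 * tau) / tau
    a0 <- w^2 / tau
    list(A = matrix(c(0, 0, -a0, 1, 0, -a1, 0, 1, -a2), 3, 3),
         B = c(0, 0, params[["K"]] * w^2 / tau))
  }
}

#' Simulate a transfer-function model with constant input
#'
#' Exact solution of the order-n linear ODE with constant input `r_star`
#' from the given initial state, evaluated on the sample grid by
#' eigendecomposition of the companion matrix (for order 2:
#' r_s'' + 2 D w r_s' + w^2 r_s = K w^2 r_star).
#'
#' @param params named list of model parameters: `K` always; `tau` for
#'   orders 1 and 3; `D`, `w` for orders 2 and 3.
#' @param r_star constant input value (the set-point, 1/s).
#' @param t sample times (uniform grid, seconds).
#' @param init_state numeric vector of length `order`: initial output and
#'   its derivatives.
#' @param order transfer-function order (1, 2 or 3); inferred from
#'   `init_state` when missing.
#' @return simulated output r_s on the grid of `t`.
#' @export
simulate_tf <- function(params, r_star, t, init_state, order = length(init_state)) {
  if (!all(vapply(params, is.finite, logical(1))))
    stop("non-finite transfer-function parameters")
  ss <- .tf_ss(as.integer(order), params)
  A <- ss$A; B <- ss$B
  xss <- tryCatch(solve(A, -B * r_star), error = function(e) NULL)
  tt <- t - t[1]
  if (is.null(xss)) return(.simulate_tf_ode(A, B, r_star, tt, init_state))
  eg <- eigen(A)
  Vv <- eg$vectors
  co <- tryCatch(solve(Vv, init_state - xss), error = function(e) NULL)
  if (is.null(co) || any(!is.finite(Mod(co))))
    return(.simulate_tf_ode(A, B, r_star, tt, init_state))
  modes <- exp(outer(eg$values, tt))            # order x n
  Re(as.vector(Vv[1, , drop = FALSE] %*% (modes * co))) + Re(xss[1])
}

# Fallback for (near-)defective companion matrices: RK4 on the state ODE.
.simulate_tf_ode <- function(A, B, r_star, tt, x0) {
  n <- length(tt)
  out <- numeric(n)
  x <- x0
  out[1] <- x[1]
  f <- function(x) as.vector(A %*% x + B * r_star)
  for (i in 2:n) {
    h <- tt[i] - tt[i - 1]
    k1 <- f(x); k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2); k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i] <- x[1]
  }
  out
}

#' Assemble a system-identification input from a linked entry and
#' constant-r segment
#'
#' Concatenates the raw r over the entry segment and its constant-r segment,
#' filters it at 5 Hz, and builds the constant set-point input signal.
#'
#' @param states a `"state_series"`.
#' @param entry an `"entry_segment"`.
#' @param seg the linked row of a `"constant_r_segments"` data frame.
#' @return a list of class `"sysid_input"` with `t`, `r_c`, `r_f`,
#'   `r_star`, and `fs`.
#' @export
build_sysid_input <- function(states, entry, seg) {
  idx <- entry$idx_start:seg$idx_end
  fs <- attr(states, "fs") %||% .BEELAND_FS
  r_c <- states$r[idx]
  if (length(r_c) < 19L) stop("combined segment too short for filtering")
  structure(list(t = states$t[idx], r_c = r_c,
                 r_f = lowpass_r(r_c, fs = fs),
                 r_star = seg$r_star, fs = fs),
            class = "sysid_input")
}

# Deterministic multi-start grid (Latin-style) over the parameter box.
.tf_starts <- function(order, r_f, t, r_star) {
  Ks <- c(0.6, 0.8, 1.0, 1.1, 0.9, 1.2, 0.7, 1.4)
  Ds <- c(0.3, 1.6, 0.7, 1.1, 2.0, 0.5, 1.3, 0.9)
  ws <- c(35, 5, 12, 25, 8, 50, 18, 3)
  taus <- 1 / ws
  dt0 <- t[2] - t[1]
  d0 <- (r_f[2] - r_f[1]) / dt0
  span <- max(t) - min(t)
  # data-driven start: K from the plateau level, w from the rise time
  Kd <- max(0.2, min(2, r_f[length(r_f)] / r_star))
  rise <- span / 3
  wd <- max(2, 1.8 / rise)
  starts <- list()
  for (i in seq_along(Ks)) {
    starts[[i]] <- switch(order,
      `1` = list(K = Ks[i], tau = taus[i]),
      `2` = list(K = Ks[i], D = Ds[i], w = ws[i]),
      `3` = list(K = Ks[i], D = Ds[i], w = ws[i], tau = taus[i] / 2))
  }
  starts[[length(starts) + 1L]] <- switch(order,
    `1` = list(K = Kd, tau = 1 / wd),
    `2` = list(K = Kd, D = 0.8, w = wd),
    `3` = list(K = Kd, D = 0.8, w = wd, tau = 0.3 / wd))
  attr(starts, "d0") <- d0
  starts
}

# pack/unpack: positive parameters on the log scale, initial state free.
.tf_pack <- function(order, params, init) {
  p <- switch(order,
    `1` = c(log(params$K), log(params$tau)),
    `2` = c(log(params$K), log(params$D), log(params$w)),
    `3` = c(log(params$K), log(params$D), log(params$w), log(params$tau)))
  c(p, init)
}

.tf_unpack <- function(order, theta) {
  np <- c(2L, 3L, 4L)[order]
  p <- exp(theta[seq_len(np)])
  params <- switch(order,
    `1` = list(K = p[1], tau = p[2]),
    `2` = list(K = p[1], D = p[2], w = p[3]),
    `3` = list(K = p[1], D = p[2], w = p[3], tau = p[4]))
  list(params = params, init = theta[(np + 1L):length(theta)])
}

#' Identify a transfer function from a step-response input
#'
#' Estimates the transfer-function parameters and initial state that jointly
#' minimise the quadratic prediction error sum((r_f - r_s)^2), using
#' deterministic multi-start local optimisation (Nelder-Mead followed by a
#' BFGS polish). The initial output and its derivatives are free parameters,
#' initialised from r_f(0) and finite differences.
#'
#' @param input a `"sysid_input"` (see [build_sysid_input()]), or any list
#'   with elements `t`, `r_f`, `r_star`.
#' @param order transfer-function order (1, 2 or 3).
#' @param f_stop early-stopping fit percentage: remaining starts are skipped
#'   once a fit exceeds this value (set above 100 to disable).
#' @return a list of class `"tf_fit"`: `order`, `params`, `init_state`,
#'   `r_s` (simulated output), `F` (fit percentage, `-Inf` when no start
#'   converged), `converged`.
#' @export
identify_tf <- function(input, order = 2L, f_stop = 99.9) {
  order <- as.integer(order)
  stopifnot(order %in% 1:3)
  t <- input$t; r_f <- input$r_f; r_star <- input$r_star
  if (max(t) - min(t) < 0.15) stop("span too short for identification (< 0.15 s)")
  sse <- function(theta) {
    up <- .tf_unpack(order, theta)
    if (any(!is.finite(unlist(up$params))) || up$params$K > 1e3) return(1e12)
    rs <- tryCatch(simulate_tf(up$params, r_star, t, up$init, order),
                   error = function(e) NULL)
    if (is.null(rs) || any(!is.finite(rs))) return(1e12)
    sum((r_f - rs)^2)
  }
  starts <- .tf_starts(order, r_f, t, r_star)
  d0 <- attr(starts, "d0")
  init0 <- switch(order, `1` = r_f[1], `2` = c(r_f[1], d0), `3` = c(r_f[1], d0, 0))
  best <- NULL
  den2 <- sum((r_f - mean(r_f))^2)
  for (st in rev(starts)) {          # data-driven start first
    theta0 <- .tf_pack(order, st, init0)
    fit <- try(optim(theta0, sse, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-9)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    Fnow <- 100 * (1 - sqrt(best$value / den2))
    if (Fnow >= f_stop) break
  }
  if (!is.null(best) && best$value < 1e12) {
    # polish the winning start only
    fit2 <- try(optim(best$par, sse, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-14)), silent = TRUE)
    if (!inherits(fit2, "try-error") && is.finite(fit2$value) &&
        fit2$value < best$value) best <- fit2
    fit3 <- try(optim(best$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-13)), silent = TRUE)
    if (!inherits(fit3, "try-error") && is.finite(fit3$value) &&
        fit3$value < best$value) best <- fit3
  }
  if (is.null(best) || best$value >= 1e12) {
    return(structure(list(order = order, params = NULL, init_state = NULL,
                          r_s = NULL, F = -Inf, converged = FALSE),
                     class = "tf_fit"))
  }
  up <- .tf_unpack(order, best$par)
  r_s <- simulate_tf(up$params, r_star, t, up$init, order)
  structure(list(order = order, params = up$params, init_state = up$init,
                 r_s = r_s, F = fit_percentage(r_f, r_s), converged = TRUE),
            class = "tf_fit")
}

#' @export
#' @method print tf_fit
print.tf_fit <- function(x, ...) {
  cat("<tf_fit> order", x$order, "F =", sprintf("%.2f%%", x$F), "\n")
  if (!is.null(x$params))
    cat("  params:", paste(names(x$params), sprintf("%.4g", unlist(x$params)),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Compare transfer-function orders over a collection of inputs
#'
#' Fits the requested orders to each input and summarises the fit
#' percentages per order (median and interquartile range over the cohort).
#' Non-converged fits (F = -Inf) are excluded from the summaries.
#'
#' @param inputs list of `"sysid_input"` objects.
#' @param orders integer vector of orders to fit.
#' @param ... passed to [identify_tf()].
#' @return a list with `per_input` (data frame of F by input and order) and
#'   `summary` (data frame with order, n, median_F, q1_F, q3_F).
#' @export
compare_orders <- function(inputs, orders = 1:3, ...) {
  if (length(inputs) == 0L) {
    return(list(per_input = data.frame(input = integer(), order = integer(),
                                       F = numeric()),
                summary = data.frame(order = integer(), n = integer(),
                                     median_F = numeric(), q1_F = numeric(),
                                     q3_F = numeric())))
  }
  rows <- list()
  for (i in seq_along(inputs)) {
    for (o in orders) {
      fit <- tryCatch(identify_tf(inputs[[i]], order = o, ...),
                      error = function(e) list(F = -Inf))
      rows[[length(rows) + 1L]] <- data.frame(input = i, order = o, F = fit$F)
    }
  }
  per_input <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(orders, function(o) {
    Fv <- per_input$F[per_input$order == o & is.finite(per_input$F)]
    data.frame(order = o, n = length(Fv),
               median_F = if (length(Fv)) median(Fv) else NA_real_,
               q1_F = if (length(Fv)) unname(quantile(Fv, 0.25)) else NA_real_,
               q3_F = if (length(Fv)) unname(quantile(Fv, 0.75)) else NA_real_)
  }))
  list(per_input = per_input, summary = summ)
}
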