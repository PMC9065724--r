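# Landing state variables: y(t), V(t), A(t) and the relative rate of
# expansion r(t) = V(t)/y(t), plus the algebraic expansion-acceleration
# identities that tie them together.

#' Second-order finite-difference derivative on a uniform grid
#'
#' Central differences at interior samples; one-sided second-order stencils
#' at the two endpoints. Exact for polynomials up to degree 2.
#'
#' @param x sampled signal.
#' @param t sample times (uniform grid).
#' @return the sampled derivative dx/dt.
#' @export
differentiate <- function(x, t) {
  n <- length(x)
  if (n < 3L) stop("differentiate needs at least 3 samples")
  if (length(t) != n) stop("x and t lengths differ")
  h <- (t[n] - t[1]) / (n - 1)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * h)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * h)
  d
}

#' Compute landing state variables from a trajectory
#'
#' For a filtered, touchdown-aligned trajectory, computes the approach
#' distance y (the platform-normal coordinate), approach velocity
#' V = -dy/dt (positive toward the platform), approach acceleration
#' A = dV/dt, and the relative rate of optical expansion r = V/y.
#' Samples with y at or below `y_min_clip` are removed: r diverges at
#' contact and the set-point analysis operates away from the surface.
#'
#' @param traj a [trajectory()], filtered and touchdown-aligned.
#' @param y_min_clip near-contact clip distance in metres (default 5 mm).
#' @return a data frame of class `"state_series"` with columns
#'   `t, y, V, A, r` and a `receding` flag (TRUE where V < 0, i.e. the
#'   animal moves away from the platform); metadata attached as attribute
#'   `meta`, sampling rate as `fs`.
#' @export
compute_states <- function(traj, y_min_clip = 0.005) {
  y <- traj$pos[, 2]
  V <- -differentiate(y, traj$t)
  A <- differentiate(V, traj$t)
  keep <- y > y_min_clip
  if (!any(keep)) stop("track '", traj$track_id, "': all samples below clip distance")
  st <- data.frame(t = traj$t[keep], y = y[keep], V = V[keep], A = A[keep])
  st$r <- st$V / st$y
  st$receding <- st$V < 0
  structure(st, class = c("state_series", "data.frame"),
            meta = attr(traj, "meta", exact = TRUE) %||% traj$meta,
            fs = traj$fs, track_id = traj$track_id)
}

#' Expansion-acceleration from instantaneous kinematic state
#'
#' The time derivative of r = V/y follows algebraically from the kinematics:
#' rdot = (y A + V^2) / y^2. For constant-r flight (A = -V^2/y) this is zero.
#'
#' @param y distance in metres (> 0).
#' @param V approach velocity in m/s.
#' @param A approach acceleration in m/s^2.
#' @return rdot in 1/s^2.
#' @export
expansion_accel_identity <- function(y, V, A) {
  if (any(y <= 0)) stop("y must be positive")
  (y * A + V^2) / y^2
}

#' Approach acceleration implied by an expansion-acceleration
#'
#' Inverse of [expansion_accel_identity()]: A = rdot * y - V^2 / y.
#'
#' @param rdot expansion-acceleration in 1/s^2.
#' @param y distance in metres (> 0).
#' @param V approach velocity in m/s.
#' @return A in m/s^2.
#' @export
accel_from_expansion <- function(rdot, y, V) {
  if (any(y <= 0)) stop("y must be positive")
  rdot * y - V^2 / y
}

#' Restrict a state series to the final approach
#'
#' The set-point analysis consumes the last contiguous stretch of
#' approach flight ending at touchdown; receding samples earlier in the
#' track are dropped. A sample counts as receding when V < -v_tol: the
#' tolerance keeps noise-induced sign flips of the near-zero approach
#' velocity close to touchdown from truncating the approach.
#'
#' @param states a `"state_series"`.
#' @param v_tol receding-velocity tolerance in m/s.
#' @return the trimmed state series (attributes preserved).
#' @export
final_approach <- function(states, v_tol = 0.02) {
  n <- nrow(states)
  # drop the trailing near-zero-velocity tail (at touchdown V = r y falls
  # to the noise floor, so sign flips there carry no information), then
  # take the last contiguous approach run
  while (n > 1L && states$V[n] < v_tol) n <- n - 1L
  if (n == 1L && states$V[1L] < v_tol)
    stop("track has no approach samples ending at touchdown")
  appr <- states$V[1:n] > -v_tol
  last_bad <- if (any(!appr)) max(which(!appr)) else 0L
  if (last_bad >= n) stop("track has no approach samples ending at touchdown")
  out <- states[(last_bad + 1L):n, , drop = FALSE]
  attributes(out)[c("meta", "fs", "track_id")] <-
    attributes(states)[c("meta", "fs", "track_id")]
  class(out) <- class(states)
  rownames(out) <- NULL
  out
}
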