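# Detection of constant-r (set-point) segments and extraction of the
# transient entry segments that precede them.
#
# The detector scans candidate windows over the final approach and fits a
# linear regression of r on t in each. Six regression statistics govern
# acceptance, each limited to f scale parameters of a t-distribution:
#   * slope — must lie within f scale parameters of zero, the scale being
#     the slope's own standard error (its sampling distribution is
#     Student-t with that scale);
#   * level (fitted r at the window centre) — consecutive accepted windows
#     in a merged run must agree within f joint level-SE scale parameters
#     (this splits runs that would otherwise bridge distinct set-points);
#   * residual scale, slope SE, level SE, lag-1 residual autocorrelation —
#     must lie within f scale parameters of a robust t-distribution
#     location/scale fit to that statistic's distribution over all windows
#     of the track (these statistics measure noise, which is homogeneous
#     along a track, so excursions flag transient motion).
# Accepted windows are merged into maximal covered runs.

# ML location/scale fit of a t-distribution with fixed df.
# Returns c(m, s); s floored at 1e-12 so that degenerate (zero-spread)
# statistics accept only exact matches.
.t_locscale <- function(x, df = 4) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(c(m = 0, s = 1e-12))
  m0 <- median(x)
  s0 <- mad(x)
  if (!is.finite(s0) || s0 < 1e-12) return(c(m = m0, s = 1e-12))
  nll <- function(p) {
    s <- exp(p[2])
    -sum(stats::dt((x - p[1]) / s, df, log = TRUE) - p[2])
  }
  fit <- try(optim(c(m0, log(s0)), nll, method = "Nelder-Mead",
                   control = list(maxit = 300)), silent = TRUE)
  if (inherits(fit, "try-error")) return(c(m = m0, s = max(s0, 1e-12)))
  c(m = fit$par[1], s = max(exp(fit$par[2]), 1e-12))
}

# Regression statistics for one window of (t, r): slope, level at window
# centre, residual scale, slope SE, level SE, lag-1 residual autocorrelation.
.window_stats <- function(tt, rr) {
  L <- length(tt)
  tc <- tt - mean(tt)
  Sxx <- sum(tc^2)
  slope <- sum(tc * rr) / Sxx
  level <- mean(rr)
  e <- rr - level - slope * tc
  rss <- sum(e^2)
  s <- sqrt(max(rss, 0) / (L - 2))
  se_slope <- s / sqrt(Sxx)
  se_level <- s / sqrt(L)
  den <- sum(e^2)
  rho <- if (den > 0) sum(e[-1] * e[-L]) / den else 0
  c(slope, level, s, se_slope, se_level, rho)
}

#' Detect constant-r (set-point) segments in a state series
#'
#' Finds maximal, non-overlapping intervals over which the relative rate of
#' expansion r is statistically constant, using a threshold factor `f` that
#' bounds the allowed variation of six windowed regression statistics in
#' units of the scale parameter of a t-distribution fitted to each
#' statistic's track-level distribution. Larger `f` admits more and wider
#' segments (coverage grows monotonically with `f`).
#'
#' Each detected segment is summarised by the mean state variables over the
#' interval: the set-point `r_star` plus `y_star`, `V_star`, `A_star`.
#'
#' @param states a `"state_series"` covering a final approach (see
#'   [final_approach()]).
#' @param f threshold factor (dimensionless, default 1.5).
#' @param min_duration minimum segment duration in seconds (default 0.1).
#' @param start_step window-start grid step in samples.
#' @param length_grow geometric growth factor of the window-length grid.
#' @param n_lengths number of window lengths in the grid (kept short:
#'   windows much longer than `min_duration` straddle brief transients and
#'   dilute their slope below the acceptance bounds; long segments are
#'   recovered by merging overlapping short windows instead).
#' @param drift_frac allowed net drift across a window, as a fraction of
#'   the window level per scale parameter (the drift bound is
#'   `f * drift_frac * level`).
#' @return a data frame of class `"constant_r_segments"` with one row per
#'   segment: `idx_start, idx_end, r_star, y_star, V_star, A_star, f_used`;
#'   zero rows when no interval qualifies.
#' @export
detect_constant_r <- function(states, f = 1.5, min_duration = 0.1,
                              start_step = 1L, length_grow = 1.35,
                              n_lengths = 3L, drift_frac = 0.02) {
  fs <- attr(states, "fs") %||% .BEELAND_FS
  n <- nrow(states)
  Lmin <- as.integer(ceiling(min_duration * fs))
  empty <- structure(
    data.frame(idx_start = integer(), idx_end = integer(), r_star = numeric(),
               y_star = numeric(), V_star = numeric(), A_star = numeric(),
               f_used = numeric()),
    class = c("constant_r_segments", "data.frame"))
  if (n < Lmin) return(empty)
  lengths <- unique(pmin(as.integer(round(Lmin * length_grow^(0:(n_lengths - 1)))), n))
  tt <- states$t
  rr <- states$r
  wins <- list()
  k <- 0L
  for (L in lengths) {
    starts <- seq.int(1L, n - L + 1L, by = start_step)
    for (s0 in starts) {
      k <- k + 1L
      idx <- s0:(s0 + L - 1L)
      wins[[k]] <- c(s0, L, .window_stats(tt[idx], rr[idx]))
    }
  }
  W <- do.call(rbind, wins)
  colnames(W) <- c("start", "len", "slope", "level", "rscale", "se_slope",
                   "se_level", "rho")
  # slope consistent with zero within f slope-SE scale parameters, and the
  # net drift across the window bounded by f drift_frac of the level (the
  # SE criterion alone goes blind where measurement noise in r inflates
  # close to the platform)
  T_win <- (W[, "len"] - 1) / fs
  ok <- abs(W[, "slope"]) <= f * W[, "se_slope"] + 1e-12
  ok <- ok & (abs(W[, "slope"]) * T_win <=
                f * drift_frac * abs(W[, "level"]) + 1e-12)
  # noise statistics within f scale parameters of their track-level t fit
  for (j in c("rscale", "se_slope", "se_level", "rho")) {
    ls <- .t_locscale(W[, j])
    ok <- ok & (abs(W[, j] - ls["m"]) <= f * ls["s"] + 1e-12)
  }
  covered <- logical(n)
  for (i in which(ok)) covered[W[i, 1]:(W[i, 1] + W[i, 2] - 1L)] <- TRUE
  # level-consistency: split covered runs where consecutive accepted
  # windows disagree in level by more than f scale parameters of the
  # joint level sampling distribution (SE plus the within-window residual
  # scale, which carries the tolerated approximately-constant wobble)
  acc <- W[ok, , drop = FALSE]
  if (nrow(acc) > 1L) {
    acc <- acc[order(acc[, "start"]), , drop = FALSE]
    lev_jump <- abs(diff(acc[, "level"]))
    ja <- seq_len(nrow(acc) - 1L); jb <- ja + 1L
    tol <- f * (sqrt(acc[ja, "se_level"]^2 + acc[jb, "se_level"]^2) +
                0.5 * (acc[ja, "rscale"] + acc[jb, "rscale"])) + 1e-12
    for (j in which(lev_jump > tol)) {
      cut_lo <- acc[j, "start"] + acc[j, "len"] - 1L      # end of window j
      cut_hi <- acc[j + 1L, "start"]                      # start of window j+1
      if (cut_hi <= cut_lo) {                             # overlapping: cut between centres
        cut <- as.integer((2 * acc[j, "start"] + acc[j, "len"] +
                           2 * acc[j + 1L, "start"] + acc[j + 1L, "len"]) / 4)
        covered[max(1L, cut)] <- FALSE
      }
    }
  }
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  seg_start <- starts[keep]; seg_end <- ends[keep]
  # close short gaps between level-consistent runs: a lone rejected window
  # inside an approximately-constant stretch must not split the segment
  if (length(seg_start) > 1L) {
    gap_max <- max(1L, as.integer(ceiling(0.05 * fs)))
    ms <- mapply(function(a, b) mean(rr[a:b]), seg_start, seg_end)
    ss <- mapply(function(a, b) sd(rr[a:b]), seg_start, seg_end)
    i <- 1L
    while (i < length(seg_start)) {
      gap <- seg_start[i + 1L] - seg_end[i] - 1L
      lev_ok <- abs(ms[i + 1L] - ms[i]) <=
        f * (max(ss[i], ss[i + 1L], 1e-12)) + 1e-12
      if (gap <= gap_max && lev_ok) {
        seg_end[i] <- seg_end[i + 1L]
        ms[i] <- mean(rr[seg_start[i]:seg_end[i]])
        ss[i] <- sd(rr[seg_start[i]:seg_end[i]])
        seg_start <- seg_start[-(i + 1L)]; seg_end <- seg_end[-(i + 1L)]
        ms <- ms[-(i + 1L)]; ss <- ss[-(i + 1L)]
      } else i <- i + 1L
    }
  }
  long_enough <- (seg_end - seg_start + 1L) >= Lmin
  if (!any(long_enough)) return(empty)
  segs <- data.frame(idx_start = seg_start[long_enough],
                     idx_end = seg_end[long_enough])
  segs$r_star <- mapply(function(a, b) mean(rr[a:b]), segs$idx_start, segs$idx_end)
  segs$y_star <- mapply(function(a, b) mean(states$y[a:b]), segs$idx_start, segs$idx_end)
  segs$V_star <- mapply(function(a, b) mean(states$V[a:b]), segs$idx_start, segs$idx_end)
  segs$A_star <- mapply(function(a, b) mean(states$A[a:b]), segs$idx_start, segs$idx_end)
  segs$f_used <- f
  structure(segs, class = c("constant_r_segments", "data.frame"))
}

#' Sweep the detector threshold factor
#'
#' Runs [detect_constant_r()] over a grid of threshold factors and reports
#' the detected segments and sample coverage per `f` (sensitivity analysis).
#'
#' @param states a `"state_series"`.
#' @param f_values numeric vector of threshold factors.
#' @param ... passed to [detect_constant_r()].
#' @return a list with one element per `f`: `list(f, segments, coverage)`,
#'   where coverage is the fraction of samples inside detected segments.
#' @export
sweep_f <- function(states, f_values = seq(0.25, 2.5, by = 0.25), ...) {
  n <- nrow(states)
  lapply(f_values, function(fv) {
    segs <- detect_constant_r(states, f = fv, ...)
    cov <- if (nrow(segs)) sum(segs$idx_end - segs$idx_start + 1L) / n else 0
    list(f = fv, segments = segs, coverage = cov)
  })
}

#' Extract the entry segment preceding a constant-r segment
#'
#' An entry segment is the transient interval during which r varies
#' monotonically toward the set-point of the following constant-r segment.
#' Monotonicity is assessed on the 5 Hz zero-phase-filtered r with tolerance
#' `eps_mono`. The entry starts where the monotonic run starts or — for
#' increasing runs that begin below `r_low` — at the crossing of
#' `r_low` (located by linear interpolation and snapped to the nearest
#' sample), whichever occurs later. It ends at the sample before the
#' constant-r segment begins.
#'
#' @param states a `"state_series"`.
#' @param seg one row of a `"constant_r_segments"` data frame.
#' @param r_low low-r start rule threshold in 1/s (default 0.5; applied to
#'   increasing runs only).
#' @param eps_mono monotonicity tolerance on the filtered r, in 1/s.
#' @param min_run minimum monotonic run length in samples.
#' @param lower_bound earliest sample index the entry may start at (e.g. the
#'   end of the preceding constant-r segment).
#' @param r_f optional precomputed 5 Hz-filtered r over `states` (see
#'   [lowpass_r()]); computed internally when `NULL`.
#' @return a list of class `"entry_segment"` with elements `idx_start,
#'   idx_end, r0, y0, r_star, delta_re, direction`, or `NULL` when no
#'   monotonic run abuts the segment.
#' @export
extract_entry_segment <- function(states, seg, r_low = 0.5, eps_mono = 0.02,
                                  min_run = 5L, lower_bound = 1L, r_f = NULL) {
  i1 <- seg$idx_start
  lb <- max(1L, as.integer(lower_bound))
  if (i1 - lb < min_run) return(NULL)
  if (is.null(r_f)) {
    fs <- attr(states, "fs") %||% .BEELAND_FS
    r_f <- lowpass_r(states$r, fs = fs)
  }
  # direction of the net variation before the segment: where does the
  # set-point sit relative to the flight shortly before it? (the filtered r
  # immediately before the segment lies in the flat settling zone, so a
  # local difference cannot carry the direction)
  probe <- max(lb, i1 - 6L * min_run)
  dd <- seg$r_star - r_f[probe]
  if (abs(dd) < eps_mono) return(NULL)
  dir <- sign(dd)
  onset <- i1
  for (j in seq.int(i1 - 1L, lb)) {
    if (dir * (r_f[j + 1L] - r_f[j]) < -eps_mono) break
    onset <- j
  }
  # trim the flat lead-in (e.g. the settling tail of a preceding plateau):
  # variation has not started while the per-sample step stays below half
  # the run's mean step; capped at 20% of the run's total change so a slow
  # homogeneous rise is never eaten
  r_onset0 <- r_f[onset]
  total <- r_f[i1] - r_onset0
  step_thresh <- 0.5 * abs(total) / (i1 - onset)
  while (onset < i1 - min_run &&
         dir * (r_f[onset + 1L] - r_f[onset]) < step_thresh &&
         abs(r_f[onset] - r_onset0) < 0.20 * abs(total))
    onset <- onset + 1L
  if (i1 - onset < min_run) return(NULL)
  if (dir > 0 && r_f[onset] < r_low) {
    # last upward crossing of r_low in [onset, i1)
    cross <- which(r_f[onset:(i1 - 1L)] <= r_low & r_f[(onset + 1L):i1] > r_low)
    if (length(cross)) {
      k <- onset + max(cross) - 1L
      frac <- (r_low - r_f[k]) / (r_f[k + 1L] - r_f[k])
      onset <- if (frac > 0.5) k + 1L else k
    }
  }
  idx_end <- i1 - 1L
  if (idx_end - onset + 1L < 3L) return(NULL)
  structure(list(idx_start = onset, idx_end = idx_end,
                 r0 = states$r[onset], y0 = states$y[onset],
                 r_star = seg$r_star, delta_re = seg$r_star - states$r[onset],
                 direction = if (dir > 0) "increasing" else "decreasing"),
            class = "entry_segment")
}

#' Extract the entry segments for all detected constant-r segments
#'
#' Applies [extract_entry_segment()] to each segment in order, bounding each
#' search at the end of the preceding constant-r segment (an entry may share
#' its onset with that end).
#'
#' @param states a `"state_series"`.
#' @param segs a `"constant_r_segments"` data frame.
#' @param ... passed to [extract_entry_segment()].
#' @return a list of `"entry_segment"` objects (entries that do not exist
#'   are dropped); each element carries the index of its linked segment as
#'   `seg_index`.
#' @export
extract_entries <- function(states, segs, ...) {
  fs <- attr(states, "fs") %||% .BEELAND_FS
  r_f <- if (nrow(states) >= 19L) lowpass_r(states$r, fs = fs) else states$r
  out <- list()
  for (i in seq_len(nrow(segs))) {
    lb <- if (i > 1L) segs$idx_end[i - 1L] else 1L
    ent <- extract_entry_segment(states, segs[i, ], lower_bound = lb,
                                 r_f = r_f, ...)
    if (!is.null(ent)) {
      ent$seg_index <- i
      out[[length(out) + 1L]] <- ent
    }
  }
  out
}
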