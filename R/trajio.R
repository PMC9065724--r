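# Trajectory containers, canonical file formats, filtering and time alignment.

.LIGHT_LEVELS <- c("twilight", "medium", "sunrise")
.PATTERN_LEVELS <- c("checkerboard", "spoke")
.LANDING_TYPE_LEVELS <- c("free_flight", "after_takeoff")
.SIDE_LEVELS <- c("hive", "food")

.CSV_COLUMNS <- c("track_id", "t_s", "x_m", "y_m", "z_m", "light", "pattern",
                  "landing_type", "day", "approach_number", "landing_side")

#' Landing metadata record
#'
#' Per-track experimental metadata: light condition, landing-platform pattern,
#' landing type (from free flight or directly after a take-off), experimental
#' day, approach number and landing side (hive or food platform).
#'
#' @param light one of `"twilight"`, `"medium"`, `"sunrise"`.
#' @param pattern one of `"checkerboard"`, `"spoke"`.
#' @param landing_type one of `"free_flight"`, `"after_takeoff"`.
#' @param day integer day label.
#' @param approach_number integer approach label.
#' @param landing_side one of `"hive"`, `"food"`.
#' @return an object of class `"landing_metadata"` (a named list).
#' @export
landing_metadata <- function(light = "twilight", pattern = "checkerboard",
                             landing_type = "free_flight", day = 1L,
                             approach_number = 1L, landing_side = "hive") {
  light <- match.arg(light, .LIGHT_LEVELS)
  pattern <- match.arg(pattern, .PATTERN_LEVELS)
  landing_type <- match.arg(landing_type, .LANDING_TYPE_LEVELS)
  landing_side <- match.arg(landing_side, .SIDE_LEVELS)
  structure(list(light = light, pattern = pattern, landing_type = landing_type,
                 day = as.integer(day), approach_number = as.integer(approach_number),
                 landing_side = landing_side),
            class = "landing_metadata")
}

#' Construct a 3-D landing trajectory
#'
#' A trajectory is a uniformly sampled 3-D track in the landing coordinate
#' frame: origin at the platform centre, `y` normal to the platform pointing
#' into the arena, `z` vertically up, `x` lateral.
#'
#' @param track_id character identifier.
#' @param t numeric vector of sample times in seconds, strictly increasing on
#'   a uniform grid (nominal step 1/175 s).
#' @param pos numeric matrix with one row per sample and columns `x`, `y`, `z`
#'   in metres.
#' @param meta a [landing_metadata()] object.
#' @param fs sampling rate in Hz (default 175).
#' @param validate check the uniform-grid and finiteness invariants.
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(track_id, t, pos, meta = landing_metadata(),
                       fs = .BEELAND_FS, validate = TRUE) {
  pos <- as.matrix(pos)
  colnames(pos) <- c("x", "y", "z")
  obj <- structure(list(track_id = as.character(track_id), t = as.numeric(t),
                        pos = pos, meta = meta, fs = fs),
                   class = "trajectory")
  if (validate) validate_trajectory(obj)
  obj
}

#' Validate a trajectory's sampling-grid and finiteness invariants
#'
#' @param traj a [trajectory()].
#' @param tol relative tolerance on the deviation of each time step from the
#'   nominal 1/fs step.
#' @return `traj`, invisibly; errors with the offending `track_id` otherwise.
#' @export
validate_trajectory <- function(traj, tol = 1e-6) {
  dt <- diff(traj$t)
  if (length(dt) == 0L)
    stop("track '", traj$track_id, "': fewer than 2 samples")
  if (any(dt <= 0))
    stop("track '", traj$track_id, "': time not strictly increasing")
  h <- 1 / traj$fs
  if (max(abs(dt - h)) / h > tol)
    stop("track '", traj$track_id, "': non-uniform sampling grid")
  if (!all(is.finite(traj$pos)))
    stop("track '", traj$track_id, "': non-finite position sample")
  if (nrow(traj$pos) != length(traj$t))
    stop("track '", traj$track_id, "': pos/t length mismatch")
  invisible(traj)
}

#' @export
#' @method print trajectory
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$track_id, "-", length(x$t), "samples,",
      sprintf("%.3f s", diff(range(x$t))), "\n")
  cat("  light:", x$meta$light, " pattern:", x$meta$pattern,
      " type:", x$meta$landing_type, "\n")
  invisible(x)
}

.meta_from_row <- function(row) {
  landing_metadata(light = as.character(row$light),
                   pattern = as.character(row$pattern),
                   landing_type = as.character(row$landing_type),
                   day = row$day, approach_number = row$approach_number,
                   landing_side = as.character(row$landing_side))
}

#' Read trajectories from a canonical long-format table
#'
#' The canonical CSV dialect has one row per sample with columns
#' `track_id, t_s, x_m, y_m, z_m, light, pattern, landing_type, day,
#' approach_number, landing_side`. A binary Feather container with the same
#' columns is supported when the `arrow` package is available.
#'
#' @param path file path.
#' @param format `"canonical_csv"` or `"feather"`.
#' @param fs sampling rate in Hz.
#' @return a named list of [trajectory()] objects, one per `track_id`,
#'   samples sorted by time.
#' @export
read_tracks <- function(path, format = c("canonical_csv", "feather"),
                        fs = .BEELAND_FS) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- switch(format,
    canonical_csv = read.csv(path, stringsAsFactors = FALSE),
    feather = {
      if (!requireNamespace("arrow", quietly = TRUE))
        stop("the 'arrow' package is required for format = \"feather\"")
      as.data.frame(arrow::read_feather(path))
    })
  missing_cols <- setdiff(.CSV_COLUMNS, names(df))
  if (length(missing_cols))
    stop("format error: missing column(s): ", paste(missing_cols, collapse = ", "))
  ids <- unique(df$track_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$track_id == id, , drop = FALSE]
    sub <- sub[order(sub$t_s), , drop = FALSE]
    if (any(diff(sub$t_s) <= 0))
      stop("validation error: non-monotone time in track '", id, "'")
    trajectory(id, sub$t_s, cbind(sub$x_m, sub$y_m, sub$z_m),
               meta = .meta_from_row(sub[1, ]), fs = fs)
  })
  names(out) <- ids
  out
}

#' Write trajectories to the canonical table format
#'
#' @param tracks a list of [trajectory()] objects.
#' @param path output file path.
#' @param format `"canonical_csv"` or `"feather"`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, format = c("canonical_csv", "feather")) {
  format <- match.arg(format)
  if (inherits(tracks, "trajectory")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id, t_s = tr$t,
               x_m = tr$pos[, 1], y_m = tr$pos[, 2], z_m = tr$pos[, 3],
               light = tr$meta$light, pattern = tr$meta$pattern,
               landing_type = tr$meta$landing_type, day = tr$meta$day,
               approach_number = tr$meta$approach_number,
               landing_side = tr$meta$landing_side)
  }))
  if (format == "canonical_csv") {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for format = \"feather\"")
    arrow::write_feather(df, path)
  }
  invisible(path)
}

# --- zero-phase filtering -----------------------------------------------

# Direct-form II transposed IIR filter with initial state zi (order 2).
.iir2 <- function(b, a, x, zi) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z1
    z1 <- b[2] * xi - a[2] * yi + z2
    z2 <- b[3] * xi - a[3] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-step input (so DC passes untouched).
.iir2_zi <- function(b, a) {
  g <- sum(b) / sum(a)
  z2 <- b[3] - a[3] * g
  z1 <- b[2] - a[2] * g + z2
  c(z1, z2)
}

#' Zero-phase second-order Butterworth low-pass filter
#'
#' Applies a second-order low-pass Butterworth filter forward and backward
#' (zero net phase lag, squared magnitude response). Edges are handled with
#' odd-reflection padding of three filter lengths and steady-state initial
#' conditions, so constant signals pass through unchanged.
#'
#' @param x numeric signal on a uniform grid.
#' @param cutoff cutoff frequency in Hz (must be below the Nyquist frequency).
#' @param fs sampling rate in Hz.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_lowpass <- function(x, cutoff, fs = .BEELAND_FS) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie in (0, fs/2)")
  nfact <- 6L  # 3 * (filter length - 1) for a second-order section
  if (length(x) <= 3L * nfact)
    stop("too short to filter: need more than ", 3L * nfact, " samples")
  flt <- signal::butter(2, cutoff / (fs / 2), type = "low")
  b <- flt$b; a <- flt$a
  zi <- .iir2_zi(b, a)
  n <- length(x)
  xpad <- c(2 * x[1] - x[(nfact + 1):2], x, 2 * x[n] - x[(n - 1):(n - nfact)])
  y <- .iir2(b, a, xpad, zi * xpad[1])
  y <- rev(.iir2(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1):(nfact + n)]
}

#' Low-pass filter a trajectory's position coordinates
#'
#' Filters each position coordinate with [filtfilt_lowpass()]. The default
#' 20 Hz cutoff suppresses tracking noise while preserving the manoeuvre
#' dynamics.
#'
#' @param traj a [trajectory()].
#' @param cutoff cutoff frequency in Hz.
#' @return the filtered trajectory on the same time grid.
#' @export
lowpass_track <- function(traj, cutoff = 20) {
  if (length(traj$t) < 19L)
    stop("too short to filter: track '", traj$track_id, "' has ",
         length(traj$t), " samples (< 19)")
  pos <- apply(traj$pos, 2, filtfilt_lowpass, cutoff = cutoff, fs = traj$fs)
  trajectory(traj$track_id, traj$t, pos, traj$meta, traj$fs, validate = FALSE)
}

#' Align trajectory time to touchdown
#'
#' Shifts the time axis so that t = 0 at the sample of minimum perpendicular
#' distance y (closest approach to the platform). Ties are broken to the
#' latest sample, since the final approach terminates the manoeuvre.
#'
#' @param traj a [trajectory()].
#' @return the trajectory with shifted `t`; approach samples have t < 0.
#' @export
align_touchdown <- function(traj) {
  y <- traj$pos[, 2]
  k <- max(which(y == min(y)))
  trajectory(traj$track_id, traj$t - traj$t[k], traj$pos, traj$meta, traj$fs,
             validate = FALSE)
}
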