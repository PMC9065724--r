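# Closed-loop landing simulator. The hypothesized control loop compares the
# visually measured expansion rate r with the current set-point r* and drives
# r toward it with second-order dynamics, while the position follows the
# kinematic coupling dy/dt = -r y. Set-points switch stepwise (mostly
# upward) after the current one has been reached and held for a dwell time,
# reproducing the modular structure of real landing manoeuvres. Every
# generated plateau and transient is recorded as ground truth.

#' Configuration for the synthetic landing generator
#'
#' Defaults define the study conditions emulated by the simulator: landings
#' approaching a vertical platform sampled at 175 Hz, stepwise-increasing
#' expansion-rate set-points, second-order convergence to each set-point,
#' and sub-millimetre tracking noise.
#'
#' @param n_tracks number of tracks in a cohort.
#' @param fs sampling rate in Hz.
#' @param y_start_meanlog,y_start_sdlog lognormal starting distance (m).
#' @param r_init_range uniform range of the initial expansion rate (1/s).
#' @param n_setpoints_range integer range of set-points per landing.
#' @param r1_meanlog,r1_sdlog lognormal first set-point (median 1.5 1/s).
#' @param step_range uniform range of the multiplicative set-point step.
#' @param schedule optional fixed set-point schedule (1/s); overrides the
#'   random schedule draw when non-NULL.
#' @param K controller DC gain.
#' @param D_range uniform range of the damping ratio.
#' @param w_meanlog,w_sdlog lognormal natural frequency (rad/s).
#' @param dwell_range uniform range of the at-set-point dwell time (s)
#'   before switching.
#' @param reach_tol relative proximity |r - r*| / r* counting as "reached".
#' @param noise_sd_pos additive white position noise SD in metres.
#' @param y_floor touchdown clip distance in metres.
#' @param condition_effects multiplicative effects of light and landing type
#'   on the controller natural frequency (response speed).
#' @param day_sd,side_sd,approach_sd log-scale SDs of the day / landing-side
#'   / approach-number random multipliers on the natural frequency.
#' @param n_days,n_approaches numbers of day and approach-number levels.
#' @param seed integer cohort seed.
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(n_tracks = 1L, fs = .BEELAND_FS,
                             y_start_meanlog = log(0.4), y_start_sdlog = 0.15,
                             r_init_range = c(0.15, 0.35),
                             n_setpoints_range = c(2L, 4L),
                             r1_meanlog = log(1.5), r1_sdlog = 0.25,
                             step_range = c(1.3, 2.0), schedule = NULL,
                             K = 1, D_range = c(0.8, 1.05),
                             w_meanlog = log(18), w_sdlog = 0.2,
                             dwell_range = c(0.15, 0.4), reach_tol = 0.05,
                             noise_sd_pos = 5e-4, y_floor = 0.005,
                             condition_effects = list(
                               light = c(twilight = 1, medium = 1.04, sunrise = 1.10),
                               landing_type = c(free_flight = 1, after_takeoff = 0.97)),
                             day_sd = 0.05, side_sd = 0.02, approach_sd = 0.03,
                             n_days = 4L, n_approaches = 8L, seed = 1L) {
  structure(as.list(environment()), class = "generator_config")
}

#' Simulate one closed-loop landing
#'
#' Integrates the closed loop at a 1 ms internal step with classical
#' fourth-order (RK4) stepping — r follows the second-order law toward the
#' current set-point, y follows dy/dt = -r y — then resamples to the 175 Hz
#' camera grid, adds small lateral (x, z) motion, and adds white position
#' noise. Terminates at y <= `y_floor`.
#'
#' @param cfg a [generator_config()].
#' @param track_seed integer seed; identical seeds give bit-identical tracks.
#' @param meta a [landing_metadata()] assigned to the track.
#' @param w_multiplier extra multiplier on the natural frequency (used by
#'   [simulate_cohort()] to inject condition and random effects).
#' @return a list with `trajectory` (a [trajectory()]) and `truth` (ground
#'   truth: `schedule`, `entries` data frame with per-transient
#'   `t_switch, r0, y0, r_target, delta_re, rdot_true, t_reach`,
#'   `params`, `seed`).
#' @export
simulate_landing <- function(cfg, track_seed = cfg$seed,
                             meta = landing_metadata(), w_multiplier = 1) {
  set.seed(as.integer(track_seed) %% .Machine$integer.max)
  y0 <- rlnorm(1, cfg$y_start_meanlog, cfg$y_start_sdlog)
  r0 <- runif(1, cfg$r_init_range[1], cfg$r_init_range[2])
  if (!is.null(cfg$schedule)) {
    schedule <- as.numeric(cfg$schedule)
    n_sp <- length(schedule)
  } else {
    n_sp <- sample(cfg$n_setpoints_range[1]:cfg$n_setpoints_range[2], 1)
    schedule <- numeric(n_sp)
    schedule[1] <- rlnorm(1, cfg$r1_meanlog, cfg$r1_sdlog)
    if (n_sp > 1)
      for (k in 2:n_sp)
        schedule[k] <- schedule[k - 1] * runif(1, cfg$step_range[1], cfg$step_range[2])
  }
  D <- runif(1, cfg$D_range[1], cfg$D_range[2])
  w_base <- rlnorm(1, cfg$w_meanlog, cfg$w_sdlog)
  le <- cfg$condition_effects$light[[meta$light]]
  te <- cfg$condition_effects$landing_type[[meta$landing_type]]
  w <- w_base * le * te * w_multiplier
  K <- cfg$K
  dwells <- runif(n_sp, cfg$dwell_range[1], cfg$dwell_range[2])

  dt <- 1e-3
  nmax <- as.integer(30 / dt)
  tg <- numeric(nmax); yg <- numeric(nmax); rg <- numeric(nmax)
  y <- y0; r <- r0; rd <- 0
  k_sp <- 1L
  target <- schedule[1]
  sustained <- 0
  reached_at <- NA_real_
  # per-transient truth; t_cross05 and rdot_true_eff account for the
  # r = 0.5 1/s entry start rule applied to increasing entries from below
  ent <- list(data.frame(t_switch = 0, r0 = r0, y0 = y0, r_target = target,
                         delta_re = target - r0, rdot_true = NA_real_,
                         t_reach = NA_real_, t_cross05 = NA_real_,
                         rdot_true_eff = NA_real_))
  i <- 1L
  tg[1] <- 0; yg[1] <- y; rg[1] <- r
  w2 <- w^2; tDw <- 2 * D * w; h2 <- dt / 2; h6 <- dt / 6
  while (y > cfg$y_floor && i < nmax) {
    # RK4 on (y, r, rd), inlined for speed
    Kt <- K * target
    k1y <- -r * y;                 k1r <- rd;                 k1d <- w2 * (Kt - r) - tDw * rd
    y2 <- y + h2 * k1y; r2 <- r + h2 * k1r; d2 <- rd + h2 * k1d
    k2y <- -r2 * y2;               k2r <- d2;                 k2d <- w2 * (Kt - r2) - tDw * d2
    y3 <- y + h2 * k2y; r3 <- r + h2 * k2r; d3 <- rd + h2 * k2d
    k3y <- -r3 * y3;               k3r <- d3;                 k3d <- w2 * (Kt - r3) - tDw * d3
    y4 <- y + dt * k3y; r4 <- r + dt * k3r; d4 <- rd + dt * k3d
    k4y <- -r4 * y4;               k4r <- d4;                 k4d <- w2 * (Kt - r4) - tDw * d4
    y <- y + h6 * (k1y + 2 * k2y + 2 * k3y + k4y)
    r <- r + h6 * (k1r + 2 * k2r + 2 * k3r + k4r)
    rd <- rd + h6 * (k1d + 2 * k2d + 2 * k3d + k4d)
    i <- i + 1L
    tg[i] <- (i - 1L) * dt; yg[i] <- y; rg[i] <- r
    j <- length(ent)
    if (is.na(reached_at) && is.na(ent[[j]]$t_cross05) &&
        ent[[j]]$r0 < 0.5 && r >= 0.5)
      ent[[j]]$t_cross05 <- tg[i]
    near <- abs(r - target) < cfg$reach_tol * target
    if (near) {
      if (is.na(reached_at)) {
        reached_at <- tg[i]
        ent[[j]]$t_reach <- reached_at
        ent[[j]]$rdot_true <- (r - ent[[j]]$r0) / (reached_at - ent[[j]]$t_switch)
        # effective slope: the OLS slope of the noise-free r(t) over the
        # transient window the entry-start rule defines (from the upward
        # 0.5 1/s crossing where applicable, else from the switch)
        t_from <- if (!is.na(ent[[j]]$t_cross05)) ent[[j]]$t_cross05 else
          ent[[j]]$t_switch
        sel <- which(tg[1:i] >= t_from)
        tc <- tg[sel] - mean(tg[sel])
        ent[[j]]$rdot_true_eff <- sum(tc * rg[sel]) / sum(tc^2)
      }
      sustained <- sustained + dt
      if (sustained >= dwells[k_sp] && k_sp < n_sp) {
        k_sp <- k_sp + 1L
        target <- schedule[k_sp]
        sustained <- 0
        reached_at <- NA_real_
        ent[[length(ent) + 1L]] <-
          data.frame(t_switch = tg[i], r0 = r, y0 = y, r_target = target,
                     delta_re = target - r, rdot_true = NA_real_,
                     t_reach = NA_real_, t_cross05 = NA_real_,
                     rdot_true_eff = NA_real_)
      }
    } else {
      sustained <- 0
    }
  }
  if (y > cfg$y_floor)
    stop("configuration produced no touchdown within 30 s")
  n_fine <- i
  t_end <- tg[n_fine]
  t_out <- seq(0, t_end, by = 1 / cfg$fs)
  y_out <- approx(tg[1:n_fine], yg[1:n_fine], xout = t_out)$y
  # small lateral drift + noise on x and z
  ax <- runif(1, 0.005, 0.02); fx <- runif(1, 0.3, 1.5); px <- runif(1, 0, 2 * pi)
  az <- runif(1, 0.005, 0.02); fz <- runif(1, 0.3, 1.5); pz <- runif(1, 0, 2 * pi)
  x_out <- ax * sin(2 * pi * fx * t_out + px)
  z_out <- az * sin(2 * pi * fz * t_out + pz)
  ns <- length(t_out)
  pos <- cbind(x_out + rnorm(ns, 0, cfg$noise_sd_pos),
               y_out + rnorm(ns, 0, cfg$noise_sd_pos),
               z_out + rnorm(ns, 0, cfg$noise_sd_pos))
  traj <- trajectory(paste0("synth_", track_seed), t_out, pos, meta,
                     fs = cfg$fs, validate = FALSE)
  truth <- list(schedule = schedule, entries = do.call(rbind, ent),
                params = list(K = K, D = D, w = w, w_base = w_base),
                dwells = dwells, seed = track_seed, t_end = t_end)
  list(trajectory = traj, truth = truth)
}

#' Simulate a cohort of closed-loop landings
#'
#' Generates `cfg$n_tracks` independent tracks with balanced metadata
#' (light x pattern x landing type cycled across tracks), day / side /
#' approach random multipliers on the controller natural frequency shared
#' across tracks of the same level, and per-track seeds derived
#' deterministically from the cohort seed.
#'
#' @param cfg a [generator_config()].
#' @return a list with `tracks` (list of [trajectory()]), `truths` (list of
#'   ground-truth records) and `effects` (the realized day/side/approach
#'   multipliers).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(cfg$n_tracks >= 1L)
  set.seed(as.integer(cfg$seed) %% .Machine$integer.max)
  day_eff <- rnorm(cfg$n_days, 0, cfg$day_sd)
  side_eff <- rnorm(2, 0, cfg$side_sd)
  app_eff <- rnorm(cfg$n_approaches, 0, cfg$approach_sd)
  grid <- expand.grid(light = .LIGHT_LEVELS, pattern = .PATTERN_LEVELS,
                      landing_type = .LANDING_TYPE_LEVELS,
                      stringsAsFactors = FALSE)
  tracks <- vector("list", cfg$n_tracks)
  truths <- vector("list", cfg$n_tracks)
  for (i in seq_len(cfg$n_tracks)) {
    g <- grid[((i - 1L) %% nrow(grid)) + 1L, ]
    day <- ((i - 1L) %% cfg$n_days) + 1L
    app <- ((i - 1L) %% cfg$n_approaches) + 1L
    side <- .SIDE_LEVELS[((i - 1L) %% 2L) + 1L]
    meta <- landing_metadata(light = g$light, pattern = g$pattern,
                             landing_type = g$landing_type, day = day,
                             approach_number = app, landing_side = side)
    wm <- exp(day_eff[day] + side_eff[match(side, .SIDE_LEVELS)] + app_eff[app])
    track_seed <- (as.numeric(cfg$seed) * 7919 + i * 104729) %% 2147483629
    sim <- simulate_landing(cfg, track_seed = track_seed, meta = meta,
                            w_multiplier = wm)
    tracks[[i]] <- sim$trajectory
    truths[[i]] <- sim$truth
  }
  names(tracks) <- vapply(tracks, function(tr) tr$track_id, character(1))
  list(tracks = tracks, truths = truths,
       effects = list(day = day_eff, side = side_eff, approach = app_eff))
}
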