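# Shared fixtures, built in code.

FS <- 175

# State series with a prescribed r(t); y follows dy/dt = -r y so that the
# kinematic identities hold, V = r y, A from the expansion identity.
states_from_r <- function(r, fs = FS, y0 = 0.4) {
  n <- length(r)
  t <- seq(0, by = 1 / fs, length.out = n) - (n - 1) / fs
  y <- y0 * exp(-cumsum(c(0, (r[-1] + r[-n]) / 2)) / fs)
  V <- r * y
  rdot <- beeland::differentiate(r, t)
  A <- rdot * y - V^2 / y
  structure(data.frame(t = t, y = y, V = V, A = A, r = r,
                       receding = V < 0),
            class = c("state_series", "data.frame"),
            meta = beeland::landing_metadata(), fs = fs, track_id = "fixture")
}

# Piecewise r: ramp up -> plateau -> ramp (values per segment given as
# (from, to, n_samples) rows); exact, noise added by the caller.
piecewise_r <- function(...) {
  segs <- list(...)
  unlist(lapply(segs, function(s) seq(s[1], s[2], length.out = s[3])))
}

# Canonical CSV with n tracks x n_samples, deterministic positions.
write_fixture_csv <- function(path, n_tracks = 2, n_samples = 100) {
  tracks <- lapply(seq_len(n_tracks), function(i) {
    t <- seq(0, by = 1 / FS, length.out = n_samples)
    pos <- cbind(0.01 * sin(2 * pi * t + i), 0.4 - 0.15 * t, 0.005 * cos(2 * pi * t))
    beeland::trajectory(paste0("trk", i), t, pos,
                        beeland::landing_metadata(light = c("twilight", "sunrise")[1 + i %% 2],
                                                  day = i, approach_number = i))
  })
  beeland::write_tracks(tracks, path)
  tracks
}

# OLS slope of the noise-free fine-grid r over a window (oracle used when
# matching fitted expansion-accelerations against generator truth).
match_truth_entry <- function(truth, r_star) {
  which.min(abs(truth$entries$r_target - r_star))
}
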