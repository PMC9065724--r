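test_that("a noiseless plateau flanked by ramps yields exactly one segment
           at the plateau value", {
  r <- piecewise_r(c(0.3, 2, 60), c(2, 2, 105), c(2, 3.5, 50))
  st <- states_from_r(r)
  segs <- detect_constant_r(st)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$r_star, 2, tolerance = 1e-6)
  # covers the interior of the plateau (samples 61..165), not the ramps
  expect_gte(segs$idx_start, 60)
  expect_lte(segs$idx_end, 166)
  expect_lt(segs$idx_start, 75)
  expect_gt(segs$idx_end, 150)
  # segment summary equals the segment mean exactly
  expect_equal(segs$r_star, mean(st$r[segs$idx_start:segs$idx_end]),
               tolerance = 1e-12)
})

test_that("noisy plateaus at distinct set-points are separated and
           estimated within sampling error", {
  set.seed(41)
  r <- piecewise_r(c(0.3, 1.5, 45), c(1.5, 1.5, 90), c(1.5, 3, 40),
                   c(3, 3, 90), c(3, 3.6, 25)) + rnorm(290, 0, 0.05)
  st <- states_from_r(r)
  segs <- detect_constant_r(st)
  expect_equal(nrow(segs), 2)
  n1 <- segs$idx_end[1] - segs$idx_start[1] + 1
  n2 <- segs$idx_end[2] - segs$idx_start[2] + 1
  expect_lt(abs(segs$r_star[1] - 1.5), 3 * 0.05 / sqrt(n1) + 0.02)
  expect_lt(abs(segs$r_star[2] - 3.0), 3 * 0.05 / sqrt(n2) + 0.02)
})

test_that("coverage grows monotonically with the threshold factor", {
  set.seed(42)
  r <- piecewise_r(c(0.3, 2, 50), c(2, 2, 120), c(2, 3, 40)) + rnorm(210, 0, 0.05)
  st <- states_from_r(r)
  cover <- function(segs, n) {
    z <- logical(n)
    for (i in seq_len(nrow(segs))) z[segs$idx_start[i]:segs$idx_end[i]] <- TRUE
    z
  }
  sw <- sweep_f(st, f_values = c(0.25, 0.75, 1.5, 2.5))
  covs <- lapply(sw, function(s) cover(s$segments, nrow(st)))
  for (i in seq_len(length(covs) - 1)) {
    # every covered sample at smaller f stays covered at larger f
    expect_true(all(covs[[i + 1]][covs[[i]]]))
  }
  expect_true(sw[[4]]$coverage >= sw[[1]]$coverage)
})

test_that("increasing entries start at the r = 0.5 crossing and
           decreasing entries cover the whole fall", {
  # rise from 0.2 into a plateau at 2.0
  r_up <- piecewise_r(c(0.2, 2, 80), c(2, 2, 100))
  st_up <- states_from_r(r_up)
  segs_up <- detect_constant_r(st_up)
  expect_equal(nrow(segs_up), 1)
  ent_up <- extract_entry_segment(st_up, segs_up[1, ])
  expect_false(is.null(ent_up))
  expect_identical(ent_up$direction, "increasing")
  # r = 0.5 is crossed at sample ~14 of the 80-sample ramp
  cross <- which(r_up >= 0.5)[1]
  expect_lt(abs(ent_up$idx_start - cross), 3)
  expect_gte(ent_up$r0, 0.5 - 0.05)
  expect_equal(ent_up$idx_end + 1L, segs_up$idx_start[1])
  expect_equal(sign(ent_up$delta_re), 1)

  # fall from 4.0 into a plateau at 2.0: the 0.5 rule does not apply
  r_dn <- piecewise_r(c(4, 2, 60), c(2, 2, 100))
  st_dn <- states_from_r(r_dn)
  segs_dn <- detect_constant_r(st_dn)
  ent_dn <- extract_entry_segment(st_dn, segs_dn[1, ])
  expect_false(is.null(ent_dn))
  expect_identical(ent_dn$direction, "decreasing")
  expect_lt(ent_dn$idx_start, 10)
  expect_equal(sign(ent_dn$delta_re), -1)
})

test_that("oscillating flight before a plateau yields no entry segment", {
  n_osc <- 80
  t_osc <- seq_len(n_osc) / FS
  r <- c(2 + 0.8 * sin(2 * pi * 6 * t_osc), rep(2, 100))
  st <- states_from_r(r)
  segs <- detect_constant_r(st)
  expect_gte(nrow(segs), 1)
  seg1 <- segs[which.max(segs$idx_end - segs$idx_start), ]
  ent <- extract_entry_segment(st, seg1, lower_bound = 1)
  expect_null(ent)
})

test_that("detected segments never overlap and entries abut their segment", {
  set.seed(43)
  cfg <- generator_config(n_tracks = 6, seed = 43)
  cohort <- simulate_cohort(cfg)
  for (tr in cohort$tracks) {
    res <- tryCatch(analyze_track(tr), error = function(e) NULL)
    if (is.null(res) || nrow(res$segments) < 1) next
    segs <- res$segments
    if (nrow(segs) > 1)
      expect_true(all(segs$idx_start[-1] > segs$idx_end[-nrow(segs)]))
    for (e in res$entries) {
      expect_equal(e$idx_end + 1L, segs$idx_start[e$seg_index])
      expect_equal(sign(e$delta_re),
                   if (e$direction == "increasing") 1 else -1)
    }
  }
})

test_that("empty and degenerate inputs give empty segment tables", {
  st <- states_from_r(rep(1.2, 10))   # shorter than min_duration
  expect_equal(nrow(detect_constant_r(st)), 0)
  st2 <- states_from_r(piecewise_r(c(0.2, 4, 120)))  # pure ramp
  expect_equal(nrow(detect_constant_r(st2)), 0)
})
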