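test_that("thresholded amplitude runs map to tiling segments", {
  # 9 points, smooth 1 -> 8 angles, tau_max 4 -> 5 windows
  traj <- line_traj(9, dx = 0.1)
  amp <- c(0, 0, 9, 9, 0)
  seg <- segment_motion(traj, amp, threshold = 5, tau_max = 4,
                        alignment = "start")
  expect_equal(seg$state, c("stationary", "transport", "stationary"))
  expect_equal(seg$start_index, c(1, 3, 5))
  expect_equal(seg$end_index, c(2, 4, 5))
  # no overlap, no gap
  expect_true(all(seg$start_index[-1] == seg$end_index[-nrow(seg)] + 1))

  below <- segment_motion(traj, rep(1, 5), threshold = 5, tau_max = 4,
                          alignment = "start")
  expect_equal(nrow(below), 1)
  expect_equal(below$state, "stationary")
})

test_that("ties at the threshold count as stationary", {
  traj <- line_traj(9, dx = 0.1)
  seg <- segment_motion(traj, rep(5, 5), threshold = 5, tau_max = 4)
  expect_equal(seg$state, "stationary")
})

test_that("segment distance, duration and velocity are consistent", {
  traj <- line_traj(20, dx = 0.05, dt = 10)  # 5 um/s straight line
  amp <- rep(10, 20 - 1 - 4 + 1)
  seg <- segment_motion(traj, amp, threshold = 5, tau_max = 4,
                        alignment = "start")
  expect_equal(seg$state, "transport")
  expect_equal(seg$velocity_um_per_s,
               seg$distance_um / (seg$duration_ms / 1000))
  # straight noise-free line: net displacement equals path length
  expect_equal(seg$distance_um, seg$path_length_um)
  expect_equal(seg$velocity_um_per_s, 5)
})

test_that("inconsistent amplitude length is a domain error", {
  traj <- line_traj(9)
  expect_error(segment_motion(traj, rep(0, 7), threshold = 1, tau_max = 4),
               "inconsistent", class = "orbitrack_domain_error")
})

test_that("short label runs are absorbed by the minimum-length filter", {
  traj <- line_traj(40, dx = 0.1)
  amp <- rep(0, 40 - 1 - 4 + 1)
  amp[10] <- 9            # single-window blip
  amp[20:32] <- 9         # sustained event
  seg <- segment_motion(traj, amp, threshold = 5, tau_max = 4,
                        min_windows = 5, alignment = "start")
  tr <- seg[seg$state == "transport", ]
  expect_equal(nrow(tr), 1)
  expect_equal(tr$start_index, 20)
})

test_that("the pipeline is rotation-covariant", {
  plan <- random_recovery_scenario(101)
  traj <- simulate_trajectory(plan, jitter_sigma_um = 0.05, seed = 7)
  a <- pi / 5
  rot <- dplyr::mutate(traj,
    x_new = cos(a) * x_um - sin(a) * y_um,
    y_new = sin(a) * x_um + cos(a) * y_um,
    x_um = x_new, y_um = y_new)
  f1 <- analyze_track(traj, n_shuffles = 10, seed = 3)
  f2 <- analyze_track(rot, n_shuffles = 10, seed = 3)
  expect_equal(f2$angles$phi, f1$angles$phi, tolerance = 1e-9)
  expect_equal(f2$carpet, f1$carpet, tolerance = 1e-9)
  expect_equal(f2$amplitude$amplitude, f1$amplitude$amplitude, tolerance = 1e-9)
  expect_equal(as.data.frame(f2$segments[, c("state", "start_index", "end_index")]),
               as.data.frame(f1$segments[, c("state", "start_index", "end_index")]))
})

test_that("mirroring across the axis negates angles but preserves carpet and amplitude", {
  plan <- random_recovery_scenario(102)
  traj <- simulate_trajectory(plan, jitter_sigma_um = 0.05, seed = 8)
  axis <- reference_axis(traj)
  # reflect across the chord through the origin-shifted track
  ax <- axis[1]; ay <- axis[2]
  x0 <- traj$x_um - traj$x_um[1]; y0 <- traj$y_um - traj$y_um[1]
  mir <- dplyr::mutate(traj,
    x_um = (ax^2 - ay^2) * x0 + 2 * ax * ay * y0 + traj$x_um[1],
    y_um = 2 * ax * ay * x0 - (ax^2 - ay^2) * y0 + traj$y_um[1])
  a1 <- lateral_angles(traj, smooth_points = 8)
  a2 <- lateral_angles(mir, smooth_points = 8)
  flip <- a1$phi == pi  # boundary angle maps to itself, not to -pi
  expect_equal(a2$phi[!flip], -a1$phi[!flip], tolerance = 1e-9)
  expect_equal(correlation_carpet(a2, 32), correlation_carpet(a1, 32),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("analysis is deterministic given a seed and leaves the RNG state alone", {
  plan <- random_recovery_scenario(103)
  traj <- simulate_trajectory(plan, jitter_sigma_um = 0.05, seed = 9)
  before <- withr::with_seed(1, runif(1))
  set.seed(1)
  f1 <- analyze_track(traj, n_shuffles = 10, seed = 11)
  f2 <- analyze_track(traj, n_shuffles = 10, seed = 11)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$threshold$threshold, f2$threshold$threshold)
  expect_equal(runif(1), before)  # seed argument did not consume the stream
})

test_that("segments tile the analyzable range for random amplitudes", {
  for (seed in 1:8) {
    traj <- line_traj(120, dx = 0.02)
    nw <- 120 - 1 - 16 + 1
    amp <- withr::with_seed(seed, runif(nw, -1, 1))
    seg <- segment_motion(traj, amp, threshold = 0.5, tau_max = 16,
                          min_windows = sample(1:6, 1))
    expect_equal(seg$start_index[1], 1 + 16 %/% 2)
    expect_equal(seg$end_index[nrow(seg)], nw + 16 %/% 2)
    if (nrow(seg) > 1) {
      expect_true(all(seg$start_index[-1] == seg$end_index[-nrow(seg)] + 1))
    }
  }
})

test_that("a pure pause trajectory yields no transport events", {
  sc <- scenario_preset("null")
  hits <- vapply(1:6, function(seed) {
    traj <- simulate_scenario(sc, seed = seed)
    fit <- analyze_track(traj, n_shuffles = 30, seed = seed + 500)
    sum(fit$segments$state == "transport")
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.05)
})

test_that("run/pause structure is recovered with accurate velocities", {
  plan <- random_recovery_scenario(7)
  traj <- simulate_trajectory(plan, jitter_sigma_um = 0.05, seed = 77)
  fit <- analyze_track(traj, seed = 78)
  sc <- score_events(tidy(fit), traj$state)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_equal(sc$n_events, sum(plan$state == "run"))

  # matched event velocities within 20% of the planned speeds
  tr <- dplyr::filter(tidy(fit), state == "transport")
  runs <- dplyr::filter(plan, state == "run")
  truth_runs <- which(rle(traj$state == "run")$values)
  r <- rle(traj$state == "run")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (j in seq_len(nrow(tr))) {
    mid <- (tr$start_index[j] + tr$end_index[j]) / 2
    k <- which(starts <= mid & ends >= mid & r$values)
    expect_length(k, 1)
    true_speed <- runs$speed_um_per_s[match(k, which(r$values))]
    expect_lt(abs(tr$velocity_um_per_s[j] - true_speed) / true_speed, 0.2)
  }
})

test_that("detected event boundaries fall within half a window of the truth", {
  plan <- random_recovery_scenario(8)
  traj <- simulate_trajectory(plan, jitter_sigma_um = 0.05, seed = 88)
  fit <- analyze_track(traj, seed = 89)
  tr <- dplyr::filter(tidy(fit), state == "transport")
  r <- rle(traj$state == "run")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  gs <- starts[r$values]; ge <- ends[r$values]
  expect_equal(nrow(tr), length(gs))
  for (j in seq_len(nrow(tr))) {
    k <- which.min(abs(gs - tr$start_index[j]))
    expect_lte(abs(tr$start_index[j] - gs[k]), 32)
    expect_lte(abs(tr$end_index[j] - ge[k]), 32)
  }
})

test_that("glance and point_states summarize the segmentation consistently", {
  plan <- random_recovery_scenario(9)
  traj <- simulate_trajectory(plan, jitter_sigma_um = 0.05, seed = 99)
  fit <- analyze_track(traj, n_shuffles = 20, seed = 100)
  g <- glance(fit)
  expect_equal(g$n_transport + g$n_stationary, nrow(tidy(fit)))
  expect_identical(g$threshold, fit$threshold$threshold)
  ps <- point_states(fit)
  expect_equal(nrow(ps), nrow(fit$trajectory))
  covered <- !is.na(ps$state)
  expect_equal(sum(covered),
               sum(tidy(fit)$end_index - tidy(fit)$start_index + 1))
})
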