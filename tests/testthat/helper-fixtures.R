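# In-code fixtures shared across tests.

header_lines_fixture <- function(long_range = 1, lr_threshold = "0.5882",
                                 drop = NULL) {
  lines <- c(
    "File Path C:\\data\\mito01.txt",
    "Date 17.06.2019",
    "Time 14:02:11",
    "Orbit Time [ms]\t5.000",
    "Orbit Radius [V]\t0.050000",
    "Tracking Threshold [Hz]\t10000",
    "Delay Orbits\t1",
    "Number of Particles\t1",
    paste("Long Range", long_range),
    paste("Long Range Threshold [V]", lr_threshold)
  )
  if (!is.null(drop)) lines <- lines[-drop]
  lines
}

# random but valid record table; voltages within +-1 V, intervals ~10 ms
random_records <- function(n, delay_orbits = 1, seed = NULL) {
  gen <- function() {
    tibble::tibble(
      x_V = round(stats::runif(n, -1, 1), 6),
      y_V = round(stats::runif(n, -1, 1), 6),
      z_V = round(stats::runif(n, -0.5, 0.5), 6),
      orbit_number = as.integer(cumsum(sample(1:(1 + delay_orbits), n, TRUE))),
      orbit_interval_ms = round(stats::runif(n, 5, 80), 3),
      intensity_det1 = round(stats::runif(n, 0, 500), 3),
      intensity_det2 = round(stats::runif(n, 0, 500), 3),
      camera_frame = sample(0:99, n, TRUE),
      tracking_active = stats::runif(n) > 0.1,
      reposition_x = stats::runif(n) > 0.9,
      reposition_y = stats::runif(n) > 0.9
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# straight-line trajectory tibble in physical units
line_traj <- function(n, dx = 0.1, dy = 0, dt = 10) {
  tibble::tibble(
    point = seq_len(n),
    x_um = (seq_len(n) - 1) * dx,
    y_um = (seq_len(n) - 1) * dy,
    z_um = 0,
    t_ms = (seq_len(n) - 1) * dt,
    tracking_inactive = FALSE, repositioning = FALSE
  )
}

# independent brute-force oracle for the windowed angle correlation:
# naive double loop over window starts and lags, no shared code with the
# package implementation
carpet_oracle <- function(phi, tau_max, norm = "window") {
  n <- length(phi)
  nw <- n - tau_max + 1
  out <- matrix(NA_real_, nw, tau_max - 1)
  for (t in seq_len(nw)) {
    for (tau in seq_len(tau_max - 1)) {
      acc <- 0
      for (i in t:(t + tau_max - tau - 1)) acc <- acc + phi[i] * phi[i + tau]
      denom <- if (norm == "window") tau_max - tau else n - tau
      out[t, tau] <- acc / denom
    }
  }
  out
}

# event-level scoring of a segmentation against ground-truth labels:
# a true run counts as recalled when at least `cover` of its points are
# labeled transport; a detected event counts as correct when at least
# `cover` of its points lie inside true runs
score_events <- function(segments, truth_state, cover = 0.5) {
  n <- length(truth_state)
  lab <- rep(FALSE, n)
  tr <- segments[segments$state == "transport", , drop = FALSE]
  for (i in seq_len(nrow(tr))) lab[tr$start_index[i]:tr$end_index[i]] <- TRUE
  r <- rle(truth_state == "run")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  recall <- if (length(runs)) {
    mean(vapply(runs, function(i) mean(lab[starts[i]:ends[i]]) >= cover, logical(1)))
  } else NA_real_
  precision <- if (nrow(tr)) {
    mean(vapply(seq_len(nrow(tr)), function(j) {
      mean(truth_state[tr$start_index[j]:tr$end_index[j]] == "run") >= cover
    }, logical(1)))
  } else NA_real_
  list(recall = recall, precision = precision, n_events = nrow(tr),
       n_runs = length(runs))
}

# random curved-axon recovery scenario: even number of alternating runs so
# every run heading sits symmetrically off the chord
random_recovery_scenario <- function(seed) {
  withr::with_seed(seed, {
    n_runs <- sample(c(2L, 4L), 1)
    speeds <- stats::runif(n_runs, 0.5, 2)
    thetas <- stats::runif(n_runs, 55, 75) * rep(c(1, -1), length.out = n_runs)
    # one displacement per scenario: balanced runs keep the chord on the
    # bisector, so realized chord offsets equal the planned headings
    disp_um <- stats::runif(1, 3, 4.5)
    run_len <- pmax(150L, as.integer(round(disp_um / (speeds * 0.01))))
    pause_len <- sample(130:200, n_runs + 1, TRUE)
    segment_plan(
      state = c(rep(c("pause", "run"), n_runs), "pause"),
      duration_points = c(rbind(pause_len[-length(pause_len)], run_len),
                          pause_len[length(pause_len)]),
      speed_um_per_s = c(rbind(0, speeds), 0),
      heading_deg = c(rbind(0, thetas), 0)
    )
  })
}
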