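# Segmentation of a trajectory into transport events and stationary phases
# from the thresholded correlation amplitude.

# flip maximal runs shorter than `min_len` (shortest first) until none remain;
# events shorter than the correlation window cannot be resolved by a
# tau_max-window statistic, and threshold-crossing flicker at event edges
# otherwise fragments single runs into many spurious events
enforce_min_run <- function(lab, min_len) {
  if (min_len <= 1 || !length(lab)) return(lab)
  repeat {
    r <- rle(lab)
    len <- r$lengths
    if (length(len) == 1 || all(len >= min_len)) return(lab)
    ends <- cumsum(len)
    starts <- ends - len + 1
    i <- which(len < min_len)
    i <- i[which.min(len[i])]
    lab[starts[i]:ends[i]] <- !r$values[i]
  }
}

#' Segment a trajectory by thresholded correlation amplitude
#'
#' Labels each correlation window as transport when its amplitude strictly
#' exceeds the threshold (ties count as stationary), merges runs shorter
#' than `min_windows` into their surroundings, maps window indices back to
#' trajectory points, and summarizes each maximal run as one segment.
#' Segments tile the analyzable point range without overlap.
#'
#' Window-to-point mapping: window start `t` is assigned to the trajectory
#' point at the center of the data that produced it,
#' `t + tau_max/2 + smooth_points/2` (`alignment = "center"`), or to the
#' window start itself (`alignment = "start"`).
#'
#' Per segment, `duration_ms` comes from the timestamps, `distance_um` is
#' the net xy displacement between the segment end points,
#' `path_length_um` is the summed point-to-point xy step length (inflated
#' by localization noise, reported for completeness), and
#' `velocity_um_per_s = distance_um / (duration_ms / 1000)`.
#'
#' @param traj Physical trajectory tibble ([as_physical()] or
#'   [simulate_trajectory()]).
#' @param amplitude Numeric amplitude series from [correlation_amplitude()],
#'   computed from `traj` with the same `tau_max`, `smooth_points` and
#'   `exclude_inactive` settings.
#' @param threshold Scalar threshold `T`, or an `orbit_threshold` object.
#' @param tau_max Correlation window size used for `amplitude`.
#' @param smooth_points Displacement lag used for the angle series.
#' @param alignment `"center"` (default) or `"start"`; see Details.
#' @param min_windows Minimum run length in windows; shorter runs are
#'   absorbed. Use 1 to disable.
#' @param exclude_inactive Must match the setting used for the angles.
#'
#' @return A tibble with one row per segment: `state` ("transport" or
#'   "stationary"), `start_index`, `end_index` (inclusive point indices into
#'   the analyzed trajectory), `start_ms`, `end_ms`, `duration_ms`,
#'   `n_points`, `distance_um`, `path_length_um`, `velocity_um_per_s`.
#' @export
segment_motion <- function(traj, amplitude, threshold, tau_max = 64,
                           smooth_points = 1,
                           alignment = c("center", "start"),
                           min_windows = 1, exclude_inactive = TRUE) {
  alignment <- match.arg(alignment)
  traj <- filter_active(traj, exclude_inactive)
  if (inherits(threshold, "orbit_threshold")) threshold <- threshold$threshold
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  tau_max <- as.integer(tau_max)
  m <- as.integer(smooth_points)
  n <- nrow(traj)
  n_phi <- n - m
  nw_expected <- n_phi - tau_max + 1
  if (length(amplitude) != nw_expected) {
    abort_domain(sprintf(
      "Amplitude length %d is inconsistent with %d trajectory points (expected %d windows for tau_max = %d, smooth_points = %d).",
      length(amplitude), n, nw_expected, tau_max, m))
  }
  lab <- amplitude > threshold
  lab <- enforce_min_run(lab, min_windows)
  off <- if (alignment == "center") tau_max %/% 2 + m %/% 2 else 0L
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- purrr::map_dfr(seq_along(r$values), function(i) {
    s <- min(starts[i] + off, n)
    e <- min(ends[i] + off, n)
    idx <- s:e
    dur <- traj$t_ms[e] - traj$t_ms[s]
    net <- sqrt((traj$x_um[e] - traj$x_um[s])^2 + (traj$y_um[e] - traj$y_um[s])^2)
    path <- if (e > s) {
      sum(sqrt(diff(traj$x_um[idx])^2 + diff(traj$y_um[idx])^2))
    } else 0
    tibble::tibble(
      state = if (r$values[i]) "transport" else "stationary",
      start_index = s, end_index = e,
      start_ms = traj$t_ms[s], end_ms = traj$t_ms[e],
      duration_ms = dur, n_points = e - s + 1L,
      distance_um = net, path_length_um = path,
      velocity_um_per_s = if (dur > 0) net / (dur / 1000) else 0
    )
  })
  seg
}

#' Full correlation analysis of a trajectory
#'
#' Runs the complete pipeline on a calibrated trajectory: lateral angles
#' against the chord axis, sliding-window correlation carpet, amplitude,
#' permutation-null threshold and segmentation into transport events and
#' stationary phases. Deterministic for a given `seed`.
#'
#' Points flagged `tracking_inactive` (instrument search mode) are excluded
#' before the analysis; repositioning-flagged points are kept, since stored
#' positions are already corrected for stage moves.
#'
#' @inheritParams segment_motion
#' @inheritParams randomized_threshold
#' @param traj Physical trajectory tibble.
#' @param smooth_points Displacement lag for the angle series (points). The
#'   default 16 targets recordings whose per-interval steps are below the
#'   localization precision (e.g. 5-20 nm steps against ~50 nm noise at
#'   10 ms sampling); set to 1 for raw consecutive-orbit angles.
#' @param min_windows Minimum segment length in windows; defaults to
#'   `tau_max / 2` (events shorter than the correlation window are not
#'   resolvable).
#' @param axis Optional explicit reference axis (unit 2-vector); defaults
#'   to the trajectory chord.
#'
#' @return An object of class `orbit_analysis`: a list with `segments`
#'   (tibble), `amplitude` (tibble: `window`, `point_index`, `t_ms`,
#'   `amplitude`, `transport`), `carpet` (matrix), `threshold`
#'   (`orbit_threshold`), `angles` (tibble), `trajectory` (the analyzed
#'   points) and `params`. Use [tidy()] for the segment table, [glance()]
#'   for a one-row summary, and [autoplot()] to visualize.
#'
#' @examples
#' sc <- scenario_preset("retrograde")
#' traj <- simulate_trajectory(sc$plan, jitter_sigma_um = sc$jitter_sigma_um,
#'                             seed = 1)
#' fit <- analyze_track(traj, seed = 1)
#' tidy(fit)
#' glance(fit)
#' @export
analyze_track <- function(traj, tau_max = 64, w = 5, n_shuffles = 100,
                          smooth_points = 16,
                          norm = c("window", "global"),
                          alignment = c("center", "start"),
                          min_windows = tau_max %/% 2,
                          axis = NULL, seed = NULL,
                          exclude_inactive = TRUE) {
  norm <- match.arg(norm)
  alignment <- match.arg(alignment)
  traj <- filter_active(traj, exclude_inactive)
  if (!nrow(traj)) abort_domain("No analyzable points (all flagged tracking-inactive).")
  angles <- lateral_angles(traj, axis = axis, smooth_points = smooth_points,
                           exclude_inactive = FALSE)
  carpet <- correlation_carpet(angles, tau_max = tau_max, norm = norm)
  amplitude <- correlation_amplitude(carpet)
  thr <- randomized_threshold(angles, tau_max = tau_max, w = w,
                              n_shuffles = n_shuffles, norm = norm, seed = seed)
  segments <- segment_motion(traj, amplitude, thr, tau_max = tau_max,
                             smooth_points = smooth_points,
                             alignment = alignment, min_windows = min_windows,
                             exclude_inactive = FALSE)
  off <- if (alignment == "center") tau_max %/% 2 + smooth_points %/% 2 else 0L
  pt <- pmin(seq_along(amplitude) + off, nrow(traj))
  amp_tbl <- tibble::tibble(
    window = seq_along(amplitude),
    point_index = pt,
    t_ms = traj$t_ms[pt],
    amplitude = amplitude,
    transport = amplitude > thr$threshold
  )
  structure(
    list(segments = segments, amplitude = amp_tbl, carpet = carpet,
         threshold = thr, angles = angles, trajectory = traj,
         params = list(tau_max = as.integer(tau_max), w = w,
                       n_shuffles = as.integer(n_shuffles),
                       smooth_points = as.integer(smooth_points),
                       norm = norm, alignment = alignment,
                       min_windows = as.integer(min_windows),
                       seed = seed)),
    class = "orbit_analysis"
  )
}

#' @export
print.orbit_analysis <- function(x, ...) {
  ntr <- sum(x$segments$state == "transport")
  cat(sprintf("<orbit_analysis> %d points, %d windows (tau_max = %d, w = %g)\n",
              nrow(x$trajectory), nrow(x$amplitude), x$params$tau_max,
              x$params$w))
  cat(sprintf("  threshold T = %.4g (M = %.4g, sigma = %.4g)\n",
              x$threshold$threshold, x$threshold$null_mean, x$threshold$null_sd))
  cat(sprintf("  %d transport event(s), %d stationary phase(s)\n",
              ntr, sum(x$segments$state == "stationary")))
  if (ntr) {
    tr <- dplyr::filter(x$segments, .data$state == "transport")
    cat(sprintf("  transport: %.2f um total, velocities %.3g-%.3g um/s\n",
                sum(tr$distance_um), min(tr$velocity_um_per_s),
                max(tr$velocity_um_per_s)))
  }
  invisible(x)
}

#' Tidy the segment table of an analysis
#'
#' @param x An `orbit_analysis` object.
#' @param ... Unused.
#' @return The segment tibble (see [segment_motion()]).
#' @exportS3Method generics::tidy
tidy.orbit_analysis <- function(x, ...) x$segments

#' One-row summary of an analysis
#'
#' @param x An `orbit_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble: point/window counts, parameters, threshold
#'   statistics, number of transport events, total transport distance and
#'   time fraction, and the mean transport velocity.
#' @exportS3Method generics::glance
glance.orbit_analysis <- function(x, ...) {
  tr <- dplyr::filter(x$segments, .data$state == "transport")
  total_ms <- diff(range(x$trajectory$t_ms))
  tibble::tibble(
    n_points = nrow(x$trajectory),
    n_windows = nrow(x$amplitude),
    tau_max = x$params$tau_max,
    w = x$params$w,
    smooth_points = x$params$smooth_points,
    threshold = x$threshold$threshold,
    null_mean = x$threshold$null_mean,
    null_sd = x$threshold$null_sd,
    n_transport = nrow(tr),
    n_stationary = sum(x$segments$state == "stationary"),
    transport_distance_um = sum(tr$distance_um),
    transport_time_fraction = if (total_ms > 0) sum(tr$duration_ms) / total_ms else 0,
    mean_transport_velocity_um_per_s =
      if (nrow(tr)) stats::weighted.mean(tr$velocity_um_per_s, tr$duration_ms) else NA_real_
  )
}

#' Per-point motion-state labels of an analysis
#'
#' @param x An `orbit_analysis` object.
#' @return A tibble `point_index`, `t_ms`, `state` covering the analyzable
#'   range (points outside it get `NA`).
#' @export
point_states <- function(x) {
  stopifnot(inherits(x, "orbit_analysis"))
  n <- nrow(x$trajectory)
  state <- rep(NA_character_, n)
  for (i in seq_len(nrow(x$segments))) {
    state[x$segments$start_index[i]:x$segments$end_index[i]] <- x$segments$state[i]
  }
  tibble::tibble(point_index = seq_len(n), t_ms = x$trajectory$t_ms, state = state)
}
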