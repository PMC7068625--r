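# Ground-truth trajectory simulator: alternating directed runs and pauses
# with localization noise, written out in the instrument's raw dialect so
# the whole pipeline can be exercised without real recordings.

#' Run/pause plan for a synthetic trajectory
#'
#' Describes the motion program segment by segment. Runs advance at constant
#' speed along a per-segment heading (so curved paths, where run headings
#' differ from the overall chord, can be generated); pauses have zero drift.
#'
#' @param state Character vector of `"run"` / `"pause"`.
#' @param duration_points Positive integer vector, segment lengths in data
#'   points.
#' @param speed_um_per_s Speeds in um/s; must be 0 for pauses.
#' @param heading_deg Run directions in degrees relative to the global x
#'   axis (ignored for pauses).
#'
#' @return A tibble of class `segment_plan`.
#' @examples
#' segment_plan(
#'   state = c("pause", "run", "pause", "run", "pause"),
#'   duration_points = c(150, 220, 150, 220, 150),
#'   speed_um_per_s = c(0, 0.8, 0, 0.6, 0),
#'   heading_deg = c(0, 65, 0, -65, 0)
#' )
#' @export
segment_plan <- function(state, duration_points, speed_um_per_s = 0,
                         heading_deg = 0) {
  plan <- tibble::tibble(
    state = as.character(state),
    duration_points = as.integer(duration_points),
    speed_um_per_s = as.numeric(speed_um_per_s),
    heading_deg = as.numeric(heading_deg)
  )
  if (!nrow(plan)) abort_domain("A segment plan needs at least one segment.")
  if (!all(plan$state %in% c("run", "pause"))) {
    abort_domain("Plan states must be 'run' or 'pause'.")
  }
  if (any(is.na(plan$duration_points) | plan$duration_points < 1)) {
    abort_domain("Segment durations must be positive integers (points).")
  }
  if (any(plan$state == "pause" & plan$speed_um_per_s != 0)) {
    abort_domain("Pause segments must have speed 0.")
  }
  if (any(plan$state == "run" & plan$speed_um_per_s < 0)) {
    abort_domain("Run speeds must be non-negative.")
  }
  class(plan) <- c("segment_plan", class(plan))
  plan
}

#' Acquisition settings for the simulator
#'
#' Timing, long-range-repositioning and calibration parameters used when
#' generating timestamps and when exporting a synthetic trajectory to the
#' raw voltage format. Defaults reproduce the standard recording settings:
#' 5 ms orbits, one dark orbit (10 ms effective sampling), stage
#' repositioning beyond 0.5882 V (10.18 um laterally) taking 30-70 ms.
#'
#' @param orbit_time_ms Orbit duration in ms.
#' @param delay_orbits Dark orbits interleaved per written record.
#' @param long_range_enabled Whether to emulate stage repositioning events.
#' @param long_range_threshold_V Galvanometer voltage at which the stage
#'   recenters.
#' @param calibration A [calibration()] object.
#' @param reposition_pause_ms Length-2 range (ms) from which the duration
#'   of a repositioning event is drawn uniformly.
#'
#' @return A list of class `acquisition_model`.
#' @export
acquisition_model <- function(orbit_time_ms = 5, delay_orbits = 1,
                              long_range_enabled = TRUE,
                              long_range_threshold_V = 0.5882,
                              calibration = orbitrack::calibration(),
                              reposition_pause_ms = c(30, 70)) {
  stopifnot(orbit_time_ms > 0, delay_orbits >= 0,
            long_range_threshold_V > 0,
            length(reposition_pause_ms) == 2,
            reposition_pause_ms[1] <= reposition_pause_ms[2])
  structure(
    list(orbit_time_ms = orbit_time_ms, delay_orbits = as.integer(delay_orbits),
         long_range_enabled = isTRUE(long_range_enabled),
         long_range_threshold_V = long_range_threshold_V,
         calibration = calibration,
         reposition_pause_ms = as.numeric(reposition_pause_ms)),
    class = "acquisition_model"
  )
}

#' Simulate a ground-truth trajectory
#'
#' Builds positions segment by segment from a [segment_plan()]: runs take
#' constant-speed steps along their heading (with optional per-step heading
#' wobble), pauses stay put (optionally wiggling as a random walk with step
#' `pause_step_sigma_um`, emulating a tethered but mobile particle).
#' Isotropic Gaussian localization noise `jitter_sigma_um` is then added to
#' every position -- the dominant error in orbital tracking is localization,
#' not diffusion. Timestamps advance at the effective sampling interval of
#' `acquisition` and orbit numbers skip the dark orbits.
#'
#' @param plan A [segment_plan()].
#' @param acquisition An [acquisition_model()].
#' @param jitter_sigma_um Isotropic per-point localization noise (um).
#' @param heading_wobble_deg Per-step directional noise during runs
#'   (degrees, sd).
#' @param pause_step_sigma_um Random-walk step sd during pauses (um); 0 for
#'   perfectly still pauses.
#' @param seed Optional integer for reproducible noise.
#'
#' @return A tibble with columns `point`, `orbit_number`, `t_ms`, `x_um`,
#'   `y_um`, `z_um` (always 0), `tracking_inactive`, `repositioning` (both
#'   FALSE) and the ground-truth label `state`.
#' @export
simulate_trajectory <- function(plan, acquisition = acquisition_model(),
                                jitter_sigma_um = 0.05,
                                heading_wobble_deg = 0,
                                pause_step_sigma_um = 0,
                                seed = NULL) {
  if (!inherits(plan, "segment_plan")) {
    plan <- do.call(segment_plan, as.list(plan))
  }
  dt_ms <- effective_sampling_interval(acquisition)
  n <- sum(plan$duration_points)
  states <- rep(plan$state, plan$duration_points)
  speeds <- rep(plan$speed_um_per_s, plan$duration_points)
  headings <- rep(plan$heading_deg, plan$duration_points) * pi / 180
  with_optional_seed(seed, {
    wobble <- if (heading_wobble_deg > 0) {
      rnorm(n, 0, heading_wobble_deg * pi / 180)
    } else rep(0, n)
    step_len <- speeds * dt_ms / 1000
    sx <- step_len * cos(headings + wobble)
    sy <- step_len * sin(headings + wobble)
    pause <- states == "pause"
    if (pause_step_sigma_um > 0) {
      sx[pause] <- rnorm(sum(pause), 0, pause_step_sigma_um)
      sy[pause] <- rnorm(sum(pause), 0, pause_step_sigma_um)
    } else {
      sx[pause] <- 0
      sy[pause] <- 0
    }
    # point i is reached by the step belonging to point i; point 1 is the origin
    x <- cumsum(c(0, sx[-1]))
    y <- cumsum(c(0, sy[-1]))
    if (jitter_sigma_um > 0) {
      x <- x + rnorm(n, 0, jitter_sigma_um)
      y <- y + rnorm(n, 0, jitter_sigma_um)
    }
    tibble::tibble(
      point = seq_len(n),
      orbit_number = as.integer((seq_len(n) - 1) * (1 + acquisition$delay_orbits)),
      t_ms = (seq_len(n) - 1) * dt_ms,
      x_um = x, y_um = y, z_um = 0,
      tracking_inactive = FALSE, repositioning = FALSE,
      state = states
    )
  })
}

#' Export a simulated trajectory to the raw voltage format
#'
#' Writes a trajectory as an instrument-style raw file: positions divided by
#' the calibration factors into galvanometer volts, orbit numbers skipping
#' `delay_orbits` dark orbits between written rows, constant synthetic
#' intensity columns, and -- when long-range tracking is enabled --
#' repositioning events. The galvanometer offset (particle position minus
#' stage position) is simulated along the track; whenever its magnitude on
#' an axis crosses `long_range_threshold_V` the row's reposition flag for
#' that axis is set, the row's orbit interval is drawn from
#' `reposition_pause_ms`, and the simulated stage recenters. Stored
#' voltages are the stage-corrected (continuous) positions, as in real
#' files, so conversion back through [as_physical()] reproduces the
#' generated positions to within the write precision.
#'
#' @param traj Trajectory tibble from [simulate_trajectory()].
#' @param path Output path for the raw `.txt` file.
#' @param acquisition An [acquisition_model()].
#' @param labels_path Optional path for a ground-truth CSV
#'   (`point, orbit_number, t_ms, state`) written beside the raw file.
#' @param seed Optional integer seeding the repositioning-pause draws.
#'
#' @return The header actually written (invisibly).
#' @export
write_raw_trajectory <- function(traj, path, acquisition = acquisition_model(),
                                 labels_path = NULL, seed = NULL) {
  stopifnot(all(c("x_um", "y_um", "z_um", "t_ms") %in% names(traj)))
  cal <- acquisition$calibration
  n <- nrow(traj)
  if (!n) abort_domain("Cannot export an empty trajectory.")
  dt_ms <- effective_sampling_interval(acquisition)
  x_V <- traj$x_um / cal$lateral_um_per_V
  y_V <- traj$y_um / cal$lateral_um_per_V
  z_V <- traj$z_um / cal$axial_um_per_V
  interval <- rep(dt_ms, n)
  rep_x <- rep(FALSE, n)
  rep_y <- rep(FALSE, n)
  if (acquisition$long_range_enabled && n > 1) {
    with_optional_seed(seed, {
      stage_x <- 0; stage_y <- 0
      thr <- acquisition$long_range_threshold_V
      for (i in seq_len(n)) {
        if (abs(x_V[i] - stage_x) > thr) {
          rep_x[i] <- TRUE
          stage_x <- x_V[i]
        }
        if (abs(y_V[i] - stage_y) > thr) {
          rep_y[i] <- TRUE
          stage_y <- y_V[i]
        }
        if (rep_x[i] || rep_y[i]) {
          interval[i] <- runif(1, acquisition$reposition_pause_ms[1],
                               acquisition$reposition_pause_ms[2])
        }
      }
    })
  }
  header <- orbit_header(
    file_path = path,
    orbit_time_ms = acquisition$orbit_time_ms,
    delay_orbits = acquisition$delay_orbits,
    long_range_enabled = acquisition$long_range_enabled,
    long_range_threshold_V = acquisition$long_range_threshold_V
  )
  records <- tibble::tibble(
    x_V = x_V, y_V = y_V, z_V = z_V,
    orbit_number = as.integer((seq_len(n) - 1) * (1 + acquisition$delay_orbits)),
    orbit_interval_ms = interval,
    intensity_det1 = 100, intensity_det2 = 80,
    camera_frame = 0L,
    tracking_active = TRUE,
    reposition_x = rep_x, reposition_y = rep_y
  )
  write_orbit_file(header, records, path)
  if (!is.null(labels_path)) {
    if (!"state" %in% names(traj)) {
      abort_domain("`traj` has no ground-truth `state` column to export.")
    }
    readr::write_csv(
      dplyr::select(dplyr::mutate(traj, point = dplyr::row_number()),
                    "point", "orbit_number", "t_ms", "state"),
      labels_path)
  }
  invisible(header)
}

#' Built-in simulation scenarios
#'
#' Three ready-made motion programs emulating typical mitochondrial
#' behavior in curved axons, where run headings deviate substantially from
#' the trajectory chord (the regime in which the angle-correlation detector
#' is informative):
#'
#' * `"anterograde"`: two long, fast runs separated by one pause.
#' * `"retrograde"`: four shorter, slower runs with frequent pauses.
#' * `"null"`: a single long pause (wiggling but stationary particle).
#'
#' @param name Preset name.
#' @return A list with elements `name`, `plan` (a [segment_plan()]),
#'   `jitter_sigma_um`, `heading_wobble_deg` and `pause_step_sigma_um`.
#' @export
scenario_preset <- function(name = c("anterograde", "retrograde", "null")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("anterograde", "retrograde", "null")) {
    abort_config(sprintf(
      "Unknown scenario preset '%s'; available: anterograde, retrograde, null.",
      as.character(name)[1]))
  }
  plan <- switch(name,
    anterograde = segment_plan(
      state = c("pause", "run", "pause", "run", "pause"),
      duration_points = c(150, 400, 200, 350, 150),
      speed_um_per_s = c(0, 1.1, 0, 0.9, 0),
      heading_deg = c(0, 60, 0, -58, 0)
    ),
    retrograde = segment_plan(
      state = c("pause", "run", "pause", "run", "pause", "run", "pause", "run", "pause"),
      duration_points = c(150, 250, 180, 200, 200, 220, 160, 200, 150),
      speed_um_per_s = c(0, 0.5, 0, 0.8, 0, 0.6, 0, 0.45, 0),
      heading_deg = c(0, 65, 0, -60, 0, 70, 0, -65, 0)
    ),
    null = segment_plan(state = "pause", duration_points = 1500)
  )
  list(name = name, plan = plan,
       jitter_sigma_um = 0.05,
       heading_wobble_deg = 2,
       pause_step_sigma_um = if (name == "null") 0.01 else 0.005)
}

#' Simulate a preset or custom scenario
#'
#' Convenience wrapper tying [scenario_preset()] (or a scenario list of the
#' same shape, e.g. read from YAML) to [simulate_trajectory()].
#'
#' @param scenario A preset name or a scenario list with elements `plan`
#'   (segment-plan columns) and optionally `jitter_sigma_um`,
#'   `heading_wobble_deg`, `pause_step_sigma_um`.
#' @param acquisition An [acquisition_model()].
#' @param seed Optional integer.
#' @return A trajectory tibble (see [simulate_trajectory()]).
#' @export
simulate_scenario <- function(scenario, acquisition = acquisition_model(),
                              seed = NULL) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  known <- c("name", "plan", "jitter_sigma_um", "heading_wobble_deg",
             "pause_step_sigma_um")
  extra <- setdiff(names(scenario), known)
  if (length(extra)) {
    abort_config(sprintf("Unknown scenario key(s): %s.",
                         paste(sQuote(extra), collapse = ", ")))
  }
  if (is.null(scenario$plan)) abort_config("Scenario is missing a `plan`.")
  plan <- scenario$plan
  if (!inherits(plan, "segment_plan")) {
    plan <- do.call(segment_plan, as.list(plan))
  }
  simulate_trajectory(
    plan, acquisition = acquisition,
    jitter_sigma_um = scenario$jitter_sigma_um %||% 0.05,
    heading_wobble_deg = scenario$heading_wobble_deg %||% 0,
    pause_step_sigma_um = scenario$pause_step_sigma_um %||% 0,
    seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
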