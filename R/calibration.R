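#' Voltage-to-distance calibration of the tracking galvanometers
#'
#' Positions in raw orbital-tracking files are stored as galvanometer
#' voltages. Converting them to physical distances requires the scan-system
#' scaling factors, which are instrument constants determined during
#' alignment. The defaults are the factory calibration of the microscope the
#' raw format originates from: 17.30 um/V laterally (x, y) and 10.00 um/V
#' axially (z).
#'
#' @param lateral_um_per_V Lateral (x, y) scaling factor in micrometers per
#'   volt. Must be strictly positive.
#' @param axial_um_per_V Axial (z) scaling factor in micrometers per volt.
#'   Must be strictly positive.
#'
#' @return An object of class `orbit_calibration`: a named list with the two
#'   scaling factors.
#'
#' @examples
#' cal <- calibration()
#' # the instrument's long-range threshold of 0.5882 V in micrometers:
#' round(0.5882 * cal$lateral_um_per_V, 2)
#'
#' @export
calibration <- function(lateral_um_per_V = 17.30, axial_um_per_V = 10.00) {
  if (!is.numeric(lateral_um_per_V) || length(lateral_um_per_V) != 1 ||
      !is.finite(lateral_um_per_V) || lateral_um_per_V <= 0) {
    abort_domain("`lateral_um_per_V` must be a single positive number.")
  }
  if (!is.numeric(axial_um_per_V) || length(axial_um_per_V) != 1 ||
      !is.finite(axial_um_per_V) || axial_um_per_V <= 0) {
    abort_domain("`axial_um_per_V` must be a single positive number.")
  }
  structure(
    list(lateral_um_per_V = lateral_um_per_V, axial_um_per_V = axial_um_per_V),
    class = "orbit_calibration"
  )
}

#' @export
print.orbit_calibration <- function(x, ...) {
  cat("<orbit_calibration>\n")
  cat(sprintf("  lateral: %.4f um/V\n  axial:   %.4f um/V\n",
              x$lateral_um_per_V, x$axial_um_per_V))
  invisible(x)
}

#' Effective sampling interval of a recording
#'
#' Dark (delay) orbits are interleaved with illuminated orbits to reduce
#' photobleaching; they carry an orbit number but are not written to file.
#' One written record therefore spans `1 + delay_orbits` orbit periods, and
#' the effective temporal resolution of the trajectory is
#' `orbit_time_ms * (1 + delay_orbits)`. With the standard settings of a
#' 5 ms orbit and one dark orbit this gives 10 ms per point.
#'
#' @param header An [orbit_header] (or anything with numeric
#'   `orbit_time_ms` and `delay_orbits` fields).
#'
#' @return The effective interval between written records, in milliseconds.
#' @export
effective_sampling_interval <- function(header) {
  stopifnot(is.numeric(header$orbit_time_ms), is.numeric(header$delay_orbits))
  header$orbit_time_ms * (1 + header$delay_orbits)
}
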