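# Reading and writing the instrument's plain-text raw trajectory dialect:
# a labeled header block followed by rows of 11 whitespace-delimited fields,
# one row per illuminated orbit, positions in galvanometer volts.

# Header entries in canonical file order. `type` drives value decoding;
# labels are matched case-insensitively with optional unit brackets, so
# "orbit time", "Orbit Time [ms]" and "ORBIT TIME [MS]:" all match.
.header_fields <- list(
  file_path              = list(label = "File Path",                unit = "",     type = "text"),
  date                   = list(label = "Date",                     unit = "",     type = "text"),
  time                   = list(label = "Time",                     unit = "",     type = "text"),
  orbit_time_ms          = list(label = "Orbit Time",               unit = "[ms]", type = "num"),
  orbit_radius_V         = list(label = "Orbit Radius",             unit = "[V]",  type = "num"),
  tracking_threshold_Hz  = list(label = "Tracking Threshold",       unit = "[Hz]", type = "num"),
  delay_orbits           = list(label = "Delay Orbits",             unit = "",     type = "int"),
  n_particles            = list(label = "Number of Particles",      unit = "",     type = "int"),
  long_range_enabled     = list(label = "Long Range",               unit = "",     type = "bool"),
  long_range_threshold_V = list(label = "Long Range Threshold",     unit = "[V]",  type = "num")
)

.record_cols <- c("x_V", "y_V", "z_V", "orbit_number", "orbit_interval_ms",
                  "intensity_det1", "intensity_det2", "camera_frame",
                  "tracking_active", "reposition_x", "reposition_y")

#' Construct an acquisition header
#'
#' Builds the metadata block that precedes the data rows of a raw trajectory
#' file. Defaults mirror the standard acquisition settings for mitochondrial
#' tracking in zebrafish axons: 5 ms orbits with one interleaved dark orbit
#' (10 ms effective sampling) and long-range stage repositioning at 0.5882 V
#' (10.18 um at the lateral calibration of 17.30 um/V).
#'
#' @param file_path,date,time Free-text provenance fields.
#' @param orbit_time_ms Duration of one laser orbit in ms (> 0).
#' @param orbit_radius_V Orbit radius in galvanometer volts (> 0).
#' @param tracking_threshold_Hz Count-rate threshold separating the tracking
#'   and search modes of the instrument (>= 0).
#' @param delay_orbits Number of dark orbits interleaved per illuminated
#'   orbit (>= 0).
#' @param n_particles Number of tracking channels (>= 1; only single-particle
#'   files are analyzable).
#' @param long_range_enabled Whether stage repositioning was active.
#' @param long_range_threshold_V Voltage displacement at which the stage
#'   recenters the particle (only meaningful when `long_range_enabled`).
#'
#' @return An object of class `orbit_header` (named list).
#' @seealso [parse_orbit_header()], [read_orbit_file()], [write_orbit_file()]
#' @export
orbit_header <- function(file_path = "synthetic",
                         date = format(Sys.Date(), "%d.%m.%Y"),
                         time = "00:00:00",
                         orbit_time_ms = 5,
                         orbit_radius_V = 0.05,
                         tracking_threshold_Hz = 10000,
                         delay_orbits = 1,
                         n_particles = 1,
                         long_range_enabled = TRUE,
                         long_range_threshold_V = 0.5882) {
  hdr <- structure(
    list(file_path = as.character(file_path), date = as.character(date),
         time = as.character(time), orbit_time_ms = as.numeric(orbit_time_ms),
         orbit_radius_V = as.numeric(orbit_radius_V),
         tracking_threshold_Hz = as.numeric(tracking_threshold_Hz),
         delay_orbits = as.integer(delay_orbits),
         n_particles = as.integer(n_particles),
         long_range_enabled = isTRUE(as.logical(long_range_enabled)),
         long_range_threshold_V = as.numeric(long_range_threshold_V)),
    class = "orbit_header"
  )
  validate_orbit_header(hdr)
}

validate_orbit_header <- function(hdr) {
  if (!is.finite(hdr$orbit_time_ms) || hdr$orbit_time_ms <= 0) {
    abort_format("Header field 'Orbit Time' must be a positive number.")
  }
  if (!is.finite(hdr$orbit_radius_V) || hdr$orbit_radius_V <= 0) {
    abort_format("Header field 'Orbit Radius' must be a positive number.")
  }
  if (!is.finite(hdr$tracking_threshold_Hz) || hdr$tracking_threshold_Hz < 0) {
    abort_format("Header field 'Tracking Threshold' must be non-negative.")
  }
  if (is.na(hdr$delay_orbits) || hdr$delay_orbits < 0) {
    abort_format("Header field 'Delay Orbits' must be a non-negative integer.")
  }
  if (is.na(hdr$n_particles) || hdr$n_particles < 1) {
    abort_format("Header field 'Number of Particles' must be >= 1.")
  }
  if (!is.finite(hdr$long_range_threshold_V) || hdr$long_range_threshold_V < 0) {
    abort_format("Header field 'Long Range Threshold' must be non-negative.")
  }
  hdr
}

#' @export
print.orbit_header <- function(x, ...) {
  cat("<orbit_header>\n")
  for (f in names(.header_fields)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}

.normalize_label <- function(x) {
  x <- tolower(gsub("\\[[^]]*\\]", "", x))
  trimws(gsub("\\s+", " ", x))
}

#' Parse the header block of a raw trajectory file
#'
#' Decodes the ten labeled metadata entries that open every raw file.
#' Labels are matched case-insensitively, unit brackets (`[ms]`, `[V]`,
#' `[Hz]`) are tolerated but not required, entries may appear in any order,
#' and values may be separated from their label by tabs, spaces or a colon.
#' Boolean entries are encoded 0/1 in the file.
#'
#' @param lines Character vector of header lines (one entry per line).
#' @return An [orbit_header].
#'
#' @examples
#' parse_orbit_header(c(
#'   "File Path C:\\data\\mito01.txt",
#'   "Date 17.06.2019", "Time 14:02:11",
#'   "Orbit Time [ms] 5.000", "Orbit Radius [V] 0.050000",
#'   "Tracking Threshold [Hz] 10000", "Delay Orbits 1",
#'   "Number of Particles 1", "Long Range 1",
#'   "Long Range Threshold [V] 0.5882"
#' ))
#' @export
parse_orbit_header <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  found <- list()
  # match longest labels first so "Long Range Threshold" wins over "Long Range"
  ord <- order(-nchar(vapply(.header_fields, `[[`, "", "label")))
  fields <- .header_fields[ord]
  for (ln in lines) {
    norm <- .normalize_label(ln)
    for (fname in names(fields)) {
      lab <- .normalize_label(fields[[fname]]$label)
      if (startsWith(norm, lab)) {
        # strip the label (with optional unit bracket / colon) off the raw line
        words <- strsplit(fields[[fname]]$label, "\\s+")[[1]]
        pat <- paste0("^\\s*", paste(words, collapse = "\\s+"),
                      "\\s*(\\[[^]]*\\])?\\s*:?\\s*")
        value <- sub(pat, "", ln, ignore.case = TRUE)
        found[[fname]] <- trimws(value)
        break
      }
    }
  }
  missing <- setdiff(names(.header_fields), names(found))
  if (length(missing)) {
    labs <- vapply(.header_fields[missing], `[[`, "", "label")
    abort_format(sprintf("Raw file header is missing mandatory entr%s: %s.",
                         if (length(labs) > 1) "ies" else "y",
                         paste(sQuote(labs), collapse = ", ")))
  }
  decode <- function(fname) {
    val <- found[[fname]]
    type <- .header_fields[[fname]]$type
    if (type == "text") return(val)
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) {
      abort_format(sprintf("Header entry '%s' has unparseable value: '%s'.",
                           .header_fields[[fname]]$label, val))
    }
    switch(type, num = num, int = as.integer(num), bool = num != 0)
  }
  vals <- lapply(names(.header_fields), decode)
  names(vals) <- names(.header_fields)
  validate_orbit_header(structure(vals, class = "orbit_header"))
}

.is_data_line <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  length(toks) >= 6 && !anyNA(suppressWarnings(as.numeric(toks)))
}

#' Read a raw orbital-tracking trajectory file
#'
#' Reads one `.txt` raw file (one tracked particle), returning the parsed
#' header and one record per data row, order preserved. Each row has 11
#' whitespace-delimited fields: position voltages (x, y, z), orbit number,
#' calculated orbit time, per-orbit intensity of the two detectors, camera
#' frame, tracking-active flag and the x/y repositioning flags. Orbit
#' numbers may contain gaps where dark orbits were numbered but not written.
#'
#' Orbit numbers that are not strictly increasing are reported with a
#' warning (instrument glitch) rather than an error; the rows are kept and
#' the result carries `attr(, "monotone_orbit") = FALSE`.
#'
#' @param path Path to the raw file.
#' @param quiet Suppress the row-count message.
#'
#' @return An object of class `orbit_raw`: a list with elements `header`
#'   (an [orbit_header]), `records` (a tibble with columns `x_V`, `y_V`,
#'   `z_V`, `orbit_number`, `orbit_interval_ms`, `intensity_det1`,
#'   `intensity_det2`, `camera_frame`, `tracking_active`, `reposition_x`,
#'   `reposition_y`) and `source` (the path read).
#'
#' @seealso [as_physical()] to convert the voltage records to micrometers.
#' @export
read_orbit_file <- function(path, quiet = TRUE) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort_io(sprintf("Cannot read raw trajectory file: '%s' does not exist.",
                     as.character(path)[1]))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  is_data <- vapply(lines, .is_data_line, logical(1), USE.NAMES = FALSE)
  first_data <- which(is_data)[1]
  header_lines <- if (is.na(first_data)) lines else lines[seq_len(first_data - 1)]
  header <- parse_orbit_header(header_lines)
  if (header$n_particles > 1) {
    abort_domain(sprintf(
      "File declares %d tracking channels; multi-particle column layouts are not supported.",
      header$n_particles))
  }
  data_lines <- if (is.na(first_data)) character(0) else lines[first_data:length(lines)]
  records <- parse_orbit_records(data_lines)
  if (!quiet) {
    message(sprintf("Read %d orbit records from '%s'.", nrow(records), path))
  }
  monotone <- TRUE
  if (nrow(records) > 1 && any(diff(records$orbit_number) <= 0)) {
    monotone <- FALSE
    warning(sprintf("Orbit numbers in '%s' are not strictly increasing.", path),
            call. = FALSE)
  }
  out <- structure(list(header = header, records = records, source = path),
                   class = "orbit_raw")
  attr(out, "monotone_orbit") <- monotone
  out
}

parse_orbit_records <- function(data_lines) {
  if (!length(data_lines)) {
    rec <- as.list(rep(0, 11))
    names(rec) <- .record_cols
    return(tibble::as_tibble(rec)[0, ])
  }
  toks <- strsplit(trimws(data_lines), "\\s+")
  nfield <- lengths(toks)
  bad <- which(nfield != 11)
  if (length(bad)) {
    abort_format(sprintf(
      "Data row %d has %d fields (11 expected): '%s'.",
      bad[1], nfield[bad[1]], data_lines[bad[1]]))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(toks))),
                ncol = 11, byrow = TRUE)
  if (anyNA(mat)) {
    bad_row <- which(apply(is.na(mat), 1, any))[1]
    abort_format(sprintf("Data row %d contains a non-numeric field: '%s'.",
                         bad_row, data_lines[bad_row]))
  }
  flags <- mat[, 9:11, drop = FALSE]
  if (!all(flags %in% c(0, 1))) {
    bad_row <- which(apply(!matrix(flags %in% c(0, 1), ncol = 3), 1, any))[1]
    abort_format(sprintf(
      "Data row %d has a flag value outside {0, 1}: '%s'.",
      bad_row, data_lines[bad_row]))
  }
  tibble::tibble(
    x_V = mat[, 1], y_V = mat[, 2], z_V = mat[, 3],
    orbit_number = as.integer(mat[, 4]),
    orbit_interval_ms = mat[, 5],
    intensity_det1 = mat[, 6], intensity_det2 = mat[, 7],
    camera_frame = as.integer(mat[, 8]),
    tracking_active = mat[, 9] == 1,
    reposition_x = mat[, 10] == 1,
    reposition_y = mat[, 11] == 1
  )
}

#' @export
print.orbit_raw <- function(x, ...) {
  cat(sprintf("<orbit_raw> %d records from '%s'\n", nrow(x$records), x$source))
  cat(sprintf("  orbit time %.3g ms, %d delay orbit(s) -> %.3g ms effective\n",
              x$header$orbit_time_ms, x$header$delay_orbits,
              effective_sampling_interval(x$header)))
  invisible(x)
}

# fixed decimal places used on write; round-trips are exact at this precision
.fmt_voltage <- "%.6f"
.fmt_time <- "%.3f"

#' Write records back to the raw trajectory dialect
#'
#' Inverse of [read_orbit_file()]: serializes a header and a record table to
#' the plain-text raw format. Voltages are written with 6 decimal places and
#' times with 3, so write-then-read reproduces all numeric fields at that
#' documented precision.
#'
#' @param header An [orbit_header].
#' @param records A tibble/data frame with the 11 record columns (see
#'   [read_orbit_file()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_orbit_file <- function(header, records, path) {
  header <- validate_orbit_header(header)
  records <- tibble::as_tibble(records)
  stopifnot(all(.record_cols %in% names(records)))
  fmt_field <- function(fname) {
    f <- .header_fields[[fname]]
    val <- header[[fname]]
    txt <- switch(f$type,
      text = as.character(val),
      num  = sprintf(.fmt_voltage, val),
      int  = sprintf("%d", as.integer(val)),
      bool = sprintf("%d", as.integer(val))
    )
    label <- if (nzchar(f$unit)) paste(f$label, f$unit) else f$label
    paste0(label, "\t", txt)
  }
  hdr_lines <- vapply(names(.header_fields), fmt_field, character(1))
  row_lines <- sprintf(
    paste(.fmt_voltage, .fmt_voltage, .fmt_voltage, "%d", .fmt_time,
          .fmt_time, .fmt_time, "%d %d %d %d"),
    records$x_V, records$y_V, records$z_V, records$orbit_number,
    records$orbit_interval_ms, records$intensity_det1, records$intensity_det2,
    records$camera_frame, as.integer(records$tracking_active),
    as.integer(records$reposition_x), as.integer(records$reposition_y))
  ok <- tryCatch({
    writeLines(c(hdr_lines, row_lines), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("Cannot write raw trajectory file to '%s'.", path))
  invisible(path)
}

#' Convert voltage records to a calibrated physical trajectory
#'
#' Multiplies the stored galvanometer voltages by the calibration factors
#' (x, y lateral; z axial) to obtain positions in micrometers, and builds
#' per-point timestamps from the calculated orbit time column. Stored
#' positions are already corrected for long-range repositioning events, so
#' the converted trajectory is continuous.
#'
#' The orbit-time column is interpreted, by default, as the interval since
#' the previous written record (`time_mode = "interval"`), so dark orbits
#' and 30-70 ms repositioning pauses appear as enlarged intervals;
#' timestamps are its cumulative sum anchored at `t_ms[1] = 0`. If a file
#' stores elapsed time instead, use `time_mode = "elapsed"`, which anchors
#' the stored values at zero without summing.
#'
#' @param x An `orbit_raw` object from [read_orbit_file()], or a record
#'   tibble with the 11 raw columns.
#' @param calibration A [calibration()] object.
#' @param time_mode `"interval"` (default) or `"elapsed"`; see Details.
#'
#' @return A tibble with one row per written orbit: `point`, `orbit_number`,
#'   `t_ms`, `x_um`, `y_um`, `z_um`, the carried intensity/camera columns,
#'   and the quality flags `tracking_inactive` and `repositioning`.
#'
#' @examples
#' rec <- tibble::tibble(
#'   x_V = c(0, 0.2, 0.5882), y_V = 0, z_V = 0, orbit_number = c(0L, 2L, 4L),
#'   orbit_interval_ms = 10, intensity_det1 = 100, intensity_det2 = 80,
#'   camera_frame = 0L, tracking_active = TRUE,
#'   reposition_x = FALSE, reposition_y = FALSE
#' )
#' as_physical(rec)
#' @export
as_physical <- function(x, calibration = orbitrack::calibration(),
                        time_mode = c("interval", "elapsed")) {
  time_mode <- match.arg(time_mode)
  records <- if (inherits(x, "orbit_raw")) x$records else tibble::as_tibble(x)
  if (!nrow(records)) {
    abort_domain("Cannot convert an empty record set to a physical trajectory.")
  }
  if (!inherits(calibration, "orbit_calibration")) {
    calibration <- do.call(orbitrack::calibration, as.list(calibration))
  }
  t_ms <- switch(time_mode,
    interval = {
      tt <- cumsum(records$orbit_interval_ms)
      tt - tt[1]
    },
    elapsed = records$orbit_interval_ms - records$orbit_interval_ms[1]
  )
  out <- tibble::tibble(
    point = seq_len(nrow(records)),
    orbit_number = records$orbit_number,
    t_ms = t_ms,
    x_um = records$x_V * calibration$lateral_um_per_V,
    y_um = records$y_V * calibration$lateral_um_per_V,
    z_um = records$z_V * calibration$axial_um_per_V,
    intensity_det1 = records$intensity_det1,
    intensity_det2 = records$intensity_det2,
    camera_frame = records$camera_frame,
    tracking_inactive = !records$tracking_active,
    repositioning = records$reposition_x | records$reposition_y
  )
  attr(out, "calibration") <- calibration
  out
}
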