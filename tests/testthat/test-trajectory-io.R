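test_that("header parsing decodes all ten entries regardless of case, units and order", {
  hdr <- parse_orbit_header(header_lines_fixture())
  expect_s3_class(hdr, "orbit_header")
  expect_equal(hdr$orbit_time_ms, 5)
  expect_equal(hdr$orbit_radius_V, 0.05)
  expect_equal(hdr$delay_orbits, 1L)
  expect_equal(hdr$n_particles, 1L)
  expect_true(hdr$long_range_enabled)
  expect_equal(hdr$long_range_threshold_V, 0.5882)
  expect_equal(hdr$file_path, "C:\\data\\mito01.txt")

  shuffled <- withr::with_seed(1, sample(header_lines_fixture()))
  lowered <- tolower(gsub("\\[(ms|V|Hz)\\]", "", shuffled))
  expect_equal(parse_orbit_header(lowered)$orbit_time_ms, 5)
  expect_equal(parse_orbit_header(lowered)$long_range_threshold_V, 0.5882)
})

test_that("long-range flag decodes 0/1 and prefix clash with its threshold is resolved", {
  hdr <- parse_orbit_header(header_lines_fixture(long_range = 0))
  expect_false(hdr$long_range_enabled)
  expect_equal(hdr$long_range_threshold_V, 0.5882)
})

test_that("missing or unparseable header entries raise format errors naming the entry", {
  expect_error(parse_orbit_header(header_lines_fixture(drop = 4)),
               "Orbit Time", class = "orbitrack_format_error")
  expect_error(parse_orbit_header(header_lines_fixture(lr_threshold = "banana")),
               "Long Range Threshold", class = "orbitrack_format_error")
})

make_raw_file <- function(records, path = withr::local_tempfile(fileext = ".txt",
                                                                .local_envir = parent.frame()),
                          header = orbit_header()) {
  write_orbit_file(header, records, path)
  path
}

test_that("reading preserves rows, order and dark-orbit numbering gaps", {
  rec <- random_records(3, seed = 11)
  rec$orbit_number <- c(0L, 2L, 4L)  # every second orbit dark
  path <- make_raw_file(rec)
  raw <- read_orbit_file(path)
  expect_equal(nrow(raw$records), 3)
  expect_equal(raw$records$orbit_number, c(0L, 2L, 4L))
  expect_true(attr(raw, "monotone_orbit"))
})

test_that("wrong column counts and non-monotone orbit numbers are reported", {
  rec <- random_records(4, seed = 12)
  path <- make_raw_file(rec)
  lines <- readLines(path)
  lines[12] <- "1 2 3 4 5 6 7"  # row 2 of the data block, 7 fields
  writeLines(lines, path)
  expect_error(read_orbit_file(path), "row 2", class = "orbitrack_format_error")

  rec$orbit_number <- c(0L, 4L, 2L, 6L)
  path2 <- make_raw_file(rec)
  expect_warning(raw <- read_orbit_file(path2), "not strictly increasing")
  expect_false(attr(raw, "monotone_orbit"))
  expect_equal(nrow(raw$records), 4)
})

test_that("missing files and multi-particle layouts are rejected", {
  expect_error(read_orbit_file(file.path(tempdir(), "nope.txt")),
               class = "orbitrack_io_error")
  path <- make_raw_file(random_records(2, seed = 3),
                        header = orbit_header(n_particles = 2))
  expect_error(read_orbit_file(path), "multi-particle",
               class = "orbitrack_domain_error")
})

test_that("write-then-read is the identity at the documented precision", {
  for (seed in 1:20) {
    rec <- random_records(sample(1:60, 1), seed = seed)
    hdr <- orbit_header(orbit_time_ms = round(runif(1, 1, 20), 3),
                        delay_orbits = sample(0:3, 1),
                        long_range_enabled = runif(1) > 0.5,
                        long_range_threshold_V = round(runif(1), 6))
    path <- withr::local_tempfile(fileext = ".txt")
    write_orbit_file(hdr, rec, path)
    back <- read_orbit_file(path)
    expect_equal(unclass(back$header)[names(back$header) != "file_path"],
                 unclass(hdr)[names(hdr) != "file_path"])
    expect_equal(as.data.frame(back$records), as.data.frame(rec),
                 tolerance = 1e-12)
  }
})

test_that("an empty record list round-trips to a header-only file", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_orbit_file(orbit_header(), random_records(0, seed = 1), path)
  raw <- read_orbit_file(path)
  expect_equal(nrow(raw$records), 0)
  expect_equal(raw$header$orbit_time_ms, 5)
})

test_that("reposition flags survive a round trip", {
  rec <- random_records(10, seed = 21)
  rec$reposition_x <- rep(c(TRUE, FALSE), 5)
  rec$reposition_y[3] <- TRUE
  path <- make_raw_file(rec)
  back <- read_orbit_file(path)$records
  expect_equal(back$reposition_x, rec$reposition_x)
  expect_equal(back$reposition_y, rec$reposition_y)
})

test_that("voltage-to-micrometer conversion applies the scaling factors", {
  rec <- random_records(3, seed = 5)
  rec$x_V <- c(0.5882, 0, -0.2)
  rec$y_V <- c(0.1, 0, 0.3)
  rec$z_V <- c(0.05, 0, -0.1)
  traj <- as_physical(rec)
  # the instrument's long-range threshold: 0.5882 V is 10.18 um laterally
  expect_equal(round(traj$x_um[1], 2), 10.18)
  expect_equal(traj$x_um[2], 0)
  expect_equal(traj$y_um, rec$y_V * 17.30)
  expect_equal(traj$z_um, rec$z_V * 10.00)
})

test_that("conversion is linear and origin-preserving", {
  rec <- random_records(25, seed = 6)
  scaled <- rec
  a <- 2.5
  scaled$x_V <- a * rec$x_V; scaled$y_V <- a * rec$y_V; scaled$z_V <- a * rec$z_V
  t1 <- as_physical(rec); t2 <- as_physical(scaled)
  expect_equal(t2$x_um, a * t1$x_um)
  expect_equal(t2$y_um, a * t1$y_um)
  expect_equal(t2$z_um, a * t1$z_um)
})

test_that("timestamps accumulate the per-record intervals anchored at zero", {
  rec <- random_records(5, seed = 7)
  rec$orbit_interval_ms <- rep(10, 5)
  traj <- as_physical(rec)
  expect_equal(traj$t_ms, c(0, 10, 20, 30, 40))

  rec$orbit_interval_ms <- c(10, 10, 55, 10, 10)  # repositioning pause
  traj <- as_physical(rec)
  expect_equal(diff(traj$t_ms), rec$orbit_interval_ms[-1])
  expect_equal(traj$t_ms[5], sum(rec$orbit_interval_ms[-1]))

  elapsed <- rec
  elapsed$orbit_interval_ms <- c(100, 110, 120, 175, 185)
  traj_e <- as_physical(elapsed, time_mode = "elapsed")
  expect_equal(traj_e$t_ms, c(0, 10, 20, 75, 85))
})

test_that("quality flags map to tracking_inactive and repositioning", {
  rec <- random_records(4, seed = 8)
  rec$tracking_active <- c(TRUE, FALSE, TRUE, TRUE)
  rec$reposition_x <- c(FALSE, FALSE, TRUE, FALSE)
  rec$reposition_y <- c(FALSE, FALSE, FALSE, TRUE)
  traj <- as_physical(rec)
  expect_equal(traj$tracking_inactive, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(traj$repositioning, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(as_physical(random_records(0, seed = 1)),
               class = "orbitrack_domain_error")
})

test_that("effective sampling interval combines orbit time and dark orbits", {
  expect_equal(effective_sampling_interval(orbit_header(orbit_time_ms = 5, delay_orbits = 1)), 10)
  expect_equal(effective_sampling_interval(orbit_header(orbit_time_ms = 5, delay_orbits = 0)), 5)
  expect_equal(effective_sampling_interval(orbit_header(orbit_time_ms = 2, delay_orbits = 4)), 10)
})
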