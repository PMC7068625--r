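Package: orbitrack
Title: Trajectory Analysis for 3D Orbital Tracking Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read, write and analyze single-particle trajectories produced by
    3D orbital tracking microscopes. Parses the instrument's plain-text raw
    format (header block plus 11-column orbit records stored as galvanometer
    voltages), converts records to calibrated physical trajectories, and
    segments trajectories into directed-transport events and stationary
    phases using a sliding-window correlation of lateral angles against a
    permutation-derived threshold. Includes a ground-truth trajectory
    simulator with run/pause structure, localization noise, dark-orbit
    numbering and long-range repositioning events, plus a command-line
    interface for batch conversion, segmentation and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
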