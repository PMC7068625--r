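# Classified conditions so the CLI can map failures to distinct exit codes.

abort_io <- function(message, ...) {
  rlang::abort(message, class = "orbitrack_io_error", ...)
}

abort_format <- function(message, ...) {
  rlang::abort(message, class = "orbitrack_format_error", ...)
}

abort_domain <- function(message, ...) {
  rlang::abort(message, class = "orbitrack_domain_error", ...)
}

abort_config <- function(message, ...) {
  rlang::abort(message, class = "orbitrack_config_error", ...)
}

# Evaluate `code` under a fixed RNG seed when one is given, without
# disturbing the caller's RNG state; otherwise consume the current stream.
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
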