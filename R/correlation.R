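#' Sliding-window angle correlation carpet
#'
#' For every window start `t` and lag `tau` in `1 .. tau_max - 1`, the
#' windowed correlation of the lateral angle series
#' \deqn{Cor(t, \tau) = \frac{1}{\tau_{max} - \tau}
#'   \sum_{i = t}^{t + \tau_{max} - \tau - 1} \Phi(i)\,\Phi(i + \tau),}
#' i.e. the mean product of angle pairs separated by `tau` within a window
#' of `tau_max` angles. Sustained high values across lags indicate
#' persistent directed motion; isotropic jitter averages to zero.
#'
#' Each lag sums exactly `tau_max - tau` products, all of whose indices lie
#' inside the window, and by default is normalized by that count so lags are
#' comparable unbiased window means (`norm = "window"`). `norm = "global"`
#' instead divides every lag by `n - tau` with `n` the full series length,
#' which preserves the alternative global-normalization reading; it rescales
#' rows by a constant factor per lag and does not change which windows
#' exceed a threshold derived with the same normalization.
#'
#' @param angles Numeric angle series (radians) or a [lateral_angles()]
#'   tibble.
#' @param tau_max Correlation window size in data points (>= 2). 64 is the
#'   standard compromise between noise and sensitivity; 32 and 128 are
#'   common alternatives.
#' @param norm `"window"` (default) or `"global"`; see Details.
#'
#' @return A numeric matrix with `length(angles) - tau_max + 1` rows
#'   (window starts) and `tau_max - 1` columns (lags), with `dimnames`
#'   giving window start and lag; attributes `tau_max` and `norm`.
#' @seealso [correlation_amplitude()], [randomized_threshold()]
#' @export
correlation_carpet <- function(angles, tau_max = 64,
                               norm = c("window", "global")) {
  norm <- match.arg(norm)
  phi <- as_phi(angles)
  tau_max <- as.integer(tau_max)
  if (is.na(tau_max) || tau_max < 2) abort_domain("`tau_max` must be an integer >= 2.")
  n <- length(phi)
  if (n < tau_max) {
    abort_domain(sprintf(
      "Angle series has %d values; at least tau_max = %d are required.", n, tau_max))
  }
  nw <- n - tau_max + 1
  carpet <- matrix(0, nrow = nw, ncol = tau_max - 1,
                   dimnames = list(t = seq_len(nw), tau = seq_len(tau_max - 1)))
  for (tau in seq_len(tau_max - 1)) {
    prods <- phi[1:(n - tau)] * phi[(1 + tau):n]
    k <- tau_max - tau                      # products per window
    cs <- c(0, cumsum(prods))
    denom <- if (norm == "window") k else n - tau
    carpet[, tau] <- (cs[(1:nw) + k] - cs[1:nw]) / denom
  }
  attr(carpet, "tau_max") <- tau_max
  attr(carpet, "norm") <- norm
  carpet
}

#' Correlation amplitude
#'
#' Collapses a correlation carpet to one value per window by summing over
#' lags `1 .. tau_max - 1` (lag 0 is a pure power term and is excluded).
#' The amplitude is the statistic compared against the randomization
#' threshold to call transport versus stationary phases.
#'
#' @param carpet Matrix from [correlation_carpet()].
#' @return Numeric vector, one amplitude per window start.
#' @export
correlation_amplitude <- function(carpet) {
  if (is.null(dim(carpet)) || !nrow(carpet)) {
    abort_domain("`carpet` must be a non-empty matrix from correlation_carpet().")
  }
  unname(rowSums(carpet))
}

#' Permutation-null threshold for the correlation amplitude
#'
#' Estimates how large the correlation amplitude can get by chance in a
#' trajectory with the same angle magnitudes but no temporal structure. The
#' angle series is first symmetrized by appending its negative copy (the
#' mirror image across the reference axis), removing the directional bias
#' that a large net displacement imprints on the angle distribution; the
#' augmented series therefore has sample mean exactly zero. Each of
#' `n_shuffles` random permutations of the augmented series is run through
#' the same carpet/amplitude computation, and all null amplitude values are
#' pooled into a mean `M` and standard deviation `sigma`. The threshold is
#' \deqn{T = M + w\,\sigma,}
#' with the weighting factor `w = 5` as standard: amplitudes more than five
#' null standard deviations above the null mean are called transport.
#'
#' @inheritParams correlation_carpet
#' @param w Weighting factor (number of null standard deviations).
#' @param n_shuffles Number of random permutations pooled into `M` and
#'   `sigma`.
#' @param seed Optional integer; when supplied the permutations are drawn
#'   under this seed without disturbing the caller's RNG state.
#'
#' @return A list of class `orbit_threshold`: `threshold` (`T`),
#'   `null_mean` (`M`), `null_sd` (`sigma`), `w`, `n_shuffles`, `tau_max`,
#'   `norm`, and `n_values` (number of pooled null amplitudes).
#' @export
randomized_threshold <- function(angles, tau_max = 64, w = 5,
                                 n_shuffles = 100,
                                 norm = c("window", "global"),
                                 seed = NULL) {
  norm <- match.arg(norm)
  phi <- as_phi(angles)
  if (!is.numeric(w) || length(w) != 1 || w <= 0) {
    abort_domain("`w` must be a single positive number.")
  }
  n_shuffles <- as.integer(n_shuffles)
  if (is.na(n_shuffles) || n_shuffles < 1) {
    abort_domain("`n_shuffles` must be a positive integer.")
  }
  if (length(phi) < tau_max) {
    abort_domain(sprintf(
      "Angle series has %d values; at least tau_max = %d are required.",
      length(phi), tau_max))
  }
  augmented <- c(phi, -phi)
  values <- with_optional_seed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(i) {
      shuffled <- sample(augmented)
      correlation_amplitude(correlation_carpet(shuffled, tau_max, norm))
    }), use.names = FALSE)
  })
  M <- mean(values)
  sigma <- if (length(values) > 1) stats::sd(values) else 0
  structure(
    list(threshold = M + w * sigma, null_mean = M, null_sd = sigma,
         w = w, n_shuffles = n_shuffles, tau_max = as.integer(tau_max),
         norm = norm, n_values = length(values)),
    class = "orbit_threshold"
  )
}

#' @export
print.orbit_threshold <- function(x, ...) {
  cat(sprintf(
    "<orbit_threshold> T = %.4g (M = %.4g, sigma = %.4g, w = %g; %d shuffles)\n",
    x$threshold, x$null_mean, x$null_sd, x$w, x$n_shuffles))
  invisible(x)
}
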