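#' Sampled one-dimensional signal
#'
#' Light container for a uniformly sampled real-valued time series, used for
#' the stimulation current, the artifactual source and every other 1-D
#' signal in the simulator.
#'
#' @param samples Numeric vector of finite sample values.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param units Character scalar naming the physical units (e.g. `"A"`,
#'   `"mV"`, `"s^-1"`). Purely descriptive.
#'
#' @return An object of class `sampled_signal`: a list with elements
#'   `samples`, `sampling_rate_hz` and `units`.
#' @export
#' @examples
#' s <- sampled_signal(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), 1000, "a.u.")
#' s
sampled_signal <- function(samples, sampling_rate_hz, units = "a.u.") {
  check_scalar(sampling_rate_hz, "sampling_rate_hz")
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_assrmix("`samples` must be finite and non-missing.")
  }
  structure(
    list(samples = samples, sampling_rate_hz = sampling_rate_hz,
         units = as.character(units)[1]),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf(
    "<sampled_signal> %d samples @ %g Hz (%.4g s), units: %s\n",
    length(x$samples), x$sampling_rate_hz,
    length(x$samples) / x$sampling_rate_hz, x$units
  ))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$samples)

#' @rdname sampled_signal
#' @param x A `sampled_signal`.
#' @param ... Unused.
#' @export
as_tibble.sampled_signal <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$samples) - 1) / x$sampling_rate_hz,
    value = x$samples
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# internal: duration in seconds
signal_duration <- function(x) length(x$samples) / x$sampling_rate_hz

# internal: single-sided FFT amplitude spectrum as tibble
amplitude_spectrum <- function(samples, fs) {
  n <- length(samples)
  sp <- fft(samples)
  k <- seq_len(floor(n / 2) + 1L)
  amp <- Mod(sp[k]) / n
  amp[-1L] <- 2 * amp[-1L] # single-sided except DC
  if (n %% 2 == 0) amp[length(amp)] <- amp[length(amp)] / 2
  tibble::tibble(freq_hz = (k - 1L) * fs / n, amplitude = amp)
}
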