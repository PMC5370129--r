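#' Cochlear-implant stimulus configuration
#'
#' Parameters of the pulse-width-modulated (PWM) monophasic pulse train used
#' as the model input. The implant encodes an amplitude-modulated sine tone
#' by varying the duration of constant-amplitude current pulses delivered at
#' a fixed carrier (stimulation) rate.
#'
#' @param carrier_freq_hz Carrier frequency `f_c` in Hz: the implant's pulse
#'   rate. Clinical rates are around 500 Hz. Must satisfy
#'   `f_c < sampling_rate_hz / 2`.
#' @param modulation_freq_hz Modulation frequency `f_m` in Hz of the encoded
#'   envelope; the ASSR analysis frequency. Default 39.0625 Hz (= 5000/128),
#'   the exact value conventionally displayed as "39.06 Hz", chosen so an
#'   epoch of 20 modulation cycles is an integer number of samples at 10 and
#'   50 kHz.
#' @param modulation_depth Modulation depth `MD` in \[0, 1\]: relative
#'   amplitude of the envelope oscillation.
#' @param base_pulse_width_s Maximum active-pulse width in seconds; the
#'   widest pulse emitted (at the envelope crest). Must be shorter than the
#'   inter-pulse interval `1 / f_c`.
#' @param amplitude Pulse current amplitude (amperes; the model treats this
#'   as an arbitrary unit that downstream calibration maps to scalp
#'   microvolts).
#' @param sampling_rate_hz Sampling rate `f_s` in Hz.
#' @param duration_s Duration of the generated train in seconds.
#' @param mapping Envelope-to-width mapping. `"affine"` (default) uses
#'   `w(t) = base_pulse_width_s * (1 + MD sin(2 pi f_m t)) / (1 + MD)` so the
#'   widest pulse equals `base_pulse_width_s` (bounded charge); `"linear"`
#'   drops the `1/(1+MD)` normalisation so the mean width is
#'   MD-independent.
#' @param seed Integer seed recorded with the configuration. The train
#'   itself is deterministic; the seed propagates to stochastic downstream
#'   stages.
#'
#' @return An object of class `stimulus_config`.
#' @export
#' @examples
#' cfg <- stimulus_config(duration_s = 1, sampling_rate_hz = 50e3)
#' train <- make_pwm_pulse_train(cfg)
#' train
stimulus_config <- function(carrier_freq_hz = 500,
                            modulation_freq_hz = 39.0625,
                            modulation_depth = 0.75,
                            base_pulse_width_s = 5e-5,
                            amplitude = 2e-6,
                            sampling_rate_hz = 50e3,
                            duration_s = 40,
                            mapping = c("affine", "linear"),
                            seed = 1L) {
  mapping <- match.arg(mapping)
  check_scalar(carrier_freq_hz, "carrier_freq_hz")
  check_scalar(modulation_freq_hz, "modulation_freq_hz")
  check_scalar(base_pulse_width_s, "base_pulse_width_s")
  check_scalar(amplitude, "amplitude")
  check_scalar(sampling_rate_hz, "sampling_rate_hz")
  check_scalar(duration_s, "duration_s")
  check_scalar(modulation_depth, "modulation_depth", allow_zero = TRUE)
  if (carrier_freq_hz >= sampling_rate_hz / 2) {
    stop_assrmix("`carrier_freq_hz` must be below the Nyquist frequency f_s/2.")
  }
  if (modulation_freq_hz >= carrier_freq_hz) {
    stop_assrmix("`modulation_freq_hz` must be below `carrier_freq_hz`.")
  }
  if (modulation_depth > 1) {
    stop_assrmix("`modulation_depth` must lie in [0, 1].")
  }
  if (base_pulse_width_s >= 1 / carrier_freq_hz) {
    stop_assrmix("`base_pulse_width_s` must be below the inter-pulse interval 1/f_c.")
  }
  structure(
    list(
      carrier_freq_hz = carrier_freq_hz,
      modulation_freq_hz = modulation_freq_hz,
      modulation_depth = modulation_depth,
      base_pulse_width_s = base_pulse_width_s,
      amplitude = amplitude,
      sampling_rate_hz = sampling_rate_hz,
      duration_s = duration_s,
      mapping = mapping,
      seed = as.integer(seed)
    ),
    class = "stimulus_config"
  )
}

#' @export
print.stimulus_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<stimulus_config> PWM monophasic pulse train\n",
      "  f_c = %g Hz, f_m = %g Hz, MD = %g, base width = %g us\n",
      "  amplitude = %g, f_s = %g Hz, duration = %g s, mapping = %s\n"
    ),
    x$carrier_freq_hz, x$modulation_freq_hz, x$modulation_depth,
    x$base_pulse_width_s * 1e6, x$amplitude, x$sampling_rate_hz,
    x$duration_s, x$mapping
  ))
  invisible(x)
}

#' Pulse onsets and widths of a PWM train
#'
#' Computes the per-pulse onset samples (1-based) and widths in samples for
#' a [stimulus_config()], without materialising the full signal. Widths are
#' quantized by rounding to the nearest sample with a floor of one sample.
#'
#' @param cfg A [stimulus_config()].
#' @return A tibble with columns `pulse`, `onset_sample` (1-based),
#'   `onset_time_s`, `width_samples`, `width_s`.
#' @export
pwm_pulse_table <- function(cfg) {
  stopifnot(inherits(cfg, "stimulus_config"))
  fs <- cfg$sampling_rate_hz
  n <- round(cfg$duration_s * fs)
  period_samp <- fs / cfg$carrier_freq_hz
  onset0 <- seq(0, n - 1, by = period_samp) # fractional, sample units
  onset <- floor(onset0 + 0.5 + 1e-9) # nearest integer grid point
  onset <- onset[onset < n]
  t_on <- onset / fs
  env <- 1 + cfg$modulation_depth * sin(2 * pi * cfg$modulation_freq_hz * t_on)
  denom <- if (cfg$mapping == "affine") 1 + cfg$modulation_depth else 1
  width_s <- cfg$base_pulse_width_s * env / denom
  width <- pmax(1L, as.integer(round(width_s * fs)))
  if (any(width >= floor(period_samp))) {
    stop_assrmix(paste0(
      "Quantized pulse width reaches the inter-pulse interval; ",
      "reduce `base_pulse_width_s` or increase `sampling_rate_hz`."
    ))
  }
  tibble::tibble(
    pulse = seq_along(onset),
    onset_sample = as.integer(onset) + 1L,
    onset_time_s = t_on,
    width_samples = width,
    width_s = width / fs
  )
}

#' Generate the PWM monophasic pulse train
#'
#' Builds the stimulation current `i_stim`: rectangular monophasic pulses of
#' constant amplitude starting at integer multiples of `f_s / f_c` samples,
#' whose width follows the amplitude-modulated envelope
#' `base_pulse_width_s * (1 + MD sin(2 pi f_m t)) / (1 + MD)` (affine
#' mapping), quantized to at least one sample. The signal is zero between
#' pulses.
#'
#' @param cfg A [stimulus_config()].
#' @return A [sampled_signal()] of length `round(duration_s * f_s)`, units
#'   of `cfg$amplitude`.
#' @export
make_pwm_pulse_train <- function(cfg) {
  stopifnot(inherits(cfg, "stimulus_config"))
  fs <- cfg$sampling_rate_hz
  n <- round(cfg$duration_s * fs)
  tab <- pwm_pulse_table(cfg)
  x <- numeric(n)
  for (i in seq_len(nrow(tab))) {
    a <- tab$onset_sample[i]
    b <- min(n, a + tab$width_samples[i] - 1L)
    x[a:b] <- cfg$amplitude
  }
  sampled_signal(x, fs, units = "A")
}

#' Fraction of the inter-pulse interval occupied by one pulse's artifact
#'
#' Per-pulse contamination can outlast the active pulse (e.g. the passive
#' discharge of pseudo-monophasic implants spreads over about 1 ms). This
#' helper reports the fraction of the inter-pulse interval such a span
#' occupies, i.e. the fraction of signal a blanking approach would discard,
#' capped at 1.
#'
#' @param artifact_span_s Temporal spread of a single pulse's artifact in
#'   seconds (non-negative).
#' @param carrier_freq_hz Stimulation rate in Hz (positive).
#' @return `min(1, artifact_span_s * carrier_freq_hz)`.
#' @export
#' @examples
#' contamination_fraction(1e-3, 500) # 0.5
contamination_fraction <- function(artifact_span_s, carrier_freq_hz) {
  check_scalar(artifact_span_s, "artifact_span_s", allow_zero = TRUE)
  check_scalar(carrier_freq_hz, "carrier_freq_hz")
  min(1, artifact_span_s * carrier_freq_hz)
}
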