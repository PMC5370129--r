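#' Electrode-cochlea interface parameters
#'
#' First-order electrical model of the electrode-electrolyte interface: a
#' double-layer capacitance `C_dl` in parallel with a faradaic resistance
#' `Z_f`, in series with the cochlea's input resistance `R_s`. The interface
#' impedance is `Z_ec(s) = Z_f / (1 + s Z_f C_dl)` (single pole at
#' `1/(Z_f C_dl)`), so the potential induced by a stimulation current is
#' `v_stim = Z_ec * i_stim + R_s * i_stim`.
#'
#' Defaults give an interface time constant `Z_f C_dl` of 30 us, consistent
#' with clinical cochlear-implant electrode impedances and with the strongly
#' supra-Gaussian, temporally sparse artifact such implants produce.
#'
#' @param C_dl Double-layer capacitance in farads.
#' @param Z_f Faradaic resistance in ohms.
#' @param R_s Cochlea input resistance in ohms.
#' @return An object of class `interface_params`.
#' @export
interface_params <- function(C_dl = 3e-9, Z_f = 1e4, R_s = 1e3) {
  check_scalar(C_dl, "C_dl")
  check_scalar(Z_f, "Z_f")
  check_scalar(R_s, "R_s")
  structure(list(C_dl = C_dl, Z_f = Z_f, R_s = R_s),
            class = "interface_params")
}

#' Freeman wave-to-pulse sigmoid parameters
#'
#' Static nonlinearity mapping mean membrane potential to mean firing rate:
#' `S(v) = 2 e0 / (1 + exp(r (v0 - v)))`, increasing in `v`, with midpoint
#' `S(v0) = e0` and saturation `2 e0`. Defaults are standard neural-mass
#' values.
#'
#' @param e0 Half-maximum firing rate in s^-1.
#' @param v0 Potential (mV) at which the rate equals `e0`.
#' @param r Sigmoid slope in mV^-1.
#' @param increasing If `FALSE`, use the decreasing orientation
#'   `exp(r (v - v0))` instead (non-standard; provided for parity with
#'   alternative conventions).
#' @return An object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(e0 = 2.5, v0 = 6, r = 0.56, increasing = TRUE) {
  check_scalar(e0, "e0")
  check_scalar(r, "r")
  check_scalar(v0, "v0", positive = FALSE)
  structure(list(e0 = e0, v0 = v0, r = r, increasing = isTRUE(increasing)),
            class = "sigmoid_params")
}

#' Gaussian noise specification
#'
#' @param mean Mean of the Gaussian noise.
#' @param sd Standard deviation (non-negative).
#' @param seed Integer seed for the noise stream.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mean = 0, sd = 0, seed = 1L) {
  check_scalar(mean, "mean", positive = FALSE)
  check_scalar(sd, "sd", allow_zero = TRUE)
  structure(list(mean = mean, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Interface response: stimulation current to induced potential
#'
#' Applies the electrode-cochlea interface transfer function to a
#' stimulation current: `v_stim = Z_ec * i_stim + R_s * i_stim`, with
#' `Z_ec(s) = Z_f / (1 + s Z_f C_dl)`. The first-order path is discretized
#' with an exact zero-order-hold (matched exponential) step, stable at any
#' sampling rate:
#' `y[n] = e^{-dt/tau} y[n-1] + (1 - e^{-dt/tau}) Z_f x[n]`, `tau = Z_f C_dl`.
#'
#' @param i_stim A [sampled_signal()] stimulation current (amperes).
#' @param params An [interface_params()].
#' @return A [sampled_signal()] `v_stim` in volts, same length and rate.
#' @export
interface_response <- function(i_stim, params = interface_params()) {
  stopifnot(inherits(i_stim, "sampled_signal"), inherits(params, "interface_params"))
  fs <- i_stim$sampling_rate_hz
  tau <- params$Z_f * params$C_dl
  if (1 / tau > fs) {
    rlang::warn(sprintf(
      "Interface pole 1/(Z_f C_dl) = %.3g s^-1 is coarsely sampled at f_s = %g Hz (exact ZOH discretization remains stable).",
      1 / tau, fs
    ), class = "assrmix_pole_warning")
  }
  alpha <- exp(-1 / (fs * tau))
  y <- zec_filter_cpp(i_stim$samples, alpha, params$Z_f)
  sampled_signal(y + params$R_s * i_stim$samples, fs, units = "V")
}

#' Wave-to-pulse sigmoid rate
#'
#' @param v Numeric vector of membrane potentials (mV).
#' @param params A [sigmoid_params()].
#' @return Firing rates in s^-1, strictly within `(0, 2 e0)`.
#' @export
#' @examples
#' sigmoid_rate(6) # e0 = 2.5 at the midpoint
sigmoid_rate <- function(v, params = sigmoid_params()) {
  stopifnot(inherits(params, "sigmoid_params"))
  z <- if (params$increasing) params$r * (params$v0 - v) else params$r * (v - params$v0)
  2 * params$e0 / (1 + exp(z))
}

#' Cochlear module: artifact source and auditory-nerve drive
#'
#' Transforms the stimulation current into (a) the artifactual dipole time
#' course (`v_stim`, the interface response) and (b) the auditory-nerve mean
#' firing rate that drives the neural network:
#' `nerve_rate = S(drive_gain * v_stim + residual-hearing noise)`.
#'
#' Residual hearing is modelled as Gaussian additive noise on the membrane
#' potential ahead of the sigmoid.
#'
#' @param i_stim A [sampled_signal()] stimulation current.
#' @param interface An [interface_params()].
#' @param sigmoid A [sigmoid_params()].
#' @param residual A [noise_spec()] for residual hearing (mV).
#' @param drive_gain Coupling from the interface potential (V) to the
#'   auditory-nerve membrane potential (mV); default 1000 (plain V-to-mV).
#' @return A list with elements `artifact_source` (a [sampled_signal()],
#'   volts) and `nerve_rate` (a [sampled_signal()], s^-1).
#' @export
cochlear_module <- function(i_stim,
                            interface = interface_params(),
                            sigmoid = sigmoid_params(),
                            residual = noise_spec(mean = 0, sd = 2, seed = 1L),
                            drive_gain = 1000) {
  stopifnot(inherits(i_stim, "sampled_signal"))
  check_scalar(drive_gain, "drive_gain", positive = FALSE)
  v_stim <- interface_response(i_stim, interface)
  v_mv <- drive_gain * v_stim$samples
  if (residual$sd > 0) {
    noise <- with_seed_(residual$seed,
      rnorm(length(v_mv), residual$mean, residual$sd))
  } else {
    noise <- rep(residual$mean, length(v_mv))
  }
  rate <- sigmoid_rate(v_mv + noise, sigmoid)
  list(
    artifact_source = v_stim,
    nerve_rate = sampled_signal(rate, i_stim$sampling_rate_hz, units = "s^-1")
  )
}
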