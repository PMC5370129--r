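#' Neural-mass population kernel parameters
#'
#' Second-order post-synaptic-potential kernels `h(t) = G w t exp(-w t)` for
#' the three synapse families of the model: excitatory (gain `A`, rate `a`),
#' slow GABAergic inhibition (`B`, `b`) and fast GABAergic inhibition
#' (`G`, `g`). Defaults are the standard neural-mass constants
#' (A = 3.25 mV / a = 100 s^-1, B = 22 mV / b = 50 s^-1,
#' G = 10 mV / g = 500 s^-1).
#'
#' @param A,a Excitatory kernel gain (mV) and rate (s^-1).
#' @param B,b Slow-inhibitory kernel gain (mV) and rate (s^-1).
#' @param a_bs,a_th Excitatory kernel rates (s^-1) of the brainstem and
#'   thalamic principal populations. Subcortical relay neurons phase-lock to
#'   far higher rates than cortical populations; faster kernels (defaults
#'   1000 and 300 s^-1, gains rescaled to preserve the A/a DC gain) let the
#'   brainstem output retain the stimulation carrier while the thalamus and
#'   then the cortex progressively low-pass it.
#' @param G,g Fast-inhibitory kernel gain (mV) and rate (s^-1).
#' @param sigmoid A [sigmoid_params()] shared by all populations.
#' @return An object of class `population_params`.
#' @export
population_params <- function(A = 3.25, a = 100, B = 22, b = 50,
                              G = 10, g = 500, a_bs = 1000, a_th = 300,
                              sigmoid = sigmoid_params()) {
  for (nm in c("A", "a", "B", "b", "G", "g", "a_bs", "a_th")) {
    check_scalar(get(nm), nm)
  }
  stopifnot(inherits(sigmoid, "sigmoid_params"))
  structure(list(A = A, a = a, B = B, b = b, G = G, g = g, a_bs = a_bs, a_th = a_th,
                 sigmoid = sigmoid),
            class = "population_params")
}

#' Network connectivity and per-population noise
#'
#' Directed dimensionless gains between the model's nodes and the Gaussian
#' noise inputs on the principal populations. The cochlear nerve rate drives
#' the brainstem principal population (`coch_bs`); the brainstem excites the
#' thalamic (`bs_th`) and, weakly, the cortical (`bs_a1`) principal
#' populations; the thalamo-cortical relay (`th_a1`) carries the main
#' ascending drive to each ipsilateral cortex; the brainstem receives weak
#' excitatory feedback from thalamus and cortex (`th_bs`, `a1_bs`). Within
#' each cortical/thalamic module the principal population excites the fast
#' and slow interneurons (`p_i`, `p_is`) and receives their inhibition
#' (`i_p`, `is_p`); `p_ibs`/`ibs_p` are the brainstem's internal loop.
#' `coch_th`/`coch_a1` allow direct cochlear drive to thalamus/cortex
#' (default 0: the brainstem is the relay).
#'
#' @param ... Named gain overrides (see Details above for names).
#' @param noise Named list of [noise_spec()] for the principal populations
#'   `bs`, `th_l`, `th_r`, `a1_l`, `a1_r`. Noise enters the excitatory
#'   kernel of each principal population (Euler-Maruyama, intensity in
#'   rate units per sqrt-second).
#' @return An object of class `connectivity`.
#' @export
connectivity <- function(...,
                         noise = list(
                           bs   = noise_spec(mean = 10, sd = 2),
                           th_l = noise_spec(mean = 10, sd = 0),
                           th_r = noise_spec(mean = 10, sd = 0),
                           a1_l = noise_spec(mean = 10, sd = 2),
                           a1_r = noise_spec(mean = 10, sd = 2)
                         )) {
  gains <- list(
    coch_bs = 60, coch_th = 0, coch_a1 = 0,
    bs_th = 50, th_a1 = 50, bs_a1 = 1, th_bs = 2, a1_bs = 2,
    p_i = 25, i_p = 25, p_is = 20, is_p = 20, p_ibs = 25, ibs_p = 20
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(gains))
    if (length(bad)) {
      stop_assrmix(paste0("Unknown connectivity gain(s): ",
                          paste(bad, collapse = ", ")))
    }
    gains <- modifyList(gains, dots)
  }
  if (any(unlist(gains) < 0)) stop_assrmix("Connectivity gains must be >= 0.")
  need <- c("bs", "th_l", "th_r", "a1_l", "a1_r")
  if (!all(need %in% names(noise))) {
    stop_assrmix("`noise` must name specs for bs, th_l, th_r, a1_l, a1_r.")
  }
  structure(list(gains = gains, noise = noise[need]), class = "connectivity")
}

#' Simulated source dynamics
#'
#' Container for the six dipole time courses: the five neural sources
#' (brainstem, left/right thalamus, left/right primary auditory cortex) and
#' the artifactual (cochlear stimulation) source.
#'
#' @param sources Numeric matrix `6 x n` with rownames
#'   `c("brainstem","thalamus_l","thalamus_r","a1_l","a1_r","artifact")`.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return An object of class `source_dynamics`.
#' @export
source_dynamics <- function(sources, sampling_rate_hz) {
  check_scalar(sampling_rate_hz, "sampling_rate_hz")
  roles <- c("brainstem", "thalamus_l", "thalamus_r", "a1_l", "a1_r", "artifact")
  if (!is.matrix(sources) || !identical(rownames(sources), roles)) {
    stop_assrmix("`sources` must be a matrix with rows brainstem, thalamus_l, thalamus_r, a1_l, a1_r, artifact.")
  }
  if (any(!is.finite(sources))) stop_assrmix("Source dynamics must be finite.")
  structure(list(sources = sources, sampling_rate_hz = sampling_rate_hz,
                 roles = roles),
            class = "source_dynamics")
}

#' @export
print.source_dynamics <- function(x, ...) {
  cat(sprintf("<source_dynamics> 6 sources x %d samples @ %g Hz\n",
              ncol(x$sources), x$sampling_rate_hz))
  invisible(x)
}

#' @rdname source_dynamics
#' @param x A `source_dynamics`.
#' @param ... Unused.
#' @export
as_tibble.source_dynamics <- function(x, ...) {
  tb <- tibble::as_tibble(t(x$sources))
  tb$time_s <- (seq_len(ncol(x$sources)) - 1) / x$sampling_rate_hz
  tidyr::pivot_longer(tb, -"time_s", names_to = "source", values_to = "value")
}

#' Simulate the five-module auditory network
#'
#' Integrates the neural-mass dynamics of the brainstem, bilateral thalamus
#' and bilateral primary auditory cortex driven by the auditory-nerve mean
#' firing rate. Each population's input rates pass a second-order synaptic
#' kernel and the Freeman sigmoid; Gaussian noise enters the excitatory
#' kernel of every principal population (Euler-Maruyama at `dt = 1/f_s`).
#' The module output is the principal population's mean membrane potential.
#'
#' @param nerve_rate A [sampled_signal()] of auditory-nerve firing rate
#'   (s^-1), as produced by [cochlear_module()].
#' @param pops A [population_params()].
#' @param conn A [connectivity()].
#' @param burn_in_s Initial transient discarded from the output (seconds).
#'   The nerve-rate signal must cover `burn_in_s` in addition to the
#'   returned duration; the first `burn_in_s * f_s` samples are dropped.
#' @param seed Integer seed for the population noise streams.
#' @param guard Divergence guard: integration aborts if any membrane
#'   potential exceeds this bound (mV).
#' @return A numeric matrix `5 x n` (rows `brainstem`, `thalamus_l`,
#'   `thalamus_r`, `a1_l`, `a1_r`) of mean membrane potentials (mV), with
#'   the burn-in removed.
#' @export
simulate_network <- function(nerve_rate, pops = population_params(),
                             conn = connectivity(), burn_in_s = 1,
                             seed = 1L, guard = 1e4) {
  stopifnot(inherits(nerve_rate, "sampled_signal"),
            inherits(pops, "population_params"),
            inherits(conn, "connectivity"))
  fs <- nerve_rate$sampling_rate_hz
  n_burn <- round(burn_in_s * fs)
  if (length(nerve_rate) <= n_burn) {
    stop_assrmix("`nerve_rate` must be longer than the burn-in window.")
  }
  par <- c(pops[c("A", "a", "B", "b", "G", "g", "a_bs", "a_th")],
           pops$sigmoid[c("e0", "v0", "r")],
           conn$gains, list(guard = guard))
  nm <- vapply(conn$noise, `[[`, numeric(1), "mean")
  ns <- vapply(conn$noise, `[[`, numeric(1), "sd")
  out <- with_seed_(seed,
    simulate_network_cpp(nerve_rate$samples, 1 / fs, par, nm, ns))
  rownames(out) <- c("brainstem", "thalamus_l", "thalamus_r", "a1_l", "a1_r")
  if (n_burn > 0) out <- out[, -seq_len(n_burn), drop = FALSE]
  out
}

#' Fixed point of the network under constant drive
#'
#' Solves the algebraic steady-state system of the noise-free network for a
#' constant auditory-nerve rate: every second-order kernel settles at
#' `y = (gain / rate) * input`, so the fixed point satisfies a small
#' nonlinear system in the principal-cell potentials, solved here by damped
#' fixed-point iteration.
#'
#' @param pops A [population_params()].
#' @param conn A [connectivity()].
#' @param constant_drive Constant nerve firing rate (s^-1).
#' @param tol Convergence tolerance on the potentials (mV).
#' @param max_iter Iteration cap.
#' @return Named numeric vector of steady-state principal potentials (mV)
#'   for `brainstem`, `thalamus_l`, `thalamus_r`, `a1_l`, `a1_r`.
#' @export
steady_state <- function(pops = population_params(), conn = connectivity(),
                         constant_drive = 0, tol = 1e-10, max_iter = 10000) {
  g <- conn$gains
  sig <- pops$sigmoid
  ke <- pops$A / pops$a   # DC gain of excitatory kernel
  ks <- pops$B / pops$b   # slow inhibition
  kf <- pops$G / pops$g   # fast inhibition
  nmean <- vapply(conn$noise, `[[`, numeric(1), "mean")
  S <- function(v) sigmoid_rate(v, sig)

  v <- setNames(numeric(5), c("brainstem", "thalamus_l", "thalamus_r",
                              "a1_l", "a1_r"))
  step <- function(v) {
    s <- S(v)
    # interneuron potentials are algebraic functions of the principal rates
    v_ibs <- ke * g$p_ibs * s["brainstem"]
    bs <- ke * (g$coch_bs * constant_drive +
                  g$th_bs * (s["thalamus_l"] + s["thalamus_r"]) +
                  g$a1_bs * (s["a1_l"] + s["a1_r"]) + nmean[["bs"]]) -
      ks * g$ibs_p * S(v_ibs)
    mod <- function(drive, noise_mean, s_self) {
      v_i <- ke * g$p_i * s_self
      v_is <- ke * g$p_is * s_self
      ke * (drive + noise_mean) - kf * g$i_p * S(v_i) - ks * g$is_p * S(v_is)
    }
    th_l <- mod(g$bs_th * s["brainstem"] + g$coch_th * constant_drive,
                nmean[["th_l"]], s["thalamus_l"])
    th_r <- mod(g$bs_th * s["brainstem"] + g$coch_th * constant_drive,
                nmean[["th_r"]], s["thalamus_r"])
    a1_l <- mod(g$th_a1 * s["thalamus_l"] + g$bs_a1 * s["brainstem"] +
                  g$coch_a1 * constant_drive, nmean[["a1_l"]], s["a1_l"])
    a1_r <- mod(g$th_a1 * s["thalamus_r"] + g$bs_a1 * s["brainstem"] +
                  g$coch_a1 * constant_drive, nmean[["a1_r"]], s["a1_r"])
    c(brainstem = unname(bs), thalamus_l = unname(th_l),
      thalamus_r = unname(th_r), a1_l = unname(a1_l), a1_r = unname(a1_r))
  }
  damp <- 0.5
  for (i in seq_len(max_iter)) {
    v_new <- (1 - damp) * v + damp * step(v)
    if (max(abs(v_new - v)) < tol) {
      return(v_new)
    }
    v <- v_new
  }
  stop_assrmix("Fixed-point iteration did not converge; no root found.")
}
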