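#' Cut a signal into contiguous modulation-locked epochs
#'
#' Splits a signal into consecutive non-overlapping segments whose duration
#' `D = k * (1 / f_m)` is an integer number of modulation cycles, so the
#' analysis frequency falls exactly on an FFT bin. The trailing remainder is
#' discarded.
#'
#' @param x A [sampled_signal()] or numeric vector.
#' @param f_m Analysis (modulation) frequency in Hz.
#' @param k Number of modulation cycles per epoch (default 20).
#' @param sampling_rate_hz Required if `x` is a bare numeric vector.
#' @return An object of class `epoch_set`: list with `epochs`
#'   (`n_epochs x samples` matrix), `sampling_rate_hz`, `f_m`, `k`,
#'   `epoch_length` and `duration_s`.
#' @export
epoch_signal <- function(x, f_m, k = 20, sampling_rate_hz = NULL) {
  if (inherits(x, "sampled_signal")) {
    fs <- x$sampling_rate_hz
    x <- x$samples
  } else {
    fs <- sampling_rate_hz
    if (is.null(fs)) stop_assrmix("`sampling_rate_hz` required for bare vectors.")
  }
  check_scalar(f_m, "f_m")
  check_scalar(k, "k")
  len <- round(k * fs / f_m)
  if (abs(len - k * fs / f_m) > 1) {
    stop_assrmix("Epoch duration k/f_m is not representable within one sample at this rate.")
  }
  n_ep <- floor(length(x) / len)
  if (n_ep < 1) stop_assrmix("Signal shorter than one epoch; nothing to epoch.")
  ep <- matrix(x[seq_len(n_ep * len)], nrow = n_ep, ncol = len, byrow = TRUE)
  structure(
    list(epochs = ep, sampling_rate_hz = fs, f_m = f_m, k = k,
         epoch_length = len, duration_s = len / fs),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d samples (D = %.4g s = %d cycles of %g Hz)\n",
              nrow(x$epochs), x$epoch_length, x$duration_s, x$k, x$f_m))
  invisible(x)
}

# internal: FFT bin index (1-based) of frequency f in an epoch
epoch_bin <- function(ep, f = ep$f_m) {
  1L + as.integer(round(f * ep$epoch_length / ep$sampling_rate_hz))
}

#' Epoch-averaged ASSR amplitude at the modulation frequency
#'
#' Averages consecutive modulation-locked segments in the time domain (the
#' standard coherent-averaging step that re-establishes the spectral peak at
#' `f_m`), then returns the single-sided FFT amplitude of the bin at `f_m`.
#' Because the segment length is an exact number of modulation cycles the
#' bin is leakage-free.
#'
#' @inheritParams epoch_signal
#' @param n_segments Number of segments to average; the available number is
#'   used if fewer exist (default all).
#' @return Amplitude (same units as `x`) at `f_m`.
#' @export
assr_amplitude <- function(x, f_m, k = 20, n_segments = Inf,
                           sampling_rate_hz = NULL) {
  ep <- epoch_signal(x, f_m, k, sampling_rate_hz)
  n_use <- min(n_segments, nrow(ep$epochs))
  avg <- colMeans(ep$epochs[seq_len(n_use), , drop = FALSE])
  bin <- epoch_bin(ep)
  if (bin > floor(length(avg) / 2) + 1L) {
    stop_assrmix("`f_m` is not resolvable by the segment length.")
  }
  2 * Mod(fft(avg)[bin]) / length(avg)
}

#' Phase coherence of epoch FFT phases at the analysis frequency
#'
#' Resultant-vector statistic of the per-epoch FFT phases at `f_m`:
#' `PC = (1/N) sqrt((sum cos(theta_i))^2 + (sum sin(theta_i))^2)`.
#' `PC = 1` indicates perfect phase-locking; values below 0.5 indicate poor
#' phase-locking. A response is conventionally detected when PC exceeds 0.8
#' over sweeps of 20 epochs.
#'
#' @param ep An [epoch_signal()] result, or a numeric vector of phases in
#'   radians (when `ep` is a bare numeric vector it is interpreted as the
#'   phases `theta_i` directly).
#' @param detect_threshold Detection threshold on PC (default 0.8).
#' @return A tibble with columns `pc`, `n_epochs`, `detected`.
#' @export
phase_coherence <- function(ep, detect_threshold = 0.8) {
  if (is.numeric(ep)) {
    theta <- ep
  } else {
    stopifnot(inherits(ep, "epoch_set"))
    if (nrow(ep$epochs) < 2) stop_assrmix("Phase coherence needs at least 2 epochs.")
    bin <- epoch_bin(ep)
    co <- t(apply(ep$epochs, 1, function(row) {
      z <- fft(row)[bin]
      c(Mod(z), Arg(z))
    }))
    zero <- co[, 1] < .Machine$double.eps * ep$epoch_length
    if (any(zero)) {
      rlang::warn(sprintf(
        "%d epoch(s) have zero amplitude at f_m; undefined phase, excluded.",
        sum(zero)))
    }
    theta <- co[!zero, 2]
    if (length(theta) < 2) stop_assrmix("Fewer than 2 epochs with defined phase.")
  }
  n <- length(theta)
  pc <- sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / n
  tibble::tibble(pc = pc, n_epochs = n, detected = pc > detect_threshold)
}

#' Per-electrode amplitude estimation error
#'
#' Percentage error of denoised ASSR amplitude estimates against the
#' uncontaminated neural ground truth:
#' `100 * (denoised - neural) / neural`. Positive errors indicate
#' artifactual residue in the denoised data; negative errors indicate
#' over-removal (neural response rejected together with the artifact).
#' Electrodes with zero neural amplitude are excluded and reported.
#'
#' @param denoised_amp Named numeric vector of per-electrode amplitudes from
#'   the denoised dataset.
#' @param neural_amp Named numeric vector of ground-truth amplitudes for the
#'   same electrodes.
#' @return A tibble with columns `electrode`, `denoised`, `neural`,
#'   `error_pct`, `excluded`.
#' @export
estimation_error <- function(denoised_amp, neural_amp) {
  if (!identical(names(denoised_amp), names(neural_amp)) ||
      is.null(names(denoised_amp))) {
    stop_assrmix("Amplitude vectors must be named identically (same electrodes).")
  }
  excluded <- neural_amp <= 0
  if (any(excluded)) {
    rlang::warn(sprintf("%d electrode(s) with zero neural amplitude excluded.",
                        sum(excluded)))
  }
  tibble::tibble(
    electrode = names(denoised_amp),
    denoised = unname(denoised_amp),
    neural = unname(neural_amp),
    error_pct = unname(ifelse(excluded, NA_real_,
                              100 * (denoised_amp - neural_amp) / neural_amp)),
    excluded = unname(excluded)
  )
}

#' Scott's-rule histogram bin count
#'
#' Bin width `3.49 * sd(x) * N^(-1/3)`; the bin count is the observed range
#' divided by that width, rounded up.
#'
#' @param x Numeric vector.
#' @return Integer bin count.
#' @export
scott_bins <- function(x) {
  rng <- diff(range(x))
  if (rng == 0) stop_assrmix("Constant signal: zero-width range.")
  w <- 3.49 * sd(x) * length(x)^(-1 / 3)
  as.integer(ceiling(rng / w))
}

#' Histogram mutual information with analytic bias correction
#'
#' Plug-in (naive histogram) mutual information between two signals from an
#' `M x M` equal-width 2-D histogram over each signal's observed range,
#' in nats. The estimator's upward bias is corrected analytically by
#' `(M - 1)^2 / (2 N)`; the corrected value is reported signed, so small
#' negative values indicate independence within estimator noise.
#'
#' With `bins = "auto"` the bin count follows Scott's rule per signal and
#' the smallest count across the two signals is used (minimising bias).
#'
#' @param x,y Numeric vectors of equal length `N >= 1000`.
#' @param bins Integer bin count `M`, or `"auto"`.
#' @return A tibble with columns `mi_raw`, `bias`, `mi_corrected`, `bins`,
#'   `n`.
#' @export
mutual_information <- function(x, y, bins = "auto") {
  n <- length(x)
  if (length(y) != n) stop_assrmix("`x` and `y` must have equal length.")
  if (n < 1000) stop_assrmix("Mutual information requires at least 1000 samples.")
  if (identical(bins, "auto")) {
    m <- min(scott_bins(x), scott_bins(y))
  } else {
    m <- as.integer(bins)
    if (diff(range(x)) == 0 || diff(range(y)) == 0) {
      stop_assrmix("Constant signal: zero-width range.")
    }
  }
  ix <- pmin(m, pmax(1L, as.integer(ceiling((x - min(x)) / diff(range(x)) * m))))
  iy <- pmin(m, pmax(1L, as.integer(ceiling((y - min(y)) / diff(range(y)) * m))))
  joint <- tabulate(ix + m * (iy - 1L), nbins = m * m) / n
  px <- tabulate(ix, nbins = m) / n
  py <- tabulate(iy, nbins = m) / n
  jm <- matrix(joint, m, m)
  prod_p <- outer(px, py)
  nz <- jm > 0
  mi <- sum(jm[nz] * log(jm[nz] / prod_p[nz]))
  bias <- (m - 1)^2 / (2 * n)
  tibble::tibble(mi_raw = mi, bias = bias, mi_corrected = mi - bias,
                 bins = m, n = n)
}

# G(u) = log(cosh(a u)) / a, evaluated in overflow-safe form
logcosh_contrast <- function(u, a = 1) {
  z <- abs(a * u)
  (z + log1p(exp(-2 * z)) - log(2)) / a
}

# E[ G(g) ] for g ~ N(0,1); cached per `a`
gauss_logcosh_env <- new.env(parent = emptyenv())
gauss_logcosh <- function(a) {
  key <- format(a, digits = 17)
  if (is.null(gauss_logcosh_env[[key]])) {
    gauss_logcosh_env[[key]] <- integrate(
      function(u) logcosh_contrast(u, a) * exp(-u^2 / 2) / sqrt(2 * pi),
      -Inf, Inf, rel.tol = 1e-12
    )$value
  }
  gauss_logcosh_env[[key]]
}

#' Log-cosh negentropy estimate
#'
#' Distance of a signal's distribution from Gaussianity:
#' `J = (E[G(y)] - E[G(g)])^2` with `G(u) = log(cosh(a u)) / a` and `g` a
#' standard normal variable. The signal is standardised to zero mean and
#' unit variance first, so the estimate is invariant to affine rescaling;
#' `E[G(g)]` is computed once by high-precision quadrature (0.3745672...
#' for `a = 1`) and cached.
#'
#' @param y Numeric vector (non-constant).
#' @param a Contrast parameter in `[1, 2]` (default 1).
#' @return Negentropy estimate (non-negative up to estimator noise).
#' @export
negentropy <- function(y, a = 1) {
  if (sd(y) == 0) stop_assrmix("Constant input: negentropy undefined.")
  z <- (y - mean(y)) / sd(y)
  (mean(logcosh_contrast(z, a)) - gauss_logcosh(a))^2
}

#' Non-Gaussianity screen: kurtosis and Anderson-Darling test
#'
#' Sample excess kurtosis and the Anderson-Darling composite normality test
#' (case with estimated mean and variance) at level `alpha`.
#'
#' @param x Numeric vector, `N >= 100`, non-constant.
#' @param alpha Significance level (default `1e-3`).
#' @return A tibble with columns `excess_kurtosis`, `ad_statistic`,
#'   `ad_p_value`, `normality_rejected`, `n`.
#' @export
source_stats <- function(x, alpha = 1e-3) {
  if (length(x) < 100) stop_assrmix("`x` must have at least 100 samples.")
  if (sd(x) == 0) stop_assrmix("Constant input.")
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  ad <- nortest::ad.test(x)
  tibble::tibble(
    excess_kurtosis = m4 / m2^2 - 3,
    ad_statistic = unname(ad$statistic),
    ad_p_value = ad$p.value,
    normality_rejected = ad$p.value < alpha,
    n = length(x)
  )
}
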