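#' Signal-subspace dimension from the covariance noise floor
#'
#' Counts channel-covariance eigenvalues exceeding the sensor-noise floor,
#' estimated by default as `threshold_factor` times the median eigenvalue
#' (the median is dominated by the flat noise part of the spectrum). This is
#' the component count fastICA retains automatically.
#'
#' @param eeg An [eeg_dataset()] or channels x samples matrix.
#' @param threshold_factor Multiple of the median eigenvalue an eigenvalue
#'   must exceed to count as signal (default 10).
#' @return Integer dimension estimate.
#' @export
estimate_dimension <- function(eeg, threshold_factor = 10) {
  X <- if (inherits(eeg, "eeg_dataset")) eeg$data else as.matrix(eeg)
  if (nrow(X) < 2) stop_assrmix("Need at least 2 channels.")
  Xc <- X - rowMeans(X)
  ev <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE,
              only.values = TRUE)$values
  sum(ev > threshold_factor * median(ev))
}

# internal: band energy of a spectrum (single-sided power) around centre
# frequencies, half-width band_hz
band_energy <- function(pw, freq, centres, band_hz) {
  sel <- rep(FALSE, length(freq))
  for (f0 in centres) sel <- sel | abs(freq - f0) <= band_hz
  sum(pw[sel])
}

#' Flag artifactual independent components
#'
#' Automated version of the manual rejection practice: a component is
#' flagged when both
#' (a) its spectral energy in the stimulation carrier band (`f_c +/- band_hz`
#' and its harmonics up to Nyquist) exceeds `spectral_ratio` times its
#' energy around the modulation frequency, and
#' (b) the absolute correlation of its scalp map with the supplied artifact
#' topography exceeds `topo_threshold`.
#'
#' @param res An [run_ica()] result.
#' @param f_c Stimulation carrier frequency in Hz (below Nyquist).
#' @param artifact_topography Numeric vector: expected artifact scalp map
#'   (e.g. the cochlear column of the artifact lead field), one value per
#'   channel.
#' @param f_m Modulation frequency in Hz.
#' @param spectral_ratio Carrier-to-modulation energy ratio threshold
#'   (default 5).
#' @param topo_threshold Absolute scalp-map correlation threshold
#'   (default 0.8).
#' @param band_hz Half-width of the spectral bands (default 10).
#' @return Integer vector of flagged component indices (possibly empty).
#' @export
classify_artifact_ics <- function(res, f_c, artifact_topography,
                                  f_m = 39.0625, spectral_ratio = 5,
                                  topo_threshold = 0.8, band_hz = 10) {
  stopifnot(inherits(res, "ica_result"))
  fs <- res$sampling_rate_hz
  if (!is.finite(fs)) stop_assrmix("ICA result lacks a sampling rate.")
  if (f_c >= fs / 2) stop_assrmix("`f_c` must be below the Nyquist frequency.")
  if (length(artifact_topography) != length(res$labels)) {
    stop_assrmix("`artifact_topography` must have one value per channel.")
  }
  n <- ncol(res$activations)
  freq <- (seq_len(floor(n / 2) + 1L) - 1L) * fs / n
  harmonics <- seq(f_c, fs / 2, by = f_c)
  flagged <- integer(0)
  for (i in seq_len(res$n_components)) {
    sp <- fft(res$activations[i, ])
    pw <- Mod(sp[seq_along(freq)])^2
    e_carrier <- band_energy(pw, freq, harmonics, band_hz)
    e_mod <- band_energy(pw, freq, f_m, band_hz)
    tc <- abs(stats::cor(res$scalp_maps[, i], artifact_topography))
    if (e_carrier > spectral_ratio * max(e_mod, .Machine$double.xmin) &&
        tc > topo_threshold) {
      flagged <- c(flagged, i)
    }
  }
  flagged
}

#' Reject components and reconstruct denoised EEG
#'
#' Zeroes the rejected component activations and back-projects the
#' remainder to channel space (adding back the channel means). With nothing
#' rejected this reproduces the PCA-subspace projection of the input.
#'
#' @param eeg The [eeg_dataset()] the decomposition was fitted to.
#' @param res An [run_ica()] result for `eeg`.
#' @param reject Integer indices of components to reject.
#' @return An [eeg_dataset()] with `kind = "denoised"`; metadata records the
#'   algorithm and rejected indices.
#' @export
reject_and_reconstruct <- function(eeg, res, reject = integer(0)) {
  stopifnot(inherits(eeg, "eeg_dataset"), inherits(res, "ica_result"))
  reject <- as.integer(reject)
  if (length(reject) && (min(reject) < 1 || max(reject) > res$n_components)) {
    stop_assrmix("`reject` indices out of range.")
  }
  keep <- setdiff(seq_len(res$n_components), reject)
  if (!length(keep)) stop_assrmix("Cannot reject every component.")
  recon <- res$mixing[, keep, drop = FALSE] %*%
    res$activations[keep, , drop = FALSE] + res$center
  meta <- c(eeg$meta, list(algorithm = res$algorithm, rejected = reject))
  eeg_dataset(recon, eeg$sampling_rate_hz, eeg$labels, "denoised", meta)
}
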