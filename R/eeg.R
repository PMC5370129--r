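#' Multichannel EEG dataset
#'
#' Channels-by-samples scalp potentials with montage labels and a kind tag
#' distinguishing the mixture (`mix`), the uncontaminated control (`assr`),
#' the artifact-only projection (`art`) and denoised data (`denoised`).
#'
#' @param data Numeric matrix `n_channels x n_samples` (microvolts).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param labels Character vector of channel labels (unique, one per row).
#' @param kind One of `"mix"`, `"assr"`, `"art"`, `"denoised"`, `"raw"`.
#' @param meta Named list of free-form scenario metadata (seed, scenario
#'   hash, ...).
#' @return An object of class `eeg_dataset`.
#' @export
eeg_dataset <- function(data, sampling_rate_hz, labels, kind = "raw",
                        meta = list()) {
  check_scalar(sampling_rate_hz, "sampling_rate_hz")
  kind <- match.arg(kind, c("mix", "assr", "art", "denoised", "raw"))
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_assrmix("`data` must be a numeric channels x samples matrix.")
  }
  if (any(!is.finite(data))) stop_assrmix("EEG data must be finite.")
  labels <- as.character(labels)
  if (length(labels) != nrow(data) || anyDuplicated(labels)) {
    stop_assrmix("`labels` must be unique, one per data row.")
  }
  rownames(data) <- labels
  structure(list(data = data, sampling_rate_hz = sampling_rate_hz,
                 labels = labels, kind = kind, meta = meta),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset:%s> %d channels x %d samples @ %g Hz (%.4g s)\n",
              x$kind, nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              ncol(x$data) / x$sampling_rate_hz))
  invisible(x)
}

#' @rdname eeg_dataset
#' @param x An `eeg_dataset`.
#' @param ... Unused.
#' @export
as_tibble.eeg_dataset <- function(x, ...) {
  tb <- tibble::as_tibble(t(x$data))
  tb$time_s <- (seq_len(ncol(x$data)) - 1) / x$sampling_rate_hz
  out <- tidyr::pivot_longer(tb, -"time_s", names_to = "channel",
                             values_to = "potential_uv")
  out$kind <- x$kind
  out
}

#' Synthesize the scalp EEG triple from source dynamics
#'
#' Projects the source dynamics through the fixed-orientation lead fields
#' and adds white sensor noise:
#' `EEG_ASSR = LF1 S_n`, `EEG_Art = LF2 S_Art`,
#' `EEG_mix = EEG_ASSR + EEG_Art + b`, where `b` is i.i.d. Gaussian noise
#' at the recording electrodes. Dipole orientations are already folded into
#' the lead-field columns. Calibration scalars map the arbitrary-unit
#' neural and artifactual source amplitudes to scalp microvolts.
#'
#' @param src A [source_dynamics()].
#' @param lf1 A [sphere_lead_field()] for the five neural dipoles (columns
#'   `brainstem`, `thalamus_l`, `thalamus_r`, `a1_l`, `a1_r`).
#' @param lf2 A lead field for the artifactual (cochlear) dipole (single
#'   column `cochlea`).
#' @param sensor_noise A [noise_spec()] for the electrode noise `b`
#'   (microvolts).
#' @param neural_gain Dipole-moment calibration for the neural sources
#'   (scalp microvolts result per source unit and lead-field unit).
#' @param artifact_gain Same for the artifactual source.
#' @param seed Seed for the sensor-noise realisation.
#' @return A list with elements `mix`, `assr`, `art` (each an
#'   [eeg_dataset()]) and `noise` (the matrix `b`).
#' @export
synthesize_eeg <- function(src, lf1, lf2,
                           sensor_noise = noise_spec(mean = 0, sd = 0.25),
                           neural_gain = 1, artifact_gain = 1, seed = 1L) {
  stopifnot(inherits(src, "source_dynamics"))
  neural_rows <- c("brainstem", "thalamus_l", "thalamus_r", "a1_l", "a1_r")
  if (!identical(colnames(lf1), neural_rows)) {
    stop_assrmix("`lf1` must have columns brainstem, thalamus_l, thalamus_r, a1_l, a1_r (in order).")
  }
  if (!identical(colnames(lf2), "cochlea")) {
    stop_assrmix("`lf2` must have the single column `cochlea`.")
  }
  if (!identical(rownames(lf1), rownames(lf2))) {
    stop_assrmix("`lf1` and `lf2` must share the same electrodes.")
  }
  labels <- rownames(lf1)
  sn <- src$sources[neural_rows, , drop = FALSE]
  sa <- src$sources["artifact", , drop = FALSE]
  assr <- neural_gain * (unclass(lf1) %*% sn)
  art <- artifact_gain * (unclass(lf2) %*% sa)
  n <- ncol(assr)
  b <- matrix(0, nrow(assr), n)
  if (sensor_noise$sd > 0 || sensor_noise$mean != 0) {
    b <- with_seed_(seed,
      matrix(rnorm(nrow(assr) * n, sensor_noise$mean, sensor_noise$sd),
             nrow(assr), n))
  }
  mix <- assr + art + b
  meta <- list(seed = seed, neural_gain = neural_gain,
               artifact_gain = artifact_gain,
               sensor_noise_sd = sensor_noise$sd)
  list(
    mix = eeg_dataset(mix, src$sampling_rate_hz, labels, "mix", meta),
    assr = eeg_dataset(assr, src$sampling_rate_hz, labels, "assr", meta),
    art = eeg_dataset(art, src$sampling_rate_hz, labels, "art", meta),
    noise = b
  )
}

#' Import a precomputed lead field
#'
#' Reads a plain-text lead-field matrix with its JSON sidecar (electrode
#' labels and dipole roles), e.g. one exported from a boundary-element
#' forward model, for use in place of the analytic sphere solution.
#'
#' @param path Path to the matrix file (TSV, electrodes x dipoles) written
#'   by [write_lead_field()]; `<path>.json` must hold the sidecar.
#' @return A `lead_field` with provenance `"imported"`.
#' @export
load_lead_field <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json"))) {
    stop_assrmix("Lead-field matrix or JSON sidecar not found.")
  }
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  if (nrow(m) != length(side$labels) || ncol(m) != length(side$roles)) {
    stop_assrmix(sprintf(
      "Lead-field shape %d x %d does not match sidecar (%d electrodes, %d dipoles).",
      nrow(m), ncol(m), length(side$labels), length(side$roles)))
  }
  dimnames(m) <- list(side$labels, side$roles)
  structure(m, provenance = "imported", labels = side$labels,
            roles = side$roles, class = c("lead_field", "matrix", "array"))
}

#' Export a lead field
#'
#' @param lf A `lead_field`.
#' @param path Output path for the TSV matrix; a JSON sidecar with
#'   electrode labels and dipole roles is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_lead_field <- function(lf, path) {
  stopifnot(inherits(lf, "lead_field"))
  utils::write.table(format(unclass(lf), digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(labels = rownames(lf), roles = colnames(lf),
         provenance = attr(lf, "provenance")),
    paste0(path, ".json")
  )
  invisible(path)
}
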