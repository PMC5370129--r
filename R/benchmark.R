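#' Fronto-central region of interest
#'
#' The twelve fronto-central electrodes over which ASSR estimation error is
#' aggregated.
#'
#' @return Character vector of electrode labels.
#' @export
roi_electrodes <- function() {
  c("Fz", "F3", "F7", "FC5", "FC1", "C3", "Cz", "C4", "FC6", "FC2", "F4", "F8")
}

#' Per-electrode epoch-averaged ASSR amplitudes
#'
#' Applies [assr_amplitude()] to every channel of an EEG dataset.
#'
#' @param eeg An [eeg_dataset()].
#' @param f_m Modulation frequency (Hz).
#' @param k Modulation cycles per segment.
#' @param n_segments Segments to average (default all).
#' @return Named numeric vector of amplitudes (microvolts).
#' @export
eeg_amplitudes <- function(eeg, f_m = 39.0625, k = 20, n_segments = Inf) {
  stopifnot(inherits(eeg, "eeg_dataset"))
  fs <- eeg$sampling_rate_hz
  len <- round(k * fs / f_m)
  n_ep <- min(floor(ncol(eeg$data) / len), n_segments)
  if (n_ep < 1) stop_assrmix("Signal shorter than one epoch.")
  # average the epochs of all channels at once, then one multi-column FFT
  avg <- matrix(0, nrow(eeg$data), len)
  for (e in seq_len(n_ep)) {
    avg <- avg + eeg$data[, ((e - 1) * len + 1):(e * len)]
  }
  avg <- avg / n_ep
  bin <- 1L + as.integer(round(f_m * len / fs))
  sp <- stats::mvfft(t(avg))
  setNames(2 * Mod(sp[bin, ]) / len, eeg$labels)
}

# internal: decompose + classify + reconstruct + score one algorithm run
benchmark_one <- function(sim, algorithm, neural_amp, f_m, k, n_segments) {
  cfg <- sim$config
  an <- cfg$analysis
  mix <- sim$eeg$mix
  n_comp <- if (algorithm == "fastica") {
    max(2L, estimate_dimension(mix, an$dim_threshold_factor))
  } else {
    min(an$n_components, nrow(mix$data))
  }
  t0 <- proc.time()[["elapsed"]]
  # convergence is recorded in the run table; the advisory would be noise here
  res <- withCallingHandlers(
    run_ica(mix, algorithm, n_components = n_comp,
            seed = sub_seed(cfg$seed, 10)),
    assrmix_convergence_warning = function(w) invokeRestart("muffleWarning")
  )
  runtime <- proc.time()[["elapsed"]] - t0
  flagged <- classify_artifact_ics(
    res, cfg$stimulus$carrier_freq_hz, as.numeric(sim$lf2[, "cochlea"]),
    f_m = f_m, spectral_ratio = an$spectral_ratio,
    topo_threshold = an$topo_threshold, band_hz = an$band_hz
  )
  den <- reject_and_reconstruct(mix, res, flagged)
  den_amp <- eeg_amplitudes(den, f_m, k, n_segments)
  err <- estimation_error(den_amp, neural_amp)
  j_comp <- mean(apply(res$activations, 1, negentropy))
  j_chan <- mean(apply(mix$data, 1, negentropy))
  list(
    errors = err,
    run = tibble::tibble(
      algorithm = algorithm, n_components = n_comp,
      rejected = list(flagged), n_rejected = length(flagged),
      negentropy_components = j_comp, negentropy_channels = j_chan,
      runtime_s = runtime, converged = res$converged, failed = FALSE,
      failure = NA_character_
    )
  )
}

#' Benchmark ICA algorithms on simulated artifact-response mixtures
#'
#' Orchestrates the in-silico comparison: for every modulation depth and
#' simulation seed it generates a fresh mixture, decomposes it with each
#' algorithm, flags and rejects artifactual components, reconstructs the
#' denoised EEG and scores the per-electrode ASSR amplitude estimation
#' error against the uncontaminated ground truth. Component and channel
#' negentropies, rejected indices, convergence flags and runtimes are
#' recorded per run. A failing run is recorded with its error message and
#' excluded from aggregates.
#'
#' @param cfg Base [scenario_config()]; each simulation overrides its seed
#'   and modulation depth.
#' @param algorithms Algorithms to compare (default all four).
#' @param n_sims Simulations per modulation depth.
#' @param md_values Modulation depths to sweep (default 0.75; the full
#'   sweep is `c(1, 0.75, 0.5, 0.2)`).
#' @param seeds Integer seeds, one per simulation (default derived from
#'   `cfg$seed`).
#' @return An object of class `assr_benchmark` with tibbles `errors`
#'   (per md x sim x algorithm x electrode) and `runs` (per
#'   md x sim x algorithm), plus `roi`, `config`.
#' @export
run_benchmark <- function(cfg = scenario_config("bench"),
                          algorithms = c("infomax", "extended_infomax",
                                         "jade", "fastica"),
                          n_sims = 10, md_values = 0.75, seeds = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  seeds <- seeds %||% vapply(seq_len(n_sims), function(i) {
    sub_seed(cfg$seed, 100 + i)
  }, integer(1))
  if (length(seeds) != n_sims) stop_assrmix("`seeds` must have length `n_sims`.")
  fwd <- scenario_forward(cfg)
  f_m <- cfg$stimulus$modulation_freq_hz
  k <- cfg$analysis$k
  n_seg <- cfg$analysis$n_segments
  errors <- list()
  runs <- list()
  for (md in md_values) {
    for (i in seq_len(n_sims)) {
      cfg_i <- cfg
      cfg_i$stimulus$modulation_depth <- md
      cfg_i$seed <- seeds[i]
      sim <- simulate_scenario(cfg_i, forward = fwd)
      neural_amp <- eeg_amplitudes(sim$eeg$assr, f_m, k, n_seg)
      for (alg in algorithms) {
        out <- tryCatch(
          benchmark_one(sim, alg, neural_amp, f_m, k, n_seg),
          error = function(e) {
            list(
              errors = NULL,
              run = tibble::tibble(
                algorithm = alg, n_components = NA_integer_,
                rejected = list(integer(0)), n_rejected = NA_integer_,
                negentropy_components = NA_real_,
                negentropy_channels = NA_real_, runtime_s = NA_real_,
                converged = FALSE, failed = TRUE,
                failure = conditionMessage(e)
              )
            )
          }
        )
        tag <- function(tb) {
          tb$modulation_depth <- md
          tb$sim <- i
          tb$seed <- seeds[i]
          tb
        }
        if (!is.null(out$errors)) {
          e <- tag(out$errors)
          e$algorithm <- alg
          e$roi <- e$electrode %in% roi_electrodes()
          errors[[length(errors) + 1L]] <- e
        }
        runs[[length(runs) + 1L]] <- tag(out$run)
      }
    }
  }
  structure(
    list(errors = dplyr::bind_rows(errors), runs = dplyr::bind_rows(runs),
         roi = roi_electrodes(), config = cfg),
    class = "assr_benchmark"
  )
}

#' @export
print.assr_benchmark <- function(x, ...) {
  cat(sprintf("<assr_benchmark> %d runs (%d failed), %d electrode errors\n",
              nrow(x$runs), sum(x$runs$failed), nrow(x$errors)))
  print(glance(x))
  invisible(x)
}

#' @rdname run_benchmark
#' @param x An `assr_benchmark`.
#' @param ... Unused.
#' @export
tidy.assr_benchmark <- function(x, ...) {
  x$errors
}

#' @rdname run_benchmark
#' @export
glance.assr_benchmark <- function(x, ...) {
  ok <- dplyr::filter(x$runs, !.data$failed)
  err <- x$errors
  roi_sum <- err |>
    dplyr::filter(.data$roi, !.data$excluded) |>
    dplyr::group_by(.data$algorithm, .data$modulation_depth) |>
    dplyr::summarise(
      mean_roi_error_pct = mean(.data$error_pct),
      mean_abs_roi_error_pct = mean(abs(.data$error_pct)),
      sd_roi_error_pct = sd(.data$error_pct),
      .groups = "drop"
    )
  all_sum <- err |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$algorithm, .data$modulation_depth) |>
    dplyr::summarise(
      mean_abs_error_pct = mean(abs(.data$error_pct)),
      .groups = "drop"
    )
  run_sum <- ok |>
    dplyr::group_by(.data$algorithm, .data$modulation_depth) |>
    dplyr::summarise(
      mean_rejected = mean(.data$n_rejected),
      negentropy_components = mean(.data$negentropy_components),
      negentropy_channels = mean(.data$negentropy_channels),
      mean_runtime_s = mean(.data$runtime_s),
      n_runs = dplyr::n(),
      .groups = "drop"
    )
  roi_sum |>
    dplyr::left_join(all_sum, by = c("algorithm", "modulation_depth")) |>
    dplyr::left_join(run_sum, by = c("algorithm", "modulation_depth"))
}

#' @importFrom rlang .data
NULL
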