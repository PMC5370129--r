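#' @importFrom ggplot2 ggplot aes geom_line geom_boxplot geom_hline facet_wrap
#'   labs theme_minimal geom_col
NULL

#' Plot a sampled signal
#'
#' @param object A [sampled_signal()].
#' @param max_points Downsample to at most this many points for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sampled_signal <- function(object, max_points = 20000, ...) {
  tb <- as_tibble(object)
  if (nrow(tb) > max_points) {
    tb <- tb[seq(1, nrow(tb), length.out = max_points), ]
  }
  ggplot(tb, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = object$units) +
    theme_minimal()
}

#' Plot EEG traces
#'
#' Stacked per-channel traces of an EEG dataset.
#'
#' @param object An [eeg_dataset()].
#' @param channels Channel labels to show (default: first 6).
#' @param max_points Downsample to at most this many points per channel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_dataset <- function(object, channels = NULL, max_points = 20000,
                                 ...) {
  channels <- channels %||% head(object$labels, 6)
  tb <- as_tibble(object)
  tb <- dplyr::filter(tb, .data$channel %in% channels)
  if (nrow(tb) > max_points * length(channels)) {
    tb <- dplyr::slice_sample(dplyr::group_by(tb, .data$channel),
                              n = max_points) |>
      dplyr::arrange(.data$channel, .data$time_s)
  }
  ggplot(tb, aes(x = .data$time_s, y = .data$potential_uv)) +
    geom_line(linewidth = 0.25) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = "potential (uV)",
         title = sprintf("EEG (%s)", object$kind)) +
    theme_minimal()
}

#' Plot benchmark estimation errors
#'
#' Boxplots of the per-electrode ASSR amplitude estimation error by
#' algorithm, optionally restricted to the fronto-central region of
#' interest, faceted by modulation depth.
#'
#' @param object An [run_benchmark()] result.
#' @param roi_only Show only the fronto-central electrodes (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assr_benchmark <- function(object, roi_only = TRUE, ...) {
  tb <- dplyr::filter(object$errors, !.data$excluded)
  if (roi_only) tb <- dplyr::filter(tb, .data$roi)
  ggplot(tb, aes(x = .data$algorithm, y = .data$error_pct,
                 fill = .data$algorithm)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    facet_wrap(~modulation_depth, labeller = ggplot2::label_both) +
    labs(x = NULL, y = "ASSR amplitude estimation error (%)") +
    theme_minimal()
}

#' Per-electrode amplitude topography as a bar chart
#'
#' A montage-ordered summary of per-electrode amplitudes (full interpolated
#' scalp maps are outside this package's scope).
#'
#' @param amplitudes Named numeric vector (one value per electrode).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_amplitudes <- function(amplitudes, title = "ASSR amplitude") {
  tb <- tibble::tibble(
    electrode = factor(names(amplitudes), levels = names(amplitudes)),
    amplitude = unname(amplitudes)
  )
  ggplot(tb, aes(x = .data$electrode, y = .data$amplitude)) +
    geom_col() +
    labs(x = NULL, y = "amplitude (uV)", title = title) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname run_ica
#' @param x An `ica_result`.
#' @param ... Unused.
#' @export
tidy.ica_result <- function(x, ...) {
  vr <- apply(x$activations, 1, var)
  expl <- colSums(x$mixing^2) * vr
  tibble::tibble(
    component = rownames(x$activations),
    explained_variance = expl / sum(expl),
    negentropy = apply(x$activations, 1, negentropy),
    excess_kurtosis = apply(x$activations, 1, function(u) {
      m2 <- mean((u - mean(u))^2)
      mean((u - mean(u))^4) / m2^2 - 3
    })
  )
}

#' @rdname run_ica
#' @export
glance.ica_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_components = x$n_components,
    n_channels = length(x$labels),
    converged = x$converged,
    iterations = x$iterations,
    seed = x$seed
  )
}
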