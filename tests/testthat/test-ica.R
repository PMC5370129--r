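# two-source Laplace mixture every algorithm must unmix
laplace_mixture <- function(n = 20000, seed = 5) {
  set.seed(seed)
  s <- rbind(rlaplace(n), rlaplace(n))
  a <- matrix(c(2, 1, 1, 1.5), 2)
  list(sources = s, x = a %*% s)
}

# best absolute correlation pairing between recovered and true sources
match_correlation <- function(est, truth) {
  co <- abs(stats::cor(t(est), t(truth)))
  max(min(co[1, 1], co[2, 2]), min(co[1, 2], co[2, 1]))
}

test_that("all four algorithms unmix an independent Laplace pair", {
  mx <- laplace_mixture()
  for (alg in c("infomax", "extended_infomax", "jade", "fastica")) {
    # default iteration caps are sized for the 25-component EEG benchmark;
    # tiny 2-source problems take many more cheap passes (the extended rule
    # slowest of all, as in the literature), so give them headroom here
    mi <- if (alg %in% c("infomax", "extended_infomax")) 2000L else NULL
    res <- suppressWarnings(run_ica(mx$x, alg, n_components = 2, seed = 3,
                                    max_iter = mi))
    expect_gt(match_correlation(res$activations, mx$sources), 0.99)
    # unmixing and mixing invert each other on the retained subspace
    expect_equal(res$unmixing %*% res$mixing, diag(2), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("decomposition is deterministic given the seed", {
  mx <- laplace_mixture(n = 5000)
  a <- run_ica(mx$x, "fastica", n_components = 2, seed = 9)
  b <- run_ica(mx$x, "fastica", n_components = 2, seed = 9)
  expect_identical(a$unmixing, b$unmixing)
  expect_identical(a$activations, b$activations)
})

test_that("mixing times activations reconstructs the PCA projection", {
  sim <- quick_sim()
  X <- sim$eeg$mix$data[, 1:20000]
  res <- run_ica(X, "fastica", n_components = nrow(X), seed = 2)
  recon <- res$mixing %*% res$activations + res$center
  expect_equal(recon, X, tolerance = 1e-6, ignore_attr = TRUE)
  # components are ordered by explained channel-space variance
  ev <- colSums(res$mixing^2) * apply(res$activations, 1, var)
  expect_true(all(diff(ev) <= 1e-8))
})

test_that("rejecting nothing or nearly everything behaves as documented", {
  sim <- quick_sim()
  eeg <- eeg_dataset(sim$eeg$mix$data[, 1:20000], 1e4, sim$eeg$mix$labels,
                     "mix")
  res <- run_ica(eeg, "fastica", n_components = 10, seed = 2)
  full <- reject_and_reconstruct(eeg, res, integer(0))
  proj <- res$mixing %*% res$activations + res$center
  expect_equal(full$data, proj, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(full$kind, "denoised")
  expect_identical(full$labels, eeg$labels)
  one <- reject_and_reconstruct(eeg, res, 2:10)
  expect_equal(qr(one$data - rowMeans(one$data))$rank, 1)
  expect_error(reject_and_reconstruct(eeg, res, 1:10), "every component")
  expect_error(reject_and_reconstruct(eeg, res, 99), "out of range")
})

test_that("rank-deficient requests are refused", {
  x <- matrix(rnorm(3 * 1000), 3)
  x <- rbind(x, x[1, ] + x[2, ]) # rank 3, 4 channels
  expect_error(run_ica(x, "fastica", n_components = 4, seed = 1),
               "rank")
  expect_error(run_ica(x, "fastica", n_components = 9, seed = 1),
               "channel count")
})

test_that("dimension estimate counts eigenvalues above the noise floor", {
  set.seed(13)
  n <- 20000
  latent <- matrix(rnorm(4 * n), 4)
  mixmat <- matrix(rnorm(32 * 4), 32)
  noise_amp <- sqrt(mean((mixmat %*% latent)^2)) * 1e-2 # -40 dB
  x <- mixmat %*% latent + matrix(rnorm(32 * n, sd = noise_amp), 32)
  expect_equal(estimate_dimension(x), 4)
  # pure white noise has a flat spectrum: at most one eigenvalue clears 10x
  expect_lte(estimate_dimension(matrix(rnorm(32 * n), 32)), 1)
})

test_that("artifact classifier uses both spectrum and topography", {
  fs <- 1e4
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  pulses <- as.numeric(make_pwm_pulse_train(
    stimulus_config(sampling_rate_hz = fs, duration_s = 2,
                    base_pulse_width_s = 2.5e-4))$samples) * 1e6
  tone <- sin(2 * pi * 39.0625 * t)
  topo_art <- c(3, 1, 0.2)
  topo_tone <- c(0.5, 1, 2)
  x <- topo_art %o% pulses + topo_tone %o% tone +
    matrix(rnorm(3 * length(t), sd = 1e-3), 3)
  eeg <- eeg_dataset(x, fs, c("e1", "e2", "e3"), "mix")
  res <- run_ica(eeg, "jade", n_components = 3, seed = 4)
  flagged <- classify_artifact_ics(res, 500, topo_art)
  expect_length(flagged, 1)
  # the flagged component is the pulsatile one
  expect_gt(abs(stats::cor(res$activations[flagged, ], pulses)), 0.9)
  # a pure f_m sinusoid component is never flagged
  expect_false(any(vapply(flagged, function(i) {
    abs(stats::cor(res$activations[i, ], tone)) > 0.9
  }, logical(1))))
})
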