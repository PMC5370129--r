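test_that("epoching cuts exact modulation-locked segments", {
  fs <- 10e3
  x <- rnorm(40 * fs)
  ep <- epoch_signal(x, 39.0625, 20, sampling_rate_hz = fs)
  expect_equal(ep$epoch_length, 5120) # 0.512 s
  expect_equal(ep$duration_s, 0.512)
  expect_equal(nrow(ep$epochs), 78)
  # concatenated epochs reconstruct the signal minus the remainder
  expect_identical(as.numeric(t(ep$epochs)), x[seq_len(78 * 5120)])
  # one-cycle epochs
  ep1 <- epoch_signal(x[1:5120], 39.0625, 1, sampling_rate_hz = fs)
  expect_equal(ep1$epoch_length, 256)
  expect_error(epoch_signal(x[1:100], 39.0625, 20, sampling_rate_hz = fs),
               "shorter than one epoch")
})

test_that("amplitude of a pure sinusoid at f_m is recovered exactly", {
  fs <- 10e3
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  for (amp in c(1, 0.35)) {
    x <- amp * sin(2 * pi * 39.0625 * t + 0.7)
    expect_equal(assr_amplitude(x, 39.0625, 20, sampling_rate_hz = fs), amp,
                 tolerance = 1e-6)
  }
  expect_equal(assr_amplitude(numeric(2 * fs), 39.0625, 20,
                              sampling_rate_hz = fs), 0)
  # linearity in signal amplitude
  x <- sin(2 * pi * 39.0625 * t) + 0.3 * sin(2 * pi * 7 * t)
  expect_equal(assr_amplitude(5 * x, 39.0625, 20, sampling_rate_hz = fs),
               5 * assr_amplitude(x, 39.0625, 20, sampling_rate_hz = fs),
               tolerance = 1e-12)
})

test_that("averaging more segments shrinks the amplitude error like 1/sqrt(n)", {
  fs <- 2000
  f_m <- 40
  t <- seq(0, 32 - 1 / fs, by = 1 / fs)
  base <- sin(2 * pi * f_m * t)
  set.seed(99)
  err <- sapply(1:20, function(i) {
    x <- base + rnorm(length(t), sd = 3)
    sapply(c(4, 64), function(ns) {
      abs(assr_amplitude(x, f_m, 1, n_segments = ns, sampling_rate_hz = fs) - 1)
    })
  })
  ratio <- mean(err[1, ]) / mean(err[2, ])
  expect_gt(ratio, 4 / 2) # ideal sqrt(64/4) = 4; allow factor-2 slack
  expect_lt(ratio, 4 * 2)
})

test_that("phase coherence is exact for locked, antiphase and degenerate cases", {
  expect_equal(phase_coherence(rep(1.234, 20))$pc, 1, tolerance = 1e-12)
  expect_equal(phase_coherence(c(0, pi))$pc, 0, tolerance = 1e-12)
  # FFT path: identical epochs give PC = 1 and a detection
  fs <- 2560
  x <- rep(sin(2 * pi * 40 * seq(0, 0.5 - 1 / fs, by = 1 / fs)), 20)
  pc <- phase_coherence(epoch_signal(x, 40, 20, sampling_rate_hz = fs))
  expect_equal(pc$pc, 1, tolerance = 1e-9)
  expect_true(pc$detected)
  # zero-amplitude epochs are flagged and excluded
  x2 <- c(x, numeric(0.5 * fs * 20))
  expect_warning(
    pc2 <- phase_coherence(epoch_signal(x2, 40, 20, sampling_rate_hz = fs)),
    "zero amplitude")
  expect_equal(pc2$n_epochs, 20)
})

test_that("random-phase epochs give low phase coherence", {
  set.seed(7)
  pcs <- replicate(2000, phase_coherence(runif(20, 0, 2 * pi))$pc)
  expect_true(all(pcs >= 0 & pcs <= 1))
  expect_gt(mean(pcs < 0.5), 0.99)
})

test_that("estimation error reports signed percentages and exclusions", {
  neural <- c(Cz = 1, Fz = 2, Pz = 0.5)
  expect_equal(estimation_error(neural, neural)$error_pct, c(0, 0, 0))
  err <- estimation_error(neural * 1.1, neural)
  expect_equal(err$error_pct, rep(10, 3), tolerance = 1e-9)
  err2 <- estimation_error(neural * 0.8, neural)
  expect_equal(err2$error_pct, rep(-20, 3), tolerance = 1e-9)
  expect_warning(err3 <- estimation_error(c(Cz = 1, Fz = 1),
                                          c(Cz = 1, Fz = 0)),
                 "zero neural amplitude")
  expect_true(err3$excluded[2])
  expect_true(is.na(err3$error_pct[2]))
  expect_error(estimation_error(c(a = 1), c(b = 1)), "named identically")
})

test_that("mutual information matches entropy, symmetry and the bias formula", {
  set.seed(5)
  x <- rnorm(5000)
  self <- mutual_information(x, x, bins = 32)
  # MI(x, x) equals the marginal histogram entropy (independent calculation)
  p <- tabulate(pmin(32, pmax(1, ceiling((x - min(x)) / diff(range(x)) * 32))),
                nbins = 32) / length(x)
  expect_equal(self$mi_raw, -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-12)
  y <- rnorm(5000)
  expect_equal(mutual_information(x, y, 40)$mi_raw,
               mutual_information(y, x, 40)$mi_raw, tolerance = 1e-12)
  expect_gte(mutual_information(x, y, 40)$mi_raw, 0)
  # bias arithmetic at the study's histogram settings
  mi <- mutual_information(rnorm(2e4), rnorm(2e4), bins = 160)
  expect_equal(mi$bias, 159^2 / (2 * 2e4))
  expect_equal(mi$mi_corrected, mi$mi_raw - mi$bias)
  expect_error(mutual_information(rep(1, 2000), rnorm(2000), 10),
               "zero-width")
  expect_error(mutual_information(rnorm(100), rnorm(100)), "1000")
})

test_that("corrected MI of independent streams is centred on zero", {
  set.seed(11)
  vals <- replicate(20, {
    mutual_information(runif(1e5), runif(1e5), bins = 40)$mi_corrected
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * se)
})

test_that("Scott's rule reproduces the reference bin width", {
  set.seed(3)
  x <- rnorm(1e4, sd = 2)
  m <- scott_bins(x)
  w <- 3.49 * sd(x) * length(x)^(-1 / 3)
  expect_identical(m, as.integer(ceiling(diff(range(x)) / w)))
})

test_that("negentropy vanishes for Gaussians and detects heavy tails", {
  set.seed(21)
  g <- rnorm(2e5)
  expect_lt(negentropy(g), 1e-4)
  lap <- rlaplace(2e5)
  expect_gt(negentropy(lap), 10 * negentropy(g))
  # affine invariance through internal standardization
  expect_equal(negentropy(5 + 3 * lap), negentropy(lap), tolerance = 1e-12)
  expect_error(negentropy(rep(2, 100)), "Constant")
  # cached Gaussian expectation constant
  expect_equal(gauss_logcosh(1), 0.3745672, tolerance = 1e-6)
})

test_that("normality screen accepts Gaussians and rejects uniforms", {
  set.seed(31)
  sg <- source_stats(rnorm(1e4))
  expect_false(sg$normality_rejected)
  expect_lt(abs(sg$excess_kurtosis), 0.3)
  su <- source_stats(runif(1e5))
  expect_true(su$normality_rejected)
  expect_lt(su$excess_kurtosis, 0) # uniform is sub-Gaussian
  expect_error(source_stats(rnorm(50)), "100")
  expect_error(source_stats(rep(1, 200)), "Constant")
})
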