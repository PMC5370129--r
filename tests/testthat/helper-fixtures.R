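# Shared simulation fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# short quick-profile simulation shared across module tests
quick_sim <- function(seed = 1, duration_s = 10) {
  cached(sprintf("quick_%d_%g", seed, duration_s), {
    simulate_scenario(scenario_config("quick", seed = seed,
                                      duration_s = duration_s))
  })
}

# benchmark batch shared by the acceptance tests: ten simulations at
# MD = 0.75 with all four algorithms (10 kHz, 10 s)
acceptance_bench <- function() {
  cached("acceptance_bench", {
    run_benchmark(scenario_config("quick", seed = 1), n_sims = 10,
                  md_values = 0.75, seeds = 1:10)
  })
}

# modulation-depth sweep at further-reduced duration: MD 1.0 vs 0.2
acceptance_md_sweep <- function() {
  cached("acceptance_md", {
    run_benchmark(scenario_config("quick", seed = 1, duration_s = 6),
                  n_sims = 10, md_values = c(1, 0.2), seeds = 1:10)
  })
}

# one full-scale simulation for the source-statistics replication checks
paper_sim <- function() {
  cached("paper_sim", {
    simulate_scenario(scenario_config("paper_scale", seed = 1))
  })
}

# high-frequency power fraction (above cutoff_hz) of a source time course
hf_fraction <- function(x, fs, cutoff_hz = 200) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * fs / n
  sum(sp[freq > cutoff_hz]^2) / sum(sp[-1]^2)
}
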