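# assrmix

Simulation and benchmarking framework for the mixture of a cochlear-implant
(CI) electrical stimulation artifact and auditory steady-state responses
(ASSRs) on scalp EEG.

## The problem

Objective hearing measures for CI users rely on detecting ASSRs — EEG
responses phase-locked to the modulation frequency `f_m` of a continuous
amplitude-modulated stimulus — but the implant's stimulation current leaks
into the recording as an electrical artifact roughly an order of magnitude
larger than the response, and for pulse-width-modulated (PWM) implants it
is too temporally spread for sample-blanking to remove. Denoising by
independent component analysis (ICA) is the practical alternative, yet its
effect on the *response itself* cannot be audited in patients, because the
uncontaminated recording never exists. `assrmix` builds that missing ground
truth in silico, for anyone developing or validating CI artifact removal:

1. a PWM monophasic pulse train `i_stim` (carrier `f_c = 500` Hz, modulation
   `f_m = 39.0625` Hz, depth `MD = 0.75`) drives a capacitive
   electrode–cochlea interface, `v_stim = Z_ec i_stim + R_s i_stim` with
   `Z_ec(s) = Z_f / (1 + s Z_f C_dl)` — the artifactual source — and, through
   the Freeman sigmoid `S(v) = 2e0 / (1 + e^{r(v_0 − v)})`, the
   auditory-nerve firing rate;
2. five neural-mass modules (brainstem, bilateral thalamus, bilateral
   primary auditory cortex; second-order synaptic kernels
   `h(t) = G ω t e^{−ωt}`) generate the neural source dynamics `S_n`;
3. a three-shell spherical head model projects the six dipoles to a
   32-channel 10-10 montage:
   `EEG_mix = LF₁K₁S_n + LF₂K₂S_Art + b`, with `EEG_ASSR = LF₁K₁S_n` as the
   uncontaminated control;
4. four in-package ICA algorithms (infomax, extended infomax, JADE,
   fastICA) decompose the mixture; artifactual components are flagged by a
   spectral + topographic rule, rejected and back-projected; and the
   denoised ASSR amplitudes are scored against the ground truth as
   `100·(denoised − neural)/neural` per electrode.

The estimator toolbox — modulation-locked epoching, epoch-averaged FFT
amplitudes, phase coherence `PC = (1/N)√((Σcosθᵢ)² + (Σsinθᵢ)²)`,
histogram mutual information with the `(M−1)²/(2N)` bias correction,
log-cosh negentropy, kurtosis and an Anderson–Darling normality screen —
is exported for use on real recordings too (BrainVision and EEGLAB `.set`
I/O included).

## Worked example

```r
library(assrmix)

cfg <- scenario_config("quick", seed = 1)   # 10 kHz, 10 s, 32 channels
sim <- simulate_scenario(cfg)
#> <assr_simulation:quick> seed 1, 32 channels x 100000 samples @ 10000 Hz

neural <- eeg_amplitudes(sim$eeg$assr)      # ground-truth ASSR amplitudes
round(neural[c("Cz", "FC1", "FC2", "T8")], 2)
#>   Cz  FC1  FC2   T8
#> 0.96 0.92 0.91 0.48

ica <- run_ica(sim$eeg$mix, "infomax", n_components = 25, seed = 11)
#> <ica_result> infomax: 25 components over 32 channels (converged, 60 iterations)
flagged <- classify_artifact_ics(ica, f_c = 500,
                                 artifact_topography = sim$lf2[, "cochlea"])
flagged
#> [1] 1

denoised <- reject_and_reconstruct(sim$eeg$mix, ica, flagged)
err <- estimation_error(eeg_amplitudes(denoised), neural)
dplyr::filter(err, electrode %in% roi_electrodes())
#>    electrode denoised neural error_pct
#>  1 F7            0.58   0.59     -1.87
#>  2 F3            0.79   0.80     -0.73
#>  3 Fz            0.88   0.89     -0.24
#>  ...
#> 11 Cz            0.96   0.96     -0.47
#> 12 C4            0.84   0.83      1.11
```

The uncontaminated ASSR focalises fronto-centrally (≈ 1 µV around Cz) while
the artifact peaks at ≈ 8 µV over the ipsilateral mastoid. Infomax isolates
the artifact into exactly one of 25 components; after rejecting it, the
fronto-central amplitude errors sit within a few percent of the ground
truth — negative values mean a little response was removed with the
artifact, positive values mean artifactual residue. Two companion
diagnostics from the same session:

```r
estimate_dimension(sim$eeg$mix)   # eigenvalues above the sensor-noise floor
#> [1] 4
phase_coherence(epoch_signal(denoised$data["Cz", ], 39.0625, 20,
                             sampling_rate_hz = 10e3))
#>      pc n_epochs detected
#>   0.852       19 TRUE
```

`run_benchmark()` repeats the whole loop over seeds, algorithms and
modulation depths and returns tidy `errors`/`runs` tables with `tidy()`,
`glance()` and `autoplot()` methods. A thin command-line wrapper with
`simulate` / `bench` / `denoise` / `metrics` subcommands ships in
`inst/cli/assrmix`. The methods vignette (`vignettes/methods.Rmd`)
documents every model, parameter and design decision.

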