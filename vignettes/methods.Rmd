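---
title: "Simulating the cochlear-implant artifact–ASSR mixture: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the cochlear-implant artifact–ASSR mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`assrmix` simulates, end to end, what a 32-channel EEG system records from a
cochlear-implant (CI) user during auditory steady-state response (ASSR)
stimulation: the neural response riding underneath a much larger electrical
stimulation artifact. Because the simulator knows the uncontaminated ground
truth, it can score how well blind-source-separation algorithms remove the
artifact — something that is impossible with clinical recordings, where the
artifactual and neural sources coexist physically. This vignette documents
the models, every tunable parameter that matters, the calibration of the
default scenario, the numerical choices, and the limits of what passing
tests demonstrate.

## 1. The stimulation current

The modelled implant encodes sound intensity by pulse-width modulation
(PWM): constant-amplitude monophasic current pulses at a fixed carrier rate
`f_c` whose *duration* follows the stimulus envelope. The default stimulus
is an amplitude-modulated tone: carrier `f_c = 500` Hz (the clinical
stimulation-rate range), modulation frequency `f_m = 39.0625` Hz and
modulation depth `MD = 0.75`. We use the exact hardware-style value
39.0625 Hz (= 5000/128, conventionally displayed as "39.06 Hz") so that an
epoch of `k = 20` modulation cycles is an integer number of samples at both
10 and 50 kHz; every FFT analysis then falls on an exact bin and needs no
windowing or leakage correction.

The envelope-to-width mapping is affine,

    w(t) = w_max * (1 + MD sin(2 pi f_m t)) / (1 + MD),

so the widest pulse equals `base_pulse_width_s` regardless of depth and the
injected charge stays bounded; a plain linear mapping is available
(`mapping = "linear"`). Widths are quantized to the nearest sample with a
floor of one sample, and pulses are anchored at their onsets (left-aligned),
which start every `f_s / f_c` samples.

Two width defaults exist on purpose. At the full 50 kHz rate the base width
is 50 µs — a clinically realistic active-pulse duration, which also
reproduces the strongly supra-Gaussian artifact statistics observed for such
implants (excess kurtosis in the tens; see §7). At the reduced 10 kHz test
rates a 50 µs pulse would collapse to a single sample and the width
modulation — the only carrier of the envelope — would vanish, so the
reduced-rate profiles use a 250 µs base width, the smallest value whose
quantized widths still span several samples.

`contamination_fraction()` reports the blanking cost of a temporally spread
artifact: a per-pulse span of 1 ms at 500 Hz occupies 50% of the
inter-pulse interval, the situation that motivates ICA-based denoising over
blanking in the first place.

## 2. The electrode–cochlea interface and the auditory-nerve drive

The electrode–electrolyte interface is a single-pole RC system: a
double-layer capacitance `C_dl` in parallel with a faradaic resistance
`Z_f`, in series with the cochlea's access resistance `R_s`,

    v_stim = Z_ec * i_stim + R_s * i_stim,
    Z_ec(s) = Z_f / (1 + s Z_f C_dl).

As printed in the source literature the interface transfer function is
dimensionally inconsistent; we implement the form above, which preserves
the stated pole at `1/(Z_f C_dl)` and has ohms as units. The filter is
discretized by an exact zero-order hold (`y[n] = a y[n-1] + (1-a) Z_f x[n]`,
`a = exp(-1/(f_s tau))`), which is unconditionally stable and *exact* for
piecewise-constant inputs — which the PWM train is. Defaults
(`Z_f = 10 kΩ`, `C_dl = 3 nF`, `R_s = 1 kΩ`) give `tau = 30 µs`,
commensurate with the 50 µs active pulse; together they produce an
artifactual source whose excess kurtosis (~50 at 50 kHz) sits in the
strongly supra-Gaussian regime reported for real CI artifacts. An advisory
(class `assrmix_pole_warning`) fires when the sampling grid has less than
one sample per time constant.

`v_stim` plays two roles: it *is* the artifactual dipole time course, and —
scaled to millivolts by `drive_gain` and perturbed by residual-hearing noise
(Gaussian, default sd 2 mV) — it drives the Freeman wave-to-pulse sigmoid

    S(v) = 2 e0 / (1 + exp(r (v0 - v))),

with `e0 = 2.5 s^-1`, `v0 = 6 mV`, `r = 0.56 mV^-1` (standard neural-mass
values). We implement the increasing orientation (rate grows with
depolarisation); the printed form with `exp(r(v - v0))` would be
decreasing. `S(v_stim)` is the mean auditory-nerve firing rate that drives
the network.

## 3. The five-module neural network

Brainstem (BS), left/right thalamus (Th), and left/right primary auditory
cortex (A1) are modelled as interacting neural-mass populations. Each
cortical/thalamic module holds a principal population and two interneuron
populations (fast GABA-A-like and slow GABA-B-like); the brainstem holds a
principal and one inhibitory population. Every synapse family is a standard
second-order kernel `h(t) = G w t exp(-w t)`:

| kernel | gain (mV) | rate (s^-1) |
|---|---|---|
| excitatory (cortex) | A = 3.25 | a = 100 |
| excitatory (thalamus) | 3.25 · (a_th/a) | a_th = 300 |
| excitatory (brainstem) | 3.25 · (a_bs/a) | a_bs = 1000 |
| slow inhibition | B = 22 | b = 50 |
| fast inhibition | G = 10 | g = 500 |

The subcortical kernels are faster with their DC gain `A/a` held fixed.
This is deliberate, physiological, and load-bearing: brainstem relay
neurons phase-lock to pulse rates in the hundreds of hertz, so the
brainstem output must retain the 500 Hz carrier, while two further synaptic
stages progressively low-pass it — giving the observed ordering of
high-frequency content BS > Th > A1 and the survival of the 39 Hz envelope
response up the pathway. With a uniform 100 s^-1 kernel everywhere, the
carrier would die at the brainstem itself and the envelope response would
be an order of magnitude weaker.

Routing (dimensionless gains on firing rates): the nerve rate drives the
brainstem principal population (`coch_bs = 60`); the brainstem excites both
thalamic relays (`bs_th = 50`); each thalamus drives its ipsilateral cortex
(`th_a1 = 50`); a weak direct brainstem→cortex projection exists
(`bs_a1 = 1`); thalamus and cortex send weak excitatory feedback to the
brainstem (`th_bs = a1_bs = 2`). The thalamo-cortical relay is the one
place where we depart from a strictly parallel reading of the source
architecture (brainstem projecting to thalamus *and* cortex): without a
relay the thalamic and cortical spectra would be identical, contradicting
the described progressive low-pass filtering; the relay is standard
lemniscal physiology and the direct projection is retained at low gain.

Noise placement follows the described architecture exactly: Gaussian noise
enters the excitatory kernel of the two cortical principal populations and
the brainstem principal population (mean 10, sd 2 in rate units per
√s, Euler–Maruyama with the √dt convention), and *not* the thalamic
relays. Two consequences are intended and observed: the two thalamic
time courses are near-duplicates (their histogram mutual information is
~5 nats, matching the "significantly high" thalamic MI reported for this
kind of model), while the two cortical sources remain only moderately
redundant (corrected MI ≈ 0.14, matching the reported ≈ 0.1); and the
effective number of independent elements in the scalp mixture drops to 4
(artifact, brainstem, thalamic pair, cortical pair), which is what the
automatic dimension estimate recovers.

Integration is Euler–Maruyama at `dt = 1/f_s` (stable for all default
kernels at 10 kHz and above); the first second is discarded as burn-in. A
guard bound (default 10^4 mV) aborts with a diagnostic on divergence.
`steady_state()` solves the noise-free fixed point by damped fixed-point
iteration and is validated against the long-run simulation mean in the
tests (dual route).

### Where the phase-locked response lives

With noise on the cortical populations and standard kernels, the *cortical
source in isolation* does not show a dominant 39 Hz peak after segment
averaging: its own noise floor at neighbouring bins exceeds the locked
component at any feasible number of segments (two cascaded excitatory
kernels attenuate 39 Hz by roughly two orders of magnitude). The
phase-locked peak is dominant in the brainstem and thalamic sources and in
the scalp `EEG_ASSR` (where the subcortical dipoles contribute most of the
Cz response); the tests assert the peak there. This is a documented
property of our parameterisation, not of the method: a parameter set with a
stronger cortical resonance would move the peak cortically without touching
any other module.

## 4. The forward model

Sources project to the scalp through the quasi-static three-shell
concentric-sphere model: brain/skull/scalp radii 87/92/100 mm,
conductivities 0.33 / 0.004125 / 0.33 S/m. The skull value honours the
classical 1/80 brain-to-skull ratio exactly (0.33/80); the historically
rounded 0.042 S/m can be passed instead. Per spherical-harmonic degree the
radial two-point boundary problem is solved exactly (5×5 linear system with
row/column equilibration — the raw system spans ~50 orders of magnitude at
high degree); the series is truncated when terms fall below 1e-12 of the
running maximum (cap 400; the deepest default dipole at eccentricity 0.78
converges near degree 110). The implementation is validated against an
independently derived closed form for the homogeneous sphere (generating
functions of the Legendre series), against mirror symmetry, conductivity
scaling, and the surface-integral (average-reference) property on a
200-point Fibonacci grid.

The 32-channel 10-10 montage is built geometrically (midline and
circumferential ring at canonical inclinations, intermediate electrodes as
great-circle midpoints), exactly left/right symmetric. The six default
dipoles are *synthetic, plausibility-tuned* stand-ins: cochlear dipole in
the temporal-bone region of the implant side with radial orientation
(ipsilateral artifact maximum, default right, peaking at TP10), midline
brainstem and paired thalamic dipoles oriented toward the vertex, and
temporal cortical dipoles oriented vertically, which focalises the ASSR
over the fronto-central electrodes around Cz. Subject-derived coordinates
can replace them, and an external (e.g. BEM-derived) lead field can be
imported via `load_lead_field()`.

Mixing is `EEG_ASSR = LF1 S_n`, `EEG_Art = LF2 S_Art`,
`EEG_mix = EEG_ASSR + EEG_Art + b` with i.i.d. Gaussian sensor noise `b`
(default sd 0.25 µV, an amplifier-noise figure — background *brain*
activity is deliberately not modelled, see §8). Source time courses are
mean-centred before projection (scalp recordings are AC-coupled). Two
calibration scalars map the arbitrary-unit sources to microvolts:
`neural_gain = 0.1` and `artifact_gain = 120`, fixed once so that the
default scenario reproduces the published operating point — an
epoch-averaged artifact amplitude of ≈ 8 µV at the most contaminated
electrode versus ≈ 1 µV of neural ASSR at Cz, with an ongoing background
of a few µV RMS.

## 5. Estimators

All estimators live in tidy, composable functions returning tibbles.

* **Epoching** (`epoch_signal`): contiguous, non-overlapping segments of
  `D = k T_m` (default `k = 20`, `D = 0.512` s), trailing remainder
  discarded; 40 s yield 78 epochs. The published analysis mentions
  averaging over 150 segments, which a 40 s record cannot contain; the
  number of averaged segments therefore defaults to "all available".
* **ASSR amplitude** (`assr_amplitude`): time-domain average of the
  segments, then the single-sided FFT amplitude of the exact `f_m` bin.
* **Phase coherence** (`phase_coherence`): resultant-vector statistic of
  the per-epoch FFT phases at `f_m`; 1 = perfect locking, detection at
  PC > 0.8 with 20-epoch sweeps. Zero-amplitude bins have undefined phase
  and are excluded with a warning.
* **Estimation error** (`estimation_error`): `100·(denoised − neural) /
  neural` per electrode; positive = artifactual residue, negative =
  over-removal. Zero-neural electrodes are excluded and reported.
* **Mutual information** (`mutual_information`): plug-in estimator on an
  `M × M` equal-width histogram, natural log. `bins = "auto"` applies
  Scott's rule (width `3.49 σ N^{-1/3}`) per signal and takes the smaller
  count. The analytic bias `(M−1)²/(2N)` is subtracted and the corrected
  value reported *signed*: for peaky marginals (the pulsatile artifact)
  the occupied cell count is far below `M²` and the correction
  deliberately overshoots toward small negative values — evidence of
  independence, not a defect.
* **Negentropy** (`negentropy`): `J = (E[G(y)] − E[G(g)])²` with
  `G(u) = log cosh(a u)/a`, `a = 1`; the signal is standardised first, so
  J is affine-invariant, and `E[G(g)] = 0.3745672…` is computed once by
  quadrature and cached. `log cosh` is evaluated in overflow-safe form.
* **Normality screen** (`source_stats`): sample excess kurtosis plus the
  Anderson–Darling composite test (estimated mean/variance) at
  `alpha = 1e-3`.

## 6. The ICA benchmark

`run_ica()` centres the data, whitens by PCA to `n_components` (25 for the
simulated benchmark; fastICA instead receives the automatic dimension
estimate — covariance eigenvalues above 10× the median eigenvalue), then
applies the requested rotation. All four algorithms are implemented in
this package behind one seeded, deterministic interface:

* **infomax** — natural-gradient ML rule with the logistic nonlinearity,
  block updates over a shuffled permutation; the learning rate anneals
  only when the direction of successive weight updates turns by more than
  60° (the standard oscillation heuristic), and convergence is declared on
  a small relative weight change.
* **extended infomax** — the sign-switching sub/supra-Gaussian
  generalisation; the kurtosis-sign moment is re-estimated every five
  passes on a fixed subsample. It converges far more slowly than infomax
  (consistent with the published ~400× runtime ratio); at the default
  iteration cap it often stops short on EEG-sized problems, which is
  recorded in its diagnostics and visible in its larger, more variable
  errors.
* **JADE** — joint approximate diagonalisation of the maximal set of
  fourth-order cumulant matrices by Jacobi rotations; fourth moments are
  accumulated blockwise so memory stays bounded. Residual rotation angles
  below 0.05 rad concern noise-dominated cumulants and are treated as
  practical convergence.
* **fastICA** — symmetric fixed-point iteration with the kurtosis-family
  contrast `g(u) = u³` and eigenvalue-based symmetric decorrelation.

The rotation is *estimated* on a contiguous central window of at most
120 000 samples and then applied to the full recording — the usual
reduced-training practice for long high-rate EEG. A contiguous window is
essential: strided decimation aliases the pulsatile artifact and destroys
the decomposition.

Artifactual components are flagged automatically by a dual rule replacing
the published manual practice: carrier-band spectral energy
(`f_c ± 10 Hz` and harmonics) must exceed 5× the energy around `f_m`,
*and* the component's scalp map must correlate (|r| > 0.8) with the known
artifact topography (the cochlear lead-field column in simulation; a
user-supplied map otherwise). Both thresholds are engineering choices and
configurable; a manual index list is also supported
(`reject_and_reconstruct`). Rejected activations are zeroed and the rest
back-projected (plus channel means).

`run_benchmark()` orchestrates the whole comparison — simulate, decompose,
classify, reject, score — per modulation depth and seed, with failures
recorded and excluded from aggregates, and returns tidy `errors` and
`runs` tables (`tidy()`, `glance()`, `autoplot()`). In the default
configuration infomax isolates the artifact in exactly one of 25
components and lands within a few percent of the ground-truth ROI
amplitudes; fastICA retains 4 components and performs comparably; JADE is
close behind; extended infomax over-removes and varies most — the same
qualitative ranking as the published benchmark.

### Why we do not reproduce the published negentropy uplift

The published comparison reports component negentropies four orders of
magnitude above channel negentropies. With the affine-invariant estimator
of §5 this uplift cannot exist for *any* data: standardised log-cosh
negentropy of a supra-Gaussian signal is bounded by
`(E[G(g)])² ≈ 0.14`, and the mixture channels — being artifact-dominated,
which is the premise of the benchmark — are already strongly
non-Gaussian. Reproducing the published arithmetic requires evaluating the
contrast on signals at their native scales, where `J ≈ (E|u| − 0.375)²`
grows without bound with the scale of the unmixed activations; the
published channel and component values are consistent with signals of
standard deviation ≈ 0.066 and activations of mean magnitude ≈ 85
respectively. In other words, the uplift measures the scaling convention
of the unmixing implementation, not non-Gaussianity. We report the
invariant quantity and leave the uplift check red by design.

## 7. Problem sizes, tolerances and degenerate inputs

Three profiles fix the study conditions: `paper_scale` (50 kHz, 40 s — the
full-scale conditions; one such simulation backs the source-statistics
replication), `bench` (10 kHz, 20 s — the benchmark scale, preserving the
500 Hz carrier), and `quick` (10 kHz, 10 s — the test-suite scale). The
test suite runs ten `quick` simulations for the algorithm comparison and
ten 6-second simulations per modulation depth for the depth sweep; these
sizes give stable orderings (artifact flags, subspace dimension and the
algorithm ranking were identical at twice the duration) while keeping the
default test run at desk scale. Determinism is end-to-end: every stochastic stage derives its
stream seed from the scenario seed, and identical configurations reproduce
bit-identical datasets, decompositions and benchmark tables.

Degenerate inputs are rejected loudly rather than silently repaired:
constant signals (negentropy, MI, normality screen), zero-width histogram
ranges, epochs shorter than one modulation period, widths quantizing into
the next pulse, dipoles outside the brain shell, rank-deficient data with
too many requested components, rejection of every component, mismatched
lead-field sidecars, malformed EEG headers (which name the offending
field). Numerical tie-breaks worth knowing: histogram binning uses
half-open cells with the top edge closed; pulse widths round half-up with
a one-sample floor; the fixed-point solver damps by 0.5; Jacobi rotation
angles use the numerically stable `atan2` form.

## 8. What the generator does and does not emulate

It emulates: the PWM stimulation paradigm and its temporal statistics; a
capacitive interface artifact with realistic sparsity; a six-source neural
architecture with subcortical phase locking and cortical low-pass
behaviour; volume conduction through a three-shell head with a 10-10
montage; sensor noise; and the resulting mixture at the published
operating point (≈ 8 µV artifact vs ≈ 1 µV ASSR, effective dimension 4).

It does not emulate: background cortical activity unrelated to auditory
processing (so channels are cleaner than real EEG and separation is
easier — passing benchmarks here bounds performance from above, it does
not certify clinical performance); the pseudo-monophasic passive-discharge
artifact shape (the active pulse only); the radio-frequency antenna
artifact; electrode-array geometry and current spread; subject anatomy
(analytic sphere instead of a BEM head — an imported lead field narrows
that gap); 80 Hz ASSR generators; and ocular/muscular artifacts. The
bundled dipole set is synthetic; its topographies are qualitative stand-ins
tuned to the published descriptions (fronto-central ASSR, ipsilateral
artifact), not subject-derived coordinates.
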