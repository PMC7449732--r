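---
title: "Models and methods in hddot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hddot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hddot)
```

This vignette is the package's account of the science it implements: the
acquisition model of a wearable, modular high-density diffuse optical
tomography (HD-DOT) device and the analysis chain from raw dual-integration
charges to group-level activation statistics. It also records the design
choices that were genuinely open and what the synthetic-data generator does
and does not emulate.

## The instrument model

Each 30 mm sensor board carries two dual-wavelength LED source sites
(740 and 855 nm) at opposite corners, two photodiode detectors at the other
corners and two short-separation detectors 10 mm from their paired source.
The within-board source–detector separation multiset
{10, 10, 23, 23, 23, 23, 28, 28} mm is the tested geometric contract; exact
board coordinates are configuration (`moduleLayout()`), because only the
separations are physically meaningful to the measurement model. A 2 × 6
raster of modules with a 2 mm inter-module gap (the thickness of the
elastic strapping in the physical device) gives 24 sources × 48 detectors =
1152 channels per wavelength; channels are enumerated across module
boundaries without a distance cutoff, because the usable maximum separation
is an empirical property handled by pruning, not geometry.

**Dual integration.** Each 6.8 ms illumination slot contains a short
(A, 0.5 ms) and a long (B, 6.3 ms) charge integration on a converter with a
50 pC full well and 0.63 fC RMS noise. The LED switches on τ_ovp before B
begins, so the short integration sees the source for only
τ_ovp ∈ {0.02, …, 0.5} ms. Channels that saturate the long integration are
read from the short one, extending the maximum detectable intensity by
t_long/τ_ovp — a factor of 315 at the grid minimum. With 48 illuminations
plus one dark slot per frame, the frame rate is 1/(49 × 6.8 ms) = 3.0 Hz.

**Units and derived constants.** Charges are pC, integration times ms,
optical powers W, geometry mm, concentrations molar. The photodiode
responsivity is not independently specified by the device's published
figures; requiring 0.63 fC over 6.3 ms ↔ 205 fW fixes R = 0.488 A/W, which
then also maps the 50 pC full well to 16.3 nW. We adopt that value as the
default and expose it in `detectorSpec()`. Dynamic range is
20·log10(p_max/p_min): 98.0 dB in the charge domain and 94.2 dB against a
318 fW noise-equivalent power. Note that combining 94.2 dB with the
20·log10(315) ≈ 50 dB dual-integration gain gives 144.2 dB, not the 142.6
dB sometimes quoted for this class of device; the package implements the
formula and does not attempt to reproduce the latter figure, which implies
an unexplained effective minimum overlap of ≈ 0.024 ms.

## The synthetic-data generator

The generator (`makeProtocol()`, `groundTruth()`, `simulateChannels()`,
`toFrames()`, `injectMotion()`, `simulateMpu()`) exists so that every
downstream stage is testable without any instrument. Its defaults describe
the study conditions the pipeline targets:

- **Stimulus timing:** 17.5 s blocks, inter-stimulus intervals jittered
  uniformly on 17.5–22.5 s, 30 s lead/tail rest; 16 blocks (8 per hand)
  for a texting-style paradigm (≈ 11 min), 12 blocks for a walking
  paradigm (≈ 8.5 min).
- **Activation:** per condition, a Gaussian blob (σ = 6 mm, configurable
  down to a single voxel) at cortical depth with +10 µM ΔHbO and −3 µM
  ΔHbR plateau amplitudes, driven by the block boxcar convolved with a
  double-gamma kernel (peak 6 s, undershoot 16 s, ratio 1/6). The kernel is
  a generator choice, not an estimate the pipeline assumes — the
  deconvolution stage is basis-based precisely so tests are shape-agnostic.
- **Superficial physiology:** cardiac 1.1 Hz, respiratory 0.25 Hz, Mayer
  waves 0.1 Hz, with optical-density amplitudes at a 23 mm channel of
  0.01/0.008/0.012 and a partial pathlength that decays with separation, so
  short channels carry relatively more scalp signal — the property the
  short-separation regressor exploits. The 1.1 Hz cardiac line aliases at
  the 3 Hz frame rate by construction; that is a deliberate feature of the
  emulated sampling regime. No published superficial-to-brain ratio exists
  for this device class, so these amplitudes are stated choices, not fits.
- **Baseline intensity:** 1 nW at 23 mm, scaled by an inverse-square ×
  exp(−μ_eff·Δd) distance law. This makes 10 mm channels saturate the long
  integration (exercising integration selection) and pushes channels beyond
  ≈ 45 mm under the noise floor (exercising pruning), which is the
  qualitative behaviour of the physical device.
- **Noise:** Poisson-equivalent shot noise on the expected charge plus
  Gaussian dark noise at a noise-equivalent power of 318 fW, the in-vivo
  figure for this device class; the frame converter adds 0.63 fC RMS on
  every count.
- **Motion:** spikes (exponential decay, < 2 s), baseline shifts, and
  "walking micro-artifacts" — sustained low-amplitude broadband OD noise —
  applied coherently to all channels of a module. The accelerometer model
  produces 1 g baselines, high-variance step-frequency oscillations during
  walking blocks, and artifact-coincident spikes with a configurable
  probability (0 reproduces envelope independence).

What the generator does **not** emulate: real anatomy (no MRI meshes, no
tissue layers), curved probes, optode-scalp coupling variation, hair,
thermal drift, or the biomechanics of any task. Consequently, passing
closed-loop tests demonstrates internal consistency of the pipeline and
correct implementation of each algorithm — not that the pipeline would
achieve the same figures on in-vivo recordings.

## Preprocessing

The channel-space chain is, in order: prune → optical density → artifact
detection (pre) → kurtosis-wavelet correction → artifact detection (post) →
band-pass → Beer–Lambert → deconvolution. The order is contractual and
asserted by a test.

**Pruning.** A channel is good iff its mean intensity is ≥ 500 ppm of the
full-scale power (the "500 ppm" criterion is interpreted against the
converter full scale, since raw units are counts), its mean/SD is ≥ 12, and
it never saturated. A constant series (SD = 0) passes: the SNR threshold
targets noisy dim channels, and synthetic fixtures legitimately produce
constants. Both wavelengths of a source–detector pair must pass.

**Motion detection.** Sliding ~1 s windows (50 % overlap); a window is
artifactual when its excursion exceeds 0.5 OD or its SD exceeds 50 × the
channel's median windowed SD, and the envelope is padded by 1 s. These
four parameters follow channel-space fNIRS processing conventions — they
are not instrument constants — and are exposed in `detectMotion()`. The
same scan applied to accelerometer-norm traces (lower thresholds, g units)
marks walking blocks essentially wholesale, which is exactly the behaviour
that makes naive accelerometer gating of optical artifacts unreliable.

**Wavelet correction.** Per channel, a 4-level periodized orthogonal
discrete wavelet transform (symlet-8 filter bank, embedded as constants;
symmetric padding to a block multiple). At each detail level, while the
coefficient kurtosis exceeds 3.3, the largest-magnitude coefficient is
zeroed. Because the transform is orthonormal and the edit terminates at or
below the threshold, a second pass is a no-op — idempotence is tested to
machine precision. The cited kurtosis criterion leaves the wavelet family,
depth and boundary handling open; ours are recorded here and in
`waveletCorrect()`.

**Band-pass.** Third-order Butterworth high-pass (0.01 Hz) and low-pass
(0.5 Hz) sections, each applied forward-backward for zero phase, after
explicit mean removal (a recursive filter at 0.0067 × Nyquist leaves
transients that mean removal eliminates exactly for the DC component). The
0.5 Hz edge sits below the 1.5 Hz Nyquist of the 3 Hz frame rate; 1.1 Hz
cardiac-band power is attenuated by > 20 dB.

**Beer–Lambert.** ΔOD_λ = (ε_HbO,λ ΔHbO + ε_HbR,λ ΔHbR)·d·DPF_λ per time
point, natural-log convention, DPF 7.5 (740 nm) and 7 (855 nm). The
extinction table (standard compiled haemoglobin spectra, converted to
natural-log mm⁻¹ M⁻¹) is plain data in `extinctionTable()` so tests pin the
version in use.

**Deconvolution.** For each condition, Gaussian bases (σ = spacing = 1.5 s)
span −5…30 s around onsets; the design adds an intercept and, per channel,
the concentration series of the nearest good ≤ 10 mm pair. Ordinary least
squares per chromophore; the HRF is the basis expansion of the fitted
coefficients (35 s per channel, condition and chromophore), with standard
errors propagated through the basis. The short-separation regressor enters
per chromophore (post-Beer–Lambert); regressing per wavelength
(pre-conversion) is algebraically equivalent for a shared DPF and was not
implemented separately. Drift regressors are off by default. Rank-deficient
designs raise an error carrying the condition number.

## Forward model and reconstruction

Subject-specific finite-element light transport is out of scope by design;
the package substitutes the continuous-wave diffusion Green's function for
a homogeneous semi-infinite medium: an isotropic source one transport mean
free path below the surface, an image source across the extrapolated
boundary (z_b = 2AD with A from the standard refractive-index-mismatch
polynomial at n = 1.4), and optionally a 2 mm lateral Gaussian source
profile. Default optical properties are scalp-like literature values
(μ_a = 0.0164/0.0190 mm⁻¹, μ_s′ = 0.74/0.64 mm⁻¹ at 740/855 nm),
configurable in `opticalProperties()`. Jacobians use the adjoint Rytov
form J[ch,v] = Φ(s,v)Φ(v,d)/Φ(s,d)·V_vox on the reconstruction grid
directly — with no mesh there is no mesh-to-voxel mapping step. Voxel
coordinates are mm, z ≥ 0 into the medium, voxel centres reported.

The multispectral system stacks both wavelengths' Jacobians scaled by the
extinction coefficients, mapping (ΔHbO, ΔHbR) voxel fields to
dual-wavelength ΔOD in one linear operator, and is inverted with
first-order Tikhonov regularization via LSQR (λ = 10⁻³, ≤ 50 iterations,
tolerance 10⁻⁵). Numerical choices: columns of the system matrix are
normalized to unit norm before solving (so λ acts on a dimensionless
system) and rescaled afterwards; the gradient-operator stacking weight is
λ × the largest row norm of the normalized matrix; the solve is restricted
to the 5 % sensitivity mask and voxels outside are exactly zero; forward
differences are taken only between in-mask neighbours. All of these are
config-switchable in `reconConfig()`. Reconstruction defaults to consuming
the deconvolved HRFs (mapped back to attenuation via the forward
Beer–Lambert step), since the response window is where per-time-point
images are scientifically meaningful; raw filtered ΔOD series are equally
accepted.

One property worth recording: with a first-order (gradient) penalty the
quantity that is provably monotone in λ is the penalty seminorm ‖Lx‖ and
the data residual — not the solution norm ‖x‖, which we verified is
non-monotone at small λ. The property tests assert the correct quantities,
over λ ∈ [10⁻³, 1] where the iterative solver converges.

## Group statistics

With no anatomy, the "cortical surface" is a planar node sheet at a
configurable depth (12 mm default) below the probe. Volume images map to
nodes as the mean of voxel values within 3 mm; activation is the 6–16 s
window mean against a −5–0 s baseline. The group test is a one-sample
sign-flip permutation t-test: under the null of symmetric subject maps,
all 2ⁿ sign assignments are exchangeable; we enumerate them fully when
2ⁿ ≤ 500 (n = 7 subjects → 128) and sample 500 otherwise, and control
family-wise error with the max-|T| distribution across masked nodes. The
threshold-free cluster enhancement and generalized-Pareto tail machinery
used by surface-statistics toolboxes is deliberately replaced by max-T: it
is exact under exchangeability, has no tuning parameters, and its error
control is testable by simulation (the calibration test runs 200 null
cohorts). Tests default to two-tailed; note that two-tailed sign-flip
enumeration ties every statistic with its global sign flip, so the smallest
achievable family-wise p is 2/2ⁿ — with 7 subjects 0.0156, comfortably
below α = 0.05, but with 5 subjects 0.0625, which can never reach
significance. This is why the pipeline's default cohort is 7.

Dice overlap binarizes each map at 30 % of its own maximum and computes
2|A∩B|/(|A|+|B|). Artifact-envelope concordance reports P(accelerometer
artifact | optical artifact) and P(no accelerometer artifact | no optical
artifact) on a common time base, with the 150 Hz accelerometer envelope
resampled to the frame rate by any-within-frame OR.

## Problem sizes

The package's own experiments are desk-scale by choice: unit tests use one-
and two-module probes with 8³-voxel grids at 5 mm; the end-to-end pipeline
default is the full 12-module probe with 4 blocks per subject, a 7-subject
cohort, and an ~8 mm grid covering the probe (≈ 1700 voxels), which runs in
about two minutes on one CPU. The permutation calibration uses 200 null
cohorts of 7 subjects × 50 nodes. The 50 × 60 × 50 grid at 2 mm remains the
`voxelGrid()` default for production-scale use.

## Known limitations

- The homogeneous semi-infinite medium ignores skull/CSF light piping;
  absolute sensitivities and depth profiles differ from subject-specific
  models, so reconstructed amplitudes are internally consistent rather than
  physiologically calibrated.
- Amplitude recovery through the full pipeline is partial-volume limited;
  closed-loop tests constrain it only under noise-free, matched-forward
  conditions.
- The motion-detection thresholds are conventions, not fitted values; the
  artifact-burden figures produced on synthetic cohorts depend on them
  jointly with the generator's artifact amplitudes.
- Spline/PCA motion correction, spatially varying regularization, drift
  regressors and between-group designs are out of scope.
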