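---
title: "Directed coupling of infraslow multimodal brain signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed coupling of infraslow multimodal brain signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocouple)
```

## The scientific problem

Spontaneous brain activity below 0.1 Hz — infraslow oscillations — appears
simultaneously in hemodynamic signals (BOLD from ultrafast fMRI sampled at
10 Hz), in direct-current-coupled EEG, and in tissue water concentration
measured optically with a 980 nm NIRS channel. Whether the electrical,
vascular, and water (CSF/hydrodynamic) components of this rhythm drive one
another, and whether the drive direction reorganizes between wakefulness and
NREM sleep, is a question about *directed* coupling that symmetric measures
(correlation, coherence) cannot answer.

`isocouple` implements the full analysis chain for this question: band-limit
each modality to 0.01–0.08 Hz, extract instantaneous Hilbert phases,
quantify directed interactions with discrete phase transfer entropy (TE),
summarize net direction with ΔTE, estimate infraslow spectral power with
Morlet wavelets, and perform group inference with Wilcoxon rank-sum tests
under FDR control and TFCE-corrected randomization tests. Because suitable
human recordings are access-restricted, the package ships a synthetic
multimodal generator with *known, imposed* coupling so that every stage has
a ground-truth recovery test.

## Phase transfer entropy

For two phase series discretized to symbols, with target $y$, source $x$,
and analysis lag $\delta$ (writing $y_t' = y_{t-\delta}$):

$$\mathrm{TE}_{x \to y} = H(y_t, y_{t'}) + H(y_{t'}, x_{t'}) - H(y_{t'}) -
H(y_t, y_{t'}, x_{t'}),$$

with plug-in (empirical frequency) entropies in bits. TE is the reduction in
uncertainty about the target's next phase afforded by the source's past,
beyond the target's own past; $\mathrm{TE} = 0$ bits indicates no
connection. The net direction statistic is

$$\Delta \mathrm{TE}_{x,y} = \mathrm{TE}_{x \to y} - \mathrm{TE}_{y \to x},$$

so for the BOLD–EEG pair a positive value means the hemodynamic signal
predicts the electrical one and a negative value the reverse.

Key estimator properties, each enforced by tests:

* **Nonnegativity and exact zeros.** Plug-in TE is nonnegative; a constant
  source or constant target gives exactly 0 bits.
* **Antisymmetry.** $\Delta\mathrm{TE}(x,y) = -\Delta\mathrm{TE}(y,x)$
  holds exactly, term by term.
* **Bias cancellation.** With ~870 usable triples and up to $8^3$ cells,
  each directional plug-in TE is strongly positively biased. The bias is
  symmetric for exchangeable pairs, so ΔTE is centred at zero under the
  null; the package's null-calibration tests verify the ensemble mean of
  ΔTE over 500 independent band-limited noise pairs sits inside its 99%
  Monte-Carlo confidence interval of zero.
* **Copy-process unit.** For a delayed binary copy $y_t = x_{t-\delta}$
  with i.i.d. uniform $x$, $\mathrm{TE}_{x\to y} = 1$ bit and
  $\mathrm{TE}_{y \to x} = 0$; the estimator reproduces this within 0.05
  bits at $n = 2{,}048$.

### Parameter choices

* **Phase bins (default 8).** A power of two balancing phase resolution
  against cell occupancy at the 1,200-sample epochs used here
  (867 usable triples over 512 joint cells). Exposed as `n_bins`.
* **Lag (default one cycle at 0.03 Hz, i.e. `round(fs/f_center)` = 333
  samples at 10 Hz).** A constant one-cycle delay at the band's spectral
  peak rather than a per-pair information-maximizing lag. This is the
  analysis's most sensitive knob; it is configurable via `f_center`.
* **No bias correction.** The plug-in estimator is used as-is: group
  inference rests on ΔTE, where the bias cancels, not on directional
  magnitudes.

## Band-limiting and phases

The band filter is a Hamming-window FIR of order 3,000 with cutoffs 0.01
and 0.08 Hz, excluding respiratory (~0.25 Hz) and cardiac (~1 Hz) bands.
Two design points required a decision:

* **Zero phase.** The taps are applied forward and backward, which squares
  the magnitude response and cancels all phase distortion — phase estimates
  downstream must not inherit filter delay. Tests verify zero lag on a
  passband tone and < 1% RMS leakage at 1 Hz.
* **Mirror padding.** Each signal is extended by `order` samples per side
  with repeated boundary reflection before filtering (the reflection tiles
  when the signal is shorter than the filter, so 120-s epochs remain
  usable), and the padding is removed afterwards.

Phases are $\theta_t = \arg z_t$ of the FFT-based analytic (Hilbert)
signal, wrapped to $[-\pi, \pi)$, then discretized into uniform bins.
EEG-rate inputs are decimated to 10 Hz after zero-phase anti-alias
filtering; optical absorbances convert to Hb/HbO/H₂O concentration changes
by the modified Beer–Lambert law $\Delta C = (L E)^{-1} \Delta A$ with
$L = \mathrm{diag}(d \cdot \mathrm{DPF}_\lambda)$, which is exactly linear
and invertible (extinction coefficients must be supplied for real optics;
fixtures use identity-like calibrations).

## Epoch selection

Hypnograms are 30-s stage labels. For each state, epochs of 120 s are taken
from the start of the *longest* continuous run of that state (earliest run
on ties); states whose longest run is shorter than one epoch contribute
nothing, and data outside selected epochs are excluded. A `max_per_state`
switch permits multiple non-overlapping epochs from the same run, which the
pipeline averages within subject–state before any group statistic, keeping
subjects as the inferential units.

## Spectral estimation

Time–frequency power uses complex Morlet wavelets on a 50-step logarithmic
grid from 0.01 to 5 Hz (the 10 Hz Nyquist), 8 cycles at every frequency,
kernels truncated at ±4 SD and normalized to unit energy. Band power is the
time-averaged spectrum integrated over 0.01–0.08 Hz by the rectangle rule
with bin widths from geometric midpoints of the log grid. Voxel-wise cost is
cut by simple random subsampling without replacement (5% default — 3,405 of
68,100 voxels at whole-brain scale), with every voxel equally likely.

One limitation matters for 2-min epochs: kernels below ~0.03 Hz are longer
than the epoch even after one full mirror extension per side, so their
power is damped by truncation. `tf_power()` flags these frequencies
(`low_freq_flag`) rather than refusing to compute; state *contrasts* of
band power are unaffected because the damping is common to both states, but
absolute low-frequency power from short epochs should be read with care.
Tests of peak localization therefore use signals long enough for the kernel
to fit; tests of power *ratios* use the 2-min epochs themselves.

## Group inference

* **Wilcoxon rank-sum (two-tailed)** with midranks; exact enumeration for
  combined $n \le 12$, otherwise the normal approximation with tie and
  continuity corrections. The standardized $Z$ accompanies every
  comparison.
* **FDR control** by Benjamini–Hochberg across the family of contrasts.
* **Voxelwise randomization test**: the statistic is the absolute
  difference of group mean maps, enhanced by TFCE ($E = 0.5$, $H = 2$,
  $dh = \max/100$, 6-connectivity — the field's standard defaults), with a
  max-statistic null over label permutations (exhaustive when feasible,
  Monte-Carlo with seed otherwise; 5,000 permutations by default). The
  returned voxel p-values are FWER-corrected; the suite verifies type-I
  error ≤ 0.05 under a null generator and detection of planted effects.

## The synthetic generator

Three latent phase oscillators — ELEC (electrophysiology), BLOOD (blood
volume/BOLD), WATER (tissue water) — follow a delayed Kuramoto-style
update:

$$\theta_i[n+1] = \theta_i[n] + 2\pi f_i / f_s +
\sum_j \kappa_{j \to i} \sin(\theta_j[n-\delta] - \theta_i[n] + \psi_{ji})
+ \sigma_\theta \, \xi[n],$$

with $\delta$ one cycle at 0.03 Hz, so the imposed drive matches the
analysis lag. Latents are amplitude-scaled cosines of these phases plus
broadband noise. Rendering maps BLOOD onto a 12³ voxel grid through a
spatially smooth positive loading plus voxel noise and global 1 Hz
"cardiac" and 0.25 Hz "respiratory" tones; ELEC onto 16 electrodes through
per-channel gains; and the optical channels as Hb $= -0.25\,$BLOOD,
HbO $= +0.5\,$BLOOD, H₂O $= \mp 0.15\,$BLOOD $+$ WATER. The atlas slices
the mask into 9 contiguous blocks standing in for the 9 bilateral ROIs.

Design choices worth recording:

* **Antiphase water–blood coupling.** With `anticorr_water` (default), the
  WATER↔BLOOD edges attract with a π offset ($\psi = \pi$), so blood
  volume and water oscillate in opposition — the Monro–Kellie expectation —
  while remaining directionally coupled. A constant phase offset shifts
  symbols by exactly half the bin alphabet and leaves every TE term
  unchanged, so directionality results are unaffected; the rendered H₂O
  channel stays anticorrelated with HbO even under coupled dynamics.
* **State profiles.** Defaults impose the awake pattern of one-way drive
  onto BLOOD ($\kappa_{\mathrm{ELEC}\to\mathrm{BLOOD}} =
  \kappa_{\mathrm{WATER}\to\mathrm{BLOOD}} = 0.3$) and near-symmetric
  bidirectional coupling (0.15 each way) in N1/N2, where ΔTE should sit
  near zero. Observed awake whole-brain ΔTE medians under these defaults
  are on the order of $-0.1$ bits for both BOLD pairs. Awake coupling
  strengths are not quantified by physiology; these are generator design
  values, chosen once.
* **Power profiles.** Electrical and hemodynamic latent amplitudes scale by
  $\sqrt{2}$ in N1 and 2 in N2 (band power ×2 and ×4); the water amplitude
  is state-independent.
* **Noise scales.** Phase diffusion $\sigma_\theta = 0.07$ rad/sample
  (≈ 1.3 rad drift per cycle — strongly stochastic oscillators), 5%
  frequency individuality per oscillator, broadband latent noise SD 0.05,
  observation noise SD 0.1. These were chosen so that the generator
  satisfies its stated calibration: a one-way $\kappa = 0.3$ drive is
  recovered with the correct ΔTE sign in ≥ 95% of 1,200-sample
  realizations, while the uncoupled case remains null-calibrated.
* **Initialization.** The first coupling-delay's worth of phase history is
  prefilled with free-running rotation; letting the delayed term reference
  a static initial phase creates a spurious phase-locked fixed point that
  can freeze the dynamics entirely.

What the generator does **not** emulate: hemodynamic response convolution,
head geometry and leadfields, scanner artifacts, non-stationary arousal
transitions, and spatially structured physiological noise. Passing recovery
tests on this generator therefore demonstrates the *estimator chain* is
correct and calibrated, not that real recordings satisfy its assumptions.

## Problem sizes used in the shipped analyses

The package's own tests and the acceptance script run at desk scale, chosen
to keep full runs reproducible on a laptop: 4×4×9 voxel grids (the longest
axis must hold the 9 ROI blocks), 2–16 electrodes, cohorts of 6–20
synthetic subjects, 200–500 Monte-Carlo realizations for calibration
checks, and 500 permutations on 8³ grids for the randomization-test
calibration (100 repetitions). All counts are configurable upward; the
statistical structure does not change with scale.

## Numerical conventions and degenerate inputs

* Phases live in $[-\pi, \pi)$; the single closed endpoint from `Arg`
  ($+\pi$) is folded to $-\pi$. Bin $k$ covers
  $[-\pi + 2\pi k/K, -\pi + 2\pi(k+1)/K)$.
* Plug-in TE values within $10^{-12}$ below zero are clipped to zero;
  anything lower is an internal error, not a clip.
* An all-zero signal has no phase and is an explicit error, as are empty
  masks, empty ROIs, misaligned hypnograms, singular extinction matrices,
  non-even filter orders, and coupling strengths whose per-step pull
  reaches π.
* A constant lag map (e.g. a single global driver) yields `NA` for the
  lag-vs-TE control correlation rather than a spurious value.
* Wilcoxon ties use midranks in both the exact and approximate branches;
  the exact two-tailed p counts assignments at least as extreme on either
  side.

## Known limitations

* Only bivariate TE is implemented; common drivers can induce spurious
  pairwise transfer, and the lag-map control quantifies only the
  delay-structure confound.
* The one-cycle lag is a convention; true interaction delays off the cycle
  are attenuated.
* Short-epoch wavelet power below ~0.03 Hz is truncation-damped (flagged,
  see above).
* The permutation test assumes exchangeable subjects across states
  (unpaired contrasts).
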