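# isocouple

Directed coupling among infraslow (< 0.1 Hz) brain signals across arousal
states, for researchers combining ultrafast fMRI (10 Hz BOLD),
direct-current-coupled EEG, and water-sensitive (980 nm) fNIRS. The package
asks the question correlation cannot: which signal *predicts* which, and
does the prediction direction reorganize between wakefulness and NREM
sleep?

## The core statistic

Signals are band-limited to 0.01–0.08 Hz (Hamming FIR, order 3000, applied
forward–backward for zero phase, with mirror padding), and instantaneous
phases θ = arg z are taken from the Hilbert analytic signal and discretized
into 8 uniform bins. Directed interaction is measured by discrete phase
transfer entropy at a one-cycle lag δ (333 samples at 10 Hz for a 0.03 Hz
centre), with t′ = t − δ:

    TE(x→y) = H(y_t, y_t′) + H(y_t′, x_t′) − H(y_t′) − H(y_t, y_t′, x_t′)

in bits, with plug-in entropies; TE = 0 bits indicates no connection. The
net direction is

    ΔTE(x,y) = TE(x→y) − TE(y→x),

whose sign gives the dominant prediction direction (each directional TE is
finite-sample biased, but the bias cancels in ΔTE). Around the statistic
the package provides Morlet wavelet band power (50-step log grid,
0.01–5 Hz, 8 cycles), Wilcoxon rank-sum group contrasts with
Benjamini–Hochberg FDR control, TFCE-corrected randomization tests for
voxel maps, a seed-based lag-map control, and a synthetic multimodal
generator with known imposed coupling that gives every stage a ground-truth
test.

## Worked example

Simulate an awake-state recording in which the electrophysiological latent
drives the hemodynamic one, then ask the estimator which way information
flows:

```r
library(isocouple)

cfg <- synthetic_config(states = c("AWAKE", "N2"))
lat <- simulate_coupled_latents(cfg, "AWAKE", seed = 42)

taps      <- design_fir()
bold_like <- filter_band(lat[, "BLOOD"], taps)
eeg_like  <- filter_band(lat[, "ELEC"],  taps)

phase_te_signals(bold_like, eeg_like, lag = default_lag(0.03, 10))
#> phase TE (lag 333 samples, 8 bins, n = 867)
#>   TE(x->y) = 0.7336 bits, TE(y->x) = 1.1176 bits, delta TE = -0.3840 bits
```

ΔTE is negative: the EEG-like signal predicts the BOLD-like signal, exactly
the direction the generator imposed (the individual TE values are far above
their asymptotic magnitudes because the plug-in estimator is biased at
n = 867; the *difference* is the meaningful quantity). The same chain runs
at cohort scale, here with the default generator whose N2 state doubles
hemodynamic and electrical amplitudes:

```r
sc  <- synthetic_config(grid_shape = c(4, 4, 9), n_electrodes = 4,
                        states = c("AWAKE", "N2"))
res <- run_power_analysis(run_config(synthetic = sc, n_subjects = 6, seed = 3))
res$contrasts
#>   modality         z           p n_awake n_sleep       p_adj
#> 1     BOLD -2.802243 0.002164502       6       6 0.003246753
#> 2      EEG -2.802243 0.002164502       6       6 0.003246753
#> 3     NIRS -2.481986 0.008658009       6       6 0.008658009
```

All three modalities show significantly higher infraslow band power in the
sleep state (negative z: awake ranks lower), as configured.
`run_coupling_analysis()` produces the companion directed-coupling results:
voxelwise ΔTE maps per pair, whole-brain and 9-ROI aggregates with
directional components, an EEG–H₂O electrode topography, TFCE-corrected
state contrasts, and the lag-map control. A thin command-line front end
(`exec/isocouple generate|power|coupling|all`) wraps the same functions for
one-shot reproducible runs.

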