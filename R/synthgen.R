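#' Configuration for the synthetic multimodal generator
#'
#' Defines the study conditions emulated by the generator: three latent
#' infraslow phase oscillators (ELEC, BLOOD, WATER) with directed,
#' state-dependent sinusoidal phase coupling, state-dependent amplitudes,
#' spatially smooth voxel loadings, and cardiorespiratory nuisance tones.
#'
#' The coupling matrix `kappa[[state]][j, i]` is the strength (rad/sample)
#' with which oscillator j pulls the phase of oscillator i, acting at a
#' delay of one cycle at `f_center`. Defaults impose the awake pattern of
#' one-way drive onto the hemodynamic latent (ELEC -> BLOOD and
#' WATER -> BLOOD) and near-symmetric bidirectional coupling in N1/N2,
#' where the net direction statistic should sit near zero.
#'
#' `power_scale[[state]]` multiplies latent amplitudes: infraslow power in
#' the electrical and hemodynamic latents doubles in N1 and quadruples in N2
#' relative to wakefulness (amplitude scales sqrt(2) and 2), while the water
#' latent amplitude is state-independent.
#'
#' @param fs sampling rate, Hz.
#' @param epoch_len_s epoch length in seconds.
#' @param n_epochs_per_state number of epochs generated per state.
#' @param states ordered arousal-state labels, subset of AWAKE/N1/N2.
#' @param osc_band infraslow band (f_lo, f_hi) in Hz.
#' @param f_center centre frequency of the latent oscillators, Hz.
#' @param kappa named list (one 3x3 matrix per state) of directed coupling
#'   strengths among latents ELEC, BLOOD, WATER; `kappa[[s]][j, i]` couples
#'   j -> i. NULL for the defaults described above.
#' @param power_scale named list (one length-3 vector per state) of
#'   amplitude multipliers for ELEC, BLOOD, WATER. NULL for the defaults.
#' @param anticorr_water if TRUE the NIRS water channel loads negatively on
#'   the blood-volume latent (Monro-Kellie style anticorrelation).
#' @param grid_shape 3D voxel grid dimensions.
#' @param n_electrodes number of EEG channels.
#' @param noise_sd SD of additive voxel/channel observation noise.
#' @param latent_noise_sd SD of broadband noise added to each latent.
#' @param phase_noise_sd SD of the per-sample phase innovation (rad).
#' @param freq_jitter fractional SD of per-oscillator frequency detuning
#'   around `f_center`.
#' @param nuisance amplitudes of the 1 Hz "cardiac" and 0.25 Hz
#'   "respiratory" tones, named vector c(cardiac=, respiratory=).
#' @param seed RNG seed; identical configs produce bit-identical recordings.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(fs = 10, epoch_len_s = 120, n_epochs_per_state = 1,
                             states = c("AWAKE", "N1", "N2"),
                             osc_band = c(0.01, 0.08), f_center = 0.03,
                             kappa = NULL, power_scale = NULL,
                             anticorr_water = TRUE,
                             grid_shape = c(12, 12, 12), n_electrodes = 16,
                             noise_sd = 0.1, latent_noise_sd = 0.05,
                             phase_noise_sd = 0.07, freq_jitter = 0.05,
                             nuisance = c(cardiac = 0.05, respiratory = 0.05),
                             seed = 1L) {
  latents <- c("ELEC", "BLOOD", "WATER")
  states <- match.arg(states, c("AWAKE", "N1", "N2"), several.ok = TRUE)
  stopifnot(fs > 0, epoch_len_s > 0, n_epochs_per_state >= 1,
            length(osc_band) == 2, osc_band[1] > 0, osc_band[1] < osc_band[2],
            length(grid_shape) == 3, all(grid_shape >= 1), n_electrodes >= 1,
            noise_sd >= 0, latent_noise_sd >= 0, phase_noise_sd >= 0)
  if (fs <= 2 * osc_band[2])
    stop("sampling rate must exceed twice the band upper edge")
  if (f_center <= 0 || f_center >= fs / 2)
    stop("f_center must lie in (0, fs/2)")
  if (epoch_len_s < 1 / f_center)
    stop("epoch must exceed one oscillation cycle at f_center")

  if (is.null(kappa)) {
    k0 <- matrix(0, 3, 3, dimnames = list(latents, latents))
    awake <- k0; awake["ELEC", "BLOOD"] <- 0.3; awake["WATER", "BLOOD"] <- 0.3
    sleep <- k0
    sleep["ELEC", "BLOOD"] <- sleep["BLOOD", "ELEC"] <- 0.15
    sleep["WATER", "BLOOD"] <- sleep["BLOOD", "WATER"] <- 0.15
    kappa <- list(AWAKE = awake, N1 = sleep, N2 = sleep)
  }
  if (is.null(power_scale)) {
    power_scale <- list(AWAKE = c(ELEC = 1, BLOOD = 1, WATER = 1),
                        N1 = c(ELEC = sqrt(2), BLOOD = sqrt(2), WATER = 1),
                        N2 = c(ELEC = 2, BLOOD = 2, WATER = 1))
  }
  for (s in states) {
    k <- kappa[[s]]
    if (is.null(k) || !is.matrix(k) || any(dim(k) != 3))
      stop("kappa must hold a 3x3 matrix for state ", s)
    if (any(!is.finite(k)) || any(k < 0))
      stop("kappa entries must be finite and >= 0")
    if (any(colSums(k) >= pi))
      stop("total incoming coupling >= pi per step destabilizes the phase update")
    ps <- power_scale[[s]]
    if (is.null(ps) || length(ps) != 3 || any(!(ps > 0)))
      stop("power_scale must hold 3 positive values for state ", s)
  }

  structure(list(fs = fs, epoch_len_s = epoch_len_s,
                 n_epochs_per_state = n_epochs_per_state, states = states,
                 osc_band = osc_band, f_center = f_center, kappa = kappa,
                 power_scale = power_scale, anticorr_water = anticorr_water,
                 grid_shape = as.integer(grid_shape),
                 n_electrodes = as.integer(n_electrodes),
                 noise_sd = noise_sd, latent_noise_sd = latent_noise_sd,
                 phase_noise_sd = phase_noise_sd, freq_jitter = freq_jitter,
                 nuisance = nuisance, seed = as.integer(seed),
                 latents = latents),
            class = "synthetic_config")
}

#' Simulate the three coupled infraslow latents for one state
#'
#' Integrates three Kuramoto-style phase oscillators with directed delayed
#' coupling: theta_i[n+1] = theta_i[n] + 2*pi*f_i/fs +
#' sum_j kappa[j,i] * sin(theta_j[n - delta] - theta_i[n]) + phase noise,
#' where delta is one cycle at `f_center`. Each latent is
#' amplitude * cos(theta) plus broadband noise; amplitudes follow
#' `power_scale[[state]]`. A burn-in of two coupling delays is discarded so
#' the delayed interaction is fully engaged.
#'
#' @param config a [synthetic_config()].
#' @param state one of the configured state labels.
#' @param seed RNG seed; defaults to the config seed.
#' @return an n x 3 matrix with columns ELEC, BLOOD, WATER; the phase paths
#'   are attached as attribute "phases".
#' @export
simulate_coupled_latents <- function(config, state, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  state <- match.arg(state, config$states)
  fs <- config$fs
  n <- round(config$epoch_len_s * fs) * config$n_epochs_per_state
  del <- default_lag(config$f_center, fs)
  kap <- config$kappa[[state]]
  amp <- config$power_scale[[state]]

  # with anticorr_water, the WATER-BLOOD edges attract in antiphase so the
  # blood-volume and water latents oscillate in opposition (Monro-Kellie)
  # while remaining directionally coupled; a constant phase offset leaves
  # the phase transfer entropy unchanged
  psi <- matrix(0, 3, 3)
  if (isTRUE(config$anticorr_water)) {
    psi[3, 2] <- pi  # WATER -> BLOOD
    psi[2, 3] <- pi  # BLOOD -> WATER
  }

  with_seed(seed, {
    f <- config$f_center * (1 + config$freq_jitter * rnorm(3))
    f <- pmin(pmax(f, config$osc_band[1]), config$osc_band[2])
    w <- 2 * pi * f / fs
    burn <- 3L * del
    ntot <- n + burn
    th <- matrix(0, ntot, 3)
    xi <- matrix(rnorm(3 * (ntot - 1), sd = config$phase_noise_sd), ntot - 1, 3)
    # prefill one delay period with free-running rotation so the delayed
    # coupling term never sees a static history (which would create a
    # spurious phase-locked fixed point)
    th0 <- runif(3, -pi, pi)
    for (i in 1:3)
      th[1:(del + 1L), i] <- th0[i] + w[i] * (0:del) +
        cumsum(c(0, xi[seq_len(del), i]))
    for (t in (del + 1L):(ntot - 1L)) {
      tp <- t - del
      dphi <- sin(matrix(th[tp, ], 3, 3) - matrix(th[t, ], 3, 3, byrow = TRUE) +
                    psi)
      th[t + 1, ] <- th[t, ] + w + colSums(kap * dphi) + xi[t, ]
    }
    th <- th[(burn + 1):ntot, , drop = FALSE]
    lat <- sweep(cos(th), 2, amp, `*`) +
      config$latent_noise_sd * matrix(rnorm(n * 3), n, 3)
    colnames(lat) <- config$latents
    attr(lat, "phases") <- th
    attr(lat, "state") <- state
    lat
  })
}

# Smooth a white-noise field on a 3D grid with a separable Gaussian kernel
# (sd in voxels) to obtain spatially correlated loadings.
smooth_field3d <- function(dims, sd_vox = 1.5) {
  field <- array(rnorm(prod(dims)), dims)
  half <- max(1L, ceiling(3 * sd_vox))
  kern <- exp(-((-half):half)^2 / (2 * sd_vox^2))
  kern <- kern / sum(kern)
  smooth_axis <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    cols <- matrix(m, dm[1], dm[2] * dm[3])
    sm <- apply(cols, 2, function(v) {
      np <- length(v)
      li <- mirror_indices(np, half)
      vp <- c(v[li], v, v[np + 1L - rev(li)])
      as.numeric(stats::filter(vp, kern, sides = 2))[(half + 1):(half + np)]
    })
    aperm(array(sm, dm), order(perm))
  }
  for (ax in 1:3) field <- smooth_axis(field, ax)
  field
}

#' Render a multimodal recording from latent series
#'
#' Maps the three latents onto the observed modalities: BOLD voxels are a
#' spatially smooth positive loading of the BLOOD latent plus voxel noise
#' and global cardiorespiratory nuisance tones; EEG channels are per-channel
#' gains on the ELEC latent; the NIRS water channel loads negatively on
#' BLOOD (when `anticorr_water`) plus the WATER latent, while HbO loads
#' positively and Hb negatively on BLOOD. The atlas partitions the mask into
#' 9 contiguous blocks along the longest grid axis.
#'
#' @param latents matrix from [simulate_coupled_latents()].
#' @param config the [synthetic_config()] used.
#' @param state state label stored in the hypnogram.
#' @param seed RNG seed for loadings/gains/noise; defaults to config seed
#'   offset so it does not reuse the latent stream.
#' @return an object of class `multimodal_recording` with elements
#'   bold (4D array), mask, eeg (channels x t), nirs (3 x t: Hb, HbO, H2O),
#'   hypnogram, fs, atlas.
#' @export
render_recording <- function(latents, config, state,
                             seed = config$seed + 104729L) {
  stopifnot(inherits(config, "synthetic_config"), is.matrix(latents),
            ncol(latents) == 3)
  state <- match.arg(state, c("AWAKE", "N1", "N2"))
  dims <- config$grid_shape
  if (max(dims) < 9)
    stop("grid too small: longest axis must hold 9 nonempty ROI labels")
  n <- nrow(latents)
  fs <- config$fs
  nv <- prod(dims)
  tt <- (seq_len(n) - 1) / fs
  tone <- config$nuisance[["cardiac"]] * sin(2 * pi * 1.0 * tt) +
    config$nuisance[["respiratory"]] * sin(2 * pi * 0.25 * tt)

  with_seed(seed, {
    load_field <- 1 + 0.3 * as.vector(scale_field(smooth_field3d(dims)))
    load_field <- pmax(load_field, 0.2)
    bold <- outer(load_field, latents[, "BLOOD"]) +
      matrix(rnorm(nv * n, sd = config$noise_sd), nv, n)
    bold <- bold + rep(tone, each = nv)
    dim(bold) <- c(dims, n)

    gains <- runif(config$n_electrodes, 0.8, 1.2)
    eeg <- outer(gains, latents[, "ELEC"]) +
      matrix(rnorm(config$n_electrodes * n, sd = config$noise_sd),
             config$n_electrodes, n) +
      rep(tone, each = config$n_electrodes)
    rownames(eeg) <- sprintf("ch%02d", seq_len(config$n_electrodes))

    # haemoglobin channels carry the blood-volume latent strongly; the water
    # channel is dominated by the WATER latent with a light blood-volume
    # loading whose sign implements the Monro-Kellie anticorrelation
    sgn <- if (isTRUE(config$anticorr_water)) -1 else 1
    nirs <- rbind(
      Hb  = -0.25 * latents[, "BLOOD"],
      HbO = 0.5 * latents[, "BLOOD"],
      H2O = sgn * 0.15 * latents[, "BLOOD"] + latents[, "WATER"])
    nirs <- nirs + matrix(rnorm(3 * n, sd = config$noise_sd), 3, n) +
      rep(tone, each = 3)

    mask <- array(TRUE, dims)
    atlas <- build_block_atlas(dims)
    hyp <- rep(state, ceiling(n / (30 * fs)))
    new_recording(bold, mask, eeg, nirs, hyp, fs, atlas)
  })
}

scale_field <- function(a) (a - mean(a)) / max(sd(a), 1e-12)

# Partition the grid into 9 contiguous blocks along its longest axis;
# labels 1..9 stand for the 9 bilateral ROIs (caudate, cerebellum, frontal,
# insula, occipital, parietal, putamen, temporal, thalamus).
build_block_atlas <- function(dims) {
  ax <- which.max(dims)
  lab_along <- as.integer(ceiling(seq_len(dims[ax]) * 9 / dims[ax]))
  atlas <- array(0L, dims)
  idx <- slice.index(atlas, ax)
  atlas[] <- lab_along[idx]
  atlas
}

new_recording <- function(bold, mask, eeg, nirs, hypnogram, fs, atlas) {
  n <- dim(bold)[4]
  stopifnot(ncol(eeg) == n, ncol(nirs) == n,
            all(dim(mask) == dim(bold)[1:3]), all(dim(atlas) == dim(mask)),
            length(hypnogram) * 30 * fs >= n,
            all(atlas[atlas != 0L] %in% 1:9))
  structure(list(bold = bold, mask = mask, eeg = eeg, nirs = nirs,
                 hypnogram = hypnogram, fs = fs, atlas = atlas),
            class = "multimodal_recording")
}

#' @export
print.multimodal_recording <- function(x, ...) {
  d <- dim(x$bold)
  cat("multimodal_recording:", d[4], "samples at", x$fs, "Hz\n")
  cat("  bold grid ", paste(d[1:3], collapse = "x"),
      " (", sum(x$mask), " in mask), ", nrow(x$eeg), " EEG channels, ",
      nrow(x$nirs), " NIRS channels\n", sep = "")
  cat("  hypnogram:", paste(rle(x$hypnogram)$values,
                            rle(x$hypnogram)$lengths, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a full multistate recording
#'
#' Generates latents and renders a recording for each configured state, then
#' concatenates them in the configured state order into one synchronized
#' recording whose hypnogram tracks the state blocks.
#'
#' @param config a [synthetic_config()].
#' @param seed base RNG seed; per-state streams are derived from it.
#' @return a `multimodal_recording`.
#' @export
simulate_recording <- function(config, seed = config$seed) {
  parts <- lapply(seq_along(config$states), function(i) {
    s <- config$states[i]
    lat <- simulate_coupled_latents(config, s, seed = seed + 1000L * i)
    render_recording(lat, config, s, seed = seed + 1000L * i + 500L)
  })
  if (length(parts) == 1) return(parts[[1]])
  bold <- array(unlist(lapply(parts, function(p) p$bold)),
                c(config$grid_shape, sum(sapply(parts, function(p) dim(p$bold)[4]))))
  new_recording(bold, parts[[1]]$mask,
                do.call(cbind, lapply(parts, function(p) p$eeg)),
                do.call(cbind, lapply(parts, function(p) p$nirs)),
                unlist(lapply(parts, function(p) p$hypnogram)),
                config$fs, parts[[1]]$atlas)
}

#' Write a recording to disk as NIfTI + TSV fixtures
#'
#' BOLD and atlas volumes are written as NIfTI-1; EEG and NIRS as
#' tab-separated tables with one column per channel; the hypnogram as a TSV
#' with columns epoch_index, onset_s, label; acquisition metadata as JSON.
#' [read_recording()] round-trips the files within float precision.
#'
#' @param rec a `multimodal_recording`.
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of file paths written.
#' @export
write_fixture <- function(rec, dir) {
  stopifnot(inherits(rec, "multimodal_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("bold.nii", "atlas.nii", "mask.nii",
                            "eeg.tsv", "nirs.tsv", "hypnogram.tsv",
                            "meta.json"))
  names(paths) <- c("bold", "atlas", "mask", "eeg", "nirs", "hypnogram", "meta")
  RNifti::writeNifti(RNifti::asNifti(rec$bold, datatype = "double"),
                     paths["bold"])
  RNifti::writeNifti(RNifti::asNifti(rec$atlas, datatype = "int16"),
                     paths["atlas"])
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(rec$mask), dim(rec$mask)),
                                     datatype = "int16"), paths["mask"])
  write.table(as.data.frame(t(rec$eeg)), paths["eeg"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(as.data.frame(t(rec$nirs)), paths["nirs"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  hyp <- data.frame(epoch_index = seq_along(rec$hypnogram) - 1L,
                    onset_s = 30 * (seq_along(rec$hypnogram) - 1L),
                    label = rec$hypnogram)
  write.table(hyp, paths["hypnogram"], sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs), paths["meta"], auto_unbox = TRUE)
  invisible(paths)
}

#' Read a recording written by [write_fixture()]
#'
#' @param dir directory containing the fixture files.
#' @return a `multimodal_recording`.
#' @export
read_recording <- function(dir) {
  bold <- as.array(RNifti::readNifti(file.path(dir, "bold.nii")))
  atlas <- array(as.integer(as.array(RNifti::readNifti(file.path(dir, "atlas.nii")))),
                 dim(bold)[1:3])
  mask <- array(as.array(RNifti::readNifti(file.path(dir, "mask.nii"))) != 0,
                dim(bold)[1:3])
  eeg <- t(as.matrix(read.table(file.path(dir, "eeg.tsv"), header = TRUE,
                                sep = "\t")))
  nirs <- t(as.matrix(read.table(file.path(dir, "nirs.tsv"), header = TRUE,
                                 sep = "\t")))
  hyp <- read.table(file.path(dir, "hypnogram.tsv"), header = TRUE,
                    sep = "\t", colClasses = c("integer", "numeric",
                                               "character"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  new_recording(bold, mask, eeg, nirs, hyp$label, meta$fs, atlas)
}
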