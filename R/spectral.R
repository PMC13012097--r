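#' Logarithmic frequency grid for wavelet analysis
#'
#' 50 log-spaced frequencies from 0.01 to 5 Hz by default (5 Hz being the
#' Nyquist frequency of 10 Hz acquisitions), with a fixed number of wavelet
#' cycles at every frequency.
#'
#' @param n number of frequencies.
#' @param range (low, high) in Hz.
#' @param n_cycles Morlet cycles, constant across the grid.
#' @return an object of class `freq_grid`.
#' @export
freq_grid <- function(n = 50, range = c(0.01, 5), n_cycles = 8) {
  stopifnot(n >= 2, range[1] > 0, range[1] < range[2], n_cycles > 0)
  f <- exp(seq(log(range[1]), log(range[2]), length.out = n))
  f[1] <- range[1]; f[n] <- range[2]
  structure(list(frequencies = f, n_cycles = n_cycles), class = "freq_grid")
}

#' Complex Morlet wavelet kernel
#'
#' A complex exponential at frequency `f` tapered by a Gaussian whose
#' time-domain SD is `n_cycles / (2 pi f)`, truncated at +/- 4 SD and
#' normalized to unit energy (sum of |kernel|^2 = 1), so power estimates are
#' comparable across frequencies.
#'
#' @param f frequency in Hz, below Nyquist.
#' @param n_cycles number of cycles.
#' @param fs sampling rate in Hz.
#' @return complex vector of odd length, centred at time zero.
#' @export
morlet_kernel <- function(f, n_cycles = 8, fs = 10) {
  if (f > fs / 2) stop("wavelet frequency must not exceed Nyquist")
  stopifnot(f > 0, n_cycles > 0)
  sd_t <- n_cycles / (2 * pi * f)
  m <- ceiling(4 * sd_t * fs)
  tt <- (-m:m) / fs
  k <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
  k / sqrt(sum(Mod(k)^2))
}

#' Morlet time-frequency power
#'
#' Convolves the signal with the complex Morlet kernel of every grid
#' frequency and returns squared magnitudes at the original sample times.
#' The signal is mirrored once on each side before convolution so that edge
#' effects do not contaminate low-frequency estimates; the padding is
#' removed from the output. Frequencies with fewer than two full cycles per
#' epoch are computed but flagged in the `low_freq_flag` element, since
#' their temporal support exceeds the data.
#'
#' @param x numeric vector (one signal).
#' @param grid a [freq_grid()].
#' @param fs sampling rate in Hz.
#' @return object of class `tf_spectrum`: list with `power`
#'   (frequencies x time, signal units squared), `grid`, `fs`,
#'   `low_freq_flag` (logical per frequency).
#' @export
tf_power <- function(x, grid = freq_grid(), fs = 10) {
  stopifnot(inherits(grid, "freq_grid"))
  n <- length(x)
  if (n < 4) stop("signal too short for time-frequency analysis")
  xp <- c(rev(x), x, rev(x))
  np <- length(xp)
  freqs <- grid$frequencies
  kernels <- lapply(freqs, morlet_kernel, n_cycles = grid$n_cycles, fs = fs)
  maxk <- max(lengths(kernels))
  L <- nextn(np + maxk - 1L, 2)
  Xf <- fft(c(xp, rep(0, L - np)))
  pow <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    k <- kernels[[i]]
    m <- (length(k) - 1L) / 2L
    Kf <- fft(c(k, rep(0, L - length(k))))
    y <- fft(Xf * Kf, inverse = TRUE) / L
    # centre-aligned ("same") convolution, then drop the mirrored pads
    pow[i, ] <- Mod(y[(m + n + 1L):(m + 2L * n)])^2
  }
  # quality flag: fewer than two cycles per epoch, or kernel support longer
  # than the mirrored data (power estimates there are damped by truncation)
  structure(list(power = pow, grid = grid, fs = fs,
                 low_freq_flag = freqs * n / fs < 2 | lengths(kernels) > np),
            class = "tf_spectrum")
}

#' Random voxel subsample of a mask
#'
#' Simple random sampling without replacement of `round(fraction * n)`
#' in-mask voxel indices, used to cut the cost of voxelwise spectral
#' estimation while keeping every voxel equally likely.
#'
#' @param mask logical 3D array (or logical vector).
#' @param fraction fraction of in-mask voxels to keep, in (0, 1].
#' @param seed RNG seed for a deterministic subsample.
#' @return sorted integer vector of linear voxel indices.
#' @export
subsample_voxels <- function(mask, fraction = 0.05, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  idx <- which(mask)
  if (length(idx) == 0) stop("mask is empty")
  k <- round(fraction * length(idx))
  if (k >= length(idx)) return(idx)
  with_seed(seed, sort(sample(idx, k)))
}

# Rectangular integration bin widths for a (log-spaced) grid: bin edges at
# geometric midpoints of neighbouring frequencies, end bins closed by
# geometric reflection of the adjacent edge.
grid_bin_widths <- function(f) {
  n <- length(f)
  mid <- sqrt(f[-n] * f[-1])
  edges <- c(f[1]^2 / mid[1], mid, f[n]^2 / mid[n - 1])
  diff(edges)
}

#' Infraslow band power from a time-frequency spectrum
#'
#' Time-averages the spectrum, then integrates over the grid bins whose
#' frequencies fall inside the band using the rectangle rule with bin widths
#' taken from the geometric midpoints of the log grid.
#'
#' @param tf a [tf_power()] result, or a numeric vector of per-frequency
#'   power paired with `grid`.
#' @param band (low, high) integration band in Hz.
#' @param grid required when `tf` is a plain vector.
#' @return scalar band power (signal units squared times Hz), with the band
#'   attached as attribute "band".
#' @export
band_power <- function(tf, band = c(0.01, 0.08), grid = NULL) {
  if (inherits(tf, "tf_spectrum")) {
    p <- rowMeans(tf$power)
    grid <- tf$grid
  } else {
    p <- as.numeric(tf)
    if (is.null(grid)) stop("grid required for plain power vectors")
  }
  f <- grid$frequencies
  if (band[1] < min(f) - 1e-12 || band[2] > max(f) + 1e-12)
    stop("band outside the frequency grid")
  w <- grid_bin_widths(f)
  sel <- f >= band[1] & f <= band[2]
  structure(sum(p[sel] * w[sel]), band = band)
}

#' Per-frequency power spectrum of a multichannel epoch
#'
#' Convenience wrapper: time-averaged Morlet power for each column of a
#' time x channels matrix, averaged over channels, as used for per-subject
#' modality spectra before group summaries.
#'
#' @param x time x channels matrix (or vector).
#' @param grid a [freq_grid()].
#' @param fs sampling rate in Hz.
#' @return numeric vector of length `length(grid$frequencies)`.
#' @export
modality_spectrum <- function(x, grid = freq_grid(), fs = 10) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  ps <- apply(x, 2, function(col) rowMeans(tf_power(col, grid, fs)$power))
  rowMeans(ps)
}

#' Group median and IQR spectra per state
#'
#' Given one per-subject spectrum per row (already averaged over voxels or
#' electrodes), returns the per-frequency median and the 25-75% envelope for
#' each state.
#'
#' @param spectra subjects x frequencies matrix.
#' @param states state label per row.
#' @return named list per state: list(median, q25, q75), each a vector over
#'   frequencies.
#' @export
group_spectrum <- function(spectra, states) {
  stopifnot(is.matrix(spectra), nrow(spectra) == length(states))
  out <- lapply(unique(states), function(s) {
    m <- spectra[states == s, , drop = FALSE]
    if (nrow(m) == 0) stop("state with no data: ", s)
    list(median = apply(m, 2, median),
         q25 = apply(m, 2, quantile, 0.25, names = FALSE),
         q75 = apply(m, 2, quantile, 0.75, names = FALSE))
  })
  names(out) <- unique(states)
  out
}
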