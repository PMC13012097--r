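#' FIR band-pass filter specification
#'
#' Hamming-windowed linear-phase FIR band-pass. The default — order 3000
#' with cutoffs 0.01 and 0.08 Hz at 10 Hz sampling — isolates the infraslow
#' band while excluding slow respiratory and cardiac frequencies.
#'
#' @param band (low, high) cutoff frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (number of taps minus one); must be even so
#'   the filter is symmetric (type-I linear phase).
#' @return an object of class `fir_spec`.
#' @export
fir_spec <- function(band = c(0.01, 0.08), fs = 10, order = 3000) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2], fs > 0,
            order >= 2)
  if (band[2] >= fs / 2) stop("band must lie inside (0, fs/2)")
  if (order %% 2 != 0) stop("order must be even for a symmetric FIR")
  structure(list(kind = "FIR", window = "hamming", order = as.integer(order),
                 band = band, fs = fs), class = "fir_spec")
}

#' Design the FIR band-pass taps
#'
#' Windowed-sinc design with a Hamming window. The returned taps are exactly
#' symmetric, so single-pass application is linear phase and the
#' forward-backward application used by [filter_band()] is zero phase.
#'
#' @param spec a [fir_spec()].
#' @return numeric vector of `order + 1` coefficients with the spec attached
#'   as attribute "spec".
#' @export
design_fir <- function(spec = fir_spec()) {
  stopifnot(inherits(spec, "fir_spec"))
  h <- as.numeric(signal::fir1(spec$order, spec$band / (spec$fs / 2),
                               type = "pass",
                               window = signal::hamming(spec$order + 1)))
  h <- (h + rev(h)) / 2  # enforce exact symmetry against float round-off
  attr(h, "spec") <- spec
  h
}

# Reflected (mirror) extension indices of length m for a series of length n;
# the extension bounces between samples 2..n repeatedly, so it works even
# when m exceeds n (short epochs against long filters).
mirror_indices <- function(n, m) {
  if (n < 2) stop("signal too short to mirror")
  period <- 2L * (n - 1L)
  # positions -1, -2, ... map onto the triangle-wave index pattern
  k <- seq_len(m)
  r <- k %% period
  idx <- ifelse(r <= n - 1L, r + 1L, period - r + 1L)
  rev(idx)
}

# Linear convolution via FFT, returning the full sequence.
fft_conv <- function(x, h) {
  nx <- length(x); nh <- length(h)
  L <- nextn(nx + nh - 1L, 2)
  y <- fft(fft(c(x, rep(0, L - nx))) * fft(c(h, rep(0, L - nh))),
           inverse = TRUE) / L
  Re(y[seq_len(nx + nh - 1L)])
}

#' Zero-phase band-pass filtering with mirror padding
#'
#' Extends the signal by `order` samples of mirrored data on each side,
#' applies the symmetric FIR taps forward and backward (zero net phase;
#' effective magnitude response squared), and removes the padding, so the
#' output has the same length as the input and no edge transients.
#'
#' @param x numeric vector, or matrix with one column per channel.
#' @param spec a [fir_spec()], or pre-designed taps from [design_fir()].
#' @return filtered series, same shape as `x`.
#' @export
filter_band <- function(x, spec = fir_spec()) {
  h <- if (is.numeric(spec) && !inherits(spec, "fir_spec")) spec
       else design_fir(spec)
  ord <- length(h) - 1L
  if (is.matrix(x)) return(apply(x, 2, filter_band, spec = h))
  n <- length(x)
  if (n < 4) stop("signal shorter than minimum padding support")
  li <- mirror_indices(n, ord)
  xp <- c(x[li], x, x[n + 1L - rev(li)])
  y <- fft_conv(fft_conv(xp, h), h)
  # two symmetric passes delay by 2*(ord/2) = ord samples in the full conv
  y[(ord + ord + 1L):(ord + ord + n)]
}

#' Decimate a series to a lower sampling rate
#'
#' Anti-alias low-pass filtering (zero-phase, cutoff at 90% of the output
#' Nyquist) followed by keeping every (fs_in/fs_out)-th sample. The output
#' has `floor(n * fs_out / fs_in)` samples.
#'
#' @param x numeric vector or matrix (columns = channels).
#' @param fs_in input sampling rate in Hz; must be an integer multiple of
#'   `fs_out`.
#' @param fs_out target sampling rate in Hz.
#' @return decimated series.
#' @export
decimate_to <- function(x, fs_in, fs_out = 10) {
  r <- fs_in / fs_out
  if (abs(r - round(r)) > 1e-9) stop("fs_in must be an integer multiple of fs_out")
  r <- as.integer(round(r))
  if (r == 1L) return(x)
  if (is.matrix(x)) return(apply(x, 2, decimate_to, fs_in = fs_in,
                                 fs_out = fs_out))
  ord <- 20L * r
  h <- signal::fir1(ord, 0.9 / r, type = "low",
                    window = signal::hamming(ord + 1))
  h <- (h + rev(h)) / 2
  n <- length(x)
  li <- mirror_indices(n, ord)
  xp <- c(x[li], x, x[n + 1L - rev(li)])
  y <- fft_conv(xp, h)[(ord + ord / 2 + 1L):(ord + ord / 2 + n)]
  y[seq(1L, by = r, length.out = n %/% r)]
}

#' Extract one epoch per state from the longest continuous run
#'
#' Scans a hypnogram of 30-s stage labels for continuous runs; for each
#' state present, takes epochs of `epoch_len_s` seconds from the start of
#' the longest run (earliest run wins ties). States whose longest run is
#' shorter than one epoch yield nothing. With `max_per_state > 1`, as many
#' non-overlapping epochs as fit in the longest run are returned, up to the
#' limit.
#'
#' @param hypnogram character vector of 30-s labels aligned to the signal
#'   start.
#' @param signals matrix with time in rows (channels/voxels in columns), or
#'   a numeric vector.
#' @param fs sampling rate of `signals` in Hz.
#' @param epoch_len_s epoch length in seconds.
#' @param max_per_state maximum epochs extracted per state.
#' @return list of epochs, each a list with `state`, `onset_s`, and
#'   `signals` (same column structure as the input, `epoch_len_s * fs` rows).
#' @export
extract_state_epochs <- function(hypnogram, signals, fs, epoch_len_s = 120,
                                 max_per_state = 1) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  n <- nrow(signals)
  if (length(hypnogram) * 30 * fs < n)
    stop("hypnogram shorter than signal: misaligned inputs")
  runs <- rle(hypnogram)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  len_samp <- round(epoch_len_s * fs)
  out <- list()
  for (s in unique(hypnogram)) {
    sel <- which(runs$values == s)
    best <- sel[which.max(runs$lengths[sel])]  # which.max takes the earliest tie
    run_samp <- runs$lengths[best] * 30 * fs
    run_samp <- min(run_samp, n - (starts[best] - 1L) * 30 * fs)
    n_fit <- min(max_per_state, run_samp %/% len_samp)
    if (n_fit < 1) next
    for (k in seq_len(n_fit)) {
      i0 <- (starts[best] - 1L) * 30 * fs + (k - 1L) * len_samp
      out[[length(out) + 1L]] <- list(
        state = s, onset_s = i0 / fs,
        signals = signals[(i0 + 1L):(i0 + len_samp), , drop = FALSE])
    }
  }
  out
}

#' Optical calibration for the modified Beer-Lambert conversion
#'
#' @param extinction 3x3 matrix of extinction coefficients, wavelengths
#'   (690/830/980 nm) in rows and chromophores (Hb, HbO, H2O) in columns.
#' @param pathlength source-detector separation in cm.
#' @param dpf differential pathlength factor per wavelength.
#' @return an object of class `optical_calibration`.
#' @export
optical_calibration <- function(extinction = diag(3), pathlength = 3,
                                dpf = c(1, 1, 1)) {
  stopifnot(is.matrix(extinction), all(dim(extinction) == 3),
            pathlength > 0, length(dpf) == 3, all(dpf > 0))
  if (rcond(extinction) < 1e-12) stop("extinction matrix is singular")
  structure(list(extinction = extinction, pathlength = pathlength, dpf = dpf),
            class = "optical_calibration")
}

#' Convert absorbance changes to chromophore concentration changes
#'
#' Modified Beer-Lambert law: delta A = E L delta C with
#' L = diag(pathlength * dpf), inverted per time point, so
#' delta C = (E L)^-1 delta A. Exactly linear in the absorbance input.
#'
#' @param absorbance_change 3 x t matrix of absorbance changes (wavelengths
#'   in rows).
#' @param cal an [optical_calibration()].
#' @return 3 x t matrix of concentration changes, rows Hb, HbO, H2O.
#' @export
mbll_concentrations <- function(absorbance_change, cal = optical_calibration()) {
  stopifnot(inherits(cal, "optical_calibration"),
            is.matrix(absorbance_change), nrow(absorbance_change) == 3)
  # delta A_lambda = L_lambda * sum_c E[lambda, c] delta C_c, so the forward
  # matrix is diag(L) %*% E (per-wavelength pathlength scaling)
  EL <- sweep(cal$extinction, 1, cal$pathlength * cal$dpf, `*`)
  dc <- solve(EL, absorbance_change)
  rownames(dc) <- c("Hb", "HbO", "H2O")
  dc
}
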