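#' Instantaneous phase via the Hilbert analytic signal
#'
#' Computes the analytic signal z of a band-limited, zero-mean series by
#' zeroing negative FFT frequencies and returns the instantaneous phase
#' theta = arg(z), wrapped to [-pi, pi).
#'
#' @param x numeric vector (band-limited signal), or matrix with one column
#'   per channel.
#' @return numeric vector (or matrix) of phases in [-pi, pi).
#' @export
analytic_phase <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (all(abs(x) < .Machine$double.eps)) stop("phase of all-zero signal is undefined")
    Z <- mvfft(x) * analytic_multiplier(n)
    th <- Arg(mvfft(Z, inverse = TRUE) / n)
  } else {
    n <- length(x)
    if (n < 2) stop("need at least two samples")
    if (all(abs(x) < .Machine$double.eps)) stop("phase of all-zero signal is undefined")
    z <- fft(fft(x) * analytic_multiplier(n), inverse = TRUE) / n
    th <- Arg(z)
  }
  # Arg returns (-pi, pi]; fold the single closed endpoint
  th[th >= pi] <- -pi
  th
}

analytic_multiplier <- function(n) {
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

#' Discretize phases into uniform bins
#'
#' Bin k (0-based) covers [-pi + k * 2*pi/n_bins, -pi + (k+1) * 2*pi/n_bins).
#'
#' @param theta phases in [-pi, pi) (vector or matrix).
#' @param n_bins number of bins, at least 2.
#' @return integer symbols in 0 .. n_bins - 1, same shape as `theta`.
#' @export
discretize_phase <- function(theta, n_bins = 8) {
  stopifnot(n_bins >= 2)
  k <- floor((theta + pi) / (2 * pi / n_bins))
  k <- pmin(pmax(k, 0), n_bins - 1)  # guard the theta == pi float edge
  storage.mode(k) <- "integer"
  k
}

#' Plug-in entropy of one or more symbol series
#'
#' Empirical-frequency (plug-in) entropy in bits with the 0 log 0 = 0
#' convention. A matrix input is treated as a joint distribution over its
#' columns.
#'
#' @param symbols integer vector, or matrix with one series per column
#'   (joint entropy over columns). Symbols must be non-negative integers.
#' @return entropy in bits.
#' @export
plugin_entropy <- function(symbols) {
  if (is.matrix(symbols)) {
    if (nrow(symbols) == 0) stop("empty input")
    code <- symbols[, 1]
    if (ncol(symbols) > 1) {
      for (j in 2:ncol(symbols)) {
        base <- max(symbols[, j]) + 1
        code <- code * base + symbols[, j]
      }
    }
  } else {
    if (length(symbols) == 0) stop("empty input")
    code <- symbols
  }
  cnt <- tabulate(match(code, unique(code)))
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

#' One-cycle analysis lag
#'
#' The constant source-target delay used by the phase transfer entropy:
#' one oscillation cycle at the band's centre frequency, in samples.
#'
#' @param f_center centre frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return integer lag in samples, `round(fs / f_center)`.
#' @export
default_lag <- function(f_center = 0.03, fs = 10) {
  stopifnot(f_center > 0, f_center < fs / 2)
  as.integer(round(fs / f_center))
}

#' Phase transfer entropy between two symbol series
#'
#' Discrete plug-in phase transfer entropy in both directions at lag delta:
#' TE(x -> y) = H(y_t, y_t') + H(y_t', x_t') - H(y_t') - H(y_t, y_t', x_t')
#' with t' = t - delta, probabilities estimated by empirical frequencies and
#' entropies in bits. The net direction statistic is
#' delta_te = TE(x -> y) - TE(y -> x); TE = 0 bits indicates no connection.
#'
#' @param x,y integer symbol series in 0 .. n_bins - 1, equal length.
#' @param lag delay delta in samples, 0 < lag < length(x).
#' @param n_bins size of the symbol alphabet.
#' @return object of class `te_pair`: list(te_xy, te_yx, delta_te,
#'   lag_samples, n_bins, n_samples_used).
#' @export
phase_te <- function(x, y, lag, n_bins = 8) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (lag <= 0) stop("lag must be positive")
  if (lag >= n) stop("lag must be smaller than the series length")
  if (any(x < 0 | x >= n_bins) || any(y < 0 | y >= n_bins))
    stop("symbols must lie in [0, n_bins)")
  te <- te_pair_cpp(as.integer(x), as.integer(y), as.integer(lag),
                    as.integer(n_bins))
  if (any(te < -1e-9)) stop("plug-in TE below rounding tolerance: internal error")
  te <- pmax(te, 0)
  structure(list(te_xy = te[1], te_yx = te[2], delta_te = te[1] - te[2],
                 lag_samples = as.integer(lag), n_bins = as.integer(n_bins),
                 n_samples_used = n - as.integer(lag)),
            class = "te_pair")
}

#' @export
print.te_pair <- function(x, ...) {
  cat(sprintf("phase TE (lag %d samples, %d bins, n = %d)\n",
              x$lag_samples, x$n_bins, x$n_samples_used))
  cat(sprintf("  TE(x->y) = %.4f bits, TE(y->x) = %.4f bits, delta TE = %+.4f bits\n",
              x$te_xy, x$te_yx, x$delta_te))
  invisible(x)
}

#' Phase transfer entropy from band-limited signals
#'
#' Full per-pair chain: Hilbert phase extraction, uniform phase binning,
#' then [phase_te()] at the given lag.
#'
#' @param x,y band-limited numeric series of equal length.
#' @param lag delay in samples; default one cycle at 0.03 Hz.
#' @param n_bins number of phase bins.
#' @return a `te_pair`.
#' @export
phase_te_signals <- function(x, y, lag = default_lag(0.03, 10), n_bins = 8) {
  sx <- discretize_phase(analytic_phase(x), n_bins)
  sy <- discretize_phase(analytic_phase(y), n_bins)
  phase_te(sx, sy, lag, n_bins)
}

#' Voxelwise delta TE maps for the three modality pairs
#'
#' For one subject-state epoch, computes per-voxel net transfer entropy
#' between the BOLD series and (a) every EEG electrode, averaged over the
#' electrode space, and (b) the NIRS water channel; plus a per-electrode
#' EEG-H2O topography. Sign conventions: positive values mean the BOLD
#' signal predicts its partner for the BOLD pairs, and the EEG signal
#' predicts H2O for the electrode topography.
#'
#' @param bold time x voxels matrix of band-limited in-mask BOLD series.
#' @param eeg time x electrodes matrix of band-limited EEG series.
#' @param h2o band-limited NIRS water concentration series.
#' @param lag delay in samples.
#' @param n_bins phase bins.
#' @return list with `bold_eeg` (per-voxel delta TE and directional means),
#'   `bold_h2o` (per-voxel), `eeg_h2o` (per-electrode), each a list of
#'   numeric vectors `delta_te`, `te_fwd`, `te_rev` (fwd = first-named
#'   modality as source).
#' @export
pairwise_te_map <- function(bold, eeg, h2o, lag = default_lag(0.03, 10),
                            n_bins = 8) {
  stopifnot(is.matrix(bold), is.matrix(eeg),
            nrow(bold) == nrow(eeg), nrow(bold) == length(h2o))
  sb <- discretize_phase(analytic_phase(bold), n_bins)
  se <- discretize_phase(analytic_phase(eeg), n_bins)
  sw <- discretize_phase(analytic_phase(as.numeric(h2o)), n_bins)
  nv <- ncol(bold); ne <- ncol(eeg)

  be_fwd <- be_rev <- numeric(nv)
  bw_fwd <- bw_rev <- numeric(nv)
  for (v in seq_len(nv)) {
    f <- r <- 0
    for (e in seq_len(ne)) {
      te <- te_pair_cpp(sb[, v], se[, e], as.integer(lag), as.integer(n_bins))
      f <- f + te[1]; r <- r + te[2]
    }
    be_fwd[v] <- f / ne; be_rev[v] <- r / ne
    te <- te_pair_cpp(sb[, v], sw, as.integer(lag), as.integer(n_bins))
    bw_fwd[v] <- te[1]; bw_rev[v] <- te[2]
  }
  ew_fwd <- ew_rev <- numeric(ne)
  for (e in seq_len(ne)) {
    te <- te_pair_cpp(se[, e], sw, as.integer(lag), as.integer(n_bins))
    ew_fwd[e] <- te[1]; ew_rev[e] <- te[2]
  }
  list(bold_eeg = list(delta_te = be_fwd - be_rev, te_fwd = be_fwd,
                       te_rev = be_rev),
       bold_h2o = list(delta_te = bw_fwd - bw_rev, te_fwd = bw_fwd,
                       te_rev = bw_rev),
       eeg_h2o = list(delta_te = ew_fwd - ew_rev, te_fwd = ew_fwd,
                      te_rev = ew_rev))
}

#' Whole-brain and ROI aggregation of a voxelwise TE map
#'
#' Means over all in-mask voxels and over each of the 9 atlas labels, for
#' the net statistic and both directional components.
#'
#' @param values per-voxel values (vector aligned with `which(mask)`),
#'   or a named list with elements `delta_te`, `te_fwd`, `te_rev` as
#'   produced by [pairwise_te_map()].
#' @param atlas integer 3D label volume (0 = background, labels 1..9).
#' @param mask logical 3D array; in-mask voxels correspond to `values`.
#' @return data.frame with rows whole_brain and roi_1 .. roi_9 and columns
#'   `roi`, `n_voxels`, `delta_te` (and `te_fwd`, `te_rev` when supplied).
#' @export
aggregate_te <- function(values, atlas, mask) {
  if (!is.list(values)) values <- list(delta_te = values)
  vidx <- which(mask)
  stopifnot(length(values$delta_te) == length(vidx),
            all(dim(atlas) == dim(mask)))
  labels <- atlas[vidx]
  groups <- c(list(whole_brain = rep(TRUE, length(vidx))),
              setNames(lapply(1:9, function(l) labels == l),
                       paste0("roi_", 1:9)))
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    if (!any(sel)) stop("empty ROI: ", g)
    out <- data.frame(roi = g, n_voxels = sum(sel))
    for (comp in names(values)) out[[comp]] <- mean(values[[comp]][sel])
    out
  })
  do.call(rbind, rows)
}

#' Voxelwise lag map relative to a seed region
#'
#' For every voxel, the lag (in seconds) of the maximum normalized
#' cross-correlation with the seed-mean signal, searched within one
#' oscillation cycle at `f_center`; optionally, the Spearman correlation of
#' the lag map with a delta TE map together with a permutation p-value —
#' the control for whether TE directionality merely reflects hemodynamic
#' delay structure.
#'
#' @param bold time x voxels matrix (band-limited, in-mask).
#' @param seed_cols columns of `bold` forming the seed region.
#' @param fs sampling rate in Hz.
#' @param f_center cycle-defining frequency in Hz.
#' @param te_map optional per-voxel delta TE values to correlate with.
#' @param n_perm permutations for the correlation p-value.
#' @param perm_seed RNG seed for the permutation draw.
#' @return list(lag_s, max_corr, te_correlation = list(rho, p) or NULL).
#' @export
xcorr_lag_map <- function(bold, seed_cols, fs = 10, f_center = 0.03,
                          te_map = NULL, n_perm = 1000, perm_seed = 1L) {
  stopifnot(is.matrix(bold), all(seed_cols >= 1), all(seed_cols <= ncol(bold)))
  s <- rowMeans(bold[, seed_cols, drop = FALSE])
  if (sd(s) < .Machine$double.eps) stop("flat seed signal")
  n <- nrow(bold)
  L <- min(default_lag(f_center, fs), n - 2L)
  s <- (s - mean(s)) / sd(s)
  lags <- -L:L
  nv <- ncol(bold)
  lag_s <- max_corr <- numeric(nv)
  for (v in seq_len(nv)) {
    x <- bold[, v]
    if (sd(x) < .Machine$double.eps) { lag_s[v] <- NA; max_corr[v] <- NA; next }
    x <- (x - mean(x)) / sd(x)
    cc <- vapply(lags, function(l) {
      if (l >= 0) mean(s[1:(n - l)] * x[(1 + l):n])
      else mean(s[(1 - l):n] * x[1:(n + l)])
    }, numeric(1))
    i <- which.max(cc)
    lag_s[v] <- lags[i] / fs
    max_corr[v] <- cc[i]
  }
  te_correlation <- NULL
  if (!is.null(te_map)) {
    stopifnot(length(te_map) == nv)
    ok <- is.finite(lag_s) & is.finite(te_map)
    if (sum(ok) < 3 || sd(lag_s[ok]) == 0 || sd(te_map[ok]) == 0) {
      # a constant lag map (e.g. a single global driver) carries no rank
      # information to correlate
      te_correlation <- list(rho = NA_real_, p = NA_real_)
    } else {
      rho <- cor(lag_s[ok], te_map[ok], method = "spearman")
      null_rho <- with_seed(perm_seed,
        replicate(n_perm, suppressWarnings(
          cor(sample(lag_s[ok]), te_map[ok], method = "spearman"))))
      p <- (1 + sum(abs(null_rho) >= abs(rho))) / (1 + n_perm)
      te_correlation <- list(rho = rho, p = p)
    }
  }
  list(lag_s = lag_s, max_corr = max_corr, te_correlation = te_correlation)
}
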