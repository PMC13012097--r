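# Independent oracles used to validate the implementation.

# Brute-force phase transfer entropy from explicit count tables built with
# string keys; intentionally naive and independent of the package's
# implementation path.
te_oracle <- function(x, y, lag) {
  n <- length(x)
  yt <- y[(lag + 1):n]; yp <- y[1:(n - lag)]; xp <- x[1:(n - lag)]
  xt <- x[(lag + 1):n]
  H <- function(...) {
    key <- do.call(paste, c(list(...), sep = "|"))
    p <- table(key) / length(key)
    -sum(p * log2(p))
  }
  list(te_xy = H(yt, yp) + H(yp, xp) - H(yp) - H(yt, yp, xp),
       te_yx = H(xt, xp) + H(xp, yp) - H(xp) - H(xt, xp, yp))
}

# Magnitude of the frequency response of FIR taps at frequency f.
freq_response <- function(h, f, fs) {
  abs(sum(h * exp(-2i * pi * f * (seq_along(h) - 1) / fs)))
}

# Hand step-up Benjamini-Hochberg with monotone enforcement.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

latent_names <- c("ELEC", "BLOOD", "WATER")

# 3x3 coupling matrix with a single directed edge.
kappa_one <- function(from, to, strength) {
  k <- matrix(0, 3, 3, dimnames = list(latent_names, latent_names))
  k[from, to] <- strength
  k
}

# Config with the same one-way coupling in every state.
one_way_config <- function(from, to, strength, ...) {
  k <- kappa_one(from, to, strength)
  synthetic_config(kappa = list(AWAKE = k, N1 = k, N2 = k), ...)
}

# Small-grid config for fast pipeline runs; explicit arguments override the
# small-grid defaults.
small_config <- function(...) {
  args <- modifyList(list(grid_shape = c(4, 4, 9), n_electrodes = 4),
                     list(...))
  do.call(synthetic_config, args)
}

# Coupling switched off in every state.
zero_kappa <- function() {
  k <- matrix(0, 3, 3, dimnames = list(latent_names, latent_names))
  list(AWAKE = k, N1 = k, N2 = k)
}
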