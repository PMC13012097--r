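test_that("FIR design meets its passband/stopband contract", {
  h <- design_fir(fir_spec())
  expect_length(h, 3001)
  hh <- as.numeric(h)
  expect_identical(hh, rev(hh))  # linear phase
  # frequency-response oracle: near-unit gain at the band centre, strong
  # rejection at DC and in the cardiorespiratory range
  expect_gt(freq_response(h, 0.03, 10), 0.9)
  expect_lt(freq_response(h, 0.03, 10), 1.1)
  expect_lt(freq_response(h, 0, 10), 0.01)     # <= -40 dB at DC
  expect_lt(freq_response(h, 1.0, 10), 0.01)
  expect_lt(freq_response(h, 0.5, 10), 0.01)
  expect_error(fir_spec(band = c(0.01, 6), fs = 10), "inside")
  expect_error(fir_spec(order = 2999), "even")
})

test_that("band filtering is zero-phase, DC-rejecting, and linear", {
  fs <- 10
  tt <- (0:1199) / fs
  tone <- cos(2 * pi * 0.03 * tt)
  y <- filter_band(tone)
  # zero phase: cross-correlation of filtered vs input peaks at lag 0
  cc <- stats::ccf(y, tone, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # stopband: a 1 Hz tone is suppressed below 1% RMS (forward-backward
  # application squares the single-pass attenuation)
  fast <- cos(2 * pi * 1.0 * tt)
  expect_lt(sqrt(mean(filter_band(fast)^2)) / sqrt(mean(fast^2)), 0.01)
  # DC rejection
  expect_lt(max(abs(filter_band(rep(2.5, 1200)))), 1e-3)
  # linearity
  set.seed(1)
  a <- rnorm(1200); b <- rnorm(1200)
  expect_equal(filter_band(2 * a - 3 * b),
               2 * filter_band(a) - 3 * filter_band(b), tolerance = 1e-9)
  expect_error(filter_band(c(1, 2)), "shorter")
})

test_that("decimation preserves infraslow content at the right length", {
  # identity when rates match
  x <- rnorm(100)
  expect_identical(decimate_to(x, 10, 10), x)
  # ratio 25: output length floor(n / 25)
  expect_length(decimate_to(rnorm(1013), 250, 10), floor(1013 / 25))
  expect_error(decimate_to(x, 25, 10), "integer multiple")
  # 1 kHz -> 10 Hz keeps a 0.03 Hz tone's spectral peak (FFT oracle)
  fs_in <- 1000
  tone <- cos(2 * pi * 0.03 * (0:(100 * fs_in - 1)) / fs_in)
  y <- decimate_to(tone, fs_in, 10)
  sp <- Mod(fft(y))^2
  fbins <- (seq_along(y) - 1) * 10 / length(y)
  half <- fbins <= 5
  expect_equal(fbins[half][which.max(sp[half][-1]) + 1], 0.03,
               tolerance = 0.005)
})

test_that("state epochs come from the longest run with earliest-run ties", {
  fs <- 10
  hyp <- c(rep("AWAKE", 4), rep("N2", 5), rep("AWAKE", 4))
  sig <- matrix(seq_len(13 * 30 * fs), ncol = 1)
  eps <- extract_state_epochs(hyp, sig, fs, epoch_len_s = 120)
  states <- vapply(eps, `[[`, "", "state")
  onsets <- vapply(eps, `[[`, numeric(1), "onset_s")
  expect_setequal(states, c("AWAKE", "N2"))
  # tie between the two 4-epoch AWAKE runs: earliest wins, onset 0
  expect_equal(onsets[states == "AWAKE"], 0)
  expect_equal(onsets[states == "N2"], 120)
  expect_equal(nrow(eps[[1]]$signals), 1200)
  # epoch content is the run's first 120 s, verified against the index ramp
  expect_equal(eps[[which(states == "N2")]]$signals[1, 1], 120 * fs + 1)

  # too little data for any epoch
  expect_length(extract_state_epochs(rep("N1", 3),
                                     matrix(rnorm(900), ncol = 1), fs), 0)
  # misalignment is refused
  expect_error(extract_state_epochs(c("AWAKE"), matrix(rnorm(600), ncol = 1),
                                    fs), "misaligned")
  # non-overlapping multiples fit inside the longest run
  eps2 <- extract_state_epochs(rep("N2", 10), matrix(rnorm(3000), ncol = 1),
                               fs, epoch_len_s = 60, max_per_state = 3)
  expect_length(eps2, 3)
  expect_equal(vapply(eps2, `[[`, numeric(1), "onset_s"), c(0, 60, 120))
})

test_that("modified Beer-Lambert conversion is linear and invertible", {
  expect_equal(mbll_concentrations(matrix(0, 3, 5)),
               matrix(0, 3, 5, dimnames = list(c("Hb", "HbO", "H2O"), NULL)))
  da <- matrix(c(1, 0, 0), 3, 1)
  unit_cal <- optical_calibration(diag(3), pathlength = 1, dpf = c(1, 1, 1))
  expect_equal(unname(mbll_concentrations(da, unit_cal)), da)
  # forward-inverse round trip with a random invertible calibration
  set.seed(7)
  E <- matrix(rnorm(9, sd = 2), 3, 3) + diag(3) * 3
  cal <- optical_calibration(E, pathlength = 3, dpf = c(5.9, 5.2, 4.7))
  dc_true <- matrix(rnorm(30), 3, 10)
  da_fwd <- sweep(E, 1, 3 * c(5.9, 5.2, 4.7), `*`) %*% dc_true
  expect_equal(unname(mbll_concentrations(da_fwd, cal)), dc_true,
               tolerance = 1e-10)
  # linearity
  cal0 <- optical_calibration()
  x1 <- matrix(rnorm(15), 3, 5); x2 <- matrix(rnorm(15), 3, 5)
  expect_equal(mbll_concentrations(2 * x1 + x2, cal0),
               2 * mbll_concentrations(x1, cal0) +
                 mbll_concentrations(x2, cal0), tolerance = 1e-12)
  expect_error(optical_calibration(matrix(1, 3, 3)), "singular")
})
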