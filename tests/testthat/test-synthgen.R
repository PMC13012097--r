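test_that("identical configs produce bit-identical recordings", {
  cfg <- small_config(states = c("AWAKE", "N2"))
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$bold, r2$bold)
  expect_identical(r1$eeg, r2$eeg)
  expect_identical(r1$nirs, r2$nirs)
  expect_identical(r1$hypnogram, r2$hypnogram)
  r3 <- simulate_recording(small_config(states = c("AWAKE", "N2"), seed = 2L))
  expect_false(identical(r1$bold, r3$bold))
})

test_that("config validation rejects destabilizing or malformed inputs", {
  expect_error(synthetic_config(fs = 0.1), "twice the band")
  expect_error(synthetic_config(epoch_len_s = 10), "one oscillation cycle")
  k <- kappa_one("ELEC", "BLOOD", 3.5)
  expect_error(synthetic_config(kappa = list(AWAKE = k, N1 = k, N2 = k)),
               "destabilizes")
  kneg <- kappa_one("ELEC", "BLOOD", -0.1)
  expect_error(synthetic_config(kappa = list(AWAKE = kneg, N1 = kneg,
                                             N2 = kneg)),
               "finite and >= 0")
  expect_error(synthetic_config(power_scale = list(AWAKE = c(0, 1, 1),
                                                   N1 = c(1, 1, 1),
                                                   N2 = c(1, 1, 1))),
               "positive")
})

test_that("noise-free latents are pure tones and rendering copies them", {
  cfg <- small_config(states = "AWAKE", noise_sd = 0, latent_noise_sd = 0,
                      phase_noise_sd = 0, freq_jitter = 0,
                      epoch_len_s = 600,
                      nuisance = c(cardiac = 0, respiratory = 0))
  lat <- simulate_coupled_latents(cfg, "AWAKE")
  # pure tone at f_center: spectral peak at the nearest grid frequency
  g <- freq_grid()
  p <- rowMeans(tf_power(lat[, "ELEC"], g, cfg$fs)$power)
  near <- which.min(abs(log(g$frequencies) - log(cfg$f_center)))
  expect_equal(which.max(p), near)
  # noiseless rendering: every voxel is a scaled copy of the BLOOD latent
  rec <- render_recording(lat, cfg, "AWAKE")
  expect_equal(cor(rec$bold[2, 3, 4, ], lat[, "BLOOD"]), 1, tolerance = 1e-9)
  expect_equal(cor(rec$eeg[1, ], lat[, "ELEC"]), 1, tolerance = 1e-9)
})

test_that("water channel is anticorrelated with HbO when configured", {
  # pure rendering contract, coupling switched off
  cfg <- small_config(states = "AWAKE", noise_sd = 0, kappa = zero_kappa(),
                      nuisance = c(cardiac = 0, respiratory = 0))
  lat <- simulate_coupled_latents(cfg, "AWAKE")
  rec <- render_recording(lat, cfg, "AWAKE")
  expect_lt(cor(rec$nirs["H2O", ], rec$nirs["HbO", ]), 0)
  # rendering the same latents without the flag flips the blood loading:
  # the water channel is strictly less anticorrelated with HbO
  cfg2 <- small_config(states = "AWAKE", noise_sd = 0, kappa = zero_kappa(),
                       anticorr_water = FALSE,
                       nuisance = c(cardiac = 0, respiratory = 0))
  rec2 <- render_recording(lat, cfg2, "AWAKE")
  expect_gt(cor(rec2$nirs["H2O", ], rec2$nirs["HbO", ]),
            cor(rec$nirs["H2O", ], rec$nirs["HbO", ]))
  # under the default coupled dynamics the antiphase water-blood coupling
  # preserves the anticorrelation in the rendered channels
  cfg3 <- small_config(states = "AWAKE", noise_sd = 0,
                       nuisance = c(cardiac = 0, respiratory = 0))
  rec3 <- render_recording(simulate_coupled_latents(cfg3, "AWAKE"), cfg3,
                           "AWAKE")
  expect_lt(cor(rec3$nirs["H2O", ], rec3$nirs["HbO", ]), 0)
})

test_that("recording invariants hold and small grids are rejected", {
  cfg <- small_config(states = "AWAKE")
  rec <- simulate_recording(cfg)
  n <- dim(rec$bold)[4]
  expect_equal(ncol(rec$eeg), n)
  expect_equal(ncol(rec$nirs), n)
  expect_gte(length(rec$hypnogram) * 30 * rec$fs, n)
  expect_setequal(unique(as.vector(rec$atlas)), 1:9)
  expect_true(all(table(rec$atlas[rec$mask]) > 0))
  cfg_small <- synthetic_config(grid_shape = c(4, 4, 4))
  lat <- simulate_coupled_latents(cfg_small, "AWAKE")
  expect_error(render_recording(lat, cfg_small, "AWAKE"), "9 nonempty ROI")
})

test_that("doubling the BLOOD amplitude quadruples downstream band power", {
  ratios <- vapply(1:8, function(s) {
    base <- synthetic_config(states = c("AWAKE", "N2"), seed = s)
    a <- simulate_coupled_latents(base, "AWAKE", seed = s)
    n2 <- simulate_coupled_latents(base, "N2", seed = s)  # BLOOD amplitude x2
    as.numeric(band_power(tf_power(n2[, "BLOOD"], freq_grid(), 10))) /
      as.numeric(band_power(tf_power(a[, "BLOOD"], freq_grid(), 10)))
  }, numeric(1))
  expect_gt(mean(ratios), 3.2)
  expect_lt(mean(ratios), 4.8)
})

test_that("fixtures round-trip through NIfTI/TSV readers", {
  cfg <- small_config(states = c("AWAKE", "N1"))
  rec <- simulate_recording(cfg)
  dir <- withr::local_tempdir()
  write_fixture(rec, dir)
  rec2 <- read_recording(dir)
  expect_equal(rec2$bold, rec$bold, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(rec2$eeg), unname(rec$eeg), tolerance = 1e-12)
  expect_equal(unname(rec2$nirs), unname(rec$nirs), tolerance = 1e-12)
  expect_identical(rec2$hypnogram, rec$hypnogram)
  expect_identical(rec2$atlas, rec$atlas)
  expect_equal(rec2$fs, rec$fs)
  # hypnogram TSV holds the state runs in order
  hyp <- read.table(file.path(dir, "hypnogram.tsv"), header = TRUE, sep = "\t")
  expect_identical(rle(hyp$label)$values, c("AWAKE", "N1"))
})

test_that("a corrupt NIfTI header raises an error rather than silent garbage", {
  cfg <- small_config(states = "AWAKE")
  rec <- simulate_recording(cfg)
  dir <- withr::local_tempdir()
  write_fixture(rec, dir)
  writeBin(charToRaw("this is not a nifti file at all, not even close"),
           file.path(dir, "bold.nii"))
  expect_error(suppressWarnings(read_recording(dir)))
})
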