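test_that("ensemble simulation is deterministic and leaves the RNG stream alone", {
  sc <- default_urban_scenario(seed = 51, n_days = 4, slots_per_day = 10,
                               B = 16)
  a <- do.call(simulate_ensemble, sc)
  b <- do.call(simulate_ensemble, sc)
  expect_identical(a$ensemble$values, b$ensemble$values)
  expect_identical(a$truth$activity, b$truth$activity)

  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(do.call(simulate_ensemble, sc))
  expect_identical(runif(3), before)
})

test_that("an always-on source adds no temporal variance beyond noise", {
  src <- list(source_spec("hum", c(1000, 3000), level = 1, prob = 1))
  sim <- simulate_ensemble(src, n_days = 4, slots_per_day = 25, B = 32,
                           noise_sd = 0.2, seed = 52)
  bb <- sim$truth$band_bins[[1]]
  sds <- apply(sim$ensemble$values[, bb], 2, sd)
  expect_true(all(abs(sds - 0.2) < 0.05))
  # and the band sits above the floor by log10((floor + level)/floor)
  lift <- mean(sim$ensemble$values[, bb]) -
    mean(sim$ensemble$values[, -bb])
  expect_equal(lift, log10((0.003 + 1) / 0.003), tolerance = 0.05)
})

test_that("a shared on/off source drives within-band R-squared toward one", {
  src <- list(source_spec("burst", c(1000, 5000), level = 1, prob = 0.5))
  sim <- simulate_ensemble(src, n_days = 10, slots_per_day = 50, B = 16,
                           noise_sd = 0.25, seed = 53)
  f <- compute_fcm(sim$ensemble, fmax = Inf, min_pairs = 10)
  bb <- sim$truth$band_bins[[1]]
  within <- f$r2[bb, bb][upper.tri(diag(length(bb)))]
  expect_gt(mean(within), 0.8)
})

test_that("independently scheduled sources stay uncorrelated across bands", {
  src <- list(source_spec("a", c(500, 2000), prob = 0.5),
              source_spec("b", c(6000, 9000), prob = 0.5))
  sim <- simulate_ensemble(src, n_days = 20, slots_per_day = 50, B = 32,
                           seed = 54)
  f <- compute_fcm(sim$ensemble, fmax = Inf, min_pairs = 10)
  across <- f$r2[sim$truth$band_bins[[1]], sim$truth$band_bins[[2]]]
  expect_lt(mean(across), 0.02)
})

test_that("waveform synthesis is deterministic and band-limited", {
  src <- list(source_spec("tone", c(1000, 2000), level = 1, prob = 1))
  ts <- as.POSIXct("2019-05-07 12:00:00", tz = "")
  r1 <- synthesize_wav(src, ts, duration = 1, seed = 55)
  r2 <- synthesize_wav(src, ts, duration = 1, seed = 55)
  expect_identical(r1$samples, r2$samples)
  expect_identical(attr(r1, "active_sources"), "tone")

  sp <- power_spectrum(r1, method = "welch")
  in_band <- sp$freqs >= 900 & sp$freqs <= 2200
  expect_gte(sum(sp$power[in_band]) / sum(sp$power), 0.9)

  expect_error(
    synthesize_wav(list(source_spec("ultra", c(30000, 40000))), ts,
                   duration = 0.1, sample_rate = 44100, seed = 1),
    "Nyquist")
})

test_that("with no active source the floor spectrum is flat within ripple", {
  src <- list(source_spec("night", c(1000, 2000), prob = 0))
  rec <- synthesize_wav(src, as.POSIXct("2019-05-07 03:00:00", tz = ""),
                        duration = 2, seed = 56)
  sp <- power_spectrum(rec, method = "welch")
  bs <- bin_spectrum(sp, make_binning(length(sp$power), max(sp$freqs), 16))
  lg <- log10(bs$values[2:15])            # skip DC and Nyquist edge bins
  expect_lt(diff(range(lg)), 0.2)
})

test_that("waveform and spectral tiers agree on band lift over the floor", {
  src <- list(source_spec("band", c(2000, 6000), level = 1, prob = 1))
  ts <- as.POSIXct("2019-05-07 12:00:00", tz = "")
  rec <- synthesize_wav(src, ts, duration = 2, seed = 57)
  sp <- power_spectrum(rec, method = "welch")
  sch <- make_binning(length(sp$power), max(sp$freqs), 32)
  bs <- log_transform(bin_spectrum(sp, sch))
  in_band <- sch$centers >= 2400 & sch$centers <= 5600    # clear of ramps
  out_band <- sch$centers >= 8000 & sch$centers <= 20000
  lift_wav <- mean(bs$values[in_band]) - mean(bs$values[out_band])
  lift_expected <- log10((0.003 + 1) / 0.003)
  expect_equal(lift_wav, lift_expected, tolerance = 0.15)
})

test_that("the default urban scenario plants three communities plus background", {
  sc <- default_urban_scenario(seed = 58, n_days = 2, slots_per_day = 10)
  sim <- do.call(simulate_ensemble, sc)
  part <- sim$truth$partition
  expect_setequal(unique(part),
                  c("traffic", "birds", "crickets", "background"))
  # schedules respect their masks: no weekend traffic, no morning crickets
  wd <- as.integer(format(sim$truth$timestamps, "%u"))
  hr <- as.integer(format(sim$truth$timestamps, "%H"))
  expect_false(any(sim$truth$activity[wd >= 6, "traffic"]))
  expect_false(any(sim$truth$activity[hr < 18, "crickets"]))
  expect_false(any(sim$truth$activity[hr >= 11, "birds"]))
})

test_that("scenario WAV export feeds back through the indexing front-end", {
  sc <- default_urban_scenario(seed = 59, n_days = 2, slots_per_day = 3,
                               B = 8)
  root <- withr::local_tempdir()
  paths <- write_scenario_wavs(sc, root, duration = 0.25, sample_rate = 22050)
  expect_length(paths, 6)
  idx <- build_index(root)
  expect_equal(nrow(idx), 6)
  expect_equal(unique(idx$site_id), "URB01")
  rec <- read_wav(idx$path[1])
  expect_equal(length(rec$samples), round(0.25 * 22050))
})

test_that("sampled recording spectra are positive, deterministic and structured", {
  S1 <- simulate_spectrum_sample(5, n_points = 2048, seed = 71)
  S2 <- simulate_spectrum_sample(5, n_points = 2048, seed = 71)
  expect_identical(S1, S2)
  expect_true(all(S1 > 0))

  base <- urban_reference_spectrum(2048)
  expect_equal(which.max(base), 1)            # low-frequency dominance
  # multiplicative noise centres on the envelope
  expect_equal(colMeans(simulate_spectrum_sample(200, n_points = 256,
                                                 seed = 72)),
               urban_reference_spectrum(256) * exp(0.2^2 / 2),
               tolerance = 0.05)
})
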