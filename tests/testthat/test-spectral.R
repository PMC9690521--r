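test_that("a pure tone peaks at its own frequency (full FFT)", {
  fs <- 8000
  t <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 1000 * t)
  sp <- power_spectrum(x, method = "fullfft", sample_rate = fs)
  expect_equal(sp$freqs[which.max(sp$power)], 1000)
  expect_true(all(sp$power >= 0))
})

test_that("silence yields an all-zero spectrum and Parseval holds on noise", {
  sp0 <- power_spectrum(numeric(256), method = "fullfft", sample_rate = 1000)
  expect_true(all(sp0$power == 0))

  set.seed(2)
  for (n in c(255, 256, 1000)) {              # odd and even lengths
    x <- rnorm(n)
    sp <- power_spectrum(x, method = "fullfft", sample_rate = 1000)
    expect_equal(sum(sp$power), mean(x^2), tolerance = 1e-6)
  }
})

test_that("Welch PSD integrates to the signal variance on white noise", {
  set.seed(3)
  x <- rnorm(50000)
  sp <- power_spectrum(x, method = "welch", sample_rate = 1000)
  df <- sp$freqs[2] - sp$freqs[1]
  expect_equal(sum(sp$power) * df, var(x), tolerance = 0.05)
  expect_error(power_spectrum(rnorm(100), method = "welch",
                              sample_rate = 1000, segment_length = 1000),
               "segment_length")
})

test_that("binning splits points with larger bins first", {
  expect_equal(make_binning(8, 1000, 2)$counts, c(4L, 4L))
  expect_equal(make_binning(7, 1000, 2)$counts, c(4L, 3L))
  expect_true(all(make_binning(4096, 22050, 1024)$counts == 4L))
  sch <- make_binning(103, 22050, 10)
  expect_true(max(sch$counts) - min(sch$counts) <= 1)
  expect_equal(sum(sch$counts), 103L)
  expect_true(all(diff(sch$edges) > 0))
  expect_equal(range(sch$edges), c(0, 22050))
  expect_error(make_binning(8, 1000, 9), "n_points")
})

test_that("bin means follow the definition and conserve total power", {
  sch <- make_binning(4, 1000, 2)
  expect_equal(bin_spectrum(c(1, 3, 2, 4), sch)$values, c(2, 3))

  expect_equal(bin_spectrum(rep(7, 10), make_binning(10, 1, 3))$values,
               rep(7, 3))
  x <- runif(10)
  expect_equal(bin_spectrum(x, make_binning(10, 1, 10))$values, x)

  set.seed(8)
  p <- runif(103)
  sch <- make_binning(103, 1, 10)
  bs <- bin_spectrum(p, sch)
  expect_equal(sum(bs$values * sch$counts), sum(p))
  expect_error(bin_spectrum(p, make_binning(50, 1, 10)), "50")
})

test_that("log transform maps powers of ten and floors zeros", {
  sch <- make_binning(3, 1, 3)
  bs <- bin_spectrum(c(1, 10, 100), sch)
  lt <- log_transform(bs)
  expect_equal(lt$values, c(0, 1, 2))
  expect_identical(lt$scale, "log")
  expect_error(log_transform(lt), "already log")

  bs0 <- bin_spectrum(c(0, 1, 1), sch)
  expect_equal(log_transform(bs0, floor_eps = 1e-12)$values[1], -12)

  mono <- log_transform(bin_spectrum(c(2, 5, 9), sch))
  expect_false(is.unsorted(mono$values))
})

test_that("mean intra-bin variance matches hand values and the total-variance oracle", {
  sch <- make_binning(4, 1, 2)
  expect_equal(mean_intra_bin_variance(c(1, 3, 2, 4), sch), 1.0)
  expect_equal(mean_intra_bin_variance(rep(3, 12), make_binning(12, 1, 4)), 0)
  expect_equal(mean_intra_bin_variance(runif(8), make_binning(8, 1, 8)), 0)

  set.seed(9)
  for (case in list(c(64, 8), c(64, 16), c(48, 4), c(60, 6))) {
    p <- runif(case[1])
    got <- mean_intra_bin_variance(p, make_binning(case[1], 1, case[2]))
    expect_equal(got, oracle_mean_intra_bin_variance(p, case[2]),
                 tolerance = 1e-12)
  }
})

test_that("Shannon evenness hits its analytic anchors and invariances", {
  expect_equal(spectral_evenness(rep(0.125, 8)), 1.0)
  expect_equal(spectral_evenness(c(0, 0, 5, 0)), 0.0)
  expect_equal(spectral_evenness(c(0.8, 0.2)), 0.7219, tolerance = 1e-4)
  expect_equal(spectral_evenness(c(5)), 1)
  expect_error(spectral_evenness(c(0, 0)), "all-zero")

  set.seed(10)
  v <- runif(20)
  expect_equal(spectral_evenness(v), spectral_evenness(37.5 * v))
  for (i in 1:20) {
    e <- spectral_evenness(runif(sample(2:50, 1)))
    expect_true(e >= 0 && e <= 1)
  }
})

test_that("the literal single-mean entropy variant differs from evenness", {
  v <- c(0.8, 0.2)
  s <- mean(v)
  expect_equal(spectral_entropy_literal(v), -s * log(s))
  expect_false(isTRUE(all.equal(spectral_entropy_literal(v),
                                spectral_evenness(v))))
})

test_that("the scan curve is zero for constant spectra and non-increasing on nested binnings", {
  S <- matrix(5, nrow = 3, ncol = 64)
  cv <- bin_selection_curve(S, c(2, 4, 8, 16))
  expect_true(all(cv$v_bar == 0))
  expect_true(all(cv$h_bar == 1))

  set.seed(12)
  S <- matrix(runif(10 * 240), nrow = 10)
  nested <- c(2, 4, 8, 16, 48, 240)         # each divides the next; 240 % B == 0
  cv <- bin_selection_curve(S, nested)
  expect_true(all(diff(cv$v_bar) <= 1e-12))
  expect_true(all(cv$rel_change_v >= 0 & cv$rel_change_v <= 1, na.rm = TRUE))
  expect_true(all(cv$rel_change_h >= 0 & cv$rel_change_h <= 1, na.rm = TRUE))
  expect_error(bin_selection_curve(S, c(10, 500)), "exceeds")
})

test_that("saturation selection follows the joint rule and power-of-two rounding", {
  curve <- list(bin_counts = c(50L, 100L, 200L, 400L),
                rel_change_v = c(1.0, 0.5, 0.05, 0.04),
                rel_change_h = c(1.0, 0.5, 0.05, 0.04))
  sel <- select_bin_count(curve, threshold = 0.1)
  expect_equal(sel$B_star, 200)
  expect_equal(sel$B_rounded, 256)

  expect_equal(select_bin_count(curve, threshold = 1.0)$B_star, 50)

  # both measures must saturate: a late bump in one series defers selection
  curve2 <- curve
  curve2$rel_change_h <- c(1.0, 0.5, 0.3, 0.04)
  expect_equal(select_bin_count(curve2, threshold = 0.1)$B_star, 400)

  never <- list(bin_counts = c(10L, 20L), rel_change_v = c(1, 0.9),
                rel_change_h = c(1, 0.9))
  expect_false(select_bin_count(never, threshold = 0.1)$saturated)

  # monotone in threshold: lower threshold never decreases B*
  b_loose <- select_bin_count(curve, threshold = 0.5)$B_star
  b_tight <- select_bin_count(curve, threshold = 0.05)$B_star
  expect_true(b_tight >= b_loose)
})

test_that("Cochran sample sizes match closed-form anchors", {
  res <- cochran_sample_size(0.01, 0.99, population = 416797)
  expect_equal(res$n, 15953)
  expect_equal(res$n_rounded_thousand, 16000)

  expect_equal(cochran_sample_size(0.05, 0.95)$n, 385)

  # the finite-population correction vanishes as N grows
  no_fpc <- cochran_sample_size(0.03, 0.95)$n
  huge <- cochran_sample_size(0.03, 0.95, population = 1e12)$n
  expect_equal(no_fpc, huge)
})
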