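test_that("daily embedding reshapes days x slots and imputes missing slots", {
  set.seed(21)
  V <- matrix(rnorm(10 * 5 * 2), ncol = 2)
  ens <- make_daily_ensemble(V, slots_per_day = 5)
  emb <- embed_bin_series(ens, 1, layout = "daily")
  expect_equal(dim(emb$matrix), c(10, 5))
  expect_equal(as.numeric(t(emb$matrix)), V[, 1])
  expect_false(any(emb$imputed))

  V2 <- V
  V2[7, 1] <- NA
  ens2 <- make_daily_ensemble(V2, slots_per_day = 5)
  emb2 <- embed_bin_series(ens2, 1, layout = "daily")
  expect_true(emb2$imputed[2, 2])                 # day 2, slot 2 (row 7)
  expect_equal(emb2$matrix[2, 2], median(V2[, 1], na.rm = TRUE))
  expect_equal(sum(emb2$imputed), 1)
})

test_that("lag embedding yields n - width + 1 sliding windows", {
  ens <- make_toy_ensemble(matrix(1:10, ncol = 2))
  emb <- embed_bin_series(ens, 1, layout = "lag", width = 3)
  expect_equal(dim(emb$matrix), c(3, 3))
  expect_equal(emb$matrix[1, ], c(1, 2, 3))
  expect_equal(emb$matrix[3, ], c(3, 4, 5))
})

test_that("rank-1 embeddings are reconstructed exactly with one component", {
  u <- c(1, 2, 3, 5)
  v <- c(2, -1, 4)
  M <- outer(u, v)
  dn <- pca_denoise_bin(M, var_threshold = 0.95)
  expect_equal(dn$k, 1L)
  expect_equal(dn$reconstruction, M, tolerance = 1e-10)
})

test_that("var_threshold = 1 reproduces the input exactly", {
  set.seed(22)
  M <- matrix(rnorm(80), nrow = 10)
  dn <- pca_denoise_bin(M, var_threshold = 1)
  expect_equal(dn$reconstruction, M, tolerance = 1e-10)
  expect_equal(dn$explained, 1, tolerance = 1e-12)
})

test_that("zero-variance embeddings come back unchanged with k = 0", {
  M <- matrix(3, nrow = 6, ncol = 4)
  dn <- pca_denoise_bin(M)
  expect_equal(dn$k, 0L)
  expect_identical(dn$reconstruction, M)
})

test_that("denoising a rank-2 diurnal signal plus noise moves toward the clean signal", {
  set.seed(23)
  n_days <- 40
  slots <- 24
  diurnal <- sin(2 * pi * seq_len(slots) / slots)
  trend <- seq(-1, 1, length.out = n_days)
  clean <- 2 * outer(rep(1, n_days), diurnal) + outer(trend, rep(1, slots))
  noisy <- clean + matrix(rnorm(n_days * slots, sd = 0.4), n_days)
  dn <- pca_denoise_bin(noisy, var_threshold = 0.95)
  rmse_in <- sqrt(mean((noisy - clean)^2))
  rmse_out <- sqrt(mean((dn$reconstruction - clean)^2))
  expect_lt(rmse_out, rmse_in)
  expect_gte(dn$explained, 0.95)

  # idempotent in the noiseless limit: a low-rank signal passes unchanged
  dn2 <- pca_denoise_bin(clean, var_threshold = 0.95)
  expect_equal(dn2$reconstruction, clean, tolerance = 1e-8)
})

test_that("ensemble denoising keeps >= 95% variance per bin and restores imputed cells", {
  set.seed(24)
  n <- 20 * 10
  diurnal <- rep(sin(2 * pi * seq_len(10) / 10), 20)
  V <- cbind(diurnal + rnorm(n, sd = 0.3), 2 * diurnal + rnorm(n, sd = 0.3))
  V[c(13, 57), 2] <- NA
  ens <- make_daily_ensemble(V, slots_per_day = 10)
  dn <- denoise_ensemble(ens, var_threshold = 0.95)
  rep <- attr(dn, "denoise_report")
  expect_true(all(rep$explained >= 0.95))
  expect_true(all(is.na(dn$values[c(13, 57), 2])))   # missing stays missing
  for (b in 1:2) {
    ok <- !is.na(V[, b])
    ratio <- var(dn$values[ok, b]) / var(V[ok, b])
    expect_gte(ratio, 0.93)
    expect_lte(ratio, 1 + 1e-8)
  }
  expect_identical(dn$provenance, c("bin", "log", "pca_denoise"))
})

test_that("eigenvalue re-weighting is exposed but distorts amplitudes", {
  set.seed(25)
  M <- matrix(rnorm(60), nrow = 10) + 5 * outer(rnorm(10), rnorm(6))
  std <- pca_denoise_bin(M, 0.95)
  lit <- pca_denoise_bin(M, 0.95, eigen_weighting = TRUE)
  expect_equal(std$k, lit$k)
  expect_false(isTRUE(all.equal(std$reconstruction, lit$reconstruction)))
})

test_that("outlier removal censors the expected tail count and nothing else", {
  set.seed(26)
  n <- 10000
  V <- matrix(rnorm(2 * n), ncol = 2)
  ens <- make_toy_ensemble(V)
  out <- remove_outliers(ens, q = 0.9995)
  rep <- attr(out, "outlier_report")$per_bin
  expected <- (1 - 0.9995) * n
  expect_true(all(rep$n_removed >= floor(expected)))
  expect_true(all(rep$n_removed <= ceiling(expected) + 1))
  # only the largest values go, and the missing mask only grows
  for (b in 1:2) {
    gone <- is.na(out$values[, b])
    expect_true(all(V[gone, b] > max(V[!gone, b])))
  }
  expect_identical(out$provenance, c("bin", "log", "outlier_removal"))
})

test_that("constant series lose nothing and injected spikes always go", {
  ens <- make_toy_ensemble(matrix(1.5, nrow = 50, ncol = 3))
  out <- remove_outliers(ens, q = 0.9995)
  expect_false(anyNA(out$values))

  set.seed(27)
  V <- matrix(runif(100, 1, 2), ncol = 1)
  V[40, 1] <- 100 * max(V[-40, 1])
  for (q in c(0.5, 0.9, 0.98)) {                # any q < 1 - 1/n
    out <- remove_outliers(make_toy_ensemble(V), q = q)
    expect_true(is.na(out$values[40, 1]))
  }
})

test_that("pre-existing missingness survives outlier removal", {
  set.seed(28)
  V <- matrix(rnorm(200), ncol = 2)
  V[5, 1] <- NA
  out <- remove_outliers(make_toy_ensemble(V), q = 0.99)
  expect_true(is.na(out$values[5, 1]))
  expect_true(all(which(is.na(V)) %in% which(is.na(out$values))))
})
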