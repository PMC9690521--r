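# Brute-force squared-Pearson oracle via the explicit covariance formula,
# pairwise-complete rows; independent of compute_fcm()'s cor() path.
oracle_r2 <- function(V) {
  B <- ncol(V)
  out <- matrix(NA_real_, B, B)
  for (a in seq_len(B)) {
    for (b in seq_len(B)) {
      ok <- !is.na(V[, a]) & !is.na(V[, b])
      x <- V[ok, a]
      y <- V[ok, b]
      n <- length(x)
      if (n < 2) next
      sxx <- sum((x - mean(x))^2)
      syy <- sum((y - mean(y))^2)
      if (sxx == 0 || syy == 0) next
      sxy <- sum((x - mean(x)) * (y - mean(y)))
      out[a, b] <- (sxy / sqrt(sxx * syy))^2
    }
  }
  out
}

# Law-of-total-variance oracle for equal-size bins: population variance of
# the whole spectrum minus the population variance of the bin means equals
# the mean intra-bin variance.
oracle_mean_intra_bin_variance <- function(power, B) {
  n <- length(power)
  stopifnot(n %% B == 0)
  popvar <- function(x) mean((x - mean(x))^2)
  bin_means <- colMeans(matrix(power, nrow = n / B))
  popvar(power) - popvar(bin_means)
}

# Small single-site ensemble from a raw value matrix, nyquist 1 kHz per bin
make_toy_ensemble <- function(values, site_id = "T01",
                              start = as.POSIXct("2020-01-01 00:00:00"),
                              scale = "log") {
  values <- as.matrix(values)
  scheme <- make_binning(ncol(values), 1000 * ncol(values), ncol(values))
  spectrum_ensemble(values, start + (seq_len(nrow(values)) - 1) * 1728,
                    site_id = site_id, scheme = scheme, scale = scale,
                    provenance = c("bin", "log"))
}

# Regular multi-day ensemble: n_days x slots_per_day rows
make_daily_ensemble <- function(values, slots_per_day,
                                start_date = as.Date("2020-01-06"),
                                scale = "log") {
  values <- as.matrix(values)
  n <- nrow(values)
  stopifnot(n %% slots_per_day == 0)
  n_days <- n / slots_per_day
  ts <- as.POSIXct(start_date, tz = "") +
    rep(seq_len(n_days) - 1, each = slots_per_day) * 86400 +
    rep(seq_len(slots_per_day) - 1, times = n_days) * (86400 / slots_per_day)
  scheme <- make_binning(ncol(values), 1000 * ncol(values), ncol(values))
  spectrum_ensemble(values, ts, site_id = "T01", scheme = scheme,
                    scale = scale, provenance = c("bin", "log"))
}

# Minimal RIFF/WAVE writer taking raw int16 (or float) payloads, independent
# of write_wav(), for exercising read_wav() against known bytes.
write_raw_wav <- function(path, payload, sample_rate = 44100, n_channels = 1L,
                          format = c("pcm16", "float32")) {
  format <- match.arg(format)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits / 8L
  n_bytes <- length(payload) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(if (format == "pcm16") 1L else 3L, n_channels), con, size = 2,
           endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_channels * bytes_per), con, size = 4,
           endian = "little")
  writeBin(c(as.integer(n_channels * bytes_per), bits), con, size = 2,
           endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(as.integer(payload), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(payload), con, size = 4, endian = "little")
  }
  invisible(path)
}
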