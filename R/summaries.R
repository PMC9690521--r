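#' Median power spectrum with 5-95% quantile band
#'
#' Per frequency bin, the median and the 5% / 95% quantiles (type-7) over all
#' non-missing recordings. The median is preferred over the mean for its
#' robustness to loud isolated events; the quantile band shows the power
#' range without being driven by extremes.
#'
#' @param ensemble A [spectrum_ensemble].
#' @param probs Lower and upper band quantiles.
#' @return A `median_spectrum_summary`: list with `median`, `q05`, `q95`
#'   (per-bin, same scale as the ensemble), `scheme`, `site_id`,
#'   `n_recordings`.
#' @export
median_power_spectrum <- function(ensemble, probs = c(0.05, 0.95)) {
  stopifnot(inherits(ensemble, "spectrum_ensemble"))
  n <- nrow(ensemble$values)
  if (n == 0) stop("empty ensemble", call. = FALSE)
  if (n < 20) {
    warning("fewer than 20 recordings; the quantile band is degenerate")
  }
  qs <- apply(ensemble$values, 2, stats::quantile,
              probs = c(probs[1], 0.5, probs[2]), na.rm = TRUE, type = 7)
  structure(
    list(median = qs[2, ], q05 = qs[1, ], q95 = qs[3, ],
         scheme = ensemble$scheme, site_id = ensemble$site_id,
         scale = ensemble$scale, n_recordings = n),
    class = "median_spectrum_summary"
  )
}

#' Daily mean spectra
#'
#' Averages the binned power spectra of all recordings per calendar date
#' (arithmetic mean over non-missing values). The returned matrix covers the
#' full calendar span: dates without any recording (maintenance days) are
#' rows of `NA`, so gaps stay visible downstream.
#'
#' @param ensemble A [spectrum_ensemble].
#' @return A numeric matrix `[dates x B]` with the `Date` vector as
#'   `attr(, "dates")` and the scheme as `attr(, "scheme")`.
#' @export
daily_mean_spectra <- function(ensemble) {
  stopifnot(inherits(ensemble, "spectrum_ensemble"))
  dates <- as.Date(ensemble$timestamps)
  all_dates <- seq(min(dates), max(dates), by = "day")
  B <- ensemble$scheme$B
  M <- matrix(NA_real_, nrow = length(all_dates), ncol = B)
  for (d in seq_along(all_dates)) {
    rows <- which(dates == all_dates[d])
    if (length(rows) == 0) next
    M[d, ] <- colMeans(ensemble$values[rows, , drop = FALSE], na.rm = TRUE)
  }
  M[is.nan(M)] <- NA
  attr(M, "dates") <- all_dates
  attr(M, "scheme") <- ensemble$scheme
  attr(M, "site_id") <- ensemble$site_id
  M
}

#' Min-max normalise a daily spectrogram per frequency bin
#'
#' Each bin's daily time series is mapped to `[0, 1]` over its non-missing
#' dates: 1 is the bin's maximum daily mean power over the whole period, 0
#' its minimum. Absolute power is deliberately discarded — the scaling makes
#' temporal patterns in weakly powered high-frequency bins as visible as
#' those in dominant low-frequency bins. A constant bin maps to 0 by
#' convention.
#'
#' @param daily Matrix from [daily_mean_spectra()] (dates x bins), or any
#'   numeric matrix.
#' @return A `normalized_spectrogram`: the normalised matrix with the same
#'   `dates` / `scheme` attributes.
#' @export
normalize_per_bin <- function(daily) {
  M <- as.matrix(daily)
  out <- M
  for (b in seq_len(ncol(M))) {
    v <- M[, b]
    ok <- !is.na(v)
    if (!any(ok)) {
      stop("bin ", b, " has no non-missing values; cannot normalise",
           call. = FALSE)
    }
    lo <- min(v[ok])
    hi <- max(v[ok])
    out[, b] <- if (hi > lo) (v - lo) / (hi - lo) else ifelse(ok, 0, NA)
  }
  attributes(out) <- attributes(M)
  class(out) <- c("normalized_spectrogram", class(out))
  out
}

#' @export
print.median_spectrum_summary <- function(x, ...) {
  cat(sprintf("<median_spectrum_summary> site=%s  %d bins over %d recordings (%s scale)\n",
              x$site_id, length(x$median), x$n_recordings, x$scale))
  invisible(x)
}

#' Write a median-spectrum summary as delimited text
#'
#' Columns: bin centre frequency (Hz), median, q05, q95.
#'
#' @param summary A [median_power_spectrum()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_median_spectrum <- function(summary, path) {
  utils::write.table(
    data.frame(freq_hz = summary$scheme$centers, median = summary$median,
               q05 = summary$q05, q95 = summary$q95),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a median power spectrum with its quantile band
#'
#' @param x A `median_spectrum_summary`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.median_spectrum_summary <- function(x, ...) {
  f <- x$scheme$centers / 1000
  graphics::plot(f, x$median, type = "n", xlab = "Frequency [kHz]",
                 ylab = if (x$scale == "log") "log10 power" else "power",
                 ylim = range(c(x$q05, x$q95), finite = TRUE), ...)
  graphics::polygon(c(f, rev(f)), c(x$q05, rev(x$q95)),
                    col = grDevices::adjustcolor("steelblue", 0.4),
                    border = NA)
  graphics::lines(f, x$median, lwd = 1.5)
  invisible(x)
}

#' Plot a normalised date-by-frequency spectrogram
#'
#' Dates on the x axis, frequency on the y axis; missing dates appear as
#' black columns.
#'
#' @param x A `normalized_spectrogram`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.normalized_spectrogram <- function(x, ...) {
  dates <- attr(x, "dates")
  scheme <- attr(x, "scheme")
  z <- unclass(x)
  pal <- grDevices::hcl.colors(100, "viridis")
  graphics::image(x = as.numeric(dates), y = scheme$centers / 1000, z = z,
                  col = pal, xlab = "Date", ylab = "Frequency [kHz]",
                  xaxt = "n", useRaster = TRUE, ...)
  gap <- which(apply(z, 1, function(r) all(is.na(r))))
  if (length(gap)) {
    graphics::rect(as.numeric(dates[gap]) - 0.5, 0,
                   as.numeric(dates[gap]) + 0.5, max(scheme$centers) / 1000,
                   col = "black", border = NA)
  }
  at <- pretty(as.numeric(dates))
  graphics::axis(1, at = at, labels = format(as.Date(at, origin = "1970-01-01"),
                                             "%b %y"))
  invisible(x)
}
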