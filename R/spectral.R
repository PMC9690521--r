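#' Estimate the one-sided power spectrum of a recording
#'
#' Two estimators are provided. `method = "fullfft"` takes a single FFT of
#' the whole recording with a rectangular window and returns discrete power
#' per frequency point, normalised so that `sum(power)` equals the mean
#' square of the signal (Parseval). `method = "welch"` averages modified
#' periodograms over Hann-windowed segments (default 1 s, 50% overlap) and
#' returns a power spectral *density* (power per Hz), so that
#' `sum(power) * df` approximates the signal variance; it is the default for
#' multi-minute recordings because it trades frequency resolution for a far
#' lower estimator variance.
#'
#' @param rec An [audio_recording] (or a plain numeric vector, in which case
#'   `sample_rate` must be given).
#' @param method `"welch"` or `"fullfft"`.
#' @param segment_length Welch segment length in samples; defaults to one
#'   second of audio.
#' @param overlap Welch fractional segment overlap.
#' @param sample_rate Only used when `rec` is a bare numeric vector.
#' @return A `raw_spectrum`: list with `power` (nonnegative), `freqs` (Hz,
#'   ascending from 0 to Nyquist), `recording_id`, and the estimator settings.
#' @export
power_spectrum <- function(rec, method = c("welch", "fullfft"),
                           segment_length = NULL, overlap = 0.5,
                           sample_rate = NULL) {
  method <- match.arg(method)
  if (inherits(rec, "audio_recording")) {
    x <- rec$samples
    fs <- rec$sample_rate
    id <- if (!is.na(rec$site_id)) {
      paste0(rec$site_id, "_", format(rec$timestamp, "%Y%m%d_%H%M%S"))
    } else rec$source_path
  } else {
    stopifnot(is.numeric(rec), !is.null(sample_rate))
    x <- rec
    fs <- sample_rate
    id <- NA_character_
  }
  n <- length(x)
  if (n < 2) stop("need at least 2 samples for a power spectrum", call. = FALSE)

  if (method == "fullfft") {
    X <- stats::fft(x)
    p_full <- Mod(X)^2 / n^2
    n_freq <- n %/% 2 + 1
    power <- p_full[seq_len(n_freq)]
    # fold the negative frequencies in; DC (and Nyquist, for even n) are unique
    if (n %% 2 == 0) {
      if (n_freq > 2) power[2:(n_freq - 1)] <- 2 * power[2:(n_freq - 1)]
    } else {
      if (n_freq > 1) power[2:n_freq] <- 2 * power[2:n_freq]
    }
    freqs <- (seq_len(n_freq) - 1) * fs / n
  } else {
    if (is.null(segment_length)) segment_length <- min(n, round(fs))
    L <- as.integer(segment_length)
    if (L > n) {
      stop("segment_length (", L, ") exceeds recording length (", n, ")",
           call. = FALSE)
    }
    if (L < 2) stop("segment_length must be >= 2", call. = FALSE)
    step <- max(1L, as.integer(round(L * (1 - overlap))))
    starts <- seq(1L, n - L + 1L, by = step)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)     # periodic Hann
    U <- sum(w^2)
    n_freq <- L %/% 2 + 1
    acc <- numeric(n_freq)
    for (s in starts) {
      X <- stats::fft(x[s:(s + L - 1L)] * w)
      acc <- acc + Mod(X[seq_len(n_freq)])^2
    }
    power <- acc / (length(starts) * fs * U)
    if (L %% 2 == 0) {
      if (n_freq > 2) power[2:(n_freq - 1)] <- 2 * power[2:(n_freq - 1)]
    } else {
      if (n_freq > 1) power[2:n_freq] <- 2 * power[2:n_freq]
    }
    freqs <- (seq_len(n_freq) - 1) * fs / L
  }
  structure(list(power = power, freqs = freqs, recording_id = id,
                 method = method, sample_rate = fs),
            class = "raw_spectrum")
}

#' Partition spectral points into B equal-width frequency bins
#'
#' Points are split into `B` contiguous bins of `floor(n/B)` or
#' `ceiling(n/B)` points; when `n mod B != 0` the first `n mod B` bins take
#' the extra point (larger bins first). Each point is treated as a frequency
#' cell of width `nyquist / n_points`, so the returned Hz edges span exactly
#' `[0, nyquist]`.
#'
#' @param n_points Number of spectral points to bin.
#' @param nyquist Nyquist frequency in Hz.
#' @param B Number of bins, `1 <= B <= n_points`.
#' @return A `binning_scheme`: list with `B`, `n_points`, `nyquist`, `counts`
#'   (points per bin), `bin_of` (bin id per point), `edges` (B+1 Hz values),
#'   `centers` (Hz).
#' @export
make_binning <- function(n_points, nyquist, B) {
  stopifnot(n_points >= 1, nyquist > 0)
  if (B < 1 || B > n_points) {
    stop("B must satisfy 1 <= B <= n_points (got B = ", B, ", n_points = ",
         n_points, ")", call. = FALSE)
  }
  B <- as.integer(B)
  n_points <- as.integer(n_points)
  base <- n_points %/% B
  rem <- n_points %% B
  counts <- rep(base, B)
  if (rem > 0) counts[seq_len(rem)] <- base + 1L
  delta <- nyquist / n_points
  edges <- delta * c(0, cumsum(counts))
  structure(list(B = B, n_points = n_points, nyquist = nyquist,
                 counts = counts, bin_of = rep(seq_len(B), counts),
                 edges = edges,
                 centers = (edges[-1] + edges[-(B + 1)]) / 2),
            class = "binning_scheme")
}

#' Average spectral power inside each frequency bin
#'
#' @param raw A `raw_spectrum` from [power_spectrum()] (or a bare numeric
#'   power vector).
#' @param scheme A [make_binning()] scheme built for the spectrum's length.
#' @return A `binned_spectrum`: list with `values` (B arithmetic bin means),
#'   `scheme`, `scale = "linear"`, `recording_id`.
#' @export
bin_spectrum <- function(raw, scheme) {
  power <- if (inherits(raw, "raw_spectrum")) raw$power else raw
  if (length(power) != scheme$n_points) {
    stop("binning scheme was built for ", scheme$n_points,
         " points but spectrum has ", length(power), call. = FALSE)
  }
  values <- as.numeric(rowsum(power, scheme$bin_of, reorder = TRUE)) /
    scheme$counts
  structure(list(values = values, scheme = scheme, scale = "linear",
                 recording_id = if (inherits(raw, "raw_spectrum"))
                   raw$recording_id else NA_character_),
            class = "binned_spectrum")
}

#' Log-transform a binned spectrum
#'
#' Applies `log10(max(value, floor_eps))` bin-wise. The floor keeps empty
#' bins finite; by default it is `1e-12` times the largest bin value.
#'
#' @param bs A linear-scale `binned_spectrum`.
#' @param floor_eps Power floor; `NULL` for the relative default.
#' @return The transformed `binned_spectrum` with `scale = "log"`.
#' @export
log_transform <- function(bs, floor_eps = NULL) {
  stopifnot(inherits(bs, "binned_spectrum"))
  if (bs$scale == "log") {
    stop("spectrum is already log-scaled; refusing a double transform",
         call. = FALSE)
  }
  if (is.null(floor_eps)) floor_eps <- 1e-12 * max(bs$values, 1e-300)
  bs$values <- log10(pmax(bs$values, floor_eps))
  bs$scale <- "log"
  bs
}

#' Mean intra-bin variance of a spectrum under a binning
#'
#' The complexity lost by binning: the population variance of the spectral
#' power values inside each bin, averaged (unweighted) over the B bins.
#' Zero for a constant spectrum and for single-point bins.
#'
#' @inheritParams bin_spectrum
#' @return A single nonnegative number.
#' @export
mean_intra_bin_variance <- function(raw, scheme) {
  power <- if (inherits(raw, "raw_spectrum")) raw$power else raw
  if (length(power) != scheme$n_points) {
    stop("binning scheme was built for ", scheme$n_points,
         " points but spectrum has ", length(power), call. = FALSE)
  }
  g <- scheme$bin_of
  m1 <- as.numeric(rowsum(power, g)) / scheme$counts
  m2 <- as.numeric(rowsum(power^2, g)) / scheme$counts
  mean(pmax(m2 - m1^2, 0))
}

#' Shannon evenness of a binned power spectrum
#'
#' The binned powers are normalised to a probability vector
#' `p_b = values_b / sum(values)` and the evenness is
#' `-sum(p_b log p_b) / log(B)`: 1 for a flat spectrum, 0 when a single bin
#' holds all the power. Defined as 1 when `B = 1`. Invariant under positive
#' rescaling of the spectrum.
#'
#' @param bs A linear-scale `binned_spectrum`, or a bare nonnegative numeric
#'   vector of bin values.
#' @return Evenness in `[0, 1]`.
#' @export
spectral_evenness <- function(bs) {
  v <- if (inherits(bs, "binned_spectrum")) {
    if (bs$scale != "linear") {
      stop("evenness is defined on linear-scale power", call. = FALSE)
    }
    bs$values
  } else bs
  stopifnot(is.numeric(v), all(v >= 0))
  tot <- sum(v)
  if (tot == 0) stop("evenness undefined for an all-zero spectrum", call. = FALSE)
  B <- length(v)
  if (B == 1) return(1)
  p <- v / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(B)
}

#' Literal single-mean spectral entropy (comparison variant)
#'
#' Reduces the binned spectrum to the grand mean of its bin means `s` and
#' returns `-s * log(s)`. Kept only for comparison with
#' [spectral_evenness()]: it is not an entropy of a distribution and is not
#' scale-invariant.
#'
#' @inheritParams spectral_evenness
#' @return A single number (can fall outside `[0, 1]`).
#' @export
spectral_entropy_literal <- function(bs) {
  v <- if (inherits(bs, "binned_spectrum")) bs$values else bs
  s <- mean(v)
  if (s <= 0) return(0)
  -s * log(s)
}

#' Scan candidate bin counts for intra-bin variance and evenness saturation
#'
#' For every bin count `B` in `bin_counts`, computes the mean intra-bin
#' variance and the mean Shannon evenness over all spectra in `sample`, then
#' the relative-change series used by the saturation rule:
#' `rel_change[k] = |x[k] - x[k-1]| / max_j |x[j] - x[j-1]|` (aligned with
#' `bin_counts[k]`; the first element is `NA`).
#'
#' @param sample List of `raw_spectrum` objects (equal length), or a numeric
#'   matrix with one spectrum per row.
#' @param bin_counts Ascending candidate bin counts.
#' @param nyquist Nyquist frequency (taken from the spectra if available).
#' @return A `bin_selection_curve`: data-frame-like list with `bin_counts`,
#'   `v_bar`, `h_bar`, `rel_change_v`, `rel_change_h`.
#' @export
bin_selection_curve <- function(sample, bin_counts, nyquist = NULL) {
  if (is.list(sample) && inherits(sample[[1]], "raw_spectrum")) {
    if (is.null(nyquist)) nyquist <- max(sample[[1]]$freqs)
    S <- do.call(rbind, lapply(sample, `[[`, "power"))
  } else {
    S <- as.matrix(sample)
    if (is.null(nyquist)) nyquist <- 1
  }
  stopifnot(nrow(S) >= 1, !is.unsorted(bin_counts))
  n <- ncol(S)
  if (max(bin_counts) > n) {
    stop("largest bin count (", max(bin_counts),
         ") exceeds spectrum length (", n, ")", call. = FALSE)
  }
  v_bar <- h_bar <- numeric(length(bin_counts))
  for (k in seq_along(bin_counts)) {
    sch <- make_binning(n, nyquist, bin_counts[k])
    g <- sch$bin_of
    M1 <- rowsum(t(S), g) / sch$counts            # bins x recordings
    M2 <- rowsum(t(S^2), g) / sch$counts
    v_bar[k] <- mean(colMeans(pmax(M2 - M1^2, 0)))
    tot <- colSums(M1)
    P <- sweep(M1, 2, tot, "/")
    plogp <- ifelse(P > 0, P * log(P), 0)
    h <- if (bin_counts[k] == 1) rep(1, ncol(P)) else -colSums(plogp) / log(bin_counts[k])
    h_bar[k] <- mean(h)
  }
  structure(list(bin_counts = as.integer(bin_counts), v_bar = v_bar,
                 h_bar = h_bar,
                 rel_change_v = .rel_change(v_bar),
                 rel_change_h = .rel_change(h_bar),
                 n_recordings = nrow(S)),
            class = "bin_selection_curve")
}

.rel_change <- function(x) {
  d <- abs(diff(x))
  m <- max(d)
  if (m == 0) return(c(NA, rep(0, length(d))))
  c(NA, d / m)
}

#' Select the bin count at which the scan saturates
#'
#' Returns the smallest scanned bin count from which on *both*
#' relative-change series (intra-bin variance and evenness) stay at or below
#' `threshold` for every subsequent scan point (`NA` entries — the undefined
#' change before the first scan point — are ignored). Optionally rounds the
#' result up to the nearest power of two, the usual storage convention.
#'
#' @param curve A [bin_selection_curve()] result (or any list carrying
#'   `bin_counts`, `rel_change_v`, `rel_change_h`).
#' @param threshold Saturation threshold as a fraction of the maximum change.
#' @param round_to_power_of_two Round the selected count up to a power of 2?
#' @return A list with `B_star` (scanned value; `NA` if the criterion is
#'   never met), `B_rounded`, `threshold`. Class `bin_selection`.
#' @export
select_bin_count <- function(curve, threshold = 0.1,
                             round_to_power_of_two = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  rv <- curve$rel_change_v
  rh <- curve$rel_change_h
  n <- length(curve$bin_counts)
  ok <- vapply(seq_len(n), function(k) {
    all(c(rv[k:n], rh[k:n]) <= threshold, na.rm = TRUE)
  }, logical(1))
  if (!any(ok)) {
    return(structure(list(B_star = NA_integer_, B_rounded = NA_integer_,
                          threshold = threshold, saturated = FALSE),
                     class = "bin_selection"))
  }
  b <- curve$bin_counts[which(ok)[1]]
  structure(list(
    B_star = b,
    B_rounded = if (round_to_power_of_two) as.integer(2^ceiling(log2(b))) else b,
    threshold = threshold, saturated = TRUE
  ), class = "bin_selection")
}

#' Cochran sample size with optional finite-population correction
#'
#' `n0 = z^2 * 0.25 / margin^2` with `z` the two-sided normal quantile for
#' the given confidence (maximum-variance proportion p = 0.5); with a finite
#' population `N`, `n = n0 / (1 + (n0 - 1) / N)`. The required size is the
#' ceiling; a nearest-thousand rounding is returned as a convenience for
#' planning.
#'
#' @param margin Margin of error as a fraction (e.g. `0.01`).
#' @param confidence Confidence level as a fraction (e.g. `0.99`).
#' @param population Population size `N`, or `NULL` for the infinite limit.
#' @return List with `n` (ceiling), `n_rounded_thousand`, `n0`, `z`.
#' @examples
#' cochran_sample_size(0.01, 0.99, 416797)
#' @export
cochran_sample_size <- function(margin, confidence, population = NULL) {
  stopifnot(margin > 0, margin < 1, confidence > 0, confidence < 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * 0.25 / margin^2
  n <- if (is.null(population)) n0 else n0 / (1 + (n0 - 1) / population)
  list(n = ceiling(n), n_rounded_thousand = round(n / 1000) * 1000,
       n0 = n0, z = z)
}

#' Export a bin-selection curve as delimited text
#'
#' @param curve A [bin_selection_curve()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bin_selection_curve <- function(curve, path) {
  utils::write.table(
    data.frame(B = curve$bin_counts, v_bar = curve$v_bar, h_bar = curve$h_bar,
               rel_change_v = curve$rel_change_v,
               rel_change_h = curve$rel_change_h),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
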