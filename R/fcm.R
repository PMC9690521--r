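#' Frequency correlation matrix (FCM)
#'
#' Squared Pearson correlations between every pair of frequency-bin power
#' time series of one site. High `R^2` between two bins means sound sources
#' occupying both bins co-occur over the recording schedule; blocks of
#' mutually high `R^2` ("frequency communities") characterise a site's mix of
#' sources. Because Pearson correlation normalises each series, the FCM is
#' invariant to per-bin affine rescaling, and its dimension depends only on
#' the bin count — never on the number of recordings.
#'
#' Missing values (removed outliers, maintenance gaps) are handled with
#' pairwise-complete observations; entries backed by fewer than `min_pairs`
#' complete pairs, and rows/columns of zero-variance bins, are set to `NA`
#' and reported rather than silently zeroed.
#'
#' @param ensemble A [spectrum_ensemble].
#' @param fmax Frequency cap in Hz; bins whose centre exceeds it are
#'   excluded (most acoustic power in built environments sits below ~13 kHz).
#'   `Inf` keeps all bins.
#' @param min_pairs Minimum pairwise-complete sample size per entry.
#' @param daily_means If `TRUE`, correlate daily mean spectra instead of
#'   per-recording spectra.
#' @param keep_signed Also retain the signed correlation matrix (diagnostic;
#'   squaring discards anti-correlation structure).
#' @return An `fcm` object: list with `r2` (`[B' x B']`, symmetric, unit
#'   diagonal), `n_pairs` (effective sample sizes), `scheme` (capped bin
#'   edges/centres), `bins` (original bin indices kept), `site_id`, and
#'   optionally `r_signed`.
#' @export
compute_fcm <- function(ensemble, fmax = 13000, min_pairs = 30,
                        daily_means = FALSE, keep_signed = FALSE) {
  stopifnot(inherits(ensemble, "spectrum_ensemble"))
  V <- if (daily_means) {
    dm <- daily_mean_spectra(ensemble)
    unclass(dm)[, , drop = FALSE]
  } else ensemble$values
  keep <- which(ensemble$scheme$centers <= fmax)
  if (length(keep) < 2) stop("fewer than 2 bins under fmax", call. = FALSE)
  V <- V[, keep, drop = FALSE]
  dimnames(V) <- NULL

  r <- suppressWarnings(stats::cor(V, use = "pairwise.complete.obs"))
  n_pairs <- crossprod(!is.na(V))
  r[n_pairs < min_pairs] <- NA
  zero_var <- apply(V, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2 || stats::var(v) == 0
  })
  r[zero_var, ] <- NA
  r[, zero_var] <- NA
  r2 <- r^2
  diag(r2)[!zero_var] <- 1

  structure(list(
    r2 = r2, n_pairs = n_pairs,
    freq_centers = ensemble$scheme$centers[keep],
    freq_edges = c(ensemble$scheme$edges[keep],
                   ensemble$scheme$edges[max(keep) + 1]),
    bins = keep, zero_variance_bins = which(zero_var),
    site_id = ensemble$site_id, fmax = fmax, min_pairs = min_pairs,
    daily_means = daily_means,
    r_signed = if (keep_signed) r else NULL
  ), class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("<fcm> site=%s  %d x %d bins (<= %g Hz)\n", x$site_id,
              nrow(x$r2), ncol(x$r2), x$fmax))
  if (length(x$zero_variance_bins)) {
    cat("  zero-variance bins:", paste(x$zero_variance_bins, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Histogram of off-diagonal R-squared values
#'
#' Tallies the strict upper triangle of an FCM (the diagonal 1s from
#' correlating a bin with itself carry no information) into equal-width bins
#' on `[0, 1]`, half-open with the last bin closed. Multimodality of this
#' distribution indicates several distinct groups of interlinked frequency
#' bins, i.e. a diversity of sound sources.
#'
#' @param fcm An [compute_fcm()] result.
#' @param n_bins Number of histogram bins on `[0, 1]`.
#' @return An `r2_histogram`: list with `breaks` (length `n_bins + 1`),
#'   `mids`, `counts`, `n_missing` (upper-triangle entries that were `NA`).
#' @export
r2_histogram <- function(fcm, n_bins = 50) {
  stopifnot(inherits(fcm, "fcm"), n_bins >= 1)
  vals <- fcm$r2[upper.tri(fcm$r2)]
  n_missing <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(vals, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-n_bins - 1]) / 2,
                 counts = counts, n_missing = n_missing,
                 n_values = length(vals)),
            class = "r2_histogram")
}

#' Locate local maxima of an R-squared histogram
#'
#' A histogram bin is a mode if its count strictly exceeds the counts of both
#' neighbouring non-equal bins (plateaus are collapsed to their centre) and
#' is at least `min_count`. Used to check multimodality of FCM histograms.
#'
#' @param hist An [r2_histogram()] result.
#' @param min_count Minimum count for a bin to qualify as a mode.
#' @return Data frame with the mode positions (`r2`) and `count`s, ordered by
#'   decreasing count.
#' @export
histogram_modes <- function(hist, min_count = 1) {
  cnt <- hist$counts
  n <- length(cnt)
  is_mode <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1) max(cnt[seq_len(i - 1)][cnt[seq_len(i - 1)] != cnt[i]],
                           -Inf) else -Inf
    j <- i
    while (j < n && cnt[j + 1] == cnt[i]) j <- j + 1
    right <- if (j < n) cnt[j + 1] else -Inf
    prev <- if (i > 1) cnt[i - 1] else -Inf
    nxt <- if (j < n) cnt[j + 1] else -Inf
    is_mode[i] <- cnt[i] >= min_count && cnt[i] > prev && cnt[i] > nxt
  }
  out <- data.frame(r2 = hist$mids[is_mode], count = cnt[is_mode])
  out[order(-out$count), , drop = FALSE]
}

#' Mean within-block vs between-block R-squared
#'
#' Given a partition of the (capped) bins into blocks — e.g. the planted
#' communities of a synthetic scenario — returns the mean off-diagonal `R^2`
#' within blocks and between blocks. A large positive difference confirms the
#' block structure visible in FCM heatmaps.
#'
#' @param fcm An [compute_fcm()] result.
#' @param blocks Vector of block labels, one per FCM bin.
#' @return List with `within`, `between`, `contrast` (`within - between`).
#' @export
block_contrast <- function(fcm, blocks) {
  stopifnot(inherits(fcm, "fcm"), length(blocks) == nrow(fcm$r2))
  same <- outer(blocks, blocks, "==")
  ut <- upper.tri(fcm$r2)
  within <- mean(fcm$r2[ut & same], na.rm = TRUE)
  between <- mean(fcm$r2[ut & !same], na.rm = TRUE)
  list(within = within, between = between, contrast = within - between)
}

#' Write an R-squared histogram as delimited text
#'
#' @param hist An [r2_histogram()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_r2_histogram <- function(hist, path) {
  utils::write.table(
    data.frame(lo = hist$breaks[-length(hist$breaks)], hi = hist$breaks[-1],
               mid = hist$mids, count = hist$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot an FCM heatmap with an inset R-squared histogram
#'
#' @param x An `fcm` object.
#' @param inset_hist Draw the histogram inset?
#' @param ... Passed to [graphics::image()].
#' @export
plot.fcm <- function(x, inset_hist = TRUE, ...) {
  f <- x$freq_centers / 1000
  pal <- grDevices::hcl.colors(100, "viridis")
  graphics::image(f, f, x$r2, zlim = c(0, 1), col = pal,
                  xlab = "Frequency [kHz]", ylab = "Frequency [kHz]",
                  useRaster = TRUE, ...)
  if (inset_hist) {
    h <- r2_histogram(x)
    op <- graphics::par(fig = c(0.12, 0.45, 0.6, 0.95), new = TRUE,
                        mar = c(2, 2, 0.5, 0.5))
    on.exit(graphics::par(op))
    graphics::barplot(h$counts, space = 0, col = "grey30", border = NA,
                      names.arg = NULL, axes = FALSE)
    graphics::axis(1, at = c(0, length(h$counts)), labels = c(0, 1),
                   cex.axis = 0.7)
  }
  invisible(x)
}
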