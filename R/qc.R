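#' Quality-control flags for recordings
#'
#' Generic plausibility screen used to exclude faulty recordings before any
#' spectral analysis. Three flags are computed per recording:
#'
#' * `clipped`: fraction of samples at full scale (|x| >= `clip_level`)
#'   exceeds `clip_frac`.
#' * `silent`: RMS amplitude below `silence_rms`.
#' * `stat_outlier`: a summary statistic (log total power) outside
#'   `median +/- k * IQR` computed over the recordings of the same site.
#'   Requires at least 5 recordings per site; otherwise `NA`.
#'
#' When the input is a [spectrum_ensemble] only `stat_outlier` is available
#' (total binned power per recording); waveform flags are `NA`.
#'
#' An optional `short` flag marks recordings more than 1% shorter than
#' `nominal_length_s` (tolerant of device truncation) rather than rejecting
#' them.
#'
#' @param x List of [audio_recording] objects, or a [spectrum_ensemble].
#' @param k IQR multiplier for the statistical-outlier rule.
#' @param clip_level Amplitude treated as full scale.
#' @param clip_frac Maximum tolerated fraction of full-scale samples.
#' @param silence_rms RMS below which a recording is flagged silent.
#' @param nominal_length_s Nominal recording length in seconds, or `NA` to
#'   skip the `short` flag.
#' @return A `qc_report`: data frame with one row per recording (`site_id`,
#'   `timestamp`, logical flag columns) plus the thresholds as attributes.
#' @export
qc_flags <- function(x, k = 3, clip_level = 32767 / 32768, clip_frac = 0.01,
                     silence_rms = 1e-4, nominal_length_s = NA) {
  if (inherits(x, "spectrum_ensemble")) {
    vals <- if (x$scale == "log") 10^x$values else x$values
    stat <- log10(pmax(rowSums(vals, na.rm = TRUE), .Machine$double.xmin))
    rep <- data.frame(site_id = x$site_id, timestamp = x$timestamps,
                      clipped = NA, silent = NA, short = NA)
    rep$stat_outlier <- .iqr_outlier(stat, k)
  } else {
    stopifnot(is.list(x), length(x) > 0,
              all(vapply(x, inherits, logical(1), "audio_recording")))
    clipped <- vapply(x, function(r) {
      mean(abs(r$samples) >= clip_level) > clip_frac
    }, logical(1))
    rms <- vapply(x, function(r) sqrt(mean(r$samples^2)), numeric(1))
    stat <- log10(pmax(rms^2, .Machine$double.xmin))
    rep <- data.frame(
      site_id = vapply(x, `[[`, character(1), "site_id"),
      timestamp = as.POSIXct(vapply(x, function(r) as.numeric(r$timestamp),
                                    numeric(1)), origin = "1970-01-01", tz = ""),
      clipped = clipped,
      silent = rms < silence_rms,
      short = if (is.na(nominal_length_s)) NA else
        vapply(x, function(r) r$duration < 0.99 * nominal_length_s, logical(1))
    )
    rep$stat_outlier <- stats::ave(stat, rep$site_id,
                                   FUN = function(s) .iqr_outlier(s, k))
    rep$stat_outlier <- as.logical(rep$stat_outlier)
  }
  attr(rep, "thresholds") <- list(k = k, clip_level = clip_level,
                                  clip_frac = clip_frac,
                                  silence_rms = silence_rms,
                                  nominal_length_s = nominal_length_s)
  class(rep) <- c("qc_report", class(rep))
  rep
}

# median +/- k*IQR rule; NA when fewer than 5 observations
.iqr_outlier <- function(stat, k) {
  if (length(stat) < 5) return(rep(NA, length(stat)))
  med <- stats::median(stat)
  iqr <- stats::IQR(stat, type = 7)
  stat < med - k * iqr | stat > med + k * iqr
}
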