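#' Construct a spectrum ensemble for one site
#'
#' The object every downstream stage consumes: a time-ordered stack of binned
#' spectra for one site. Rows are recordings (sorted by timestamp), columns
#' are frequency bins. Values may be `NA` (e.g. after outlier removal). The
#' `provenance` field records the transforms applied, in order.
#'
#' @param values Numeric matrix `[n_recordings x B]`.
#' @param timestamps `POSIXct` vector, one per row.
#' @param site_id Site label.
#' @param scheme The [make_binning()] scheme the columns refer to.
#' @param scale `"linear"` or `"log"`.
#' @param provenance Character vector of applied transforms.
#' @return Object of class `spectrum_ensemble`.
#' @export
spectrum_ensemble <- function(values, timestamps, site_id, scheme,
                              scale = "linear", provenance = character()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(timestamps), ncol(values) == scheme$B,
            scale %in% c("linear", "log"))
  ord <- order(timestamps)
  structure(
    list(values = values[ord, , drop = FALSE], timestamps = timestamps[ord],
         site_id = site_id, scheme = scheme, scale = scale,
         provenance = provenance),
    class = "spectrum_ensemble"
  )
}

#' @export
print.spectrum_ensemble <- function(x, ...) {
  cat(sprintf(
    "<spectrum_ensemble> site=%s  %d recordings x %d bins (%s scale)\n",
    x$site_id, nrow(x$values), x$scheme$B, x$scale))
  cat("  span:", format(min(x$timestamps)), "..", format(max(x$timestamps)), "\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Bin and log-transform a set of recordings into a site ensemble
#'
#' Convenience wrapper: estimates a power spectrum per recording, bins it,
#' optionally log-transforms, and stacks the results.
#'
#' @param recordings List of [audio_recording] objects from one site.
#' @param B Bin count.
#' @param method Spectrum estimator, see [power_spectrum()].
#' @param log Apply [log_transform()]?
#' @param exclude Optional logical vector marking recordings to drop (e.g.
#'   from [qc_flags()]).
#' @return A [spectrum_ensemble].
#' @export
ensemble_from_recordings <- function(recordings, B, method = "welch",
                                     log = TRUE, exclude = NULL) {
  stopifnot(length(recordings) >= 1)
  if (!is.null(exclude)) recordings <- recordings[!exclude]
  specs <- lapply(recordings, power_spectrum, method = method)
  n_pts <- length(specs[[1]]$power)
  scheme <- make_binning(n_pts, max(specs[[1]]$freqs), B)
  rows <- lapply(specs, function(s) {
    bs <- bin_spectrum(s, scheme)
    if (log) bs <- log_transform(bs)
    bs$values
  })
  spectrum_ensemble(
    do.call(rbind, rows),
    as.POSIXct(vapply(recordings, function(r) as.numeric(r$timestamp),
                      numeric(1)), origin = "1970-01-01", tz = ""),
    site_id = recordings[[1]]$site_id, scheme = scheme,
    scale = if (log) "log" else "linear",
    provenance = c("bin", if (log) "log")
  )
}

#' Write / read a spectrum ensemble as delimited text
#'
#' The container is a TSV with a `# key: value` header block (site, scale,
#' nyquist, bin edges, provenance) followed by one row per recording
#' (ISO-8601 timestamp + B bin values). Missing values are empty fields.
#'
#' @param ensemble A [spectrum_ensemble].
#' @param path Output path.
#' @return `path` invisibly (`write_ensemble`); a [spectrum_ensemble]
#'   (`read_ensemble`).
#' @export
write_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# site_id: ", ensemble$site_id),
    paste0("# scale: ", ensemble$scale),
    paste0("# nyquist: ", format(ensemble$scheme$nyquist, digits = 17)),
    paste0("# n_points: ", ensemble$scheme$n_points),
    paste0("# edges: ", paste(format(ensemble$scheme$edges, digits = 17),
                              collapse = ",")),
    paste0("# provenance: ", paste(ensemble$provenance, collapse = ";"))
  ), con)
  df <- data.frame(timestamp = format(ensemble$timestamps, "%Y-%m-%dT%H:%M:%S"))
  df <- cbind(df, as.data.frame(ensemble$values))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    sub(paste0("^# ", key, ": "), "",
        grep(paste0("^# ", key, ": "), hdr, value = TRUE))
  }
  body <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                            sep = "\t", header = TRUE, na.strings = "")
  values <- as.matrix(body[, -1, drop = FALSE])
  dimnames(values) <- NULL
  B <- ncol(values)
  n_points <- as.integer(get("n_points"))
  scheme <- make_binning(n_points, as.numeric(get("nyquist")), B)
  prov <- get("provenance")
  spectrum_ensemble(
    values,
    as.POSIXct(body$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = ""),
    site_id = get("site_id"), scheme = scheme, scale = get("scale"),
    provenance = if (nzchar(prov)) strsplit(prov, ";")[[1]] else character()
  )
}
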