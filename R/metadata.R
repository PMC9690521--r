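#' Parse site and timestamp metadata from a recording filename
#'
#' Filenames from scheduled recorders conventionally encode the site label and
#' the recording start time, e.g. `S01_20190507_120000.wav`. The template
#' language has two placeholders: `{site}` (any non-empty label) and
#' `{datetime}` (a `YYYYMMDD_HHMMSS` stamp). Everything else in the template
#' is matched literally.
#'
#' @param filename File name (directories are stripped).
#' @param pattern Template containing `{site}` and `{datetime}`. Default
#'   matches `SITE_YYYYMMDD_HHMMSS.wav`.
#' @return A list with `site_id` (character) and `timestamp` (`POSIXct`,
#'   naive local time).
#' @examples
#' parse_metadata("S01_20190507_120000.wav")
#' @export
parse_metadata <- function(filename, pattern = "{site}_{datetime}.wav") {
  filename <- basename(filename)
  if (!grepl("{site}", pattern, fixed = TRUE) ||
      !grepl("{datetime}", pattern, fixed = TRUE)) {
    stop("pattern must contain {site} and {datetime} placeholders: ", pattern,
         call. = FALSE)
  }
  rx <- gsub("([][(){}+*^$|\\\\?.])", "\\\\\\1", pattern)
  rx <- sub("\\{site\\}", "(.+?)", rx, fixed = TRUE)
  rx <- sub("\\{datetime\\}", "([0-9]{8}_[0-9]{6})", rx, fixed = TRUE)
  rx <- paste0("^", rx, "$")
  m <- regmatches(filename, regexec(rx, filename))[[1]]
  if (length(m) != 3) {
    stop("filename does not match metadata pattern\n  pattern:  ", pattern,
         "\n  filename: ", filename, call. = FALSE)
  }
  # placeholder order in the template decides which capture is which
  site_first <- regexpr("{site}", pattern, fixed = TRUE) <
    regexpr("{datetime}", pattern, fixed = TRUE)
  site <- if (site_first) m[2] else m[3]
  dt <- if (site_first) m[3] else m[2]
  ts <- as.POSIXct(dt, format = "%Y%m%d_%H%M%S", tz = "")
  if (is.na(ts)) {
    stop("unparseable datetime field '", dt, "' in filename: ", filename,
         call. = FALSE)
  }
  list(site_id = site, timestamp = ts)
}

#' Index a directory of WAV recordings
#'
#' Walks `root` recursively, parses site/timestamp metadata from every `.wav`
#' filename, and returns a sorted index. Files whose names do not match the
#' template are reported with a warning and skipped, never fatal.
#'
#' @param root Directory containing the recordings.
#' @param pattern Filename template, see [parse_metadata()].
#' @param read_durations If `TRUE`, open each file to record its duration
#'   (seconds); otherwise durations are `NA`.
#' @return A `recording_index`: data frame with columns `site_id`,
#'   `timestamp`, `path`, `duration_s`, sorted by `(site_id, timestamp)`.
#' @export
build_index <- function(root, pattern = "{site}_{datetime}.wav",
                        read_durations = FALSE) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  paths <- list.files(root, pattern = "\\.wav$", ignore.case = TRUE,
                      recursive = TRUE, full.names = TRUE)
  if (length(paths) == 0) {
    warning("no WAV files found under ", root)
    idx <- data.frame(site_id = character(), timestamp = as.POSIXct(character()),
                      path = character(), duration_s = numeric())
    class(idx) <- c("recording_index", class(idx))
    return(idx)
  }
  meta <- lapply(paths, function(p) {
    tryCatch(parse_metadata(p, pattern), error = function(e) NULL)
  })
  bad <- vapply(meta, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " file(s) did not match the metadata pattern and were ",
            "skipped: ", paste(utils::head(basename(paths[bad]), 5),
                               collapse = ", "),
            if (sum(bad) > 5) ", ...")
  }
  paths <- paths[!bad]
  meta <- meta[!bad]
  idx <- data.frame(
    site_id = vapply(meta, `[[`, character(1), "site_id"),
    timestamp = as.POSIXct(vapply(meta, function(m) as.numeric(m$timestamp),
                                  numeric(1)), origin = "1970-01-01", tz = ""),
    path = paths,
    duration_s = NA_real_
  )
  if (read_durations) {
    idx$duration_s <- vapply(paths, function(p) {
      rec <- read_wav(p)
      rec$duration
    }, numeric(1))
  }
  key <- paste(idx$site_id, format(idx$timestamp, "%Y%m%d%H%M%S"))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (site, timestamp) entries:\n  ",
         paste(idx$path[key == d], collapse = "\n  "), call. = FALSE)
  }
  idx <- idx[order(idx$site_id, idx$timestamp), , drop = FALSE]
  rownames(idx) <- NULL
  class(idx) <- c("recording_index", class(idx))
  idx
}

#' Summarise a recording index
#'
#' Dataset bookkeeping for fixed-length scheduled recordings: with `n`
#' recordings of `recording_length_min` minutes each, total minutes are
#' `n * recording_length_min` and total days that figure divided by 1440,
#' rounded to whole days.
#'
#' @param index A `recording_index` from [build_index()], or a plain count of
#'   recordings.
#' @param recording_length_min Nominal recording length in minutes (> 0).
#' @return A list with `n_recordings`, `recording_length_min`,
#'   `total_minutes`, `total_days`, `n_sites`, `date_range`.
#' @examples
#' summarize_index(130017, recording_length_min = 3)
#' @export
summarize_index <- function(index, recording_length_min = 3) {
  stopifnot(recording_length_min > 0)
  if (is.numeric(index) && length(index) == 1) {
    n <- as.numeric(index)
    n_sites <- NA_integer_
    date_range <- c(NA, NA)
  } else {
    n <- nrow(index)
    n_sites <- length(unique(index$site_id))
    date_range <- if (n > 0) range(index$timestamp) else c(NA, NA)
  }
  total_minutes <- n * recording_length_min
  structure(
    list(n_recordings = n,
         recording_length_min = recording_length_min,
         total_minutes = total_minutes,
         total_days = round(total_minutes / 1440),
         n_sites = n_sites,
         date_range = date_range),
    class = "dataset_summary"
  )
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary> %s recordings x %g min = %s min (%s days)",
              format(x$n_recordings, big.mark = ","), x$recording_length_min,
              format(x$total_minutes, big.mark = ","),
              format(x$total_days, big.mark = ",")))
  if (!is.na(x$n_sites)) cat(sprintf(", %d site(s)", x$n_sites))
  cat("\n")
  invisible(x)
}

#' Write a recording index (with optional QC flags) as delimited text
#'
#' One row per recording: `site_id`, ISO-8601 timestamp, path, duration and
#' any flag columns present.
#'
#' @param index A `recording_index`, optionally with extra flag columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  out <- as.data.frame(index)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
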