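#' Read a WAV recording
#'
#' Reads a RIFF/WAVE file containing integer PCM (16-bit) or IEEE float
#' (32-bit) samples and returns an [audio_recording] with samples scaled to
#' `[-1, 1]`. Multi-channel files are averaged to mono when `mixdown = TRUE`
#' (the default), matching single-point recorder deployments.
#'
#' 16-bit samples are scaled by 1/32768, so full positive scale maps to
#' 32767/32768 and full negative scale to -1.
#'
#' @param path Path to a `.wav` file.
#' @param mixdown Average channels to mono? If `FALSE`, a multi-channel file
#'   is an error.
#' @param site_id,timestamp Optional metadata attached to the recording;
#'   usually filled in by [parse_metadata()] / [build_index()].
#' @return An [audio_recording].
#' @seealso [write_wav()], [parse_metadata()], [build_index()]
#' @export
read_wav <- function(path, mixdown = TRUE, site_id = NA_character_,
                     timestamp = as.POSIXct(NA)) {
  if (!file.exists(path)) {
    stop("cannot read WAV file (no such file): ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  readBin(con, "integer", 1, size = 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                             endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) {
        stop("truncated WAV data chunk in: ", path, call. = FALSE)
      }
    } else {
      seek(con, size + size %% 2, origin = "current")
      next
    }
    if (size %% 2 == 1) seek(con, 1, origin = "current")
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("truncated or malformed WAV file (missing fmt/data chunk): ", path,
         call. = FALSE)
  }

  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) %/% 4, size = 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ", ",
         fmt$bits, " bit) in: ", path, call. = FALSE)
  }

  if (fmt$n_channels > 1L) {
    if (!mixdown) {
      stop("multi-channel WAV and mixdown = FALSE: ", path, call. = FALSE)
    }
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }

  audio_recording(x, fmt$sample_rate, site_id = site_id,
                  timestamp = timestamp, source_path = path)
}

#' Write samples to a 16-bit PCM WAV file
#'
#' Quantises with the same 1/32768 full-scale convention [read_wav()] uses,
#' so representable samples round-trip bit-exactly.
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) >= 1, sample_rate > 0)
  pcm <- as.integer(pmax(pmin(round(samples * 32768), 32767), -32768))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")      # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")     # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Construct an audio recording
#'
#' Container for one fixed-length recording: mono samples in `[-1, 1]`, the
#' sampling rate, and site/timestamp metadata.
#'
#' @param samples Numeric vector of mono PCM samples.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param site_id Site label.
#' @param timestamp Recording start time (`POSIXct`, naive local time).
#' @param source_path Originating file, if any.
#' @return Object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate, site_id = NA_character_,
                            timestamp = as.POSIXct(NA), source_path = NA_character_) {
  stopifnot(is.numeric(samples), sample_rate > 0, all(is.finite(samples)))
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         duration = length(samples) / sample_rate,
         site_id = site_id, timestamp = timestamp, source_path = source_path),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> site=%s  %s  %.2f s @ %d Hz (%d samples)\n",
              x$site_id, format(x$timestamp), x$duration,
              as.integer(x$sample_rate), length(x$samples)))
  invisible(x)
}
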