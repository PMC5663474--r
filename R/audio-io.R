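#' Construct an audio recording
#'
#' The raw unit of field data: a mono amplitude series in \code{[-1, 1]}
#' together with its sample rate and optional survey metadata.
#'
#' @param samples Numeric vector of amplitudes, nominally in \code{[-1, 1]}.
#' @param sample_rate Sampling rate in Hz (integer, 8000--48000).
#' @param metadata Optional \code{\link{recording_metadata}} object.
#' @param source Optional character label (e.g. the source file path).
#'
#' @return An object of class \code{audio_recording} with fields
#'   \code{samples}, \code{sample_rate}, \code{duration_s}, \code{metadata}
#'   and \code{source}.
#' @export
audio_recording <- function(samples, sample_rate, metadata = NULL,
                            source = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("empty audio: recording contains no samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("audio samples must all be finite", call. = FALSE)
  sample_rate <- as.integer(sample_rate)
  if (is.na(sample_rate) || sample_rate < 8000L || sample_rate > 48000L)
    stop("sample_rate must be an integer in [8000, 48000] Hz", call. = FALSE)
  if (max(abs(samples)) > 1 + 1e-6)
    samples <- samples / max(abs(samples))
  if (!is.null(metadata) && !inherits(metadata, "recording_metadata"))
    stop("metadata must be a recording_metadata object", call. = FALSE)
  structure(
    list(samples = samples,
         sample_rate = sample_rate,
         duration_s = length(samples) / sample_rate,
         metadata = metadata,
         source = source),
    class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %.3f s at %d Hz (%d samples)\n",
              x$duration_s, x$sample_rate, length(x$samples)))
  if (!is.null(x$metadata)) print(x$metadata)
  invisible(x)
}

#' Survey metadata attached to a recording
#'
#' Phones register the time and place of a human--mosquito encounter
#' alongside the audio; these fields drive the location filter and the
#' temporal activity histograms. All fields are optional, but the location
#' filter requires a country (or coordinates resolvable to one).
#'
#' @param timestamp ISO-8601 datetime string or \code{POSIXct}, optional.
#' @param latitude,longitude Degrees WGS84, optional.
#' @param country ISO-3166 alpha-2 country code, optional.
#' @param device_label Free-text phone model label, optional.
#' @param capture_mode One of \code{"free_flight"}, \code{"cup"},
#'   \code{"bottle"}, \code{"bag"}, \code{"cage"}; optional.
#'
#' @return An object of class \code{recording_metadata}.
#' @seealso \code{\link{validate_metadata}}
#' @export
recording_metadata <- function(timestamp = NULL, latitude = NULL,
                               longitude = NULL, country = NULL,
                               device_label = NULL, capture_mode = NULL) {
  structure(
    list(timestamp = timestamp, latitude = latitude, longitude = longitude,
         country = country, device_label = device_label,
         capture_mode = capture_mode,
         naive_time = NA, location_filter_ok = NA, time_filter_ok = NA),
    class = "recording_metadata")
}

#' @export
print.recording_metadata <- function(x, ...) {
  parts <- c(
    if (!is.null(x$timestamp)) paste0("t=", format(x$timestamp)),
    if (!is.null(x$latitude)) sprintf("lat=%.4f lon=%.4f", x$latitude, x$longitude),
    if (!is.null(x$country)) paste0("country=", x$country),
    if (!is.null(x$device_label)) paste0("device=", x$device_label))
  cat("  metadata:", if (length(parts)) paste(parts, collapse = ", ") else "(empty)", "\n")
  invisible(x)
}

#' Validate and normalize recording metadata
#'
#' Range-checks coordinates, upper-cases country codes, parses timestamps,
#' and flags which downstream filters (location, time) the metadata can
#' support. Timestamps without a timezone are treated as local time of
#' recording and flagged naive.
#'
#' @param meta A \code{\link{recording_metadata}} object.
#' @return The normalized \code{recording_metadata}, with logical flags
#'   \code{location_filter_ok}, \code{time_filter_ok} and \code{naive_time}.
#' @export
validate_metadata <- function(meta) {
  stopifnot(inherits(meta, "recording_metadata"))
  has_coords <- !is.null(meta$latitude) || !is.null(meta$longitude)
  if (has_coords) {
    if (is.null(meta$latitude) || is.null(meta$longitude))
      stop("latitude and longitude must be given together", call. = FALSE)
    if (!is.finite(meta$latitude) || meta$latitude < -90 || meta$latitude > 90)
      stop("latitude out of range [-90, 90]", call. = FALSE)
    if (!is.finite(meta$longitude) || meta$longitude < -180 || meta$longitude > 180)
      stop("longitude out of range [-180, 180]", call. = FALSE)
  }
  if (!is.null(meta$country)) {
    meta$country <- toupper(trimws(meta$country))
    if (!grepl("^[A-Z]{2,3}$", meta$country))
      stop("country must be an ISO-3166 code (2-3 letters)", call. = FALSE)
  }
  meta$naive_time <- FALSE
  if (!is.null(meta$timestamp) && !inherits(meta$timestamp, "POSIXct")) {
    ts <- as.character(meta$timestamp)
    meta$naive_time <- !grepl("(Z|[+-][0-9]{2}:?[0-9]{2})$", ts)
    parsed <- tryCatch(
      as.POSIXct(ts, tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                "%Y-%m-%dT%H:%M", "%Y-%m-%d")),
      error = function(e) NA)
    if (is.na(parsed)) stop("unparseable timestamp: ", ts, call. = FALSE)
    meta$timestamp <- parsed
  }
  if (!is.null(meta$capture_mode)) {
    meta$capture_mode <- match.arg(meta$capture_mode,
                                   c("free_flight", "cup", "bottle", "bag", "cage"))
  }
  meta$location_filter_ok <- has_coords || !is.null(meta$country)
  meta$time_filter_ok <- !is.null(meta$timestamp)
  meta
}

#' Read a WAV file into an audio recording
#'
#' Parses RIFF/WAVE containers with PCM (8/16/24-bit integer) or IEEE-float
#' (32-bit) sample data. Multi-channel audio is averaged to mono; integer
#' samples are rescaled by the type's full-scale value so amplitudes land in
#' \code{[-1, 1]} without peak normalization (which would destroy relative
#' level estimates such as SNR).
#'
#' @param path Path to a WAV file.
#' @param metadata Optional \code{\link{recording_metadata}} to attach.
#' @return An \code{\link{audio_recording}}.
#' @export
read_wav <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF/WAV file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      if (length(fmt_raw) < 16L)
        stop("truncated fmt chunk in ", path, call. = FALSE)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, size = 2,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size)
        stop("truncated data chunk in ", path, call. = FALSE)
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  if (length(data_raw) == 0L)
    stop("empty audio: WAV data chunk has zero length", call. = FALSE)

  x <- decode_wav_samples(data_raw, fmt)
  if (fmt$n_channels > 1L) {
    n_per <- length(x) %/% fmt$n_channels
    x <- x[seq_len(n_per * fmt$n_channels)]
    x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  }
  audio_recording(x, fmt$sample_rate, metadata = metadata, source = path)
}

# Decode the raw data chunk to double amplitudes in [-1, 1].
decode_wav_samples <- function(raw, fmt) {
  n_bytes <- fmt$bits %/% 8L
  n <- length(raw) %/% n_bytes
  if (fmt$audio_format == 3L) {               # IEEE float
    if (fmt$bits != 32L) stop("only 32-bit float WAV supported", call. = FALSE)
    return(readBin(raw, "double", n, size = 4, endian = "little"))
  }
  if (fmt$audio_format != 1L)
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")",
         call. = FALSE)
  switch(as.character(fmt$bits),
    "8" = (readBin(raw, "integer", n, size = 1, signed = FALSE) - 128) / 128,
    "16" = readBin(raw, "integer", n, size = 2, endian = "little") / 32768,
    "24" = {
      m <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE))
}

#' Write an audio recording to a WAV file
#'
#' @param rec An \code{\link{audio_recording}}.
#' @param path Output path.
#' @param bit_depth 16 (PCM, default) or 32 (IEEE float).
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(rec, path, bit_depth = 16) {
  stopifnot(inherits(rec, "audio_recording"), bit_depth %in% c(16, 32))
  x <- pmin(1, pmax(-1, rec$samples))
  n <- length(x)
  fmt_tag <- if (bit_depth == 32) 3L else 1L
  block <- bit_depth %/% 8L
  data_size <- n * block
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rec$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Resample a recording up to a standard rate
#'
#' Field recordings arrive at rates from 8 to 44.1 kHz depending on the
#' phone; analysis standardizes on 44.1 kHz by band-limited polyphase
#' interpolation. Only upsampling is supported: downsampling would discard
#' spectral content.
#'
#' @param rec An \code{\link{audio_recording}}.
#' @param target_rate Target sampling rate in Hz (default 44100).
#' @return An \code{\link{audio_recording}} at \code{target_rate}; the input
#'   is returned unchanged when already at the target rate.
#' @export
resample_to_standard <- function(rec, target_rate = 44100) {
  stopifnot(inherits(rec, "audio_recording"))
  target_rate <- as.integer(target_rate)
  if (target_rate == rec$sample_rate) return(rec)
  if (target_rate < rec$sample_rate)
    stop("downsampling not supported (target ", target_rate,
         " < source ", rec$sample_rate, " Hz)", call. = FALSE)
  g <- gcd_int(target_rate, rec$sample_rate)
  y <- signal::resample(rec$samples, p = target_rate %/% g,
                        q = rec$sample_rate %/% g)
  y <- pmin(1, pmax(-1, y))
  audio_recording(y, target_rate, metadata = rec$metadata, source = rec$source)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)
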