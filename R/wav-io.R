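#' Read a mono RIFF/WAVE file
#'
#' Minimal WAV reader for the formats contact-call recordings come in:
#' integer PCM (16- or 24-bit) and IEEE float (32-bit).  Samples are
#' returned as amplitudes in `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @param channel For multi-channel files, the 1-based channel to keep.
#'   The default (`NA`) refuses multi-channel input with an error, so that
#'   a stereo recording is never averaged or truncated silently.
#' @return A list with `waveform` (numeric vector in `[-1, 1]`),
#'   `sample_rate_hz`, and `bit_depth`.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, channel = NA) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2)
      fmt <- list(
        audio_format = .le_uint(body[1:2]),
        n_channels   = .le_uint(body[3:4]),
        sample_rate  = .le_uint(body[5:8]),
        bit_depth    = .le_uint(body[15:16])
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("no fmt chunk in ", path)
  if (is.null(data_raw)) stop("no data chunk in ", path)

  bytes_per <- fmt$bit_depth / 8
  n_total <- length(data_raw) %/% bytes_per
  x <- switch(
    as.character(fmt$bit_depth),
    "16" = {
      if (fmt$audio_format != 1L) stop("16-bit WAV must be integer PCM")
      readBin(data_raw, "integer", n_total, 2, signed = TRUE,
              endian = "little") / 32768
    },
    "24" = {
      if (fmt$audio_format != 1L) stop("24-bit WAV must be integer PCM")
      .decode_pcm24(data_raw, n_total)
    },
    "32" = {
      if (fmt$audio_format != 3L) stop("32-bit WAV must be IEEE float")
      readBin(data_raw, "double", n_total, 4, endian = "little")
    },
    stop("unsupported bit depth: ", fmt$bit_depth)
  )

  if (fmt$n_channels > 1L) {
    if (is.na(channel)) {
      stop(sprintf("%s has %d channels; select one with `channel=`",
                   path, fmt$n_channels))
    }
    if (channel < 1 || channel > fmt$n_channels) stop("bad channel index")
    x <- x[seq(channel, length(x), by = fmt$n_channels)]
  }
  list(waveform = x, sample_rate_hz = fmt$sample_rate,
       bit_depth = fmt$bit_depth)
}

#' Write a mono WAV file
#'
#' @param waveform Numeric amplitudes; values outside `[-1, 1]` are clipped.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param path Output path.
#' @param bit_depth 16 or 24 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate_hz, path, bit_depth = 16) {
  stopifnot(is.numeric(waveform), length(waveform) > 0,
            sample_rate_hz > 0, bit_depth %in% c(16, 24, 32))
  x <- pmin(1, pmax(-1, waveform))
  bytes_per <- bit_depth / 8
  n_bytes <- length(x) * bytes_per
  audio_format <- if (bit_depth == 32) 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(audio_format, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bit_depth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, 4, endian = "little")
  if (bit_depth == 16) {
    writeBin(as.integer(round(x * 32767)), con, 2, endian = "little")
  } else if (bit_depth == 24) {
    v <- as.integer(round(x * 8388607))
    v[v < 0] <- v[v < 0] + 16777216L
    b <- integer(3 * length(v))
    b[seq(1, length(b), 3)] <- v %% 256L
    b[seq(2, length(b), 3)] <- (v %/% 256L) %% 256L
    b[seq(3, length(b), 3)] <- (v %/% 65536L) %% 256L
    writeBin(as.raw(b), con)
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}

# little-endian unsigned integer from raw bytes
.le_uint <- function(b) sum(as.integer(b) * 256^(seq_along(b) - 1))

.decode_pcm24 <- function(raw, n) {
  b <- as.integer(raw)
  i <- seq_len(n)
  v <- b[3 * i - 2] + 256 * b[3 * i - 1] + 65536 * b[3 * i]
  v[v >= 8388608] <- v[v >= 8388608] - 16777216
  v / 8388608
}
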