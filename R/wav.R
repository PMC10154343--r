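# Minimal RIFF/WAVE reader and writer (mono or first channel of
# multichannel; PCM 16/24-bit and IEEE float32).  Kept deliberately small:
# enough to round-trip stimuli and impulse responses.

#' Read a WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float 32-bit encodings.  For
#' multichannel files only the first channel is returned.  Samples are
#' scaled to \[-1, 1\] for PCM encodings.
#'
#' @param path path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(riff, "RIFF"), "not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(wave, "WAVE"), "not a WAVE file")

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  assert_that(!is.null(fmt) && !is.null(data_raw), "malformed WAV: missing fmt or data chunk")

  x <- switch(
    as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) / 3
      m <- matrix(as.integer(data_raw), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v[v >= 2^23] <- v[v >= 2^23] - 2^24
      v[seq_len(n)] / 2^23
    },
    "32" = {
      assert_that(fmt$audio_format == 3, "32-bit WAV must be IEEE float")
      readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
    },
    stop("unsupported WAV bit depth: ", fmt$bits, call. = FALSE)
  )
  if (fmt$n_channels > 1) x <- x[seq(1, length(x), by = fmt$n_channels)]
  audio_signal(x, fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param signal an [audio_signal()].
#' @param path output path.
#' @param bits 16 (PCM, samples clipped to \[-1, 1\]) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 32) {
  assert_that(inherits(signal, "audio_signal"), "signal must be an audio_signal")
  assert_that(bits %in% c(16, 32), "bits must be 16 or 32")
  x <- signal$samples
  fs <- as.integer(round(signal$sample_rate))
  bytes_per <- bits / 8
  data_size <- as.integer(length(x) * bytes_per)
  fmt_code <- if (bits == 32) 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(fs, con, 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmin(pmax(x, -1), 1) * 32767)), con, 2, endian = "little")
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}
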