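#' Write a waveform to a PCM WAV file
#'
#' Minimal RIFF/WAVE writer covering the two encodings used by full-spectrum
#' acoustic loggers: 16-bit integer PCM and 32-bit IEEE float. Samples are
#' expected on a nominal \[-1, 1\] scale; 16-bit output clips values outside
#' that range.
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param path Output file path.
#' @param encoding `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @seealso [read_wav()], [audiomoth_filename()]
#' @export
write_wav <- function(samples, sample_rate_hz, path,
                      encoding = c("pcm16", "float32")) {
  encoding <- match.arg(encoding)
  stopifnot(is.numeric(samples), length(samples) > 0L)
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 1)
  bits <- if (encoding == "pcm16") 16L else 32L
  fmt <- if (encoding == "pcm16") 1L else 3L
  block <- bits %/% 8L
  data_bytes <- length(samples) * block
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (encoding == "pcm16") {
    x <- pmin(pmax(samples, -1), 1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono PCM WAV file
#'
#' Counterpart of [write_wav()]; accepts 16-bit integer PCM and 32-bit float
#' mono files and returns the waveform rescaled to \[-1, 1\] (for PCM).
#'
#' @param path WAV file path.
#' @return A list with `samples` and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop_carollia("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop_carollia("not a WAVE file: ", path)
  fmt_tag <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop_carollia("no data chunk in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_tag <- readBin(con, integer(), size = 2, endian = "little")
      n_chan <- readBin(con, integer(), size = 2, endian = "little")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16L) invisible(readBin(con, raw(), n = size - 16L))
      if (n_chan != 1L) stop_carollia("only mono WAV supported")
    } else if (id == "data") {
      if (is.null(fmt_tag)) stop_carollia("data chunk before fmt chunk")
      if (fmt_tag == 1L && bits == 16L) {
        x <- readBin(con, integer(), n = size %/% 2L, size = 2,
                     signed = TRUE, endian = "little") / 32767
      } else if (fmt_tag == 3L && bits == 32L) {
        x <- readBin(con, numeric(), n = size %/% 4L, size = 4,
                     endian = "little")
      } else {
        stop_carollia("unsupported WAV encoding (fmt ", fmt_tag, ", ",
                      bits, " bit)")
      }
      return(list(samples = x, sample_rate_hz = sr))
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
}

#' AudioMoth-style timestamped filename
#'
#' @param time A `POSIXct` timestamp (local time).
#' @return Filename of the form `YYYYMMDD_HHMMSS.WAV`.
#' @export
audiomoth_filename <- function(time) {
  format(time, "%Y%m%d_%H%M%S.WAV")
}
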