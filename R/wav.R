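#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader supporting IEEE 32-bit float (format 3) and
#' 16-bit PCM (format 1) mono files, the two encodings this package writes
#' or is expected to ingest.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `audio` (numeric vector in -1..1) and `fs`
#'   (sample rate, samples/s).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  audio <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        format    = readBin(raw_fmt[1:2], "integer", 1, size = 2,
                            endian = "little", signed = FALSE),
        channels  = readBin(raw_fmt[3:4], "integer", 1, size = 2,
                            endian = "little", signed = FALSE),
        fs        = readBin(raw_fmt[5:8], "integer", 1, size = 4,
                            endian = "little"),
        bits      = readBin(raw_fmt[15:16], "integer", 1, size = 2,
                            endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1L) stop("only mono WAV is supported")
      if (fmt$format == 3L && fmt$bits == 32L) {
        audio <- readBin(con, "double", size, size = 4, endian = "little")
        audio <- audio[seq_len(size %/% 4L)]
      } else if (fmt$format == 1L && fmt$bits == 16L) {
        raw16 <- readBin(con, "integer", size %/% 2L, size = 2,
                         endian = "little")
        audio <- raw16 / 32768
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bits)")
      }
      if (size %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(audio)) break
  }
  if (is.null(audio)) stop("no data chunk found in ", path)
  list(audio = as.numeric(audio), fs = fmt$fs)
}

#' Write a mono WAV file (IEEE 32-bit float)
#'
#' Float encoding is used so that write/read round trips are lossless up to
#' float32 precision (no 16-bit quantization).
#'
#' @param audio Numeric vector, nominally in -1..1.
#' @param fs Sample rate (samples/s).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, fs, path) {
  if (anyNA(audio)) stop("audio contains missing values")
  n <- length(audio)
  data_size <- n * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")     # IEEE float
  writeBin(1L, con, size = 2, endian = "little")     # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")     # block align
  writeBin(32L, con, size = 2, endian = "little")    # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(as.numeric(audio), con, size = 4, endian = "little")
  invisible(path)
}
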