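#' Read and write mono WAV files
#'
#' Minimal RIFF/WAVE support for the formats the package produces: mono
#' 16-bit PCM or 32-bit IEEE float. `writeWav()` clips samples to
#' \[-1, 1\] when writing PCM.
#'
#' @param x numeric waveform in \[-1, 1\].
#' @param sampleRate samples per second.
#' @param path file path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `readWav()` returns `list(waveform, sampleRate)`; `writeWav()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWav(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000, f)
#' w <- readWav(f)
#' w$sampleRate
#' @export
writeWav <- function(x, sampleRate, path, bits = 16L) {
  stopifnot(is.numeric(x), length(x) > 0, sampleRate > 0)
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32")
  con <- file(path, "wb")
  on.exit(close(con))
  nBytes <- length(x) * bits / 8L
  fmt <- if (bits == 16L) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nBytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * bits / 8L), con, size = 4, endian = "little")
  writeBin(as.integer(bits / 8L), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nBytes), con, size = 4, endian = "little")
  if (bits == 16L) {
    s <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    writeBin(s, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname writeWav
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audioFormat = readBin(con, "integer", size = 2, endian = "little"),
        channels = readBin(con, "integer", size = 2, endian = "little"),
        sampleRate = readBin(con, "integer", size = 4, endian = "little"),
        byteRate = readBin(con, "integer", size = 4, endian = "little"),
        blockAlign = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little"))
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", n = extra))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      if (fmt$channels != 1L) stop("only mono WAV is supported")
      n <- size %/% (fmt$bits %/% 8L)
      x <- if (fmt$bits == 16L) {
        readBin(con, "integer", n = n, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else if (fmt$bits == 32L && fmt$audioFormat == 3L) {
        readBin(con, "numeric", n = n, size = 4, endian = "little")
      } else stop("unsupported WAV sample format")
      return(list(waveform = x, sampleRate = fmt$sampleRate))
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
}
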