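# Minimal RIFF/WAVE I/O (IEEE float32 write; float32/float64/PCM16 read).
# Carried in-package because no WAV-capable R package is available in the
# analysis environment; the format subset here is the one the toolkit emits.

#' Write a multichannel WAV file (IEEE float32)
#'
#' @param samples numeric matrix, channels x samples (a vector is treated as
#'   one channel).
#' @param path output file path.
#' @param fs_hz sample rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, fs_hz) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  stopifnot_scalar_num(fs_hz, "fs_hz", positive = TRUE)
  n_ch <- nrow(samples)
  n <- ncol(samples)
  data_bytes <- n * n_ch * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")        # IEEE float
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(round(fs_hz)), con, size = 4, endian = "little")
  writeBin(as.integer(round(fs_hz) * n_ch * 4L), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 4L), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  # interleave: column-major flatten of ch x n matrix is already interleaved
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a WAV file
#'
#' Supports IEEE float32/float64 and 16-bit PCM, the subsets this toolkit
#' writes or is expected to ingest.
#'
#' @param path WAV file path.
#' @return list with `samples` (channels x samples matrix) and `fs_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) {
      stop("WAV file ", path, " has no data chunk", call. = FALSE)
    }
    sz <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1L, size = 2, endian = "little"),
        n_ch   = readBin(con, "integer", 1L, size = 2, endian = "little"),
        fs     = readBin(con, "integer", 1L, size = 4, endian = "little"),
        brate  = readBin(con, "integer", 1L, size = 4, endian = "little"),
        align  = readBin(con, "integer", 1L, size = 2, endian = "little"),
        bits   = readBin(con, "integer", 1L, size = 2, endian = "little"))
      if (sz > 16L) invisible(readBin(con, "raw", sz - 16L))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("WAV data chunk precedes fmt chunk", call. = FALSE)
      bytes_per <- fmt$bits %/% 8L
      n_total <- sz %/% bytes_per
      x <- if (fmt$format == 3L) {
        readBin(con, "numeric", n_total, size = bytes_per, endian = "little")
      } else if (fmt$format == 1L && fmt$bits == 16L) {
        readBin(con, "integer", n_total, size = 2L, signed = TRUE,
                endian = "little") / 32768
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bit) in ", path, call. = FALSE)
      }
      return(list(samples = matrix(x, nrow = fmt$n_ch), fs_hz = fmt$fs))
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
}
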