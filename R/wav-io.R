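#' Read a mono WAV file
#'
#' Parses RIFF/WAVE files holding mono 16-bit PCM or 32-bit IEEE float data.
#' Anything else (multichannel audio, other encodings) is rejected with an
#' error naming the offending property rather than silently converted.
#'
#' @param path Path to a WAV file.
#' @return A [wave_signal()]. Float samples are returned as stored; PCM16
#'   samples are scaled to \[-1, 1\] by 1/32768.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("read_wav: not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("read_wav: not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format     = readBin(body[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels   = readBin(body[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits       = readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)  # skip unknown chunk
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1)  # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("read_wav: missing fmt or data chunk in ", path)
  if (fmt$channels != 1L)
    stop(sprintf("read_wav: only mono supported, file has %d channels", fmt$channels))

  if (fmt$format == 3L && fmt$bits == 32L) {
    samples <- readBin(data_raw, "double", length(data_raw) / 4, size = 4, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    samples <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                       endian = "little") / 32768
  } else {
    stop(sprintf(
      "read_wav: unsupported encoding (format tag %d, %d bits); expected PCM16 or float32",
      fmt$format, fmt$bits))
  }
  wave_signal(samples, fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' Writes RIFF/WAVE, mono, 32-bit IEEE float by default (bit-exact round trip)
#' or 16-bit PCM. The file is written to a temporary sibling and renamed into
#' place, so an interrupted run never leaves a truncated WAV behind.
#'
#' @param w A [wave_signal()].
#' @param path Output path.
#' @param bit_depth \code{"float32"} (default) or \code{"pcm16"}.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(w, path, bit_depth = c("float32", "pcm16")) {
  stopifnot(inherits(w, "wave_signal"))
  bit_depth <- match.arg(bit_depth)
  sr <- as.integer(round(w$sample_rate))
  n <- length(w$samples)

  if (bit_depth == "float32") {
    fmt_tag <- 3L; bits <- 32L
    data_size <- 4L * n
  } else {
    fmt_tag <- 1L; bits <- 16L
    data_size <- 2L * n
  }
  block_align <- as.integer(bits / 8)
  fact_size <- if (fmt_tag == 3L) 12L else 0L  # non-PCM files carry a fact chunk
  riff_size <- 4L + 24L + fact_size + 8L + data_size

  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, "wb")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok) unlink(tmp)
  })

  writeChar("RIFF", con, eos = NULL)
  writeBin(riff_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * block_align, con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  if (fmt_tag == 3L) {
    writeChar("fact", con, eos = NULL)
    writeBin(4L, con, size = 4, endian = "little")
    writeBin(n, con, size = 4, endian = "little")
  }
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  if (bit_depth == "float32") {
    writeBin(w$samples, con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(w$samples * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  }
  close(con)
  on.exit()
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("write_wav: cannot write ", path)
  }
  ok <- TRUE
  invisible(path)
}
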