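# Reading and writing I/Q recordings as 2-channel RIFF PCM WAV files.
#
# Channel convention (fixed, documented): channel 0 carries I (real part),
# channel 1 carries Q (imaginary part). Integer PCM is scaled by 2^(bits-1)
# so the full negative rail maps exactly to -1.0. 8-bit WAV uses the standard
# unsigned-with-128-offset encoding. Capture metadata lives in a JSON sidecar
# `<name>.meta.json` rather than WAV tags.

read_chunk_header <- function(con) {
  id <- rawToChar(readBin(con, "raw", n = 4))
  size <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(size) == 0) return(NULL)
  list(id = id, size = size)
}

#' Read an I/Q recording from a 2-channel WAV file
#'
#' Reads a RIFF WAV file holding a baseband I/Q capture (channel 0 = I,
#' channel 1 = Q) into an [iq_recording]. Integer PCM samples (8 or 16 bit)
#' are scaled by `1 / 2^(bits - 1)`; 32/64-bit IEEE float WAVs are accepted
#' read-only. The sample rate is taken from the WAV header — it is honoured
#' as-is, never assumed to be the SDR's nominal 192 kHz. Metadata fields are
#' merged from the JSON sidecar when present.
#'
#' @param path Path to the WAV file.
#' @param sidecar Optional path to the JSON metadata sidecar; by default
#'   `<path without .wav>.meta.json` is used when it exists.
#' @return An [iq_recording].
#' @seealso [write_iq_wav()]
#' @export
read_iq_wav <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("I/Q WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- rawToChar(readBin(con, "raw", n = 4))
  readBin(con, "integer", n = 1, size = 4, endian = "little")
  wave <- rawToChar(readBin(con, "raw", n = 4))
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    hdr <- read_chunk_header(con)
    if (is.null(hdr) || length(hdr$id) == 0 || !nzchar(hdr$id)) break
    if (hdr$id == "fmt ") {
      body <- readBin(con, "raw", n = hdr$size)
      fmt <- list(
        code      = readBin(body[1:2], "integer", size = 2, endian = "little", signed = FALSE),
        channels  = readBin(body[3:4], "integer", size = 2, endian = "little", signed = FALSE),
        rate      = readBin(body[5:8], "integer", size = 4, endian = "little"),
        bits      = readBin(body[15:16], "integer", size = 2, endian = "little", signed = FALSE))
    } else if (hdr$id == "data") {
      data_raw <- readBin(con, "raw", n = hdr$size)
    } else {
      readBin(con, "raw", n = hdr$size + (hdr$size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw)) stop("WAV file has no data chunk: ", path)
  if (fmt$channels != 2)
    stop("expected a 2-channel I/Q WAV, got ", fmt$channels, " channel(s): ", path)

  if (fmt$code == 1L) {            # integer PCM
    if (fmt$bits == 16L) {
      v <- readBin(data_raw, "integer", n = length(data_raw) / 2L,
                   size = 2, endian = "little") / 32768
    } else if (fmt$bits == 8L) {
      v <- (as.integer(data_raw) - 128L) / 128
    } else {
      stop("unsupported PCM bit depth: ", fmt$bits)
    }
  } else if (fmt$code == 3L) {     # IEEE float, read-only convenience
    if (fmt$bits == 32L) {
      v <- readBin(data_raw, "numeric", n = length(data_raw) / 4L,
                   size = 4, endian = "little")
    } else if (fmt$bits == 64L) {
      v <- readBin(data_raw, "numeric", n = length(data_raw) / 8L,
                   size = 8, endian = "little")
    } else stop("unsupported float bit depth: ", fmt$bits)
  } else {
    stop("unsupported (non-PCM) WAV encoding, format code ", fmt$code)
  }

  n <- length(v) %/% 2L
  if (n == 0) stop("WAV file contains no samples: ", path)
  samples <- complex(real = v[seq(1, 2 * n, by = 2)],
                     imaginary = v[seq(2, 2 * n, by = 2)])

  meta <- list()
  if (is.null(sidecar)) {
    cand <- sidecar_path(path)
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar) && file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  iq_recording(samples, sample_rate_hz = fmt$rate,
               center_frequency_hz = meta$center_frequency_hz %||% NA_real_,
               source_bit_depth = if (fmt$code == 1L) fmt$bits else NA_integer_,
               label = meta$label %||% "")
}

sidecar_path <- function(path) paste0(sub("\\.wav$", "", path, ignore.case = TRUE),
                                      ".meta.json")

#' Write an I/Q recording as a 2-channel PCM WAV file
#'
#' Writes channel 0 = Re, channel 1 = Im, scaled by `2^(bit_depth - 1)` and,
#' when `clip = TRUE`, clipped to the integer range. A JSON sidecar
#' `<name>.meta.json` with the centre frequency and label is written beside
#' the WAV. A 16-bit round trip through [read_iq_wav()] preserves every
#' sample within one quantisation step (`2^-15` per component).
#'
#' @param rec An [iq_recording].
#' @param path Output WAV path.
#' @param bit_depth 8 or 16.
#' @param clip Clip out-of-range samples to full scale instead of erroring.
#' @return `path`, invisibly.
#' @export
write_iq_wav <- function(rec, path, bit_depth = 16, clip = TRUE) {
  stopifnot(inherits(rec, "iq_recording"))
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  v <- as.vector(rbind(Re(rec$samples), Im(rec$samples)))
  if (!clip && any(abs(v) > 1))
    stop("samples out of [-1, 1] range and clipping disabled")
  full <- 2^(bit_depth - 1)
  q <- pmin(pmax(round(v * full), -full), full - 1)

  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(q) * (bit_depth / 8)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(2L, con, size = 2, endian = "little")          # channels
  writeBin(as.integer(rec$sample_rate_hz), con, size = 4, endian = "little")
  byte_rate <- as.integer(rec$sample_rate_hz * 2 * bit_depth / 8)
  writeBin(byte_rate, con, size = 4, endian = "little")
  writeBin(as.integer(2 * bit_depth / 8), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    writeBin(as.integer(q), con, size = 2, endian = "little")
  } else {
    writeBin(as.raw(q + 128), con)
  }

  meta <- list(center_frequency_hz = rec$center_frequency_hz,
               label = rec$label,
               sample_rate_hz = rec$sample_rate_hz,
               bit_depth = bit_depth)
  meta <- meta[!vapply(meta, function(x) length(x) == 1 && is.na(x), logical(1))]
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
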