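#' In-memory I/Q recording
#'
#' The unit of exchange between the synthetic renderer and the decoder: a
#' complex baseband sample stream in dimensionless full-scale units (each
#' component in `[-1, 1)` once round-tripped through integer PCM), its sample
#' rate, and capture metadata.
#'
#' @param samples Complex vector of baseband samples (I = real, Q = imaginary).
#' @param sample_rate_hz Sampling rate in samples/second (> 0).
#' @param center_frequency_hz Demodulation (centre) frequency of the capture in
#'   Hz; informational only.
#' @param source_bit_depth Integer bit depth the samples came from (8 or 16),
#'   or `NA` when unknown / never quantised.
#' @param label Free-text label.
#'
#' @return An object of class `iq_recording`.
#' @examples
#' rec <- iq_recording(complex(real = rnorm(100), imaginary = rnorm(100)) / 10,
#'                     sample_rate_hz = 192000)
#' duration_s(rec)
#' @export
iq_recording <- function(samples, sample_rate_hz,
                         center_frequency_hz = NA_real_,
                         source_bit_depth = NA_integer_,
                         label = "") {
  if (!is.complex(samples)) {
    if (is.numeric(samples)) samples <- complex(real = samples,
                                                imaginary = rep(0, length(samples)))
    else stop("samples must be a complex (or numeric) vector")
  }
  if (length(samples) == 0) stop("samples must be non-empty")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be a single positive number")
  structure(
    list(samples = samples,
         sample_rate_hz = as.numeric(sample_rate_hz),
         center_frequency_hz = as.numeric(center_frequency_hz),
         source_bit_depth = as.integer(source_bit_depth),
         label = as.character(label)),
    class = "iq_recording")
}

#' @export
print.iq_recording <- function(x, ...) {
  cat(sprintf("<iq_recording> %d samples @ %g Hz (%.4f s)\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  if (is.finite(x$center_frequency_hz))
    cat(sprintf("  centre frequency: %g Hz\n", x$center_frequency_hz))
  if (!is.na(x$source_bit_depth))
    cat(sprintf("  source bit depth: %d\n", x$source_bit_depth))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Duration of a recording or baseband signal in seconds
#' @param x An `iq_recording` or `baseband_signal`.
#' @return Length of `x` in seconds.
#' @export
duration_s <- function(x) length(x$samples) / x$sample_rate_hz
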