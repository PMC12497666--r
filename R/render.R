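# Rendering a sequence script into an I/Q recording with receiver
# impairments: residual carrier offset, additive complex Gaussian noise, and
# limited-dynamic-range quantisation emulating the SDR's ADC.

#' Renderer configuration
#'
#' Receiver-side impairments applied when rendering a [sequence_script]. The
#' defaults emulate the capture chain of an RTL-class SDR dongle listening to
#' a scanner: 192 kHz audio-rate I/Q, a 1.2 kHz residual offset between the
#' scanner frequency and the SDR demodulation frequency, a small additive
#' noise floor, and 8-bit analog-to-digital conversion.
#'
#' @param sample_rate_hz Output sampling rate (Hz).
#' @param carrier_offset_hz Simulated MRI-vs-SDR frequency mismatch (Hz).
#' @param noise_sigma Standard deviation of additive Gaussian noise per
#'   component, full-scale units.
#' @param quantization_bits `NA` (none), 8, 12 or 16.
#' @param gain Overall scale applied to the superposed signal before noise.
#' @param seed Integer RNG seed; rendering is deterministic given
#'   (script, config).
#' @return An object of class `render_config`.
#' @export
render_config <- function(sample_rate_hz = 192000, carrier_offset_hz = 1200,
                          noise_sigma = 1e-3, quantization_bits = 8,
                          gain = 1, seed = 0) {
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be > 0")
  if (!is.na(quantization_bits) && !quantization_bits %in% c(8, 12, 16))
    stop("quantization_bits must be NA, 8, 12 or 16")
  structure(list(sample_rate_hz = sample_rate_hz,
                 carrier_offset_hz = carrier_offset_hz,
                 noise_sigma = noise_sigma,
                 quantization_bits = quantization_bits,
                 gain = gain, seed = as.integer(seed)),
            class = "render_config")
}

quantize_iq <- function(z, bits) {
  full <- 2^(bits - 1)
  q <- function(x) pmin(pmax(round(x * full), -full), full - 1) / full
  complex(real = q(Re(z)), imaginary = q(Im(z)))
}

#' Render a sequence script into an I/Q recording
#'
#' Superposes every scripted pulse on the timeline as
#' `amplitude * envelope(t - onset) * exp(i (2 pi (f_offset + f_carrier) t + phase))`,
#' applies the overall gain, adds complex Gaussian noise and (optionally)
#' quantises the result, emulating what the SDR records from the scanner.
#' Rendering is deterministic given the script and config (the seed is local;
#' the caller's RNG state is untouched).
#'
#' @param script A [sequence_script].
#' @param config A [render_config].
#' @return An [iq_recording] whose label is the script name.
#' @examples
#' fx <- rf_fixture("semc")
#' rec <- render(fx$script, fx$config)
#' @export
render <- function(script, config = render_config()) {
  stopifnot(inherits(script, "sequence_script"),
            inherits(config, "render_config"))
  fs <- config$sample_rate_hz
  n <- round(script$total_duration_s * fs)
  z <- complex(real = rep(0, n))

  for (ev in script$events) {
    dur <- ev$shape$duration_s
    if (dur * fs < 2)
      stop("event at onset ", ev$onset_s, " s is shorter than 2 samples")
    # sub-sample placement: evaluate the shape on the global sample grid
    k_lo <- max(0, floor(ev$onset_s * fs))
    k_hi <- ceiling((ev$onset_s + dur) * fs)
    if (k_hi + 1 > n)
      stop("event at onset ", ev$onset_s, " s extends past total_duration_s")
    idx <- (k_lo:k_hi) + 1L
    t <- (idx - 1) / fs
    env <- eval_shape(ev$shape, t - ev$onset_s - dur / 2)
    f <- ev$freq_offset_hz + config$carrier_offset_hz
    z[idx] <- z[idx] + ev$peak_amplitude * env *
      exp(1i * (2 * pi * f * t + ev$phase_rad))
  }

  z <- z * config$gain
  peak <- max(abs(Re(z)), abs(Im(z)), Mod(z))
  if (peak > 1) {
    k <- which.max(Mod(z))
    t_bad <- (k - 1) / fs
    offender <- Filter(function(e) e$onset_s <= t_bad &&
                         t_bad <= e$onset_s + e$shape$duration_s,
                       script$events)
    lab <- if (length(offender))
      paste0(offender[[1]]$role, " pulse at onset ",
             signif(offender[[1]]$onset_s, 6), " s") else "signal"
    stop("clipping after gain: ", lab, " reaches modulus ", signif(peak, 4))
  }

  if (config$noise_sigma > 0) {
    noise <- with_local_seed(config$seed, {
      complex(real = stats::rnorm(n, sd = config$noise_sigma),
              imaginary = stats::rnorm(n, sd = config$noise_sigma))
    })
    z <- z + noise
  }
  if (!is.na(config$quantization_bits))
    z <- quantize_iq(z, config$quantization_bits)

  iq_recording(z, sample_rate_hz = fs,
               center_frequency_hz = NA_real_,
               source_bit_depth = if (is.na(config$quantization_bits))
                 NA_integer_ else as.integer(config$quantization_bits),
               label = script$name)
}
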