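# Residual carrier-offset estimation and fine digital demodulation.
#
# There is no link between scanner and SDR, so the recording always carries a
# residual offset between the scanner frequency and the SDR demodulation
# frequency. The decoder estimates it from the spectrum of the strongest
# pulse and removes it digitally so that amplitude and phase can be read
# within a pulse. For a recording with several per-slice offsets, "the"
# carrier offset is by convention the offset of the strongest pulse;
# per-pulse centre frequencies are later measured relative to it.

as_baseband <- function(x) {
  if (inherits(x, "baseband_signal")) return(x)
  if (inherits(x, "iq_recording"))
    return(structure(list(samples = x$samples,
                          sample_rate_hz = x$sample_rate_hz,
                          applied_offset_hz = 0,
                          residual_offset_bound_hz = NA_real_),
                     class = "baseband_signal"))
  stop("expected an iq_recording or baseband_signal")
}

#' @export
print.baseband_signal <- function(x, ...) {
  cat(sprintf("<baseband_signal> %d samples @ %g Hz, offset removed: %.2f Hz\n",
              length(x$samples), x$sample_rate_hz, x$applied_offset_hz))
  invisible(x)
}

#' Estimate the residual carrier offset of a recording
#'
#' Finds the strongest burst in the recording (or uses the given window),
#' then returns the frequency of its dominant narrowband component from the
#' 8x zero-padded spectrum peak refined by parabolic interpolation of the
#' log-magnitude.
#'
#' @param rec An [iq_recording] (or baseband signal).
#' @param window Optional numeric `c(t_start, t_end)` in seconds selecting
#'   the analysis window; by default the span of the strongest detected
#'   burst.
#' @return A list of class `carrier_estimate` with `offset_hz`, `bound_hz`
#'   (accuracy bound, one padded spectral bin) and `window_s`.
#' @export
estimate_carrier_offset <- function(rec, window = NULL) {
  bb <- as_baseband(rec)
  fs <- bb$sample_rate_hz
  n <- length(bb$samples)
  if (is.null(window)) {
    env <- moving_average(Mod(bb$samples), round(1e-4 * fs))
    mx <- max(env)
    # low-quantile floor so high-duty-cycle recordings (one long pulse) do
    # not saturate the estimate; only the strongest burst is needed here
    floor_ <- stats::quantile(env, 0.25, names = FALSE) / 0.6745
    if (mx <= 0) stop("no burst above the noise floor; pass an explicit window")
    ratio <- mx / max(floor_, .Machine$double.xmin)
    if (ratio <= 2) {
      # near-constant envelope: either a continuous carrier or pure noise —
      # a carrier concentrates its spectrum into a narrow peak, noise does not
      mag <- Mod(stats::fft(bb$samples * hann_window(n)))
      if (max(mag) < 20 * stats::median(mag))
        stop("no burst above the noise floor; pass an explicit window")
      i0 <- 1L; i1 <- n
    } else if (ratio < 8) {
      stop("no burst above the noise floor; pass an explicit window")
    } else {
      above <- env >= 0.25 * mx
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      bursts <- which(r$values)
      peak_of <- vapply(bursts, function(j) max(env[starts[j]:ends[j]]),
                        numeric(1))
      j <- bursts[which.max(peak_of)]
      i0 <- starts[j]; i1 <- ends[j]
    }
  } else {
    if (window[1] < 0 || window[2] * fs > n || window[2] <= window[1])
      stop("window must lie inside the recording")
    i0 <- max(1, round(window[1] * fs) + 1)
    i1 <- min(n, round(window[2] * fs))
  }
  seg <- bb$samples[i0:i1]
  if (max(Mod(seg)) <= 0) stop("selected window contains no signal")
  pk <- spectral_peak(seg, fs, pad_factor = 8)
  structure(list(offset_hz = pk$freq_hz, bound_hz = pk$bound_hz,
                 window_s = c((i0 - 1) / fs, i1 / fs)),
            class = "carrier_estimate")
}

#' Fine digital demodulation
#'
#' Removes a frequency offset by complex rotation:
#' `out[k] = in[k] * exp(-i 2 pi f k / fs)`. No filtering is applied; the
#' envelope is unchanged (the modulus is invariant under rotation) while
#' phases within a pulse become readable.
#'
#' @param rec An [iq_recording] or `baseband_signal`.
#' @param offset_hz Offset to remove, Hz; `|offset_hz|` must be below the
#'   Nyquist frequency.
#' @param residual_bound_hz Optional bound on the remaining offset error
#'   (carried through from [estimate_carrier_offset()]).
#' @return A `baseband_signal`.
#' @export
fine_demodulate <- function(rec, offset_hz, residual_bound_hz = NA_real_) {
  bb <- as_baseband(rec)
  fs <- bb$sample_rate_hz
  if (abs(offset_hz) >= fs / 2)
    stop("|offset_hz| must be below the Nyquist frequency ", fs / 2)
  k <- seq_along(bb$samples) - 1
  samples <- bb$samples * exp(-1i * 2 * pi * offset_hz * k / fs)
  structure(list(samples = samples, sample_rate_hz = fs,
                 applied_offset_hz = bb$applied_offset_hz + offset_hz,
                 residual_offset_bound_hz = residual_bound_hz),
            class = "baseband_signal")
}

#' Envelope of a baseband signal
#'
#' Pointwise modulus of the complex samples, optionally smoothed by a
#' length-preserving moving average of `round(smooth_s * fs)` samples
#' (symmetric edge handling). Invariant to carrier offset and to global
#' phase rotation.
#'
#' @param bb An [iq_recording] or `baseband_signal`.
#' @param smooth_s Moving-average length in seconds (>= 0; 0 = no smoothing).
#' @return Numeric vector of envelope values, full-scale units.
#' @export
envelope <- function(bb, smooth_s = 0) {
  bb <- as_baseband(bb)
  if (smooth_s < 0) stop("smooth_s must be >= 0")
  e <- Mod(bb$samples)
  w <- round(smooth_s * bb$sample_rate_hz)
  if (w >= 2) e <- moving_average(e, w)
  e
}
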