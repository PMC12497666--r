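# RF pulse envelope shapes.
#
# All shapes are complex envelopes with unit peak modulus; the flip angle a
# pulse realises is proportional (small-tip approximation) to the envelope
# area, so relative amplitudes between pulses of the same shape encode
# flip-angle ratios (a 180-degree pulse has twice the area of a 90 of the
# same shape and duration).

#' Pulse shape specification
#'
#' Declarative description of one RF envelope shape.
#'
#' Supported kinds and their parameters:
#' * `rect` — constant envelope, no parameters;
#' * `sinc` — symmetric sinc with `n_lobes` zero-crossing pairs per side
#'   (default 3) and optional `apodization` (`"none"` or `"hann"`);
#' * `hypsec` — adiabatic hyperbolic-secant pulse
#'   `sech(beta t) * exp(i mu log sech(beta t))`, i.e. a sech amplitude
#'   envelope with a `-mu beta tanh(beta t)` frequency sweep. `beta_rad_per_s`
#'   defaults to the value that makes the envelope fall to `truncation_frac`
#'   of its peak at the support edges;
#' * `binomial121` — three rectangular sub-pulses with amplitude ratios 1:2:1
#'   (unit peak at the middle sub-pulse), centre-to-centre spacing
#'   `spacing_s`, each of width `sub_duration_s`. Its total duration is
#'   derived: `2 * spacing_s + sub_duration_s`.
#'
#' @param kind One of `"rect"`, `"sinc"`, `"hypsec"`, `"binomial121"`.
#' @param duration_s Support duration in seconds (> 0). Ignored (derived) for
#'   `binomial121`.
#' @param n_lobes,apodization `sinc` parameters.
#' @param beta_rad_per_s,mu,truncation_frac `hypsec` parameters; truncation
#'   must lie in (0, 0.5).
#' @param sub_duration_s,spacing_s `binomial121` parameters;
#'   `spacing_s > sub_duration_s` required.
#' @return An object of class `pulse_shape`.
#' @export
pulse_shape <- function(kind, duration_s = NULL,
                        n_lobes = 3L, apodization = c("none", "hann"),
                        beta_rad_per_s = NULL, mu = 5, truncation_frac = 0.05,
                        sub_duration_s = 4e-4, spacing_s = 2.38e-3) {
  kind <- match.arg(kind, c("rect", "sinc", "hypsec", "binomial121"))
  apodization <- match.arg(apodization)
  if (kind == "binomial121") {
    if (spacing_s <= sub_duration_s)
      stop("binomial121: spacing_s must exceed sub_duration_s")
    duration_s <- 2 * spacing_s + sub_duration_s
  }
  if (is.null(duration_s) || !is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be a positive number")
  if (kind == "hypsec") {
    if (truncation_frac <= 0 || truncation_frac >= 0.5)
      stop("hypsec: truncation_frac must lie in (0, 0.5)")
    if (is.null(beta_rad_per_s))
      beta_rad_per_s <- acosh(1 / truncation_frac) / (duration_s / 2)
  }
  structure(list(kind = kind, duration_s = duration_s,
                 n_lobes = as.integer(n_lobes), apodization = apodization,
                 beta_rad_per_s = beta_rad_per_s, mu = mu,
                 truncation_frac = truncation_frac,
                 sub_duration_s = sub_duration_s, spacing_s = spacing_s),
            class = "pulse_shape")
}

# Evaluate a shape's complex envelope at arbitrary times `tau` (seconds,
# relative to the envelope centre); zero outside the support. Allows
# sub-sample pulse placement when rendering.
eval_shape <- function(spec, tau) {
  half <- spec$duration_s / 2
  inside <- abs(tau) <= half + 1e-15
  out <- complex(real = rep(0, length(tau)))
  ti <- tau[inside]
  out[inside] <- switch(spec$kind,
    rect = complex(real = rep(1, length(ti))),
    sinc = {
      x <- pi * spec$n_lobes * ti / half
      y <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
      if (spec$apodization == "hann")
        y <- y * (0.5 + 0.5 * cos(pi * ti / half))
      complex(real = y)
    },
    hypsec = {
      a <- 1 / cosh(spec$beta_rad_per_s * ti)
      a * exp(1i * spec$mu * log(a))
    },
    binomial121 = {
      y <- rep(0, length(ti))
      for (j in 1:3) {
        c_j <- c(-1, 0, 1)[j] * spec$spacing_s
        y[abs(ti - c_j) <= spec$sub_duration_s / 2] <- c(0.5, 1, 0.5)[j]
      }
      complex(real = y)
    })
  out
}

#' Sample a pulse shape into a complex envelope
#'
#' Evaluates a [pulse_shape] on a symmetric midpoint grid at the given sample
#' rate. The returned envelope has unit peak modulus and carries attributes
#' `peak_offset_s` (time of the envelope peak relative to the first sample)
#' and `area` (integral of the modulus, in seconds, for a unit-amplitude
#' pulse).
#'
#' @param spec A [pulse_shape].
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Complex vector of `round(duration_s * sample_rate_hz)` samples.
#' @examples
#' env <- make_shape(pulse_shape("rect", 1e-3), 192000)
#' length(env)            # 192 samples
#' attr(env, "area")      # 1 ms
#' @export
make_shape <- function(spec, sample_rate_hz) {
  stopifnot(inherits(spec, "pulse_shape"))
  fs <- sample_rate_hz
  n <- round(spec$duration_s * fs)
  if (n < 2) stop("pulse duration ", spec$duration_s,
                  " s is shorter than 2 samples at ", fs, " Hz")
  # midpoint grid, symmetric about 0 for any n
  t <- (seq_len(n) - (n + 1) / 2) / fs
  env <- eval_shape(spec, t)
  structure(env,
            peak_offset_s = spec$duration_s / 2,   # all shapes are symmetric
            area = sum(Mod(env)) / fs)
}

#' Envelope area of a unit-amplitude pulse shape
#'
#' Integral of the envelope modulus in seconds, the quantity proportional to
#' flip angle. Used by the fixtures to calibrate amplitudes so that, e.g., a
#' refocusing pulse has exactly twice the area of an excitation pulse.
#'
#' @inheritParams make_shape
#' @return Area in seconds (full-scale units x seconds for unit amplitude).
#' @export
shape_area <- function(spec, sample_rate_hz) {
  attr(make_shape(spec, sample_rate_hz), "area")
}
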