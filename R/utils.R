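# Small numeric helpers shared across modules.

next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Length-preserving moving average with shrinking (symmetric) windows at the
# edges; n is the window length in samples.
moving_average <- function(x, n) {
  n <- as.integer(round(n))
  if (n <= 1L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  h1 <- (n - 1L) %/% 2L
  h2 <- n %/% 2L
  lo <- pmax(i - h1, 1L)
  hi <- pmin(i + h2, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Vertex offset (in bins, clamped to +/-0.5) of a parabola through three
# equally spaced ordinates.
parabolic_delta <- function(y_left, y_mid, y_right) {
  denom <- y_left - 2 * y_mid + y_right
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  d <- 0.5 * (y_left - y_right) / denom
  max(min(d, 0.5), -0.5)
}

# Frequency (Hz, in (-fs/2, fs/2]) of the dominant spectral component of a
# complex segment: Hann window, zero-padding by `pad_factor`, magnitude peak
# refined by parabolic interpolation of the log-magnitude. Returns the
# estimate together with a conservative accuracy bound (one padded bin).
spectral_peak <- function(z, fs, pad_factor = 8) {
  n <- length(z)
  if (n < 3) stop("spectral_peak: segment too short (", n, " samples)")
  np <- next_pow2(n * pad_factor)
  zw <- z * hann_window(n)
  Z <- stats::fft(c(zw, complex(real = rep(0, np - n))))
  mag <- Mod(Z)
  k <- which.max(mag)
  if (mag[k] <= 0) stop("spectral_peak: zero spectrum")
  km1 <- if (k == 1L) np else k - 1L
  kp1 <- if (k == np) 1L else k + 1L
  lm <- log(pmax(mag[c(km1, k, kp1)], 1e-300))
  delta <- parabolic_delta(lm[1], lm[2], lm[3])
  kf <- (k - 1 + delta)
  f <- kf / np * fs
  if (f > fs / 2) f <- f - fs
  list(freq_hz = f, bound_hz = fs / np)
}

trapz_area <- function(y, dx) {
  n <- length(y)
  if (n < 2) return(0)
  (sum(y) - (y[1] + y[n]) / 2) * dx
}

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
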