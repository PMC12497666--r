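# Packaged ground-truth sequence scripts emulating the recorded clinical
# sequences: multi-echo multi-slice spin echo (SEMC), TurboFLASH B1 mapping
# with a preconditioning pulse, STIR SE-EPI with binomial water excitation,
# and three 3D turbo-spin-echo (SPACE-style) variants. Timings encode the
# measured values of the sequences the decoder must recover.

FIXTURE_NAMES <- c("semc", "b1map", "se_epi",
                   "space_const", "space_restore", "space_varfa")

# slice frequency offsets (Hz) for the 5-slice 2D fixtures, spatial order,
# and the even-odd interleaved acquisition order (0-based spatial indices)
SLICE_OFFSETS_HZ <- c(-2000, -1000, 0, 1000, 2000)
ACQ_ORDER <- c(0L, 2L, 4L, 1L, 3L)

#' Packaged ground-truth sequence fixtures
#'
#' Returns the script, default render configuration and ground truth for one
#' of the packaged sequences:
#'
#' * `semc` — multi-echo multi-slice spin echo: 5 slices, each one 90-degree
#'   excitation followed by 7 refocusing pulses with twice the area; slice
#'   repetition 80 ms, echo spacing 9.9 ms (first refocusing at 4.95 ms);
#'   slice frequency offsets -2..2 kHz acquired even-odd interleaved.
#' * `b1map` — two TurboFLASH readout trains of 64 small (10-degree) pulses
#'   spaced 3.04 ms; the trains start 247 ms apart and the second is preceded
#'   by a sinc preconditioning pulse with 8x the readout pulse area (i.e. an
#'   80-degree flip for a 10-degree readout).
#' * `se_epi` — STIR-prepared spin-echo EPI: per slice a 10 ms adiabatic
#'   hyperbolic-secant inversion, a binomial 1-2-1 water-excitation composite
#'   (2.38 ms sub-pulse spacing) 156 ms later, and a refocusing pulse with
#'   twice the composite area 24 ms after the composite centre; slice
#'   repetition 356 ms, 5 slices.
#' * `space_const` — one sinc excitation then 40 rectangular refocusing
#'   pulses of constant amplitude, echo spacing 5.1 ms.
#' * `space_restore` — as `space_const` plus a final restoration pulse after
#'   the train.
#' * `space_varfa` — as `space_const` with a smooth variable flip-angle
#'   schedule (decay to 25% of maximum, plateau, ramp-up).
#'
#' The `truth` element carries the script's nominal intervals (seconds) under
#' the same names [decode()] reports, plus fixture-specific extras
#' (`flip_ratio`, `inversion_duration_s`, `acquisition_order`,
#' `train_profile`).
#'
#' @param name One of `"semc"`, `"b1map"`, `"se_epi"`, `"space_const"`,
#'   `"space_restore"`, `"space_varfa"`.
#' @param sample_rate_hz Sample rate used for the default config and for
#'   amplitude calibration (envelope areas).
#' @return A list with elements `name`, `script` ([sequence_script]),
#'   `config` ([render_config]) and `truth`.
#' @examples
#' fx <- rf_fixture("semc")
#' length(fx$script$events)   # 40
#' @export
rf_fixture <- function(name, sample_rate_hz = 192000) {
  if (!name %in% FIXTURE_NAMES)
    stop("unknown fixture '", name, "'; valid fixtures: ",
         paste(FIXTURE_NAMES, collapse = ", "))
  fx <- switch(name,
               semc = fixture_semc(sample_rate_hz),
               b1map = fixture_b1map(sample_rate_hz),
               se_epi = fixture_se_epi(sample_rate_hz),
               space_const = fixture_space(sample_rate_hz, variant = "const"),
               space_restore = fixture_space(sample_rate_hz, variant = "restore"),
               space_varfa = fixture_space(sample_rate_hz, variant = "varfa"))
  fx$name <- name
  fx$config <- render_config(sample_rate_hz = sample_rate_hz)
  fx
}

fixture_semc <- function(fs) {
  sinc <- pulse_shape("sinc", 2.56e-3, n_lobes = 3)
  half <- sinc$duration_s / 2
  events <- list()
  for (g in 0:4) {
    s <- ACQ_ORDER[g + 1]
    off <- SLICE_OFFSETS_HZ[s + 1]
    p_exc <- g * 0.080 + 0.004
    events <- c(events, list(
      pulse_event(p_exc - half, sinc, peak_amplitude = 0.45,
                  freq_offset_hz = off, role = "excitation",
                  slice_index = s)))
    for (k in 0:6) {
      p_ref <- p_exc + 4.95e-3 + k * 9.9e-3
      events <- c(events, list(
        pulse_event(p_ref - half, sinc, peak_amplitude = 0.9,
                    freq_offset_hz = off, role = "refocusing",
                    slice_index = s)))
    }
  }
  list(script = sequence_script("semc", events, 0.400),
       truth = list(
         intervals = c(slice_tr = 0.080, echo_spacing = 9.9e-3,
                       exc_to_refocus = 4.95e-3, echo_time = 9.9e-3),
         acquisition_order = ACQ_ORDER,
         interleave_even_odd = TRUE,
         slice_offsets_hz = SLICE_OFFSETS_HZ))
}

fixture_b1map <- function(fs) {
  rd <- pulse_shape("rect", 3e-4)
  sinc <- pulse_shape("sinc", 2.56e-3, n_lobes = 3)
  rd_amp <- 0.25
  rd_area <- rd_amp * shape_area(rd, fs)
  pre_amp <- 8 * rd_area / shape_area(sinc, fs)

  train <- function(t0) lapply(0:63, function(k)
    pulse_event(t0 + k * 3.04e-3 - rd$duration_s / 2, rd,
                peak_amplitude = rd_amp, role = "readout"))
  t1 <- 0.010
  t2 <- t1 + 0.247
  events <- c(train(t1),
              list(pulse_event(t2 - 0.020 - sinc$duration_s / 2, sinc,
                               peak_amplitude = pre_amp,
                               role = "preconditioning")),
              train(t2))
  list(script = sequence_script("b1map", events, 0.465),
       truth = list(
         intervals = c(slice_tr = 0.247, readout_spacing = 3.04e-3),
         flip_ratio = 8, readout_flip_deg = 10,
         preconditioning_flip_deg = 80))
}

fixture_se_epi <- function(fs) {
  hs <- pulse_shape("hypsec", 10e-3, mu = 5, truncation_frac = 0.05)
  binom <- pulse_shape("binomial121", sub_duration_s = 4e-4,
                       spacing_s = 2.38e-3)
  sinc <- pulse_shape("sinc", 2.56e-3, n_lobes = 3)
  comp_amp <- 0.25
  comp_area <- comp_amp * shape_area(binom, fs)
  ref_amp <- 2 * comp_area / shape_area(sinc, fs)

  events <- list()
  for (g in 0:4) {
    s <- ACQ_ORDER[g + 1]
    off <- SLICE_OFFSETS_HZ[s + 1]
    p_inv <- g * 0.356 + 0.008
    p_comp <- p_inv + 0.156
    p_ref <- p_comp + 0.024
    events <- c(events, list(
      pulse_event(p_inv - hs$duration_s / 2, hs, peak_amplitude = 0.85,
                  freq_offset_hz = off, role = "inversion", slice_index = s),
      pulse_event(p_comp - binom$duration_s / 2, binom,
                  peak_amplitude = comp_amp, role = "water_excitation",
                  slice_index = s),
      pulse_event(p_ref - sinc$duration_s / 2, sinc, peak_amplitude = ref_amp,
                  freq_offset_hz = off, role = "refocusing",
                  slice_index = s)))
  }
  list(script = sequence_script("se_epi", events, 1.62),
       truth = list(
         intervals = c(slice_tr = 0.356, inversion_delay = 0.156,
                       exc_to_refocus = 0.024, echo_time = 0.048,
                       composite_spacing = 2.38e-3),
         inversion_duration_s = 0.010,
         acquisition_order = ACQ_ORDER,
         interleave_even_odd = TRUE))
}

# Echo-train length and spacing of the 3D turbo-spin-echo fixtures are
# desk-scale stand-ins (40 refocusing pulses, 5.1 ms apart), not the vendor's
# (unpublished) values.
fixture_space <- function(fs, variant) {
  sinc <- pulse_shape("sinc", 2.56e-3, n_lobes = 3)
  rect <- pulse_shape("rect", 1e-3)
  ref_amp_max <- 0.8
  ref_area_max <- ref_amp_max * shape_area(rect, fs)
  exc_amp <- (ref_area_max / 2) / shape_area(sinc, fs)

  sched <- switch(variant,
    const = rep(1, 40),
    restore = rep(1, 40),
    varfa = {
      s <- numeric(40)
      s[1:15] <- 0.25 + 0.75 * (0.5 + 0.5 * cos(pi * (0:14) / 14))
      s[16:25] <- 0.25
      s[26:40] <- 0.25 + 0.35 * (1:15) / 15
      s
    })

  p_exc <- 0.005
  events <- list(pulse_event(p_exc - sinc$duration_s / 2, sinc,
                             peak_amplitude = exc_amp, role = "excitation"))
  ref_peaks <- p_exc + 2.55e-3 + (0:39) * 5.1e-3
  for (k in 1:40)
    events <- c(events, list(
      pulse_event(ref_peaks[k] - rect$duration_s / 2, rect,
                  peak_amplitude = ref_amp_max * sched[k],
                  role = "refocusing")))
  if (variant == "restore")
    events <- c(events, list(
      pulse_event(ref_peaks[40] + 7.65e-3 - rect$duration_s / 2, rect,
                  peak_amplitude = ref_amp_max / 2, role = "restoration")))

  truth <- list(intervals = c(echo_spacing = 5.1e-3,
                              exc_to_refocus = 2.55e-3,
                              echo_time = 5.1e-3))
  if (variant == "varfa") truth$train_profile <- sched / max(sched)
  list(script = sequence_script(paste0("space_", variant), events, 0.215),
       truth = truth)
}
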