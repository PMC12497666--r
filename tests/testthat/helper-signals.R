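# Shared helpers: clean render configs, tiny scripts, fake events, and a
# cache so fixtures are rendered/decoded once per run.

clean_config <- function(...) {
  args <- list(carrier_offset_hz = 0, noise_sigma = 0, quantization_bits = NA)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(render_config, args)
}

single_pulse_script <- function(shape, onset_s = 0.02, amp = 0.5,
                                freq_offset_hz = 0, phase_rad = 0,
                                margin_s = 0.02, role = "excitation") {
  sequence_script("single", list(
    pulse_event(onset_s, shape, amp, freq_offset_hz, phase_rad, role = role)),
    onset_s + shape$duration_s + margin_s)
}

random_recording <- function(n = 4096, fs = 192000, seed = 42, scale = 0.9) {
  set.seed(seed)
  iq_recording(
    complex(real = scale * stats::runif(n, -1, 1),
            imaginary = scale * stats::runif(n, -1, 1)),
    sample_rate_hz = fs, center_frequency_hz = 63.64e6, label = "random")
}

fake_event <- function(t_peak, area = 1, role = NA_character_, dur = 1e-3,
                       f_center_hz = 0) {
  structure(list(t_start_s = t_peak - dur / 2, t_end_s = t_peak + dur / 2,
                 t_peak_s = t_peak, duration_s = dur, peak_amplitude = 1,
                 area = area, f_center_hz = f_center_hz,
                 phase_at_peak_rad = 0, shape_label = NA_character_,
                 sub_events = NULL, role_guess = role),
            class = "pulse_event")
}

# render + decode each fixture once per test run
fixture_run <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      fx <- rf_fixture(name)
      rec <- render(fx$script, fx$config)
      cache[[name]] <<- list(fx = fx, rec = rec, rep = decode(rec))
    }
    cache[[name]]
  }
})
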