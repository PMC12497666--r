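# Envelope segmentation and per-pulse measurement.

test_that("a zero signal yields an empty event list with a warning flag, not an error", {
  zero <- iq_recording(complex(real = rep(0, 5000)), 192000)
  ev <- detect_pulses(zero)
  expect_length(ev, 0)
  expect_match(attr(ev, "warnings"), "no pulses|noise")
})

test_that("the SEMC fixture yields exactly 40 non-overlapping events in order", {
  run <- fixture_run("semc")
  ev <- detect_pulses(fine_demodulate(run$rec,
                                      estimate_carrier_offset(run$rec)$offset_hz))
  expect_length(ev, 40)
  bounds <- cbind(vapply(ev, `[[`, numeric(1), "t_start_s"),
                  vapply(ev, `[[`, numeric(1), "t_end_s"))
  expect_true(all(diff(as.vector(t(bounds))) > 0))   # strictly increasing intervals
  peaks <- vapply(ev, `[[`, numeric(1), "t_peak_s")
  expect_true(all(peaks > bounds[, 1] & peaks < bounds[, 2]))
})

test_that("a symmetric rect pulse peaks at its centre within a sample", {
  sc <- single_pulse_script(pulse_shape("rect", 1e-3), onset_s = 0.02)
  rec <- render(sc, clean_config())
  ev <- measure_pulse(rec, 0.0195, 0.0215)
  expect_lt(abs(ev$t_peak_s - 0.0205), 1 / 192000)
  expect_error(measure_pulse(rec, 0.02, 0.020005), "degenerate")
})

test_that("centre frequency of an offset pulse is recovered within 5 Hz", {
  sc <- single_pulse_script(pulse_shape("rect", 2e-3), amp = 0.5,
                            freq_offset_hz = 2000)
  rec <- render(sc, clean_config(noise_sigma = 1e-3, seed = 2))
  ev <- detect_pulses(rec)
  expect_length(ev, 1)
  expect_lt(abs(ev[[1]]$f_center_hz - 2000), 5)
})

test_that("the adiabatic inversion pulse spans its full 10 ms support", {
  run <- fixture_run("se_epi")
  inv <- Filter(function(e) identical(e$role_guess, "inversion"),
                run$rep$events)
  expect_length(inv, 5)
  for (e in inv) expect_equal(e$duration_s, 10e-3, tolerance = 0.05)
})

test_that("three short rects spaced 2.38 ms group into one binomial composite", {
  sc <- single_pulse_script(pulse_shape("binomial121", sub_duration_s = 4e-4,
                                        spacing_s = 2.38e-3),
                            onset_s = 0.02, amp = 0.5)
  rec <- render(sc, render_config(carrier_offset_hz = 1200,
                                  noise_sigma = 1e-3, seed = 0))
  bb <- fine_demodulate(rec, estimate_carrier_offset(rec)$offset_hz)
  raw <- detect_pulses(bb)
  expect_length(raw, 3)
  grouped <- group_composites(raw)
  expect_length(grouped, 1)
  comp <- grouped[[1]]
  expect_length(comp$sub_events, 3)
  areas <- vapply(comp$sub_events, `[[`, numeric(1), "area")
  expect_equal(areas / areas[2], c(0.5, 1, 0.5), tolerance = 0.02)
  expect_equal(comp$area, sum(areas))   # exact conservation
  spacings <- diff(vapply(comp$sub_events, `[[`, numeric(1), "t_peak_s"))
  expect_equal(spacings, rep(2.38e-3, 2), tolerance = 0.01)
  # composite peak is the central "2" sub-pulse
  expect_equal(comp$t_peak_s, comp$sub_events[[2]]$t_peak_s)
})

test_that("events far apart are never grouped", {
  ev <- list(fake_event(0.1, dur = 4e-4), fake_event(0.2, dur = 4e-4))
  expect_length(group_composites(ev), 2)
  # and events longer than the gap limit are ineligible even when close
  long <- list(fake_event(0.100, dur = 2.56e-3), fake_event(0.1049, dur = 2.56e-3))
  expect_length(group_composites(long), 2)
})

test_that("event count is invariant to global gain over [0.05, 1]", {
  for (g in c(0.05, 0.2, 1)) {
    fx <- rf_fixture("semc")
    fx$config$gain <- g
    fx$config$quantization_bits <- 16
    rec <- render(fx$script, fx$config)
    bb <- fine_demodulate(rec, estimate_carrier_offset(rec)$offset_hz)
    expect_length(detect_pulses(bb), 40)
  }
})

test_that("area ratios are invariant to gain and carrier offset within 0.5%", {
  ratio_of <- function(gain, carrier) {
    fx <- rf_fixture("semc")
    fx$config$gain <- gain
    fx$config$carrier_offset_hz <- carrier
    rep <- decode(render(fx$script, fx$config))
    rep$flip_estimates[[1]]$area_ratio
  }
  r <- c(ratio_of(1, 1200), ratio_of(0.4, 1200), ratio_of(1, -3000))
  expect_lt(diff(range(r)) / mean(r), 0.005)
})

test_that("detected peak times match the scripted peaks within half an envelope sample", {
  for (nm in c("semc", "space_const")) {
    run <- fixture_run(nm)
    truth <- sort(vapply(run$fx$script$events, event_peak_time, numeric(1)))
    det <- sort(vapply(run$rep$events, `[[`, numeric(1), "t_peak_s"))
    expect_length(det, length(truth))
    expect_lt(max(abs(det - truth)) * 192000, 0.5)
  }
})

test_that("8-bit quantisation moves peak estimates by far less than 0.1% of the echo spacing", {
  fx8 <- rf_fixture("semc")
  rec8 <- render(fx8$script, fx8$config)             # 8-bit default
  fxn <- rf_fixture("semc")
  fxn$config$quantization_bits <- NA
  recn <- render(fxn$script, fxn$config)
  p8 <- vapply(decode(rec8)$events, `[[`, numeric(1), "t_peak_s")
  pn <- vapply(decode(recn)$events, `[[`, numeric(1), "t_peak_s")
  expect_lt(max(abs(p8 - pn)) / 9.9e-3, 0.001)
})

test_that("events export to a well-formed table and CSV", {
  run <- fixture_run("se_epi")
  tab <- events_as_table(run$rep$events)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$n_sub[tab$role_guess == "water_excitation"] == 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(run$rep$events, path)
  expect_equal(nrow(utils::read.csv(path)), 15)
})
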