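# Sequence-level quantities: timings, roles, interleave, flip angles,
# classification, train profiles, full decode.

test_that("peak intervals are successive peak differences", {
  ev <- list(fake_event(0.1), fake_event(0.148))
  expect_equal(peak_intervals(ev), 0.048)            # the SE-EPI half echo time
  ev5 <- lapply(seq(0, 0.4, by = 0.1), fake_event)
  expect_equal(peak_intervals(ev5), rep(0.1, 4))
  expect_error(peak_intervals(ev[1]), "at least 2")
})

test_that("slice repetition time is recovered for dense and sparse groupings", {
  expect_equal(fixture_run("semc")$rep$slice_tr_s, 0.080, tolerance = 1e-3)
  expect_equal(fixture_run("se_epi")$rep$slice_tr_s, 0.356, tolerance = 1e-3)
  # two groups offset by exactly T
  ev <- c(lapply(c(0, 0.01, 0.02), fake_event),
          lapply(c(0, 0.01, 0.02) + 0.25, fake_event))
  expect_equal(estimate_slice_tr(ev), 0.25)
  expect_error(estimate_slice_tr(lapply(c(0, 0.01), fake_event)),
               "repeating groups")
})

test_that("echo timing follows spin-echo conventions", {
  # synthetic: excitation at t0, single refocusing at t0 + delta -> TE = 2 delta
  g <- list(fake_event(0.1, role = "excitation"),
            fake_event(0.112, role = "refocusing"))
  et <- estimate_echo_timing(g)
  expect_equal(et$echo_time_s, 0.024)
  expect_true(is.na(et$echo_spacing_s))
  expect_error(estimate_echo_timing(g[1]), "refocusing")

  expect_equal(fixture_run("se_epi")$rep$echo_time_s, 0.048,
               tolerance = 0.5e-3 / 0.048)
  expect_equal(fixture_run("semc")$rep$echo_spacing_s, 9.9e-3,
               tolerance = 1e-3)
})

test_that("roles are inferred from sequence structure", {
  roles <- vapply(fixture_run("semc")$rep$events, `[[`, character(1),
                  "role_guess")
  expect_equal(sum(roles == "excitation"), 5)
  expect_equal(sum(roles == "refocusing"), 35)
  fe <- fixture_run("semc")$rep$flip_estimates
  ref_est <- Filter(function(x) x$target_role == "refocusing", fe)[[1]]
  expect_equal(ref_est$area_ratio, 2, tolerance = 0.025)  # 180/90 area ratio

  roles_epi <- vapply(fixture_run("se_epi")$rep$events, `[[`, character(1),
                      "role_guess")
  expect_equal(roles_epi[1], "inversion")
  expect_equal(sum(roles_epi == "water_excitation"), 5)

  roles_b1 <- vapply(fixture_run("b1map")$rep$events, `[[`, character(1),
                     "role_guess")
  expect_equal(sum(roles_b1 == "readout"), 128)
  expect_equal(sum(roles_b1 == "preconditioning"), 1)

  roles_sp <- vapply(fixture_run("space_restore")$rep$events, `[[`,
                     character(1), "role_guess")
  expect_equal(roles_sp[length(roles_sp)], "restoration")

  one <- infer_roles(list(fake_event(0.1)))
  expect_equal(one[[1]]$role_guess, "excitation")
})

test_that("inversion delay is the inversion-to-excitation peak interval", {
  expect_equal(fixture_run("se_epi")$rep$inversion_delay_s, 0.156,
               tolerance = 0.5e-3 / 0.156)
  # synthetic STIR with a 120 ms delay
  hs <- pulse_shape("hypsec", 8e-3, truncation_frac = 0.05)
  sc <- sequence_script("stir", list(
    pulse_event(0.01 - 4e-3, hs, 0.8, role = "inversion"),
    pulse_event(0.13 - 1e-3, pulse_shape("rect", 2e-3), 0.4,
                role = "excitation"),
    pulse_event(0.154 - 1e-3, pulse_shape("rect", 2e-3), 0.78,
                role = "refocusing")), 0.2)
  rec <- render(sc, render_config(seed = 5))
  ev <- infer_roles(detect_pulses(fine_demodulate(
    rec, estimate_carrier_offset(rec)$offset_hz)))
  expect_equal(inversion_delay(ev), 0.120, tolerance = 1 / 192000 / 0.12)
  expect_error(inversion_delay(ev[2:3]), "inversion")
})

test_that("slice frequencies rank into an even-odd interleaved acquisition order", {
  rep <- fixture_run("semc")$rep
  expect_equal(rep$acquisition_order, c(0L, 2L, 4L, 1L, 3L))
  expect_true(rep$interleave_even_odd)
  # group frequencies match the fixture offsets relative to the strongest slice
  truth_order <- rf_fixture("semc")$truth$slice_offsets_hz[c(1, 3, 5, 2, 4) ]
  expect_equal(rank(rep$slice_frequencies_hz), rank(truth_order))

  expect_false(is_even_odd_interleaved(0:4))
  expect_true(is_even_odd_interleaved(c(1L, 3L, 0L, 2L, 4L)))  # odd-first
  expect_false(is_even_odd_interleaved(c(0L, 1L, 4L, 2L, 3L)))
})

test_that("flip angles follow area ratios with a declared reference", {
  e <- fake_event(0.1, area = 2.5)
  self <- flip_angle_from_ratio(e, 10, e)
  expect_equal(self$area_ratio, 1)
  expect_equal(self$deduced_angle_deg, 10)

  # closed form: rect(1 ms, amp .5) vs rect(2 ms, amp .5) at 30 deg -> 60 deg
  sc <- sequence_script("pair", list(
    pulse_event(0.01, pulse_shape("rect", 1e-3), 0.5, role = "excitation"),
    pulse_event(0.05, pulse_shape("rect", 2e-3), 0.5, role = "refocusing")),
    0.07)
  rec <- render(sc, clean_config())
  ev <- detect_pulses(rec)
  est <- flip_angle_from_ratio(ev[[1]], 30, ev[[2]])
  expect_equal(est$deduced_angle_deg, 60, tolerance = 0.01)

  # invariant by construction
  expect_equal(est$deduced_angle_deg, 30 * est$area_ratio)

  # spectral cross-check agrees with the time-domain area route
  bb <- fine_demodulate(rec, 0)
  est_sp <- flip_angle_from_ratio(ev[[1]], 30, ev[[2]], mode = "spectral",
                                  bb = bb)
  expect_equal(est_sp$area_ratio, est$area_ratio, tolerance = 0.02)

  zero_ref <- fake_event(0.2, area = 0)
  expect_error(flip_angle_from_ratio(zero_ref, 10, e), "zero")
})

test_that("the preconditioning flip angle is deduced from the readout reference", {
  fe <- fixture_run("b1map")$rep$flip_estimates
  pre <- Filter(function(x) x$target_role == "preconditioning", fe)[[1]]
  expect_equal(pre$reference_angle_deg, 10)
  expect_equal(pre$deduced_angle_deg, 80, tolerance = 2 / 80)
})

test_that("shape classification identifies sinc, rect, hypsec and binomial pulses", {
  run <- fixture_run("space_const")
  bb <- fine_demodulate(run$rec, run$rep$applied_offset_hz)
  first <- classify_shape(run$rep$events[[1]], bb)
  later <- classify_shape(run$rep$events[[10]], bb)
  expect_equal(first$label, "sinc")
  expect_gte(first$score, 0.97)
  expect_equal(later$label, "rect")
  expect_gte(later$score, 0.97)

  epi <- fixture_run("se_epi")$rep
  labels <- vapply(epi$events, `[[`, character(1), "shape_label")
  expect_equal(labels[1], "hypsec")
  expect_true("binomial121" %in% labels)

  # a noise segment forced through measurement scores below the floor
  set.seed(0)
  nz <- iq_recording(complex(real = rnorm(19200, sd = 0.01),
                             imaginary = rnorm(19200, sd = 0.01)), 192000)
  ev <- measure_pulse(nz, 0.02, 0.04)
  cl <- classify_shape(ev, nz)
  expect_equal(cl$label, "unknown")
  expect_lt(cl$score, 0.9)
})

test_that("make_shape -> render -> classify returns the generating label at high SNR", {
  shapes <- list(rect = pulse_shape("rect", 1e-3),
                 sinc = pulse_shape("sinc", 2.56e-3),
                 hypsec = pulse_shape("hypsec", 8e-3),
                 binomial121 = pulse_shape("binomial121"))
  for (nm in names(shapes)) {
    sc <- single_pulse_script(shapes[[nm]], amp = 0.8)
    rec <- render(sc, render_config(noise_sigma = 1e-3, seed = 4,
                                    quantization_bits = 16))
    bb <- fine_demodulate(rec, estimate_carrier_offset(rec)$offset_hz)
    ev <- group_composites(detect_pulses(bb))
    expect_length(ev, 1)
    expect_equal(classify_shape(ev[[1]], bb)$label, nm)
  }
})

test_that("refocusing train profiles are flat, restored or variable as scripted", {
  expect_true(all(abs(fixture_run("space_const")$rep$train_profile - 1) < 0.01))
  run <- fixture_run("space_varfa")
  expect_length(run$rep$train_profile, 40)
  expect_equal(run$rep$train_profile, run$fx$truth$train_profile,
               tolerance = 0.02)
  # restoration pulse is excluded from the profile
  expect_length(fixture_run("space_restore")$rep$train_profile, 40)
  expect_error(train_flip_profile(list(fake_event(0.1))), "refocusing")

  # identical pulses at integer-sample spacing -> exactly constant profile
  sc <- sequence_script("flat", c(
    list(pulse_event(0.002, pulse_shape("sinc", 2.56e-3), 0.4,
                     role = "excitation")),
    lapply(0:9, function(k)
      pulse_event(0.0075 + k * 5e-3, pulse_shape("rect", 1e-3), 0.8,
                  role = "refocusing"))), 0.06)
  rec <- render(sc, clean_config())
  ev <- infer_roles(detect_pulses(rec))
  expect_equal(train_flip_profile(ev), rep(1, 10), tolerance = 1e-9)
})

test_that("decode handles degenerate inputs and is deterministic", {
  zero <- iq_recording(complex(real = rep(0, 19200)), 192000)
  rep0 <- decode(zero)
  expect_equal(rep0$n_events, 0)
  expect_true(length(rep0$warnings) > 0)
  expect_null(rep0$slice_tr_s)
  expect_null(rep0$inversion_delay_s)

  run <- fixture_run("semc")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(decode(run$rec), f1)
  write_report_json(decode(run$rec), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # an explicit offset override is honoured and echoed
  rep_o <- decode(run$rec, offset_hz = 1200)
  expect_equal(rep_o$applied_offset_hz, 1200)
  expect_false(rep_o$offset_estimated)
})

test_that("simulate and decode round-trip through the CLI entry points", {
  wav <- withr::local_tempfile(fileext = ".wav")
  out1 <- cmd_simulate(wav, fixture = "semc", seed = 0)
  expect_true(file.exists(out1$wav))
  expect_true(file.exists(out1$sidecar))
  truth <- jsonlite::read_json(out1$truth, simplifyVector = TRUE)
  expect_equal(truth$truth$intervals[["slice_tr"]], 0.080)

  # byte-identical reruns at a fixed seed
  wav2 <- withr::local_tempfile(fileext = ".wav")
  cmd_simulate(wav2, fixture = "semc", seed = 0)
  expect_identical(readBin(wav, "raw", file.size(wav)),
                   readBin(wav2, "raw", file.size(wav2)))

  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  rep <- cmd_decode(wav, json = json, csv = csv)
  expect_equal(rep$slice_tr_s, 0.080, tolerance = 1e-3)
  parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(parsed$n_events, 40)
  expect_equal(nrow(utils::read.csv(csv)), 40)

  # swapping I and Q mirrors the spectrum: the estimated offset flips sign
  rep_sw <- cmd_decode(wav, swap_iq = TRUE)
  expect_lt(abs(rep_sw$applied_offset_hz + rep$applied_offset_hz), 10)
})
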