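# WAV I/O: lossless round trips, channel convention, PCM scaling, errors.

test_that("16-bit WAV round trip preserves every sample within one quantisation step", {
  rec <- random_recording(n = 2048, fs = 48000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_iq_wav(rec, path, bit_depth = 16)
  back <- read_iq_wav(path)

  expect_equal(back$sample_rate_hz, 48000)     # header rate honoured, not 192 kHz
  expect_lt(max(abs(Re(back$samples) - Re(rec$samples))), 2^-15)
  expect_lt(max(abs(Im(back$samples) - Im(rec$samples))), 2^-15)
  expect_equal(back$source_bit_depth, 16L)
  # sidecar metadata merged back
  expect_equal(back$center_frequency_hz, 63.64e6)
  expect_equal(back$label, "random")
})

test_that("channel convention is I = channel 0, Q = channel 1, identically for both directions", {
  # deliberately asymmetric: constant I, ramp Q
  rec <- iq_recording(complex(real = rep(0.5, 100),
                              imaginary = seq(-0.5, 0.5, length.out = 100)),
                      sample_rate_hz = 192000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_iq_wav(rec, path, 16)
  back <- read_iq_wav(path)
  expect_lt(max(abs(Re(back$samples) - 0.5)), 2^-15)
  expect_lt(max(abs(Im(back$samples) - seq(-0.5, 0.5, length.out = 100))), 2^-15)
})

test_that("zero and full-scale recordings hit the exact PCM rails", {
  path <- withr::local_tempfile(fileext = ".wav")
  zero <- iq_recording(complex(real = rep(0, 64)), 192000)
  write_iq_wav(zero, path, 16)
  expect_true(all(read_iq_wav(path)$samples == 0 + 0i))

  # unit-amplitude I clips to 32767; Q stays zero
  full <- iq_recording(complex(real = rep(1, 64)), 192000)
  write_iq_wav(full, path, 16)
  back <- read_iq_wav(path)
  expect_true(all(Re(back$samples) == 32767 / 32768))
  expect_true(all(Im(back$samples) == 0))
  # and -1 maps exactly to the negative rail
  neg <- iq_recording(complex(real = rep(-1, 64)), 192000)
  write_iq_wav(neg, path, 16)
  expect_true(all(Re(read_iq_wav(path)$samples) == -1))
})

test_that("8-bit round trip error is bounded by the 8-bit quantisation step", {
  rec <- random_recording(n = 4096, seed = 7)
  path <- withr::local_tempfile(fileext = ".wav")
  write_iq_wav(rec, path, bit_depth = 8)
  back <- read_iq_wav(path)
  expect_equal(back$source_bit_depth, 8L)
  expect_lte(max(abs(Re(back$samples) - Re(rec$samples))), 2^-7)
  expect_lte(max(abs(Im(back$samples) - Im(rec$samples))), 2^-7)
})

test_that("malformed inputs give informative errors", {
  expect_error(read_iq_wav(file.path(tempdir(), "nope.wav")), "not found")

  # hand-built mono 16-bit WAV
  mono <- withr::local_tempfile(fileext = ".wav")
  con <- file(mono, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 8), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")     # 1 channel
  writeBin(192000L, con, size = 4, endian = "little")
  writeBin(384000L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(integer(4), con, size = 2, endian = "little")
  close(con)
  expect_error(read_iq_wav(mono), "2-channel.*1 channel")

  rec <- iq_recording(complex(real = c(1.5, 0)), 192000)
  expect_error(write_iq_wav(rec, withr::local_tempfile(fileext = ".wav"),
                            16, clip = FALSE), "range")
  expect_error(write_iq_wav(rec, tempfile(), bit_depth = 24), "8 or 16")
})
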