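Package: pulsescope
Title: Decode MRI RF Pulse Sequences from Software-Defined-Radio I/Q Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monitoring the radiofrequency (RF) side of clinical MRI pulse
    sequences with an inexpensive software-defined radio (SDR): reads and
    writes two-channel I/Q recordings as PCM WAV files, renders synthetic
    ground-truth recordings of standard sequences (multi-echo spin echo,
    TurboFLASH B1 mapping, STIR SE-EPI with binomial water excitation, 3D
    turbo-spin-echo trains) with receiver impairments, and decodes recordings
    back into pulse events and sequence-level quantities: per-slice repetition
    time, echo spacing and echo time, inversion delay, slice-frequency
    interleave order, relative amplitudes and flip-angle ratios, and pulse
    shape labels (rect, sinc, hyperbolic secant, binomial 1-2-1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
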