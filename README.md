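# pulsescope

Monitoring the RF side of clinical MRI pulse sequences with a cheap
software-defined radio (SDR). Every RF pulse an MRI scanner plays is
broadcast into the room; a broadband pick-up coil and an SDR dongle record it
as a two-channel (I/Q) baseband stream, with no connection to the scanner at
all. `pulsescope` decodes such recordings back into the sequence diagram —
and, because real captures need real hardware, it also ships a synthetic
renderer that emulates the capture chain, so the whole decoder is testable at
the desk.

It is aimed at MR physicists and service engineers who want to verify what a
scanner actually plays — repetition times, echo spacings, inversion delays,
slice ordering, relative flip angles, pulse shapes — including details the
console UI never shows.

## What it computes

A recording is a complex baseband signal `z[k] = I[k] + iQ[k]`. The decoder:

1. **estimates the residual carrier offset** `Δf` between the scanner's
   Larmor frequency and the SDR demodulation frequency (spectrum peak of the
   strongest pulse, 8× zero-padded, parabolic-refined) and removes it:
   `z[k] · exp(−i2πΔf k/fs)`;
2. **segments the envelope** `|z|` into pulse events by robust hysteresis
   thresholding, and measures each event's peak time (parabolic/plateau
   refinement), envelope area `∫|z|dt`, centre frequency and phase;
3. **derives sequence quantities** from peak-to-peak intervals: per-slice
   repetition time TR, echo spacing and echo time (TE = 2× the
   excitation-to-refocusing interval), inversion delay TI, per-slice
   frequency offsets and their acquisition order (even–odd interleave
   detection);
4. **deduces flip-angle ratios** from envelope areas — in the small-tip
   regime the flip angle is proportional to `∫B1 dt`, so
   `α_target = α_ref · (area_target / area_ref)`;
5. **classifies pulse shapes** (rect, sinc, hyperbolic secant, binomial
   1–2–1 composite) by template correlation.

The synthetic side renders declarative sequence scripts into recordings with
the receiver impairments of an RTL-class dongle: 192 kHz I/Q rate, residual
carrier offset, additive noise, 8-bit quantisation. Six packaged fixtures
emulate recorded clinical sequences: a 5-slice 7-echo spin echo (`semc`), a
TurboFLASH B1-mapping sequence with a preconditioning pulse (`b1map`), a
STIR-prepared SE-EPI with binomial water excitation (`se_epi`), and three 3D
turbo-spin-echo variants (`space_const`, `space_restore`, `space_varfa`).

## Worked example

```r
library(pulsescope)

fx  <- rf_fixture("se_epi")          # script + render config + ground truth
rec <- render(fx$script, fx$config)  # what the SDR would have recorded
rep <- decode(rec)
print(rep)
```

```
<sequence_report>
  events: 15   carrier offset removed: 3198.8 Hz (estimated)
  slice repetition: 356.00 ms
  echo time:       48.00 ms
  inversion delay: 156.00 ms
  composite sub-pulse spacing: 2.38 ms
  slice frequencies (kHz): -3.62, -2.00, -0.37, -2.62, -1.38
  acquisition order: 0 2 4 1 3  (even-odd interleaved)
  flip angle (refocusing): 179.3 deg = 90 deg x 1.993
```

Reading this: each of the 5 slices repeats every 356 ms and begins with a
10 ms adiabatic (hyperbolic-secant) inversion; 156 ms later comes the
binomial 1–2–1 water-excitation composite (sub-pulses 2.38 ms apart, so fat
precesses half a turn between them), and 24 ms after that the refocusing
pulse — an echo time of 48 ms. The refocusing pulse has 2.0× the excitation
area, i.e. a 180° pulse for a 90° excitation. The removed "carrier offset"
is the offset of the strongest pulse (here a slice-selective inversion at
+2 kHz), so per-slice frequencies are relative to it; their ranks give the
even–odd interleaved acquisition order. `rep$events` holds every measured
pulse (timings, areas, frequencies, phases, shape labels).

The same flows exist as shell commands:

```sh
Rscript inst/cli/pulsescope.R simulate --fixture b1map --seed 0 --out b1.wav
Rscript inst/cli/pulsescope.R decode b1.wav --json report.json --csv events.csv
```

`simulate` writes the WAV, a `.meta.json` sidecar (centre frequency, label)
and a `.truth.json` with the scripted ground truth; `decode` reads any
2-channel I/Q PCM WAV (`--swap-iq` if your tool records Q on channel 0).

## Limitations

The renderer is a signal-chain emulator, not a Bloch simulator: pulses are
ideal shaped envelopes, there are no gradients, and amplitudes are relative
(absolute B1 in µT needs a calibrated coil geometry). Echo-train lengths and
the variable-flip-angle schedule of the 3D turbo-spin-echo fixtures are
desk-scale stand-ins, not vendor values.
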