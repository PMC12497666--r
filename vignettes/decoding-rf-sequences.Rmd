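---
title: "Decoding MRI RF pulse sequences from SDR I/Q recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding MRI RF pulse sequences from SDR I/Q recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsescope)
```

## The measurement model

An MRI scanner's RF pulses can be monitored completely passively: a
broadband coil picks up the transmitted B1 field, and a software-defined
radio (SDR) tuned near the Larmor frequency demodulates it to a complex
baseband stream recorded as a two-channel WAV (I on channel 0, Q on
channel 1). `pulsescope` models that stream as

$$ z[k] \;=\; g \sum_j a_j\, s_j\!\left(t_k - \tau_j\right)
   e^{\,i\left(2\pi (f_j + \Delta f)\, t_k + \phi_j\right)} + n[k]
   \;\rightarrow\; \mathrm{quant}_b(z), $$

where each pulse $j$ has a unit-peak complex envelope $s_j$ (rect, sinc,
hyperbolic secant, or a binomial 1–2–1 composite), amplitude $a_j$, onset
$\tau_j$, frequency offset $f_j$ (slice selection), and phase $\phi_j$;
$\Delta f$ is the residual offset between the scanner frequency and the SDR
demodulation frequency (there is no link between the two devices, so it is
never zero); $n$ is complex Gaussian receiver noise; and $\mathrm{quant}_b$
is the $b$-bit ADC. The renderer implements exactly this model (with
sub-sample pulse placement, so scripted timings are not quantised to the
sample grid), and the decoder inverts it.

Two physical conventions anchor the analysis:

* **Timing is peak-to-peak.** Every interval (echo spacing, TR, TI) is a
  difference of envelope-peak times, the measurement one can also read off a
  plotted pulse train.
* **Flip angle is envelope area.** In the small-tip regime
  $\alpha \propto \int |B_1|\,dt$, so ratios of pulse areas are ratios of
  flip angles; a 180° refocusing pulse has twice the area of the 90°
  excitation of the same shape, and a declared reference angle turns an
  area ratio into degrees. By the Fourier zero-frequency identity the
  envelope area equals the on-resonance spectral amplitude, so the
  time-domain ratio and a spectral-amplitude ratio are the same estimator;
  both are implemented (`flip_angle_from_ratio(mode = "spectral")` is the
  cross-check).

## The decoding chain

`decode()` runs the full chain; each stage is exported on its own.

**Carrier-offset estimation.** The spectrum of the strongest detected burst
(8× zero-padded FFT, Hann window, parabolic interpolation of the
log-magnitude peak) gives $\Delta f$; `fine_demodulate()` removes it by
complex rotation. No filtering is applied — the envelope is invariant under
rotation, and phases within a pulse become readable. When a recording
contains several per-slice offsets, "the" carrier offset is by convention
that of the strongest pulse; per-pulse frequencies are interpreted relative
to it, which preserves their ranks (all a slice-ordering analysis needs).
On a near-constant envelope the whole record is treated as one carrier, but
only if its spectrum is genuinely peaked (at least 20× the median bin) —
otherwise the input is noise and the estimator asks for a manual window
instead of returning a meaningless number.

**Detection.** The envelope is lightly smoothed (0.1 ms moving average) and
thresholded at $\max(k_n \cdot \hat\sigma,\; 0.02 \cdot \max)$, where
$\hat\sigma$ is the scaled median of the envelope (`median/0.6745`), robust
because pulses occupy a small fraction of the record. Hysteresis (closing at
half the opening threshold) and a 0.2 ms merge gap keep the zero-crossings
inside a sinc envelope from splitting a pulse; the merge gap is far below
the shortest real inter-pulse gap in this domain (the ~2 ms binomial
sub-pulse gap). Events shorter than 50 µs are dropped.

**Per-pulse measurement.** The peak time of a curved peak is a
least-squares parabola vertex over the top 5% of the envelope; a flat top
(rect pulses) instead takes the plateau centre, computed as the centroid of
the envelope mass above half maximum — identical by symmetry, but averaging
quantisation ripple over the whole top. Smoothing is computed with padded
context so the hysteresis-asymmetric event boundaries cannot bias it. Area
is the trapezoidal integral of the raw envelope over the event; centre
frequency and phase come from the windowed segment spectrum.

**Composites and roles.** Runs of short pulses (every member and every gap
below 2.4 ms) are grouped into composite events whose peak is the largest
sub-pulse — for a binomial 1–2–1 water excitation, the central "2". The
2.4 ms limit sits between the binomial sub-pulse gaps (~2.0 ms) and
everything else in the fixtures (TurboFLASH in-train gaps ~2.7 ms; spin-echo
excitation→refocusing gaps involve pulses longer than the limit, which the
member-duration gate excludes). Roles are then inferred structurally:
long (≥8), equal, group-covering runs of small pulses are readout trains; a
large pulse just before a train is a preconditioning pulse; a leading pulse
100 ms or more ahead of the next is an inversion; composites are water
excitations; the first remaining pulse of a group is the excitation and
later ones refocusing pulses — a trailing pulse that breaks the refocusing
rhythm is a restoration candidate. A fixed area window around "twice the
excitation area" is deliberately *not* used as the refocusing gate: variable
flip-angle trains sweep their refocusing areas down to a quarter of the
maximum, so the 2× ratio is reported as a measurement, not assumed.

**Grouping into repetitions.** Slices repeat, but a gap-based split (gaps
above 3× the median peak interval) only works when the repetition period
dwarfs the in-group spacing — it fails for a 7-echo train that fills 64 ms
of an 80 ms slice period, and for an inversion-prepared sequence whose TI
(156 ms) is comparable to its largest internal gap. `estimate_slice_tr()`
therefore falls back to periodicity: the smallest event-count stride whose
k-step peak differences are constant within 0.5% (far looser than the
sub-sample timing noise of true structure, tight enough to reject folding a
CPMG train across its half-spacing first interval). Group anchors are the
first readout pulse where a train exists — so a preconditioning pulse played
before the second TurboFLASH train does not shift the measured train-start
interval — and a lone preconditioning "group" is merged into its train.

**Shape classification.** Each event's envelope is resampled to a 256-point
grid (10% margins) and Pearson-correlated against unit templates of each
candidate shape generated by `make_shape()`; a coarse-then-fine search over
template duration (0.7–1.15× the detected span) absorbs the span's
threshold-crossing bias. Labels below a 0.9 score are `unknown`; composites
are classified per sub-event and flagged `binomial121` when three sub-areas
fit 1:2:1 within 10%.

## The synthetic fixtures

The packaged fixtures encode, as scripted ground truth, the measured
timings of five recorded clinical sequences: the 5-slice 7-echo spin echo
(80 ms slice repetition, 9.9 ms echo spacing, ±1 kHz-spaced slices acquired
even–odd interleaved), the TurboFLASH B1 map (two 64-pulse trains 247 ms
apart, 3.04 ms in-train spacing, a sinc preconditioning pulse with 8× the
10° readout area, i.e. 80°), the STIR SE-EPI (10 ms hyperbolic-secant
inversion, TI 156 ms, binomial 1–2–1 with 2.38 ms spacing, TE 48 ms, 356 ms
slice repetition), and three 3D turbo-spin-echo variants (sinc excitation
then rectangular refocusing pulses: constant, constant-with-restoration,
variable flip angle).

Values the sources do not print were fixed once at realistic desk-scale
choices and are not tuned: 3-lobe unapodized sincs of 2.56 ms; 0.4 ms
binomial sub-pulses; hyperbolic secant with $\mu = 5$ truncated at 5% of
peak (so the detected threshold-crossing span equals the full 10 ms
support); 0.3 ms readout rects; 40 refocusing pulses spaced 5.1 ms in the
3D trains, with the restoration pulse 1.5 spacings after the last echo and
a smooth decay–plateau–ramp flip-angle schedule bottoming at 25%; slice
offsets −2…+2 kHz acquired in order {1,3,5,2,4}. The default render
config is the emulated dongle: 192 kHz I/Q, 1.2 kHz carrier offset, noise
σ = 10⁻³ full scale per component, 8-bit quantisation, seed 0.

What the synthetic data does *not* emulate: vendor pulse tables (proprietary
shapes), gradients and their acoustic/eddy-current signatures, B1
inhomogeneity, receiver clock drift, room interference, and CubicSDR's
decimation filter. Passing round trips therefore demonstrate that the
decoder inverts the stated capture model to well under 1% in timing — not
that every real capture will be as clean; on real data the semi-automatic
window selection (`estimate_carrier_offset(window=)`, `--offset-hz`,
`--swap-iq`) exists precisely for the messier cases.

## Numerical choices and degenerate inputs

* WAV integers are scaled by $2^{b-1}$ so the negative rail maps exactly to
  −1.0; 8-bit files use the standard unsigned offset-128 encoding. A 16-bit
  round trip is lossless to $2^{-15}$ per component.
* The channel convention (I = channel 0) matches common SDR tooling; since
  recorders disagree, `--swap-iq` conjugates the stream on read.
* Quantisation at 8 bits leaves ~0.4% envelope ripple at typical amplitudes;
  the centroid/least-squares peak refinements keep the induced peak-time
  noise below half a sample (2.6 µs at 192 kHz), which is what makes the
  recovered intervals land within ~0.03% of ground truth — comfortably
  inside the ~1% agreement one can claim for peak-to-peak measurements.
* An all-zero or noise-only recording decodes to an empty event list with a
  warning, not an error; quantities a recording cannot support (e.g. a slice
  TR for a single-shot 3D sequence) are absent from the report rather than
  fabricated.
* Ties in a flat-top argmax resolve to the plateau centre by construction of
  the centroid rule.

## Worked round trip

```{r roundtrip}
fx  <- rf_fixture("semc")
rec <- render(fx$script, fx$config)
rep <- decode(rec)
c(slice_tr_ms = 1e3 * rep$slice_tr_s,
  echo_spacing_ms = 1e3 * rep$echo_spacing_s)
rep$acquisition_order
rep$interleave_even_odd
```

The problem sizes here are deliberate desk-scale choices: 0.4–1.6 s of
192 kHz I/Q per fixture (77k–311k complex samples), which keeps a full
six-fixture round trip, including classification, in a few seconds.

## Known limitations

Overlapping pulses are not deconvolved; detection is threshold-based, so
pulses below ~2% of the strongest peak (or inside another pulse's span) are
missed — matching the dynamic-range limit of an 8-bit front end. Durations
are threshold-crossing spans and under-report the tails of sinc/sech pulses
unless, as for the packaged inversion, the shape is truncated above the
detection threshold. Absolute flip angles require a declared reference
angle; absolute B1 requires a calibrated geometry and is out of scope.
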