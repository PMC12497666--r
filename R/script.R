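# Declarative pulse-sequence scripts: the generator-side ground truth.

#' Pulse event specification
#'
#' One timed, shaped, frequency-offset RF pulse on the sequence timeline.
#'
#' @param onset_s Seconds from record start to the first envelope sample
#'   (>= 0).
#' @param shape A [pulse_shape].
#' @param peak_amplitude Peak envelope amplitude in dimensionless relative
#'   units (> 0).
#' @param freq_offset_hz Frequency offset in Hz relative to the centre
#'   (demodulation) frequency — e.g. the per-slice offset of a selective
#'   pulse.
#' @param phase_rad RF phase in radians.
#' @param role Nominal role of the pulse in the sequence (ground-truth label;
#'   the decoder infers its own).
#' @param slice_index Spatial slice index (0-based) or `NA`.
#' @return An object of class `pulse_event_spec`.
#' @export
pulse_event <- function(onset_s, shape, peak_amplitude = 1,
                        freq_offset_hz = 0, phase_rad = 0,
                        role = c("excitation", "refocusing", "inversion",
                                 "preconditioning", "restoration", "readout",
                                 "water_excitation"),
                        slice_index = NA_integer_) {
  role <- match.arg(role)
  stopifnot(inherits(shape, "pulse_shape"))
  if (onset_s < 0) stop("onset_s must be >= 0")
  if (peak_amplitude <= 0) stop("peak_amplitude must be > 0")
  structure(list(onset_s = onset_s, shape = shape,
                 peak_amplitude = peak_amplitude,
                 freq_offset_hz = freq_offset_hz, phase_rad = phase_rad,
                 role = role, slice_index = as.integer(slice_index)),
            class = "pulse_event_spec")
}

#' Pulse-sequence script
#'
#' Ordered list of [pulse_event]s plus a total duration; the declarative
#' ground truth that [render()] turns into an I/Q recording.
#'
#' @param name Sequence name.
#' @param events List of [pulse_event]s; sorted by onset on construction.
#' @param total_duration_s Total record length in seconds; must cover the last
#'   event.
#' @return An object of class `sequence_script`.
#' @export
sequence_script <- function(name, events, total_duration_s) {
  stopifnot(all(vapply(events, inherits, logical(1), "pulse_event_spec")))
  ord <- order(vapply(events, function(e) e$onset_s, numeric(1)))
  events <- events[ord]
  last_end <- max(vapply(events, function(e) e$onset_s + e$shape$duration_s,
                         numeric(1)), 0)
  if (total_duration_s < last_end)
    stop("total_duration_s (", total_duration_s,
         ") shorter than last event end (", last_end, ")")
  structure(list(name = name, events = events,
                 total_duration_s = total_duration_s),
            class = "sequence_script")
}

#' @export
print.sequence_script <- function(x, ...) {
  cat(sprintf("<sequence_script> '%s': %d events over %.3f s\n",
              x$name, length(x$events), x$total_duration_s))
  invisible(x)
}

#' Ground-truth peak time of a scripted event
#'
#' Onset plus the shape's envelope-peak offset — the time a peak-to-peak
#' timing measurement should recover.
#' @param ev A [pulse_event].
#' @return Peak time in seconds.
#' @export
event_peak_time <- function(ev) ev$onset_s + ev$shape$duration_s / 2

shape_to_list <- function(s) {
  keep <- !vapply(s, is.null, logical(1))
  unclass(s)[keep]
}

#' Serialise / deserialise sequence scripts as JSON
#'
#' Round-trippable JSON form of a [sequence_script] (schema shipped in
#' `inst/schemas/sequence_script.schema.json`).
#'
#' @param script A [sequence_script].
#' @param path File path.
#' @return `write_sequence_script` returns `path` invisibly;
#'   `read_sequence_script` returns a [sequence_script].
#' @export
write_sequence_script <- function(script, path) {
  out <- list(
    name = script$name,
    total_duration_s = script$total_duration_s,
    events = lapply(script$events, function(e)
      list(onset_s = e$onset_s, shape = shape_to_list(e$shape),
           peak_amplitude = e$peak_amplitude,
           freq_offset_hz = e$freq_offset_hz, phase_rad = e$phase_rad,
           role = e$role, slice_index = e$slice_index)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_sequence_script
#' @export
read_sequence_script <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  events <- lapply(j$events, function(e) {
    s <- e$shape
    shape <- pulse_shape(
      kind = s$kind,
      duration_s = if (s$kind == "binomial121") NULL else s$duration_s,
      n_lobes = s$n_lobes %||% 3L,
      apodization = s$apodization %||% "none",
      beta_rad_per_s = s$beta_rad_per_s,
      mu = s$mu %||% 5,
      truncation_frac = s$truncation_frac %||% 0.05,
      sub_duration_s = s$sub_duration_s %||% 4e-4,
      spacing_s = s$spacing_s %||% 2.38e-3)
    pulse_event(e$onset_s, shape, e$peak_amplitude,
                e$freq_offset_hz %||% 0, e$phase_rad %||% 0,
                role = e$role %||% "excitation",
                slice_index = e$slice_index %||% NA_integer_)
  })
  sequence_script(j$name, events, j$total_duration_s)
}
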