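# Full decoding chain: offset estimation, fine demodulation, detection,
# composite grouping, role inference, shape classification and all applicable
# sequence-level quantities.

#' Decode an I/Q recording into a sequence report
#'
#' Runs the full chain: residual carrier-offset estimation (unless an offset
#' is given), fine digital demodulation, pulse detection, composite grouping,
#' role inference, pulse-shape classification and every applicable derived
#' quantity. Quantities the recording does not support (e.g. a slice
#' repetition time for a single-shot 3D sequence) remain absent rather than
#' fabricated; problems are collected as warnings in the report.
#'
#' @param x An [iq_recording] or `baseband_signal`.
#' @param cfg A [detect_config].
#' @param offset_hz Carrier offset to remove; `NULL` (default) estimates it.
#' @param readout_flip_deg Declared flip angle of readout-train pulses,
#'   used as the reference for the preconditioning-pulse flip-angle estimate.
#' @param excitation_flip_deg Declared excitation flip angle, used as the
#'   reference for the refocusing-pulse estimate.
#' @param classify Classify pulse shapes (template correlation).
#' @return An object of class `sequence_report`.
#' @examples
#' fx <- rf_fixture("semc")
#' rep <- decode(render(fx$script, fx$config))
#' rep$slice_tr_s          # ~0.080
#' rep$interleave_even_odd # TRUE
#' @export
decode <- function(x, cfg = detect_config(), offset_hz = NULL,
                   readout_flip_deg = 10, excitation_flip_deg = 90,
                   classify = TRUE) {
  warnings <- character()
  note <- function(e) conditionMessage(e)
  bb0 <- as_baseband(x)

  bound <- NA_real_
  offset_given <- !is.null(offset_hz)
  if (!offset_given) {
    est <- tryCatch(estimate_carrier_offset(bb0), error = function(e) e)
    if (inherits(est, "error")) {
      warnings <- c(warnings, paste("offset estimation failed:", note(est)))
      offset_hz <- 0
    } else {
      offset_hz <- est$offset_hz
      bound <- est$bound_hz
    }
  }
  bb <- fine_demodulate(bb0, offset_hz, residual_bound_hz = bound)

  events <- detect_pulses(bb, cfg)
  warnings <- c(warnings, attr(events, "warnings"))
  events <- group_composites(events, cfg$composite_max_gap_s)
  events <- infer_roles(events)
  if (classify) events <- lapply(events, classify_event, bb = bb)

  rep <- list(applied_offset_hz = offset_hz,
              offset_estimated = !offset_given,
              n_events = length(events),
              events = events)

  try_q <- function(expr) tryCatch(expr, error = function(e) NULL,
                                   warning = function(w) NULL)

  if (length(events) >= 2) {
    rep$peak_intervals_s <- peak_intervals(events)
    rep$slice_tr_s <- try_q(estimate_slice_tr(events))

    grp <- segment_events(events)
    roles <- ev_field(events, "role_guess", mode = character(1))
    per_group <- function(fn) {
      vals <- lapply(sort(unique(grp)), function(g) try_q(fn(events[grp == g])))
      vals[!vapply(vals, is.null, logical(1))]
    }

    et <- per_group(estimate_echo_timing)
    if (length(et)) {
      times <- vapply(et, `[[`, numeric(1), "echo_time_s")
      spac <- vapply(et, `[[`, numeric(1), "echo_spacing_s")
      rep$echo_time_s <- stats::median(times)
      rep$exc_to_refocus_s <- rep$echo_time_s / 2
      if (any(is.finite(spac)))
        rep$echo_spacing_s <- stats::median(spac[is.finite(spac)])
    }

    inv <- per_group(inversion_delay)
    if (length(inv)) rep$inversion_delay_s <- stats::median(unlist(inv))

    # spacing inside readout trains (TurboFLASH repetition time)
    ro <- which(roles %in% "readout")
    if (length(ro) >= 2) {
      d <- numeric()
      for (g in unique(grp[ro])) {
        ri <- ro[grp[ro] == g]
        if (length(ri) >= 2)
          d <- c(d, diff(ev_field(events[ri], "t_peak_s"))[diff(ri) == 1])
      }
      if (length(d)) rep$readout_spacing_s <- stats::median(d)
    }

    # sub-pulse spacing inside composite events
    comp <- events[vapply(events, function(e)
      !is.null(e$sub_events) && length(e$sub_events) >= 2, logical(1))]
    if (length(comp)) {
      d <- unlist(lapply(comp, function(e)
        diff(ev_field(e$sub_events, "t_peak_s"))))
      rep$composite_spacing_s <- stats::median(d)
    }

    sfa <- try_q(suppressWarnings(slice_frequency_analysis(events)))
    if (!is.null(sfa) && !is.null(sfa$acquisition_order)) {
      rep$slice_frequencies_hz <- sfa$slice_frequencies_hz
      rep$acquisition_order <- sfa$acquisition_order
      rep$interleave_even_odd <- sfa$interleave_even_odd
    }

    rep$flip_estimates <- decode_flip_estimates(
      events, roles, readout_flip_deg, excitation_flip_deg)
    rep$train_profile <- try_q(train_flip_profile(events))
  } else {
    warnings <- c(warnings, "fewer than 2 events: no derived quantities")
  }

  rep$intervals <- report_intervals(rep)
  rep$warnings <- warnings
  structure(rep, class = "sequence_report")
}

decode_flip_estimates <- function(events, roles, readout_flip_deg,
                                  excitation_flip_deg) {
  out <- list()
  areas <- ev_field(events, "area")
  ro <- which(roles %in% "readout")
  pre <- which(roles %in% "preconditioning")
  if (length(ro) && length(pre)) {
    ref_ev <- events[[ro[which.min(abs(areas[ro] - stats::median(areas[ro])))]]]
    est <- flip_angle_from_ratio(ref_ev, readout_flip_deg, events[[pre[1]]])
    est$target_role <- "preconditioning"
    out <- c(out, list(est))
  }
  exc <- which(roles %in% c("excitation", "water_excitation"))
  refs <- which(roles %in% "refocusing")
  if (length(exc) && length(refs)) {
    med_ref <- events[[refs[which.min(abs(areas[refs] -
                                            stats::median(areas[refs])))]]]
    est <- flip_angle_from_ratio(events[[exc[1]]], excitation_flip_deg, med_ref)
    est$target_role <- "refocusing"
    out <- c(out, list(est))
  }
  if (length(out)) out else NULL
}

# named vector of every interval (seconds) the report carries, used for
# ground-truth comparison
report_intervals <- function(rep) {
  nm <- c(slice_tr = "slice_tr_s", echo_spacing = "echo_spacing_s",
          echo_time = "echo_time_s", exc_to_refocus = "exc_to_refocus_s",
          inversion_delay = "inversion_delay_s",
          composite_spacing = "composite_spacing_s",
          readout_spacing = "readout_spacing_s")
  out <- numeric()
  for (k in names(nm)) {
    v <- rep[[nm[[k]]]]
    if (!is.null(v) && is.finite(v)) out[k] <- v
  }
  out
}

#' @export
print.sequence_report <- function(x, ...) {
  cat("<sequence_report>\n")
  cat(sprintf("  events: %d   carrier offset removed: %.1f Hz%s\n",
              x$n_events, x$applied_offset_hz,
              if (isTRUE(x$offset_estimated)) " (estimated)" else ""))
  ms <- function(v) sprintf("%.2f ms", 1e3 * v)
  if (!is.null(x$slice_tr_s)) cat("  slice repetition:", ms(x$slice_tr_s), "\n")
  if (!is.null(x$echo_spacing_s)) cat("  echo spacing:   ", ms(x$echo_spacing_s), "\n")
  if (!is.null(x$echo_time_s)) cat("  echo time:      ", ms(x$echo_time_s), "\n")
  if (!is.null(x$inversion_delay_s))
    cat("  inversion delay:", ms(x$inversion_delay_s), "\n")
  if (!is.null(x$readout_spacing_s))
    cat("  readout spacing:", ms(x$readout_spacing_s), "\n")
  if (!is.null(x$composite_spacing_s))
    cat("  composite sub-pulse spacing:", ms(x$composite_spacing_s), "\n")
  if (!is.null(x$slice_frequencies_hz))
    cat("  slice frequencies (kHz):",
        paste(sprintf("%.2f", x$slice_frequencies_hz / 1e3), collapse = ", "),
        "\n")
  if (!is.null(x$acquisition_order))
    cat("  acquisition order:", paste(x$acquisition_order, collapse = " "),
        if (isTRUE(x$interleave_even_odd)) " (even-odd interleaved)" else "",
        "\n")
  if (!is.null(x$flip_estimates))
    for (fe in x$flip_estimates)
      cat(sprintf("  flip angle (%s): %.1f deg = %g deg x %.3f\n",
                  fe$target_role, fe$deduced_angle_deg,
                  fe$reference_angle_deg, fe$area_ratio))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Serialise a sequence report as JSON
#'
#' Stable key order; times in seconds, frequencies in Hz. Events are
#' flattened to the CSV columns with sub-event peaks nested.
#'
#' @param rep A `sequence_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(rep, path) {
  ev <- events_as_table(rep$events)
  subs <- lapply(rep$events, function(e)
    if (is.null(e$sub_events)) NULL else events_as_table(e$sub_events))
  out <- list(
    applied_offset_hz = rep$applied_offset_hz,
    offset_estimated = rep$offset_estimated,
    n_events = rep$n_events,
    slice_tr_s = rep$slice_tr_s,
    echo_spacing_s = rep$echo_spacing_s,
    echo_time_s = rep$echo_time_s,
    exc_to_refocus_s = rep$exc_to_refocus_s,
    inversion_delay_s = rep$inversion_delay_s,
    readout_spacing_s = rep$readout_spacing_s,
    composite_spacing_s = rep$composite_spacing_s,
    slice_frequencies_hz = rep$slice_frequencies_hz,
    acquisition_order = rep$acquisition_order,
    interleave_even_odd = rep$interleave_even_odd,
    flip_estimates = lapply(rep$flip_estimates, unclass),
    train_profile = rep$train_profile,
    intervals = as.list(rep$intervals),
    warnings = rep$warnings,
    events = ev,
    sub_events = subs)
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
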