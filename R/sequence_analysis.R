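# Sequence-level quantities derived from detected pulse events: inter-pulse
# timings (per-slice repetition, echo spacing/time, inversion delay),
# per-slice frequencies and interleave order, flip-angle ratios, and
# flip-angle train profiles.

#' Successive peak-to-peak intervals
#'
#' Differences of successive event peak times — the peak-to-peak timing
#' convention used for all interval measurements (e.g. the excitation-to-
#' refocusing interval is half the echo time).
#'
#' @param events List of `pulse_event`s (>= 2), sorted by time.
#' @return Numeric vector of `length(events) - 1` intervals in seconds.
#' @export
peak_intervals <- function(events) {
  if (length(events) < 2) stop("need at least 2 events for peak intervals")
  diff(ev_field(events, "t_peak_s"))
}

# Split events into repeating groups. Primary rule: split at peak gaps
# larger than 3x the median gap. When that yields a single group (dense
# sequences whose inter-group gap is comparable to the in-group intervals,
# e.g. a 7-echo train filling most of its 80 ms slice period), fall back to
# periodicity: the smallest event-count stride k whose k-step peak
# differences are constant within 2% and larger than any single gap defines
# the repeating unit. The 0.5% consistency tolerance is far looser than the
# sub-sample timing noise of true periodic structure, yet tight enough to
# reject accidental near-periods (e.g. folding a CPMG train whose first
# interval is half an echo spacing).
segment_events <- function(events) {
  n <- length(events)
  if (n == 0) return(integer())
  if (n == 1) return(1L)
  tp <- ev_field(events, "t_peak_s")
  gaps <- diff(tp)
  med <- stats::median(gaps)
  grp <- cumsum(c(TRUE, gaps > 3 * med))
  if (max(grp) > 1) return(as.integer(grp))
  for (k in seq_len(n %/% 2)) {
    if (n - k < 2) break
    d <- tp[(k + 1):n] - tp[1:(n - k)]
    if ((max(d) - min(d)) <= 0.005 * stats::median(d) &&
        stats::median(d) > max(gaps))
      return(as.integer((seq_len(n) - 1L) %/% k + 1L))
  }
  rep(1L, n)
}

#' Infer the role of each detected pulse
#'
#' Heuristic role labelling that automates what a sequence diagram shows:
#' long runs of small, equal pulses covering a repeating group are readout
#' trains; a large pulse immediately preceding a readout train is a
#' preconditioning pulse; a leading pulse 100 ms or more before the next one
#' is an inversion; a composite event is a (water-)excitation; the first
#' remaining pulse of a group is the excitation; later pulses are refocusing
#' pulses, except a trailing pulse that breaks the refocusing rhythm after a
#' long train, which is a restoration candidate. Roles may remain unset.
#'
#' @param events List of `pulse_event`s sorted by time.
#' @return The events with `role_guess` filled in.
#' @export
infer_roles <- function(events) {
  n <- length(events)
  if (n == 0) return(events)
  grp <- segment_events(events)
  areas <- ev_field(events, "area")
  tp <- ev_field(events, "t_peak_s")
  is_comp <- vapply(events, function(e) !is.null(e$sub_events), logical(1))
  roles <- rep(NA_character_, n)

  # candidate readout runs: consecutive events with similar areas
  run_id <- integer(n); rid <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    rid <- rid + 1L; run_id[idx[1]] <- rid
    for (i in idx[-1]) {
      if (abs(areas[i] / areas[i - 1L] - 1) <= 0.15) run_id[i] <- run_id[i - 1L]
      else { rid <- rid + 1L; run_id[i] <- rid }
    }
  }
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (length(idx) < 8) next
    if (length(idx) / sum(grp == grp[idx[1]]) < 0.8) next
    a <- areas[idx]
    if (stats::sd(a) / mean(a) > 0.10) next
    outside <- areas[-idx]
    if (length(outside) > 0 && stats::median(a) >= 0.75 * max(outside)) next
    roles[idx] <- "readout"
  }

  # preconditioning: large pulse shortly before a readout train
  ro <- which(roles == "readout")
  if (length(ro)) {
    ro_med_area <- stats::median(areas[ro])
    for (i in which(is.na(roles))) {
      nxt <- ro[ro > i]
      if (length(nxt) && tp[nxt[1]] - tp[i] < 0.06 &&
          areas[i] >= 2 * ro_med_area)
        roles[i] <- "preconditioning"
    }
  }

  for (g in unique(grp)) {
    idx <- which(grp == g & is.na(roles))
    if (length(idx) == 0) next
    if (length(idx) >= 2 && tp[idx[2]] - tp[idx[1]] >= 0.1) {
      roles[idx[1]] <- "inversion"
      idx <- idx[-1]
    }
    if (length(idx) == 0) next
    comp_idx <- idx[is_comp[idx]]
    if (length(comp_idx)) {
      roles[comp_idx] <- "water_excitation"
      exc <- comp_idx[1]
    } else {
      exc <- idx[1]
      roles[exc] <- "excitation"
    }
    rest <- idx[idx > exc & is.na(roles[idx])]
    if (length(rest) == 0) next
    roles[rest] <- "refocusing"
    if (length(rest) >= 8) {
      ints <- diff(tp[rest])
      med_int <- stats::median(ints)
      last_int <- ints[length(ints)]
      if (abs(last_int - med_int) / med_int > 0.2)
        roles[rest[length(rest)]] <- "restoration"
    }
  }

  for (i in seq_len(n)) events[[i]]$role_guess <- roles[i]
  events
}

#' Per-slice repetition time
#'
#' Segments the events into repeating groups (see Details) and returns the
#' median interval between successive group anchors. The anchor of a group is
#' its first readout pulse when the group contains a readout train (so a
#' preconditioning pulse played before a train does not shift the measured
#' train-start interval), otherwise its first pulse. A group consisting only
#' of a preconditioning pulse is merged into the following train.
#'
#' @details Groups are found by splitting at peak gaps larger than 3x the
#' median gap, with a periodicity fallback for dense sequences whose
#' inter-group gap is comparable to the in-group echo spacing.
#'
#' @param events List of measured `pulse_event`s (roles from [infer_roles()]
#'   are honoured when present).
#' @return Slice repetition time in seconds.
#' @export
estimate_slice_tr <- function(events) {
  if (length(events) < 2)
    stop("cannot estimate slice repetition from fewer than 2 events")
  tp <- ev_field(events, "t_peak_s")
  roles <- ev_field(events, "role_guess", mode = character(1))
  grp <- segment_events(events)
  ug <- sort(unique(grp))
  if (length(ug) >= 2) {
    for (gi in seq_len(length(ug) - 1)) {
      idx <- which(grp == ug[gi])
      if (length(idx) <= 2 && all(roles[idx] %in% "preconditioning"))
        grp[idx] <- ug[gi + 1]
    }
  }
  ug <- sort(unique(grp))
  if (length(ug) < 2)
    stop("cannot determine slice repetition: fewer than 2 repeating groups")
  anchors <- vapply(ug, function(g) {
    idx <- which(grp == g)
    ridx <- idx[roles[idx] %in% "readout"]
    tp[if (length(ridx)) ridx[1] else idx[1]]
  }, numeric(1))
  stats::median(diff(anchors))
}

#' Echo timing of one repetition group
#'
#' The echo time is twice the excitation-to-first-refocusing peak interval
#' (spin-echo timing); the echo spacing is the median interval between
#' successive refocusing peaks (equal to the echo time for CPMG-timed
#' trains), `NA` when the group has a single refocusing pulse.
#'
#' @param group List of `pulse_event`s of one repetition with roles set.
#' @return List with `echo_spacing_s` and `echo_time_s`.
#' @export
estimate_echo_timing <- function(group) {
  roles <- ev_field(group, "role_guess", mode = character(1))
  tp <- ev_field(group, "t_peak_s")
  exc <- which(roles %in% c("excitation", "water_excitation"))
  refs <- which(roles == "refocusing")
  if (length(exc) == 0) stop("group has no excitation-role event")
  if (length(refs) == 0) stop("group has no refocusing-role events")
  exc <- exc[1]
  echo_time <- 2 * (tp[refs[1]] - tp[exc])
  echo_spacing <- if (length(refs) >= 2) stats::median(diff(tp[refs]))
                  else NA_real_
  list(echo_spacing_s = echo_spacing, echo_time_s = echo_time)
}

#' Inversion delay of one repetition group
#'
#' Peak-to-peak interval from the inversion pulse to the excitation pulse
#' (for a composite excitation, the composite peak — its largest sub-pulse —
#' is used). This is the measured inversion time of a STIR preparation.
#'
#' @param group List of `pulse_event`s of one repetition with roles set.
#' @return Inversion delay in seconds.
#' @export
inversion_delay <- function(group) {
  roles <- ev_field(group, "role_guess", mode = character(1))
  tp <- ev_field(group, "t_peak_s")
  inv <- which(roles == "inversion")
  exc <- which(roles %in% c("excitation", "water_excitation"))
  if (length(inv) == 0 || length(exc) == 0)
    stop("group needs both an inversion-role and an excitation-role event")
  tp[exc[1]] - tp[inv[1]]
}

#' Per-slice frequencies, acquisition order and interleave detection
#'
#' Assigns one representative frequency to each repeating group (median of
#' its events' centre frequencies), ranks the groups by frequency to obtain
#' 0-based spatial slice indices, and reports the spatial indices in temporal
#' order. The order is flagged even-odd interleaved when it visits all even
#' spatial indices then all odd ones (or vice versa).
#'
#' @param events List of measured `pulse_event`s.
#' @param min_spread_hz Below this frequency spread the slices are considered
#'   degenerate and the order undefined (`NULL`, with a warning).
#' @return List with `slice_frequencies_hz` (per group, temporal order),
#'   `acquisition_order` (0-based spatial indices) and
#'   `interleave_even_odd`.
#' @export
slice_frequency_analysis <- function(events, min_spread_hz = 50) {
  grp <- segment_events(events)
  ug <- sort(unique(grp))
  # singleton groups (e.g. a lone preconditioning pulse between readout
  # trains) carry no reliable representative frequency; drop them
  ug <- ug[vapply(ug, function(g) sum(grp == g) >= 2, logical(1))]
  if (length(ug) < 2) stop("need >= 2 repeating groups for slice analysis")
  freqs <- vapply(ug, function(g)
    stats::median(ev_field(events[grp == g], "f_center_hz")), numeric(1))
  if (max(freqs) - min(freqs) < min_spread_hz) {
    warning("slice frequencies are degenerate; acquisition order undefined")
    return(list(slice_frequencies_hz = freqs, acquisition_order = NULL,
                interleave_even_odd = NA))
  }
  spatial <- rank(freqs, ties.method = "first") - 1L
  list(slice_frequencies_hz = freqs,
       acquisition_order = as.integer(spatial),
       interleave_even_odd = is_even_odd_interleaved(spatial))
}

#' Even-odd interleave test for a slice acquisition order
#'
#' `TRUE` when the order visits all even 0-based spatial indices then all odd
#' ones, or all odd then all even.
#'
#' @param order Integer vector, a permutation of `0:(n-1)`.
#' @return Logical.
#' @export
is_even_odd_interleaved <- function(order) {
  if (length(order) < 3) return(FALSE)
  par <- order %% 2
  one_switch <- function(p) {
    r <- rle(p)
    length(r$values) == 2
  }
  one_switch(par)
}

#' Flip-angle ratio between two pulses
#'
#' In the small-tip regime the flip angle is proportional to the envelope
#' area, so the ratio of two pulse areas equals the ratio of their flip
#' angles; given a declared reference angle the target angle follows. The
#' default estimator is the time-domain envelope area; by the Fourier
#' zero-frequency identity this equals the ratio of on-resonance spectral
#' amplitudes, which `mode = "spectral"` computes directly (the modulus of
#' the coherently demodulated segment integral) as a cross-check.
#'
#' @param reference A measured `pulse_event` with a known flip angle.
#' @param reference_angle_deg Its flip angle in degrees.
#' @param target The pulse whose angle is sought.
#' @param mode `"area"` (default) or `"spectral"`.
#' @param bb Baseband signal; required for `mode = "spectral"`.
#' @return An object of class `flip_angle_estimate`: a list with
#'   `reference_angle_deg`, `area_ratio` and
#'   `deduced_angle_deg = reference_angle_deg * area_ratio`.
#' @export
flip_angle_from_ratio <- function(reference, reference_angle_deg, target,
                                  mode = c("area", "spectral"), bb = NULL) {
  mode <- match.arg(mode)
  if (mode == "area") {
    if (reference$area <= .Machine$double.eps)
      stop("reference pulse area is zero; cannot form a ratio")
    ratio <- target$area / reference$area
  } else {
    if (is.null(bb)) stop("spectral mode needs the baseband signal")
    amp0 <- function(ev) {
      bbx <- as_baseband(bb)
      fs <- bbx$sample_rate_hz
      i0 <- max(1L, round(ev$t_start_s * fs) + 1L)
      i1 <- min(length(bbx$samples), round(ev$t_end_s * fs))
      t <- (seq(i0, i1) - 1) / fs
      Mod(sum(bbx$samples[i0:i1] * exp(-1i * 2 * pi * ev$f_center_hz * t))) / fs
    }
    a_ref <- amp0(reference)
    if (a_ref <= .Machine$double.eps)
      stop("reference pulse spectral amplitude is zero; cannot form a ratio")
    ratio <- amp0(target) / a_ref
  }
  structure(list(reference_angle_deg = reference_angle_deg,
                 area_ratio = ratio,
                 deduced_angle_deg = reference_angle_deg * ratio),
            class = "flip_angle_estimate")
}

#' @export
print.flip_angle_estimate <- function(x, ...) {
  cat(sprintf("<flip_angle_estimate> ref %g deg x ratio %.4f = %.2f deg\n",
              x$reference_angle_deg, x$area_ratio, x$deduced_angle_deg))
  invisible(x)
}

#' Normalised flip-angle profile of a refocusing train
#'
#' Areas of the refocusing-role events divided by the maximum area, in
#' temporal order — constant at 1 for a constant-angle train, and tracing the
#' flip-angle schedule of a variable-flip-angle turbo-spin-echo train.
#'
#' @param events List of `pulse_event`s with roles set (>= 3 refocusing).
#' @return Numeric vector of normalised amplitudes.
#' @export
train_flip_profile <- function(events) {
  roles <- ev_field(events, "role_guess", mode = character(1))
  refs <- events[roles == "refocusing" & !is.na(roles)]
  if (length(refs) < 3) stop("need >= 3 refocusing-role events for a profile")
  a <- ev_field(refs, "area")
  a / max(a)
}
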