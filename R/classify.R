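# Template-correlation pulse-shape classification.

ev_field <- function(events, field, mode = numeric(1))
  vapply(events, `[[`, mode, field)

# Sample the envelope of a candidate shape, centred at `center_s`, onto the
# time grid `tg` (zero outside its support).
template_on_grid <- function(kind, duration_s, center_s, tg, fs) {
  env <- Mod(make_shape(pulse_shape(kind, duration_s), fs))
  tt <- center_s + (seq_along(env) - (length(env) + 1) / 2) / fs
  stats::approx(tt, env, xout = tg, yleft = 0, yright = 0, rule = 2)$y
}

#' Classify the shape of a detected pulse
#'
#' Resamples the event's envelope onto a fixed 256-point grid (with a 10%
#' margin on each side), peak-normalises it, and correlates it (Pearson)
#' against unit-amplitude templates of each candidate shape generated by
#' [make_shape()] at matching duration (a small set of duration scalings
#' absorbs threshold-crossing trimming of pulse tails). The label is the
#' best-scoring candidate, or `"unknown"` when the best score falls below
#' `min_score`. Composite events are classified per sub-event and labelled
#' `"binomial121"` when they have three sub-pulses whose areas fit 1:2:1
#' within 10%.
#'
#' @param event A `pulse_event`.
#' @param bb The [iq_recording] or `baseband_signal` the event was detected
#'   on.
#' @param min_score Score below which the label is `"unknown"`.
#' @return A list with `label` (one of `"rect"`, `"sinc"`, `"hypsec"`,
#'   `"binomial121"`, `"composite"`, `"unknown"`) and `score`.
#' @export
classify_shape <- function(event, bb, min_score = 0.9) {
  bb <- as_baseband(bb)
  fs <- bb$sample_rate_hz

  if (!is.null(event$sub_events)) {
    subs <- lapply(event$sub_events, classify_shape, bb = bb,
                   min_score = min_score)
    score <- mean(vapply(subs, `[[`, numeric(1), "score"))
    areas <- ev_field(event$sub_events, "area")
    label <- "composite"
    if (length(areas) == 3 &&
        abs(2 * areas[1] / areas[2] - 1) <= 0.1 &&
        abs(2 * areas[3] / areas[2] - 1) <= 0.1)
      label <- "binomial121"
    return(list(label = label, score = score,
                sub_labels = vapply(subs, `[[`, character(1), "label")))
  }

  span <- event$t_end_s - event$t_start_s
  if (span * fs < 16) stop("event span too short to classify (< 16 samples)")
  pad <- 0.1 * span
  tg <- seq(event$t_start_s - pad, event$t_end_s + pad, length.out = 256)
  i <- seq_along(bb$samples)
  e <- stats::approx((i - 1) / fs, Mod(bb$samples), xout = tg,
                     yleft = 0, yright = 0)$y
  e <- e / max(e)
  center <- (event$t_start_s + event$t_end_s) / 2

  kinds <- c("rect", "sinc", "hypsec")
  best_label <- "unknown"; best_score <- -Inf
  # the span from threshold crossings can overshoot a short pulse (smoothing
  # ramps) or trim the tails of a long one; a coarse-then-fine search over
  # template duration absorbs both
  score_at <- function(kind, scale) {
    s <- suppressWarnings(
      stats::cor(e, template_on_grid(kind, scale * span, center, tg, fs)))
    if (is.finite(s)) s else -Inf
  }
  for (kind in kinds) {
    coarse <- seq(0.7, 1.15, by = 0.05)
    sc <- vapply(coarse, score_at, numeric(1), kind = kind)
    s0 <- coarse[which.max(sc)]
    fine <- seq(s0 - 0.04, s0 + 0.04, by = 0.01)
    sf <- vapply(fine, score_at, numeric(1), kind = kind)
    s_kind <- max(sc, sf)
    if (s_kind > best_score) { best_score <- s_kind; best_label <- kind }
  }
  if (best_score < min_score) best_label <- "unknown"
  list(label = best_label, score = best_score)
}

# classify an event in place (used by decode)
classify_event <- function(event, bb) {
  cl <- tryCatch(classify_shape(event, bb), error = function(e) NULL)
  if (is.null(cl)) return(event)
  event$shape_label <- cl$label
  if (!is.null(event$sub_events) && !is.null(cl$sub_labels)) {
    for (j in seq_along(event$sub_events))
      event$sub_events[[j]]$shape_label <- cl$sub_labels[j]
  }
  event
}
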