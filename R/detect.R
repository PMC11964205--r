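#' Discard reasons recognised for tap events
#' @export
DISCARD_REASONS <- c("post_dropout", "refractory", "pause_outlier",
                     "initial_trim", "manual")

#' Construct a tap-event series
#'
#' Container for the tap onsets of one trial: the kept times plus an
#' audit trail of discarded events, so that cleaning steps conserve
#' events rather than silently dropping them.
#'
#' @param times Tap onset times in seconds, strictly increasing.
#' @param source `"detected"` (from a force trace), `"imported"` or
#'   `"simulated"`.
#' @param discarded Data frame with columns `time`, `reason`; reasons must
#'   come from [DISCARD_REASONS].
#' @return Object of class `tap_events`.
#' @export
tap_events <- function(times, source = c("simulated", "detected", "imported"),
                       discarded = NULL) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop("tap times must be finite")
  if (is.unsorted(times, strictly = TRUE)) stop("tap times must be strictly increasing")
  if (is.null(discarded))
    discarded <- data.frame(time = numeric(0), reason = character(0))
  if (!all(discarded$reason %in% DISCARD_REASONS))
    stop("unknown discard reason")
  structure(list(times = times, source = source, discarded = discarded),
            class = "tap_events")
}

#' @export
print.tap_events <- function(x, ...) {
  cat(sprintf("<tap_events> %d kept, %d discarded (%s)\n",
              length(x$times), nrow(x$discarded), x$source))
  invisible(x)
}

discard_events <- function(events, drop_idx, reason) {
  if (length(drop_idx) == 0L) return(events)
  events$discarded <- rbind(
    events$discarded,
    data.frame(time = events$times[drop_idx], reason = reason))
  events$times <- events$times[-drop_idx]
  events
}

#' Detect tap onsets from a force-sensor trace
#'
#' Threshold-crossing detector: one event at every upward crossing of
#' `threshold` (first suprathreshold sample, no sub-sample
#' interpolation). Crossings inside a recorded dropout interval are
#' suppressed (the trace there is an artifact, not force).
#'
#' @param signal An `fsr_signal` object (see [simulate_fsr_signal()]) or a
#'   numeric vector of force samples (then `sample_rate` is required).
#' @param threshold Force threshold; `"auto"` places it midway between the
#'   baseline median and the trace maximum. The recording hardware's
#'   trigger level was not archived, so the default is a documented,
#'   reproducible stand-in.
#' @param sample_rate Samples per second, used when `signal` is a bare
#'   vector.
#' @return A [tap_events()] object with `source = "detected"`.
#' @export
detect_taps <- function(signal, threshold = "auto", sample_rate = NULL) {
  if (inherits(signal, "fsr_signal")) {
    samples <- signal$samples
    sample_rate <- signal$sample_rate
    dropout <- signal$dropout_interval
  } else {
    samples <- as.numeric(signal)
    dropout <- NULL
    if (is.null(sample_rate)) stop("`sample_rate` required for a bare sample vector")
  }
  if (length(samples) == 0L) stop("empty signal")
  if (any(!is.finite(samples))) stop("signal contains non-finite samples")
  if (identical(threshold, "auto"))
    threshold <- (stats::median(samples) + max(samples)) / 2
  above <- samples >= threshold
  crossing <- which(above & !c(TRUE, above[-length(above)]))
  times <- (crossing - 1) / sample_rate
  if (!is.null(dropout))
    times <- times[times < dropout[1] | times >= dropout[2]]
  tap_events(times, source = "detected")
}

#' Post-dropout exclusion window
#'
#' Width of the guard window applied after a signal dropout: 75% of the
#' instructed inter-tap interval, i.e. `0.75 * period_multiplier /
#' stimulus_rate`. At the study parameters (2.4 Hz, tap every 2nd beat)
#' this is 625 ms.
#'
#' @param stimulus_rate Metronome rate in Hz (> 0).
#' @param period_multiplier Instructed tapping period in stimulus
#'   intervals (default 2).
#' @return Window width in seconds.
#' @examples
#' dropout_guard_window(2.4, 2)  # 0.625
#' @export
dropout_guard_window <- function(stimulus_rate, period_multiplier = 2) {
  if (stimulus_rate <= 0) stop("`stimulus_rate` must be > 0")
  if (period_multiplier < 1) stop("`period_multiplier` must be >= 1")
  0.75 * period_multiplier / stimulus_rate
}

#' Discard taps detected just after a signal dropout
#'
#' The first force reading after a recording dropout can register a
#' spurious crossing, so any tap in the half-open window
#' `[dropout_end, dropout_end + window)` is moved to the discard list
#' with reason `post_dropout`. With no dropout the series is returned
#' unchanged.
#'
#' @param events A [tap_events()] object.
#' @param dropout_end End of the dropout interval (seconds), or `NULL`.
#' @param window Guard-window width in seconds, see
#'   [dropout_guard_window()].
#' @return The filtered `tap_events`.
#' @export
apply_dropout_guard <- function(events, dropout_end, window) {
  stopifnot(inherits(events, "tap_events"))
  if (is.null(dropout_end) || is.na(dropout_end)) return(events)
  if (window <= 0) stop("`window` must be > 0")
  hit <- which(events$times >= dropout_end & events$times < dropout_end + window)
  discard_events(events, hit, "post_dropout")
}

#' Suppress double taps
#'
#' Replaces the study's manual inspection step with a reproducible
#' refractory rule: scanning left to right, any tap closer than
#' `refractory` to the last *kept* tap is discarded (reason
#' `refractory`), so a burst collapses to its first contact.
#'
#' @param events A [tap_events()] object.
#' @param refractory Minimum inter-tap gap in seconds (default 0.15, well
#'   under half the shortest plausible instructed interval).
#' @return The filtered `tap_events`.
#' @export
remove_double_taps <- function(events, refractory = 0.15) {
  stopifnot(inherits(events, "tap_events"))
  if (refractory <= 0) stop("`refractory` must be > 0")
  t <- events$times
  if (length(t) < 2L) return(events)
  keep <- logical(length(t))
  keep[1] <- TRUE
  last <- t[1]
  for (i in 2:length(t)) {
    if (t[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  discard_events(events, which(!keep), "refractory")
}
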