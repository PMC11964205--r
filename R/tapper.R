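#' Parameters of a simulated tapper
#'
#' Generative model for one participant-condition cell. Taps are placed
#' at every `period_multiplier`-th reference stimulus starting from
#' `start_beat` (1-based), then perturbed by von Mises phase noise of
#' concentration `kappa` around `mean_phase` (one full circle = one tap
#' period). `kappa` is the generative counterpart of the scored vector
#' length: the expected population R is `bessel_ratio(kappa)`.
#' Behavioural artifacts are injected on top: mid-trial pauses
#' (geometric onset per tap, fixed length), double taps, and missed taps.
#'
#' @param kappa Von Mises concentration (`>= 0`; `Inf` = noise-free).
#' @param mean_phase Mean tap phase in radians, `(-pi, pi]`; negative
#'   values model the usual anticipation (taps lead the beat).
#' @param period_multiplier Taps every this many stimuli (1, 2 or 3;
#'   instructed value 2).
#' @param start_beat First stimulus tapped, 1-based (instructed value 3).
#' @param pause_prob Per-tap probability of starting a pause.
#' @param pause_length Pause duration in seconds (taps suppressed while
#'   it lasts). Default 3.5 s, over 4 instructed tap periods at 2.4 Hz so
#'   a pause always trips the quartile outlier rule.
#' @param double_tap_prob Per-tap probability of a sensor bounce: an
#'   extra contact `double_tap_gap` seconds after the tap.
#' @param double_tap_gap Gap of the bounce, seconds (< any sensible
#'   refractory setting).
#' @param miss_prob Per-tap probability of skipping the tap.
#' @return Object of class `tapper_params`.
#' @export
tapper_params <- function(kappa = 2, mean_phase = -0.3,
                          period_multiplier = 2, start_beat = 3,
                          pause_prob = 0, pause_length = 3.5,
                          double_tap_prob = 0, double_tap_gap = 0.05,
                          miss_prob = 0) {
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (!period_multiplier %in% 1:3) stop("`period_multiplier` must be 1, 2 or 3")
  if (start_beat < 1) stop("`start_beat` must be >= 1")
  probs <- c(pause_prob, double_tap_prob, miss_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (pause_length <= 0) stop("`pause_length` must be > 0")
  structure(list(kappa = kappa, mean_phase = mean_phase,
                 period_multiplier = period_multiplier,
                 start_beat = start_beat,
                 pause_prob = pause_prob, pause_length = pause_length,
                 double_tap_prob = double_tap_prob,
                 double_tap_gap = double_tap_gap,
                 miss_prob = miss_prob),
            class = "tapper_params")
}

#' Simulate one tapping trial
#'
#' Generates tap times against a condition's reference stream under a
#' [tapper_params()] model. The tap period is `period_multiplier * ISI`
#' of the reference stream, and phase noise is expressed on the circle of
#' that period, so a draw of `theta` shifts the tap by
#' `theta / (2 * pi) * period` seconds.
#'
#' @param condition A [condition_spec()].
#' @param params A [tapper_params()].
#' @param seed Optional integer; when given, the trial is reproducible.
#' @return Object of class `tap_trial`: `events` ([tap_events()]),
#'   `condition`, `reference_stimuli`, `secondary_stimuli`, and the
#'   ground-truth `params`.
#' @export
simulate_tapper <- function(condition, params, seed = NULL) {
  stopifnot(inherits(condition, "condition_spec"),
            inherits(params, "tapper_params"))
  if (!is.null(seed)) set.seed(seed)
  stim <- condition$reference_stimuli
  period <- params$period_multiplier * stim$isi
  anchor_idx <- seq(params$start_beat, length(stim$onsets),
                    by = params$period_multiplier)
  anchors <- stim$onsets[anchor_idx]
  theta <- rvonmises(length(anchors), params$mean_phase, params$kappa)
  taps <- anchors + theta / (2 * pi) * period

  keep <- rep(TRUE, length(taps))
  # pauses: per-tap geometric onset; all taps inside the pause suppressed
  if (params$pause_prob > 0 && length(taps) > 0) {
    i <- 1L
    while (i <= length(taps)) {
      if (keep[i] && stats::runif(1) < params$pause_prob) {
        pause_end <- anchors[i] + params$pause_length
        keep[i:length(taps)][anchors[i:length(taps)] < pause_end] <- FALSE
        # tapping resumes at the first anchor past the pause
      }
      i <- i + 1L
    }
  }
  if (params$miss_prob > 0)
    keep <- keep & (stats::runif(length(taps)) >= params$miss_prob)
  taps <- taps[keep]
  if (params$double_tap_prob > 0 && length(taps) > 0) {
    dup <- stats::runif(length(taps)) < params$double_tap_prob
    taps <- c(taps, taps[dup] + params$double_tap_gap)
  }
  taps <- sort(taps[taps >= 0 & taps <= condition$duration])
  taps <- taps[c(TRUE, diff(taps) > 1e-9)]  # enforce strict increase

  structure(list(events = tap_events(taps, source = "simulated"),
                 condition = condition,
                 reference_stimuli = stim,
                 secondary_stimuli = condition$secondary_stimuli,
                 params = params),
            class = "tap_trial")
}

#' @export
print.tap_trial <- function(x, ...) {
  cat(sprintf("<tap_trial> condition %s, %d taps (kappa = %.3g, multiplier %d)\n",
              x$condition$name, length(x$events$times),
              x$params$kappa, x$params$period_multiplier))
  invisible(x)
}

#' Synthesize a force-sensor trace for a trial
#'
#' Renders each tap as an impact-like force pulse (instantaneous attack,
#' quarter-cosine decay — a fingertip strike loads the sensor within a
#' sample but unloads gradually) on a regular sampling grid, adds
#' sub-threshold Gaussian noise, and optionally imposes the recording
#' artifact seen in the study hardware: a signal dropout of fixed length
#' at a variable location, during which the trace holds its last
#' pre-dropout value and any taps leave no pulse. The sharp attack means
#' a threshold crossing lands on the first pulse sample, so detection
#' recovers tap onsets to within one sample period.
#'
#' @param trial A `tap_trial` (or a numeric vector of tap times, with
#'   `duration` supplied).
#' @param sample_rate Samples per second (default 1000).
#' @param pulse_width Width of the half-sine contact pulse, seconds.
#' @param pulse_amplitude Peak force of a tap, arbitrary units.
#' @param noise_sd SD of additive baseline noise (keep well below half
#'   the amplitude so the default threshold separates pulses).
#' @param dropout `NULL` for a clean trace, or `c(start, length)` in
#'   seconds.
#' @param duration Trace duration, seconds; taken from the trial when
#'   omitted.
#' @return Object of class `fsr_signal`: `samples`, `sample_rate`,
#'   `dropout_interval` (`c(start, end)` or `NULL`).
#' @export
simulate_fsr_signal <- function(trial, sample_rate = 1000,
                                pulse_width = 0.04, pulse_amplitude = 1,
                                noise_sd = 0, dropout = NULL,
                                duration = NULL) {
  if (inherits(trial, "tap_trial")) {
    taps <- trial$events$times
    if (is.null(duration)) duration <- trial$condition$duration
  } else {
    taps <- as.numeric(trial)
    if (is.null(duration)) stop("`duration` required for bare tap times")
  }
  if (pulse_width * sample_rate < 2) stop("`sample_rate` too low for the pulse width")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  sig <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  dropout_interval <- NULL
  if (!is.null(dropout)) {
    if (dropout[1] < 0 || dropout[1] + dropout[2] > duration)
      stop("dropout window outside the trial")
    dropout_interval <- c(dropout[1], dropout[1] + dropout[2])
  }
  for (tap in taps) {
    if (!is.null(dropout_interval) &&
        tap >= dropout_interval[1] && tap < dropout_interval[2]) next
    i0 <- floor(tap * sample_rate) + 1
    i1 <- min(i0 + round(pulse_width * sample_rate) - 1, n)
    if (i0 > n) next
    idx <- i0:i1
    sig[idx] <- sig[idx] +
      pulse_amplitude * cos(pi / 2 * (seq_along(idx) - 1) / length(idx))
  }
  if (!is.null(dropout_interval)) {
    di <- which(t >= dropout_interval[1] & t < dropout_interval[2])
    fill <- if (di[1] > 1) sig[di[1] - 1] else 0
    sig[di] <- fill  # hold-last-sample during the dropout
  }
  structure(list(samples = sig, sample_rate = sample_rate,
                 dropout_interval = dropout_interval),
            class = "fsr_signal")
}

#' @export
print.fsr_signal <- function(x, ...) {
  cat(sprintf("<fsr_signal> %d samples at %g Hz%s\n",
              length(x$samples), x$sample_rate,
              if (is.null(x$dropout_interval)) "" else
                sprintf(", dropout [%.3f, %.3f] s",
                        x$dropout_interval[1], x$dropout_interval[2])))
  invisible(x)
}
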