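#' Scoring configuration
#'
#' Collects the tunable cleaning/scoring parameters in one place so a run
#' can log every default in effect.
#'
#' @param kernel_sd SD of the Gaussian used for odd/even phase detection,
#'   seconds.
#' @param grid_dt Grid step of the smoothed event series, seconds.
#' @param refractory Double-tap refractory period, seconds.
#' @param n_trim Number of initial taps discarded (stabilization).
#' @param epsilon Logit clamping bound.
#' @param min_taps Minimum scored taps for a usable trial.
#' @param instructed_multiplier Instructed tapping period, in stimulus
#'   intervals.
#' @return List of class `scoring_config`.
#' @export
scoring_config <- function(kernel_sd = 0.05, grid_dt = 0.001,
                           refractory = 0.15, n_trim = 5,
                           epsilon = 1e-6, min_taps = 8,
                           instructed_multiplier = 2) {
  structure(list(kernel_sd = kernel_sd, grid_dt = grid_dt,
                 refractory = refractory, n_trim = n_trim,
                 epsilon = epsilon, min_taps = min_taps,
                 instructed_multiplier = instructed_multiplier),
            class = "scoring_config")
}

#' Detect the tapping-interval multiple of a trial
#'
#' Participants sometimes tapped every stimulus or every third stimulus
#' instead of every second. The overall tapping interval is classified by
#' the stimulus-interval multiple nearest to the trial's median inter-tap
#' interval; candidates are 1, 2 and 3, with ties broken to the smaller
#' multiple.
#'
#' @param events A [tap_events()] object or numeric tap times.
#' @param stimulus_isi Inter-stimulus interval of the reference stream,
#'   seconds.
#' @return Integer 1, 2 or 3, or `NA` when fewer than 3 taps.
#' @export
detect_tap_interval <- function(events, stimulus_isi) {
  t <- if (inherits(events, "tap_events")) events$times else as.numeric(events)
  if (length(t) < 3L) return(NA_integer_)
  med_iti <- stats::median(diff(t))
  dev <- abs(med_iti - (1:3) * stimulus_isi)
  as.integer(which.min(dev))  # which.min takes the first = smaller multiple on ties
}

#' Wrong-rate exclusion rule
#'
#' Trials tapped at every stimulus (multiple 1) or every third stimulus
#' (multiple 3) are excluded; only the instructed every-second-stimulus
#' rate is analysed.
#'
#' @param multiplier Detected interval multiple (1, 2 or 3).
#' @return `TRUE` when the trial must be excluded.
#' @export
exclude_wrong_rate <- function(multiplier) {
  if (is.na(multiplier)) return(TRUE)
  if (!multiplier %in% 1:3) stop("`multiplier` must be 1, 2 or 3")
  multiplier %in% c(1L, 3L)
}

gaussian_event_series <- function(times, grid, kernel_sd) {
  # delta train binned to the grid, smoothed by direct accumulation of the
  # (truncated, +-4 sd) kernel at each event: events are sparse, so this is
  # much cheaper than a full-length convolution
  dt <- grid[2] - grid[1]
  half <- ceiling(4 * kernel_sd / dt)
  kern <- stats::dnorm(seq(-half, half) * dt, sd = kernel_sd)
  n <- length(grid)
  padded <- numeric(n + 2 * half)
  centers <- pmin(pmax(round(times / dt) + 1, 1), n)
  for (i in centers) {
    j <- i:(i + 2 * half)
    padded[j] <- padded[j] + kern
  }
  padded[(half + 1):(half + n)]
}

#' Detect the tapping phase (odd vs even stimuli)
#'
#' Participants were instructed to tap on the odd stimuli (3rd, 5th, ...)
#' but often locked to the even ones. Both candidate anchor trains and
#' the tap train are convolved with a Gaussian on a common time grid; the
#' parity whose smoothed stimulus series correlates more strongly
#' (Pearson) with the smoothed tap series wins. An exact tie falls back
#' to odd with a warning.
#'
#' @param events A [tap_events()] object or numeric tap times.
#' @param reference_stimuli A `stimulus_sequence`.
#' @param kernel_sd Gaussian SD in seconds (default 50 ms).
#' @param grid_dt Grid step in seconds (default 1 ms).
#' @return `"odd"` or `"even"` (1-based stimulus indices).
#' @export
detect_phase <- function(events, reference_stimuli, kernel_sd = 0.05,
                         grid_dt = 0.001) {
  t <- if (inherits(events, "tap_events")) events$times else as.numeric(events)
  if (length(t) < 3L) stop("phase detection needs at least 3 taps")
  if (kernel_sd <= 0 || grid_dt <= 0) stop("`kernel_sd` and `grid_dt` must be > 0")
  onsets <- reference_stimuli$onsets
  t_max <- max(c(t, onsets)) + 4 * kernel_sd
  grid <- seq(0, t_max, by = grid_dt)
  odd <- gaussian_event_series(onsets[seq(1, length(onsets), by = 2)], grid, kernel_sd)
  even <- gaussian_event_series(onsets[seq(2, length(onsets), by = 2)], grid, kernel_sd)
  taps <- gaussian_event_series(t, grid, kernel_sd)
  r_odd <- stats::cor(odd, taps)
  r_even <- stats::cor(even, taps)
  if (isTRUE(all.equal(r_odd, r_even))) {
    warning("odd/even correlations tied; defaulting to odd")
    return("odd")
  }
  if (r_odd >= r_even) "odd" else "even"
}

#' Discard the initial stabilization taps
#'
#' The first taps of a trial are produced before synchronization settles
#' and are removed (reason `initial_trim`).
#'
#' @param events A [tap_events()] object.
#' @param n_trim How many initial taps to discard (default 5).
#' @return The trimmed `tap_events`.
#' @export
trim_initial_taps <- function(events, n_trim = 5) {
  stopifnot(inherits(events, "tap_events"))
  k <- min(n_trim, length(events$times))
  discard_events(events, seq_len(k), "initial_trim")
}

#' Prune taps that terminate a pause
#'
#' Inter-tap intervals are screened for outliers with the quartile rule
#' `Q3 + 3 * IQR` (type-7 quantiles); the tap at the end of each outlying
#' interval is discarded (reason `pause_outlier`). A single pass is made:
#' the threshold is not recomputed after removal. With fewer than 4 taps
#' the quartiles are undefined and the series is returned unchanged with
#' a warning.
#'
#' @param events A [tap_events()] object.
#' @return The pruned `tap_events`.
#' @export
remove_pause_taps <- function(events) {
  stopifnot(inherits(events, "tap_events"))
  t <- events$times
  if (length(t) < 4L) {
    warning("fewer than 4 taps; pause pruning skipped")
    return(events)
  }
  iti <- diff(t)
  q <- stats::quantile(iti, c(0.25, 0.75), names = FALSE, type = 7)
  threshold <- q[2] + 3 * (q[2] - q[1])
  # 1 ns guard so equal intervals are never flagged through rounding noise
  drop_idx <- which(iti > threshold + 1e-9) + 1L  # tap terminating the interval
  discard_events(events, drop_idx, "pause_outlier")
}

#' Convert tap times to circular phase angles
#'
#' One full revolution corresponds to one beat = `multiplier` x ISI
#' (twice the inter-stimulus interval at the instructed rate), anchored
#' on the stimuli of the detected parity. Each tap's angle is its signed
#' offset from the nearest anchor, wrapped to `(-pi, pi]`; negative
#' angles mean the tap led the beat. Because the anchor grid is
#' isochronous, offsets are computed modulo the beat period from the
#' first anchor.
#'
#' @param events A [tap_events()] object or numeric tap times.
#' @param reference_stimuli A `stimulus_sequence`.
#' @param parity `"odd"` or `"even"`.
#' @param multiplier Beat period in stimulus intervals (instructed 2).
#' @return Angles in radians, one per kept tap.
#' @export
taps_to_angles <- function(events, reference_stimuli, parity = c("odd", "even"),
                           multiplier = 2) {
  parity <- match.arg(parity)
  t <- if (inherits(events, "tap_events")) events$times else as.numeric(events)
  onsets <- reference_stimuli$onsets
  start <- if (parity == "odd") 1L else 2L
  anchors <- onsets[seq(start, length(onsets), by = 2)]
  if (length(anchors) == 0L) stop("empty anchor grid")
  period <- multiplier * reference_stimuli$isi
  wrap_angle(2 * pi * (t - anchors[1]) / period)
}

#' Score one tapping trial
#'
#' Runs the full cleaning and scoring pipeline in the study's order:
#' dropout guard, double-tap removal, interval-multiple detection,
#' wrong-rate exclusion, odd/even phase detection, initial trim, pause
#' pruning, conversion to angles, mean resultant vector, logit transform
#' and Rayleigh chance test. Excluded or unusable trials are flagged with
#' a reason instead of raising.
#'
#' @param trial A `tap_trial` (from [simulate_tapper()] or assembled from
#'   imported tables), with optional `dropout_end` attribute or element.
#' @param config A [scoring_config()].
#' @param dropout_end End of the signal dropout for this trial, seconds,
#'   or `NULL`.
#' @return One-row data frame: `multiplier`, `parity`, `n_taps`, `R`,
#'   `direction_rad`, `logit_R`, `rayleigh_p`, `excluded`, `reason`.
#' @export
score_trial <- function(trial, config = scoring_config(), dropout_end = NULL) {
  stopifnot(inherits(trial, "tap_trial"))
  stim <- trial$reference_stimuli
  ev <- trial$events
  if (is.null(dropout_end) && !is.null(trial$dropout_end))
    dropout_end <- trial$dropout_end

  empty <- function(reason, multiplier = NA_integer_, parity = NA_character_) {
    data.frame(multiplier = multiplier, parity = parity,
               n_taps = NA_integer_, R = NA_real_, direction_rad = NA_real_,
               logit_R = NA_real_, rayleigh_p = NA_real_,
               excluded = TRUE, reason = reason)
  }

  if (!is.null(dropout_end)) {
    win <- dropout_guard_window(stim$rate, config$instructed_multiplier)
    ev <- apply_dropout_guard(ev, dropout_end, win)
  }
  ev <- remove_double_taps(ev, config$refractory)
  if (length(ev$times) < 3L) return(empty("too_few_taps"))

  multiplier <- detect_tap_interval(ev, stim$isi)
  if (exclude_wrong_rate(multiplier)) return(empty("wrong_rate", multiplier))

  parity <- detect_phase(ev, stim, config$kernel_sd, config$grid_dt)
  ev <- trim_initial_taps(ev, config$n_trim)
  if (length(ev$times) >= 4L) ev <- remove_pause_taps(ev)
  if (length(ev$times) < config$min_taps)
    return(empty("too_few_taps", multiplier, parity))

  angles <- taps_to_angles(ev, stim, parity, config$instructed_multiplier)
  mr <- mean_resultant(angles)
  ray <- rayleigh_test(angles)
  data.frame(multiplier = multiplier, parity = parity,
             n_taps = mr$n, R = mr$R, direction_rad = mr$direction,
             logit_R = logit_transform(mr$R, config$epsilon),
             rayleigh_p = ray$p,
             excluded = FALSE, reason = NA_character_)
}
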