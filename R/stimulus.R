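#' Experimental condition names
#'
#' The four metronome conditions: auditory-only (`A`), visual-only (`V`),
#' synchronous audiovisual (`AVsync`, both streams at the same rate) and
#' asynchronous audiovisual (`AVasync`, visual and auditory streams at
#' different rates).
#' @export
CONDITIONS <- c("A", "V", "AVsync", "AVasync")

#' Generate an isochronous stimulus train
#'
#' Onset times of a metronome stream: onsets at `k / rate` for
#' `k = 0, 1, ..., floor(duration * rate)`, so the train starts at time 0
#' and no onset exceeds `duration`.
#'
#' @param rate Metronome rate in Hz (> 0).
#' @param duration Total sequence duration in seconds (> 0).
#' @param modality `"auditory"` or `"visual"`.
#' @return An object of class `stimulus_sequence`: a list with `onsets`
#'   (seconds, strictly increasing), `rate`, `duration`, `modality` and
#'   the inter-stimulus interval `isi = 1/rate`.
#' @examples
#' s <- generate_stimulus_train(2.4, 39.5, "auditory")
#' length(s$onsets)  # 95
#' @export
generate_stimulus_train <- function(rate, duration, modality = c("auditory", "visual")) {
  modality <- match.arg(modality)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) || duration <= 0)
    stop("`duration` must be a single positive number (seconds)")
  # tolerance so that duration an exact multiple of the ISI keeps its last onset
  k_max <- floor(duration * rate + 1e-9)
  structure(
    list(onsets = (0:k_max) / rate,
         rate = rate, duration = duration, modality = modality,
         isi = 1 / rate),
    class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("<stimulus_sequence> %s, %.3g Hz, %d onsets over %.4g s\n",
              x$modality, x$rate, length(x$onsets), x$duration))
  invisible(x)
}

#' Define an experimental condition
#'
#' Builds the stimulus-stream specification for one of the four conditions.
#' Rates default to the study values: 2.4 Hz metronomes everywhere except
#' the asynchronous visual stream, which runs at 2.6 Hz. In the audiovisual
#' conditions the visual stream is the reference (synchronization target)
#' by default; this is configurable because the instruction wording leaves
#' the target stream open in the asynchronous case.
#'
#' @param name One of `"A"`, `"V"`, `"AVsync"`, `"AVasync"`.
#' @param auditory_rate,visual_rate Stream rates in Hz; `NULL` omits the
#'   stream (only valid where the condition has no such stream).
#' @param duration Trial duration in seconds.
#' @param reference_stream Which stream taps are synchronized with and
#'   scored against; must name a stream the condition contains.
#' @return An object of class `condition_spec` with `reference_stimuli` and
#'   (for audiovisual conditions) `secondary_stimuli` as
#'   [generate_stimulus_train()] objects.
#' @export
condition_spec <- function(name = CONDITIONS,
                           auditory_rate = NULL, visual_rate = NULL,
                           duration = 39.5,
                           reference_stream = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    A       = list(auditory = 2.4, visual = NA,  ref = "auditory"),
    V       = list(auditory = NA,  visual = 2.4, ref = "visual"),
    AVsync  = list(auditory = 2.4, visual = 2.4, ref = "visual"),
    AVasync = list(auditory = 2.4, visual = 2.6, ref = "visual"))
  a_rate <- if (is.null(auditory_rate)) defaults$auditory else auditory_rate
  v_rate <- if (is.null(visual_rate)) defaults$visual else visual_rate
  ref <- if (is.null(reference_stream)) defaults$ref else
    match.arg(reference_stream, c("auditory", "visual"))

  if (name == "A" && !is.na(v_rate)) stop("condition A has no visual stream")
  if (name == "V" && !is.na(a_rate)) stop("condition V has no auditory stream")
  if (name == "AVsync" && !isTRUE(all.equal(a_rate, v_rate)))
    stop("AVsync requires equal auditory and visual rates")
  if (name == "AVasync" && isTRUE(all.equal(a_rate, v_rate)))
    stop("AVasync requires unequal auditory and visual rates")
  streams <- list()
  if (!is.na(a_rate)) streams$auditory <- generate_stimulus_train(a_rate, duration, "auditory")
  if (!is.na(v_rate)) streams$visual <- generate_stimulus_train(v_rate, duration, "visual")
  if (is.null(streams[[ref]]))
    stop(sprintf("reference stream '%s' absent from condition %s", ref, name))
  secondary <- setdiff(names(streams), ref)
  structure(
    list(name = name,
         duration = duration,
         reference_stream = ref,
         reference_stimuli = streams[[ref]],
         secondary_stimuli = if (length(secondary)) streams[[secondary]] else NULL),
    class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition_spec> %s (reference: %s at %.3g Hz)\n",
              x$name, x$reference_stream, x$reference_stimuli$rate))
  invisible(x)
}
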