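# Shared fixtures and cached simulations for the test suite.

# A clean, correctly behaved simulated trial.
make_clean_trial <- function(kappa = Inf, mean_phase = 0, condition = "A",
                             multiplier = 2, start_beat = 3, seed = 1, ...) {
  simulate_tapper(condition_spec(condition),
                  tapper_params(kappa = kappa, mean_phase = mean_phase,
                                period_multiplier = multiplier,
                                start_beat = start_beat, ...),
                  seed = seed)
}

# Taps placed directly on an isochronous grid with Gaussian time jitter
# (independent construction, bypassing the package's tapper model).
jittered_taps <- function(multiplier, jitter_sd, isi = 1 / 2.4,
                          start_beat = 3, duration = 39.5) {
  anchors <- seq((start_beat - 1) * isi, duration, by = multiplier * isi)
  sort(anchors + stats::rnorm(length(anchors), 0, jitter_sd))
}

as_trial <- function(tap_times, condition = "A") {
  cond <- condition_spec(condition)
  structure(list(events = tap_events(tap_times, source = "imported"),
                 condition = cond,
                 reference_stimuli = cond$reference_stimuli,
                 secondary_stimuli = cond$secondary_stimuli,
                 params = NULL),
            class = "tap_trial")
}

# Equal-kappa design used by the inference calibration experiments.
null_design <- function() {
  kt <- matrix(2, 2, 4, dimnames = list(c("CI", "HC"), CONDITIONS))
  study_design(kappa_table = kt, seed = 1)
}

# One inference replicate: simulate a trial-level score table, fit the
# mixed model, return the interaction p and the congruence group-difference
# contrast p (raw and Bonferroni).
inference_replicate <- function(design) {
  st <- simulate_score_table(design)
  fit <- fit_mixed_model(st)
  om <- omnibus_tests(fit, "satterthwaite")
  pc <- posthoc_contrasts(fit, "satterthwaite")
  c(p_interaction = om$p[om$term == "group:condition"],
    p_congruence_raw = pc$p_raw[pc$name == "(AVsync_CI - V_CI) - (AVsync_HC - V_HC)"],
    p_congruence_bonf = pc$p_bonferroni[pc$name == "(AVsync_CI - V_CI) - (AVsync_HC - V_HC)"])
}

# The 500-replicate null calibration is shared by two acceptance checks;
# run it once per session and cache.
.tapsync_test_cache <- new.env(parent = emptyenv())

null_calibration <- function(n_reps = 500) {
  key <- paste0("null_", n_reps)
  if (is.null(.tapsync_test_cache[[key]])) {
    des <- null_design()
    set.seed(20240601)
    .tapsync_test_cache[[key]] <-
      t(replicate(n_reps, inference_replicate(des)))
  }
  .tapsync_test_cache[[key]]
}

binomial_ci <- function(phat, n) {
  half <- 1.96 * sqrt(phat * (1 - phat) / n)
  c(phat - half, phat + half)
}
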