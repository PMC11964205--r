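#' Default generator consistency levels
#'
#' Mean logit consistency per group and condition used by the default
#' synthetic design. The values emulate the performance pattern this
#' paradigm elicits: a clear auditory-over-visual advantage in both
#' groups, a congruence benefit of synchronous audiovisual stimulation
#' that is present in hearing controls but attenuated in implant users,
#' and near-chance performance under asynchronous interference.
#'
#' @return Matrix with rows `CI`, `HC` and columns [CONDITIONS], in logit
#'   units.
#' @export
default_cell_logits <- function() {
  m <- rbind(CI = c(A = 1.38, V = -0.69, AVsync = 0.20, AVasync = -1.72),
             HC = c(A = 2.64, V = -1.22, AVsync = 1.71, AVasync = -2.16))
  m[, CONDITIONS, drop = FALSE]
}

#' Default von Mises concentration table
#'
#' Converts [default_cell_logits()] to generative concentrations by
#' inverting the logit and the Bessel ratio, so a noise-free population
#' of tappers at these kappas would reproduce the default cell means.
#'
#' @return Matrix of `kappa` values, rows `CI`/`HC`, columns
#'   [CONDITIONS].
#' @export
default_kappa_table <- function() {
  logits <- default_cell_logits()
  k <- kappa_from_R(stats::plogis(as.numeric(logits)))
  matrix(k, nrow = 2, dimnames = dimnames(logits))
}

#' Study design for the synthetic generator
#'
#' Fixes every stochastic ingredient of a simulated study. The defaults
#' mirror the study conditions: 20 implant users and 17 hearing
#' controls, 10 trials in each of the four conditions, 39.5 s trials,
#' 2.4 Hz metronomes (2.6 Hz asynchronous visual), a 1.46 s recording
#' dropout in most trials, and wrong-rate lapse probabilities derived
#' from the observed exclusion rates (CI 88/800, HC 45/680).
#'
#' @param n_ci,n_hc Group sizes.
#' @param trials_per_condition Trials per participant per condition.
#' @param kappa_table Concentration per group x condition cell.
#' @param participant_log_kappa_sd SD of a participant-level lognormal
#'   multiplier on kappa, shared across conditions (between-participant
#'   heterogeneity / random intercept).
#' @param cell_log_kappa_sd SD of an additional participant x condition
#'   multiplier (supports per-condition random slopes).
#' @param mean_phase Mean tap phase in radians (negative = anticipatory).
#' @param wrong_rate_prob Named per-group probability that a trial is
#'   tapped at the wrong multiple (1x or 3x, equally likely).
#' @param even_phase_prob Probability a trial locks to the even stimuli.
#' @param pause_prob,double_tap_prob,miss_prob Artifact rates passed to
#'   [tapper_params()].
#' @param dropout_prob Probability a trial carries the recording dropout.
#' @param dropout_length Dropout duration, seconds.
#' @param duration Trial duration, seconds.
#' @param seed Integer seed; the same design yields the identical
#'   dataset.
#' @return List of class `study_design`.
#' @export
study_design <- function(n_ci = 20, n_hc = 17, trials_per_condition = 10,
                         kappa_table = default_kappa_table(),
                         participant_log_kappa_sd = 0.8,
                         cell_log_kappa_sd = 0.4,
                         mean_phase = -0.3,
                         wrong_rate_prob = c(CI = 88 / 800, HC = 45 / 680),
                         even_phase_prob = 0.3,
                         pause_prob = 0.02, double_tap_prob = 0.02,
                         miss_prob = 0.02,
                         dropout_prob = 0.9, dropout_length = 1.46,
                         duration = 39.5, seed = 1L) {
  stopifnot(n_ci > 0, n_hc > 0, trials_per_condition > 0)
  if (!all(CONDITIONS %in% colnames(kappa_table)) ||
      !all(c("CI", "HC") %in% rownames(kappa_table)))
    stop("`kappa_table` must cover rows CI/HC and all four conditions")
  if (any(!is.finite(kappa_table)) || any(kappa_table < 0))
    stop("`kappa_table` entries must be finite and >= 0")
  structure(list(n_ci = n_ci, n_hc = n_hc,
                 trials_per_condition = trials_per_condition,
                 kappa_table = kappa_table,
                 participant_log_kappa_sd = participant_log_kappa_sd,
                 cell_log_kappa_sd = cell_log_kappa_sd,
                 mean_phase = mean_phase,
                 wrong_rate_prob = wrong_rate_prob,
                 even_phase_prob = even_phase_prob,
                 pause_prob = pause_prob,
                 double_tap_prob = double_tap_prob,
                 miss_prob = miss_prob,
                 dropout_prob = dropout_prob,
                 dropout_length = dropout_length,
                 duration = duration, seed = as.integer(seed)),
            class = "study_design")
}

#' Clinical characteristics of the implant-user group
#'
#' Reads the packaged participant table (id, age, age at deafness onset,
#' pre-implant deafness duration, age at implantation, years of implant
#' use; onset recorded as `pre-linguistic` for onset before language
#' acquisition).
#'
#' @return Data frame, one row per implant user.
#' @export
ci_clinical_table <- function() {
  path <- system.file("extdata", "ci_clinical.tsv", package = "tapsync")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(onset_age = "character"))
}

#' Numeric onset-age coding
#'
#' Onset ages recorded as `pre-linguistic` enter regressions as 2 years.
#'
#' @param onset_age Character vector of onset ages.
#' @return Numeric vector.
#' @export
code_onset_age <- function(onset_age) {
  out <- suppressWarnings(as.numeric(onset_age))
  out[onset_age == "pre-linguistic"] <- 2
  if (any(is.na(out))) stop("unparseable onset age")
  out
}

make_participants <- function(design) {
  clin <- ci_clinical_table()
  idx <- if (design$n_ci <= nrow(clin)) seq_len(design$n_ci) else
    sample.int(nrow(clin), design$n_ci, replace = TRUE)
  ci <- data.frame(participant_id = sprintf("CI%02d", seq_len(design$n_ci)),
                   group = "CI",
                   age = clin$age[idx],
                   onset_age = clin$onset_age[idx],
                   deafness_duration = clin$deafness_duration[idx],
                   implantation_age = clin$implantation_age[idx],
                   ci_use_years = clin$ci_use_years[idx])
  hc <- data.frame(participant_id = sprintf("HC%02d", seq_len(design$n_hc)),
                   group = "HC",
                   age = round(pmin(pmax(stats::rnorm(design$n_hc, 41.1, 15.5), 18), 75)),
                   onset_age = NA_character_,
                   deafness_duration = NA_real_,
                   implantation_age = NA_real_,
                   ci_use_years = NA_real_)
  rbind(ci, hc)
}

#' Generate a full synthetic study
#'
#' Simulates every trial of a multi-participant study under a
#' [study_design()]: participant-level concentration heterogeneity,
#' per-trial wrong-rate lapses, odd/even phase choice, behavioural
#' artifacts and the recording dropout (taps inside the dropout window
#' are lost, and the dropout end time is attached for the guard).
#' Ground-truth parameters are retained on every trial for recovery
#' tests. Deterministic under the design seed.
#'
#' @param design A [study_design()].
#' @return Object of class `study_dataset`: `participants` (data frame),
#'   `trials` (list of `tap_trial`, each annotated with
#'   `participant_id`, `condition_name`, `trial`, `dropout_end`,
#'   `truth`), and `design`.
#' @export
generate_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  participants <- make_participants(design)
  conditions <- lapply(CONDITIONS, condition_spec, duration = design$duration)
  names(conditions) <- CONDITIONS
  min_dropout_start <- 3 / 2.4  # dropout never inside the first 3 beats

  trials <- list()
  k <- 0L
  for (p in seq_len(nrow(participants))) {
    grp <- participants$group[p]
    z_p <- stats::rnorm(1, 0, design$participant_log_kappa_sd)
    for (cond in CONDITIONS) {
      kappa_cell <- design$kappa_table[grp, cond] *
        exp(z_p + stats::rnorm(1, 0, design$cell_log_kappa_sd))
      for (tr in seq_len(design$trials_per_condition)) {
        wrong <- stats::runif(1) < design$wrong_rate_prob[[grp]]
        multiplier <- if (wrong) sample(c(1L, 3L), 1) else 2L
        start_beat <- if (stats::runif(1) < design$even_phase_prob) 4L else 3L
        par <- tapper_params(kappa = kappa_cell,
                             mean_phase = design$mean_phase,
                             period_multiplier = multiplier,
                             start_beat = start_beat,
                             pause_prob = design$pause_prob,
                             double_tap_prob = design$double_tap_prob,
                             miss_prob = design$miss_prob)
        trial <- simulate_tapper(conditions[[cond]], par)
        dropout_end <- NULL
        if (stats::runif(1) < design$dropout_prob) {
          d0 <- stats::runif(1, min_dropout_start,
                             design$duration - design$dropout_length)
          dropout_end <- d0 + design$dropout_length
          lost <- trial$events$times >= d0 & trial$events$times < dropout_end
          trial$events$times <- trial$events$times[!lost]
        }
        k <- k + 1L
        trial$participant_id <- participants$participant_id[p]
        trial$condition_name <- cond
        trial$trial <- tr
        trial$dropout_end <- dropout_end
        trial$truth <- list(kappa = kappa_cell, multiplier = multiplier,
                            start_beat = start_beat, wrong_rate = wrong)
        trials[[k]] <- trial
      }
    }
  }
  structure(list(participants = participants, trials = trials,
                 design = design),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d participants (%d CI + %d HC), %d trials\n",
              nrow(x$participants), x$design$n_ci, x$design$n_hc,
              length(x$trials)))
  invisible(x)
}

#' Score every trial of a study
#'
#' Applies [score_trial()] to each trial of a [generate_study()] dataset
#' (or any list of annotated `tap_trial` objects) and binds the results
#' into a long table.
#'
#' @param dataset A `study_dataset`.
#' @param config A [scoring_config()].
#' @return Data frame with identification columns (`participant_id`,
#'   `group`, `condition`, `trial`) plus the [score_trial()] columns.
#' @export
score_study <- function(dataset, config = scoring_config()) {
  stopifnot(inherits(dataset, "study_dataset"))
  grp <- stats::setNames(dataset$participants$group,
                         dataset$participants$participant_id)
  rows <- lapply(dataset$trials, function(trial) {
    sc <- score_trial(trial, config)
    cbind(data.frame(participant_id = trial$participant_id,
                     group = grp[[trial$participant_id]],
                     condition = trial$condition_name,
                     trial = trial$trial),
          sc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a trial-level score table directly
#'
#' Fast generator for inference-stage simulation studies: skips the
#' event-level pipeline and draws each trial's tap phases straight from
#' the von Mises model, scoring them with [mean_resultant()] and
#' [logit_transform()]. Used for calibration experiments (type-I error,
#' power, contrast behaviour) where thousands of model fits are needed
#' and the event-level artifacts are not under study.
#'
#' @param design A [study_design()]; only the sample sizes, kappa table,
#'   heterogeneity SDs and mean phase are used.
#' @param n_taps Scored taps per trial (default 38, the typical count
#'   after trimming in a 39.5 s trial).
#' @param seed Optional integer seed.
#' @return Score table: `participant_id`, `group`, `condition`, `trial`,
#'   `n_taps`, `R`, `logit_R`, `excluded` (all `FALSE`).
#' @export
simulate_score_table <- function(design = study_design(), n_taps = 38,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_p <- design$n_ci + design$n_hc
  groups <- rep(c("CI", "HC"), c(design$n_ci, design$n_hc))
  ids <- sprintf("%s%02d", groups, c(seq_len(design$n_ci), seq_len(design$n_hc)))
  rows <- vector("list", n_p * length(CONDITIONS))
  k <- 0L
  for (p in seq_len(n_p)) {
    z_p <- stats::rnorm(1, 0, design$participant_log_kappa_sd)
    for (cond in CONDITIONS) {
      kappa <- design$kappa_table[groups[p], cond] *
        exp(z_p + stats::rnorm(1, 0, design$cell_log_kappa_sd))
      R <- vapply(seq_len(design$trials_per_condition), function(i) {
        mean_resultant(rvonmises(n_taps, design$mean_phase, kappa))$R
      }, numeric(1))
      k <- k + 1L
      rows[[k]] <- data.frame(participant_id = ids[p], group = groups[p],
                              condition = cond,
                              trial = seq_len(design$trials_per_condition),
                              n_taps = n_taps, R = R,
                              logit_R = logit_transform(R),
                              excluded = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
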