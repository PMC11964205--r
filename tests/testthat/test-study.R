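small_design <- function(seed = 7, ...) {
  study_design(n_ci = 2, n_hc = 2, trials_per_condition = 2, seed = seed, ...)
}

test_that("study generator produces the designed layout", {
  ds <- generate_study(small_design())
  expect_equal(nrow(ds$participants), 4)
  expect_length(ds$trials, 4 * 4 * 2)  # participants x conditions x trials
  conds <- vapply(ds$trials, function(x) x$condition_name, character(1))
  expect_equal(sort(unique(conds)), sort(CONDITIONS))
  # ground truth retained on every trial
  expect_true(all(vapply(ds$trials,
                         function(x) is.numeric(x$truth$kappa), logical(1))))
})

test_that("default design mirrors the study scale", {
  d <- study_design()
  expect_equal(d$n_ci, 20)
  expect_equal(d$n_hc, 17)
  expect_equal(d$trials_per_condition, 10)
  expect_equal(d$duration, 39.5)
  expect_equal(d$dropout_length, 1.46)
  # 20 + 17 participants x 4 conditions x 10 trials = 1480 trials
  expect_equal((d$n_ci + d$n_hc) * 4 * d$trials_per_condition, 1480)
})

test_that("identical seeds give identical datasets, different seeds differ", {
  a <- events_table(generate_study(small_design(seed = 3)))
  b <- events_table(generate_study(small_design(seed = 3)))
  c <- events_table(generate_study(small_design(seed = 4)))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c)))
})

test_that("kappa table validation", {
  kt <- default_kappa_table()
  expect_error(study_design(kappa_table = kt[, 1:3]), "cover")
  kt_bad <- kt; kt_bad[1, 1] <- NA
  expect_error(study_design(kappa_table = kt_bad), "finite")
})

test_that("default concentrations invert the default cell consistencies", {
  kt <- default_kappa_table()
  expect_equal(logit_transform(bessel_ratio(as.numeric(kt))),
               as.numeric(default_cell_logits()), tolerance = 1e-6)
  # HC outperform CI except with visual-only and asynchronous stimulation
  expect_gt(kt["HC", "A"], kt["CI", "A"])
  expect_gt(kt["HC", "AVsync"], kt["CI", "AVsync"])
  expect_lt(kt["HC", "V"], kt["CI", "V"])
})

test_that("clinical table loads and onset ages code correctly", {
  clin <- ci_clinical_table()
  expect_equal(nrow(clin), 20)
  expect_equal(sum(clin$onset_age == "pre-linguistic"), 2)
  coded <- code_onset_age(clin$onset_age)
  expect_true(all(is.finite(coded)))
  expect_equal(coded[clin$onset_age == "pre-linguistic"], c(2, 2))
  expect_equal(code_onset_age(c("37", "pre-linguistic")), c(37, 2))
  expect_error(code_onset_age("unknown"), "unparseable")
})

test_that("scored study recovers the planted group-by-condition ordering", {
  # moderate study, artifact-free for a clean signal check
  d <- study_design(n_ci = 6, n_hc = 6, trials_per_condition = 4,
                    wrong_rate_prob = c(CI = 0, HC = 0),
                    pause_prob = 0, double_tap_prob = 0, miss_prob = 0,
                    dropout_prob = 0, seed = 11)
  scores <- score_study(generate_study(d))
  agg <- aggregate_scores(scores)
  m <- tapply(agg$scores$logit_R,
              list(agg$scores$group, agg$scores$condition), mean)
  # auditory advantage over visual in both groups
  expect_gt(m["CI", "A"], m["CI", "V"])
  expect_gt(m["HC", "A"], m["HC", "V"])
  # asynchronous interference is the worst condition in both groups
  expect_true(all(m[, "AVasync"] < m[, "V"]))
})

test_that("wrong-rate lapses are planted and excluded at the planted rate", {
  # concentrated tapping everywhere: with near-chance concentration the
  # inter-tap intervals no longer carry rate information at all
  kt <- matrix(4, 2, 4, dimnames = list(c("CI", "HC"), CONDITIONS))
  d <- study_design(n_ci = 4, n_hc = 4, trials_per_condition = 5,
                    kappa_table = kt,
                    wrong_rate_prob = c(CI = 0.5, HC = 0.5),
                    dropout_prob = 0, seed = 13)
  ds <- generate_study(d)
  planted <- vapply(ds$trials, function(x) x$truth$wrong_rate, logical(1))
  scores <- score_study(ds)
  # every planted wrong-rate trial is flagged wrong_rate, and all flagged
  # trials are excluded
  expect_true(all(scores$reason[planted] %in% "wrong_rate"))
  expect_true(all(scores$excluded[scores$reason %in% "wrong_rate"]))
})

test_that("direct score simulation matches its concentration targets", {
  kt <- matrix(c(8, 8, 2, 2, 4, 4, 1, 1), 2,
               dimnames = list(c("CI", "HC"), CONDITIONS))
  d <- study_design(n_ci = 10, n_hc = 10, trials_per_condition = 10,
                    kappa_table = kt, participant_log_kappa_sd = 0,
                    cell_log_kappa_sd = 0)
  st <- simulate_score_table(d, n_taps = 38, seed = 17)
  m <- tapply(st$R, st$condition, mean)
  for (cond in CONDITIONS)
    expect_equal(unname(m[cond]), bessel_ratio(kt["CI", cond]),
                 tolerance = 0.05)
})
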