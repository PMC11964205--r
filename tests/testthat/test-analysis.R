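make_score_table <- function(seed = 23, ...) {
  simulate_score_table(study_design(n_ci = 8, n_hc = 8,
                                    trials_per_condition = 5, ...),
                       seed = seed)
}

test_that("aggregation drops excluded trials and counts them by cell", {
  df <- data.frame(participant_id = rep(c("CI01", "HC01"), each = 10),
                   group = rep(c("CI", "HC"), each = 10),
                   condition = rep(CONDITIONS, 5),
                   trial = 1:20, logit_R = rnorm(20),
                   excluded = rep(c(TRUE, FALSE), c(2, 18)),
                   reason = c("wrong_rate", "too_few_taps", rep(NA, 18)))
  agg <- aggregate_scores(df)
  expect_equal(nrow(agg$scores), 18)
  expect_equal(sum(agg$exclusion_counts), 2)
  expect_equal(unname(agg$exclusion_counts["CI", "A"]), 1)
  expect_length(agg$empty_participants, 0)

  # a participant losing every trial is reported
  df2 <- df
  df2$excluded[df2$participant_id == "CI01"] <- TRUE
  df2$reason[df2$participant_id == "CI01"] <- "wrong_rate"
  expect_warning(agg2 <- aggregate_scores(df2), "CI01")
  expect_equal(agg2$empty_participants, "CI01")
})

test_that("mixed model fits with the full random structure and sane output", {
  st <- make_score_table()
  fit <- fit_mixed_model(st)
  expect_s3_class(fit, "tapsync_fit")
  expect_equal(fit$n_participants, 16)
  expect_true(fit$structure %in% c("full", "diagonal", "intercept"))
  om <- omnibus_tests(fit, "satterthwaite")
  expect_equal(om$term, c("group", "condition", "group:condition"))
  expect_equal(om$df1, c(1, 3, 3))
  expect_true(all(om$F >= 0))
  expect_true(all(om$p >= 0 & om$p <= 1))
})

test_that("model preconditions are enforced", {
  st <- make_score_table()
  expect_error(fit_mixed_model(st[st$group == "CI", ]), "both groups")
  one_per_group <- st[st$participant_id %in% c("CI01", "HC01"), ]
  expect_error(fit_mixed_model(one_per_group), "2 participants")
})

test_that("omnibus F values are invariant to row order and match a direct fit", {
  st <- make_score_table(seed = 29)
  f1 <- omnibus_tests(fit_mixed_model(st), "satterthwaite")
  shuffled <- st[sample(nrow(st)), ]
  f2 <- omnibus_tests(fit_mixed_model(shuffled), "satterthwaite")
  # iterative optimizer: agreement to optimizer precision, not machine
  expect_equal(f1$F, f2$F, tolerance = 1e-2)

  # independent route: raw lmerTest fit with reversed level order;
  # sum-to-zero type-III omnibus F values are invariant to level ordering
  d <- data.frame(logit_R = st$logit_R,
                  group = factor(st$group, levels = c("HC", "CI")),
                  condition = factor(st$condition, levels = rev(CONDITIONS)),
                  pid = factor(st$participant_id))
  contrasts(d$group) <- contr.sum(2)
  contrasts(d$condition) <- contr.sum(4)
  ref <- lmerTest::lmer(
    logit_R ~ group * condition + (1 + condition | pid), data = d,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore"))
  a <- anova(ref, type = 3)
  expect_equal(sort(f1$F), sort(unname(a[["F value"]])), tolerance = 1e-2)
})

test_that("the 11 planned contrasts are emitted with the Bonferroni cap", {
  fit <- fit_mixed_model(make_score_table(seed = 31))
  pc <- posthoc_contrasts(fit, "satterthwaite")
  expect_equal(nrow(pc), 11)
  expect_equal(pc$p_bonferroni, pmin(1, 11 * pc$p_raw))
  expect_true(all(pc$p_bonferroni >= pc$p_raw))
  expect_true(all(pc$df > 0))
})

test_that("contrast estimates agree with an independent linear-combination route", {
  st <- make_score_table(seed = 37)
  fit <- fit_mixed_model(st)
  pc <- posthoc_contrasts(fit, "satterthwaite")
  # oracle: cell means are X* beta for the 8 cell rows of the fixed design;
  # build the same contrasts directly from the fixed effects
  grid <- expand.grid(group = c("CI", "HC"), condition = CONDITIONS)
  g <- factor(grid$group, c("CI", "HC")); contrasts(g) <- contr.sum(2)
  cnd <- factor(grid$condition, CONDITIONS); contrasts(cnd) <- contr.sum(4)
  X <- model.matrix(~ g * cnd)
  beta <- lme4::fixef(fit$fit)
  cells <- as.numeric(X %*% beta)
  defs <- contrast_definitions(grid)
  expect_equal(pc$estimate,
               unname(vapply(defs, function(w) sum(w * cells), numeric(1))),
               tolerance = 1e-8)
  # and t = estimate / sqrt(w' Vb w) with Vb from the fitted model
  Vb <- as.matrix(vcov(fit$fit))
  ses <- vapply(defs, function(w) {
    L <- as.numeric(t(X) %*% w)
    sqrt(drop(t(L) %*% Vb %*% L))
  }, numeric(1))
  expect_equal(pc$se, unname(ses), tolerance = 1e-8)
})

test_that("planted effects are recovered with the right signs", {
  # strong auditory advantage in both groups
  kt <- matrix(c(6, 6, 0.8, 0.8, 2, 2, 2, 2), 2,
               dimnames = list(c("CI", "HC"), CONDITIONS))
  st <- simulate_score_table(
    study_design(n_ci = 10, n_hc = 10, trials_per_condition = 8,
                 kappa_table = kt), seed = 41)
  pc <- posthoc_contrasts(fit_mixed_model(st), "satterthwaite")
  expect_gt(pc$estimate[pc$name == "A_CI - V_CI"], 0)
  expect_gt(pc$estimate[pc$name == "A_HC - V_HC"], 0)
  expect_lt(pc$p_bonferroni[pc$name == "A_CI - V_CI"], 0.05)
})

test_that("clinical regression recovers a planted slope and codes onsets", {
  clin <- ci_clinical_table()
  clin$participant_id <- sprintf("CI%02d", seq_len(nrow(clin)))
  x <- code_onset_age(clin$onset_age)
  set.seed(43)
  n_reps <- 500
  b_hat <- replicate(n_reps, {
    y <- 0.5 - 0.04 * x + rnorm(length(x), 0, 0.5)
    scores <- data.frame(participant_id = rep(clin$participant_id, 2),
                         group = "CI",
                         condition = rep(c("V", "A"), each = nrow(clin)),
                         logit_R = c(y, y), excluded = FALSE)
    regress_clinical(scores, clin, "V", "onset_age")$b
  })
  expect_lt(abs(mean(b_hat) - (-0.04)), 3 * sd(b_hat) / sqrt(n_reps))

  # output shape: df = n - 2
  y <- 0.5 - 0.04 * x + rnorm(length(x), 0, 0.5)
  scores <- data.frame(participant_id = clin$participant_id, group = "CI",
                       condition = "V", logit_R = y, excluded = FALSE)
  r <- regress_clinical(scores, clin, "V", "onset_age")
  expect_equal(r$df, 18)
  expect_equal(r$n, 20)

  # zero-variance predictor errors
  clin0 <- clin; clin0$deafness_duration <- 5
  expect_error(regress_clinical(scores, clin0, "V", "deafness_duration"),
               "zero-variance")
})

test_that("congruence-effect outcome uses the AVsync minus V difference", {
  clin <- ci_clinical_table()
  clin$participant_id <- sprintf("CI%02d", seq_len(nrow(clin)))
  set.seed(47)
  v <- rnorm(20); sync <- v + 1.5 + rnorm(20, 0, 0.1)
  scores <- data.frame(participant_id = rep(clin$participant_id, 2),
                       group = "CI",
                       condition = rep(c("V", "AVsync"), each = 20),
                       logit_R = c(v, sync), excluded = FALSE)
  r <- regress_clinical(scores, clin, "AVsync_minus_V", "deafness_duration")
  expect_equal(r$outcome, "AVsync_minus_V")
  expect_equal(r$n, 20)
})
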