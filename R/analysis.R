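#' Aggregate trial scores for analysis
#'
#' Drops excluded trials and tallies exclusions by group and condition
#' (the bookkeeping reported alongside the inference). Participants who
#' lose every trial are kept in the metadata with a warning.
#'
#' @param scores Score table from [score_study()] (columns
#'   `participant_id`, `group`, `condition`, `trial`, `logit_R`,
#'   `excluded`, `reason`, ...).
#' @return List with `scores` (included rows only), `exclusion_counts`
#'   (group x condition matrix), `exclusion_reasons` (table) and
#'   `empty_participants` (ids with zero usable trials).
#' @export
aggregate_scores <- function(scores) {
  needed <- c("participant_id", "group", "condition", "excluded")
  if (!all(needed %in% names(scores))) stop("score table missing columns")
  scores$condition <- factor(scores$condition, levels = CONDITIONS)
  excl <- scores[scores$excluded, , drop = FALSE]
  kept <- scores[!scores$excluded, , drop = FALSE]
  counts <- table(factor(excl$group, levels = c("CI", "HC")),
                  factor(excl$condition, levels = CONDITIONS))
  empty <- setdiff(unique(scores$participant_id), unique(kept$participant_id))
  if (length(empty))
    warning(sprintf("participant(s) with no usable trials: %s",
                    paste(empty, collapse = ", ")))
  list(scores = kept,
       exclusion_counts = unclass(counts),
       exclusion_reasons = table(excl$reason),
       empty_participants = empty)
}

sum_coded <- function(x, levels) {
  f <- factor(x, levels = levels)
  stats::contrasts(f) <- stats::contr.sum(length(levels))
  f
}

#' Fit the group-by-condition mixed-effects model
#'
#' Models trial-level logit consistency as `group * condition` fixed
#' effects (both factors sum-to-zero coded) with a random intercept per
#' participant and random condition slopes, which absorb the unequal
#' score variance across conditions. If the full random-slope covariance
#' fails to converge, the model is refit with uncorrelated (diagonal)
#' slopes, then with a random intercept only; each downgrade is
#' recorded. A singular fit converges and is retained, flagged.
#'
#' @param table Data frame with `participant_id`, `group`, `condition`
#'   and `logit_R` (excluded trials already removed, see
#'   [aggregate_scores()]).
#' @return Object of class `tapsync_fit`: the `lmerModLmerTest` fit plus
#'   `structure` (`"full"`, `"diagonal"` or `"intercept"`), `singular`,
#'   and the sizes used.
#' @export
fit_mixed_model <- function(table) {
  if (is.list(table) && !is.data.frame(table) && !is.null(table$scores))
    table <- table$scores
  groups <- unique(table$group)
  if (length(groups) < 2) stop("need both groups")
  if (length(unique(table$condition)) < 2) stop("need at least 2 conditions")
  per_group <- tapply(table$participant_id, table$group,
                      function(x) length(unique(x)))
  if (any(per_group < 2)) stop("need at least 2 participants per group")

  d <- data.frame(logit_R = table$logit_R,
                  group = sum_coded(table$group, c("CI", "HC")),
                  condition = sum_coded(table$condition, CONDITIONS),
                  participant_id = factor(table$participant_id))
  # columns of the sum-to-zero condition coding, for the diagonal fallback
  cm <- stats::model.matrix(~condition, d)[, -1, drop = FALSE]
  colnames(cm) <- paste0("cnd", seq_len(ncol(cm)))
  d <- cbind(d, cm)

  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  try_fit <- function(formula) {
    converged <- TRUE
    fit <- withCallingHandlers(
      tryCatch(lmerTest::lmer(formula, data = d, REML = TRUE, control = ctrl),
               error = function(e) NULL),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w))) converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (is.null(fit)) return(NULL)
    if (!is.null(fit@optinfo$conv$lme4$messages) &&
        any(grepl("converge", fit@optinfo$conv$lme4$messages)))
      converged <- FALSE
    if (!converged) return(NULL)
    fit
  }

  fit <- try_fit(logit_R ~ group * condition + (1 + condition | participant_id))
  structure_used <- "full"
  if (is.null(fit)) {
    slope_terms <- paste(sprintf("(0 + %s | participant_id)", colnames(cm)),
                         collapse = " + ")
    fit <- try_fit(stats::as.formula(paste(
      "logit_R ~ group * condition + (1 | participant_id) +", slope_terms)))
    structure_used <- "diagonal"
  }
  if (is.null(fit)) {
    fit <- try_fit(logit_R ~ group * condition + (1 | participant_id))
    structure_used <- "intercept"
  }
  if (is.null(fit)) stop("mixed model failed to converge under all structures")
  structure(list(fit = fit,
                 structure = structure_used,
                 singular = lme4::isSingular(fit),
                 n_participants = length(unique(d$participant_id)),
                 n_trials = nrow(d)),
            class = "tapsync_fit")
}

#' @export
print.tapsync_fit <- function(x, ...) {
  cat(sprintf(
    "<tapsync_fit> %d trials, %d participants; random structure: %s%s\n",
    x$n_trials, x$n_participants, x$structure,
    if (x$singular) " (singular)" else ""))
  invisible(x)
}

#' Type-III omnibus tests
#'
#' Wald F tests of the group and condition main effects and their
#' interaction, with type-III sums of squares under the sum-to-zero
#' coding. Denominator degrees of freedom use the Kenward-Roger
#' approximation by default; Satterthwaite is offered for simulation
#' studies where thousands of fits make Kenward-Roger impractical.
#'
#' @param fit A [fit_mixed_model()] result.
#' @param method `"kenward-roger"` or `"satterthwaite"`.
#' @return Data frame: `term`, `F`, `df1`, `df2`, `p`.
#' @export
omnibus_tests <- function(fit, method = c("kenward-roger", "satterthwaite")) {
  stopifnot(inherits(fit, "tapsync_fit"))
  method <- match.arg(method)
  if (method == "kenward-roger") {
    a <- car::Anova(fit$fit, type = 3, test.statistic = "F")
    a <- a[rownames(a) != "(Intercept)", , drop = FALSE]
    out <- data.frame(term = rownames(a), F = a$F,
                      df1 = a$Df, df2 = a$Df.res, p = a[["Pr(>F)"]])
  } else {
    a <- stats::anova(fit$fit, type = 3)
    out <- data.frame(term = rownames(a), F = a[["F value"]],
                      df1 = a$NumDF, df2 = a$DenDF, p = a[["Pr(>F)"]])
  }
  rownames(out) <- NULL
  out
}

#' The post-hoc comparisons of interest
#'
#' Builds the cell-weight vectors of the 11 planned contrasts on the
#' group x condition estimated marginal means: the between-group
#' unisensory comparisons, the within-group auditory advantage and its
#' group difference, and the within-group congruence (synchronous) and
#' interference (asynchronous) effects relative to visual-only, each
#' with its group difference.
#'
#' @param grid Data frame with `group` and `condition` columns giving
#'   the cell order of the marginal means.
#' @return Named list of 11 weight vectors.
#' @export
contrast_definitions <- function(grid) {
  cell <- function(cond, grp)
    as.numeric(grid$group == grp & grid$condition == cond)
  stopifnot(sum(cell("V", "CI")) == 1)  # every cell present exactly once
  list(
    "V_CI - V_HC"       = cell("V", "CI") - cell("V", "HC"),
    "A_CI - A_HC"       = cell("A", "CI") - cell("A", "HC"),
    "A_CI - V_CI"       = cell("A", "CI") - cell("V", "CI"),
    "A_HC - V_HC"       = cell("A", "HC") - cell("V", "HC"),
    "(A_CI - V_CI) - (A_HC - V_HC)" =
      (cell("A", "CI") - cell("V", "CI")) - (cell("A", "HC") - cell("V", "HC")),
    "AVsync_CI - V_CI"  = cell("AVsync", "CI") - cell("V", "CI"),
    "AVsync_HC - V_HC"  = cell("AVsync", "HC") - cell("V", "HC"),
    "(AVsync_CI - V_CI) - (AVsync_HC - V_HC)" =
      (cell("AVsync", "CI") - cell("V", "CI")) -
      (cell("AVsync", "HC") - cell("V", "HC")),
    "AVasync_CI - V_CI" = cell("AVasync", "CI") - cell("V", "CI"),
    "AVasync_HC - V_HC" = cell("AVasync", "HC") - cell("V", "HC"),
    "(AVasync_CI - V_CI) - (AVasync_HC - V_HC)" =
      (cell("AVasync", "CI") - cell("V", "CI")) -
      (cell("AVasync", "HC") - cell("V", "HC")))
}

#' Post-hoc contrasts with Bonferroni correction
#'
#' Tests the 11 planned comparisons on the estimated marginal means of
#' the fitted model and applies a Bonferroni correction for the printed
#' family size of 11: `p_bonferroni = min(1, 11 * p_raw)`. The contrast
#' list is asserted to match the family size.
#'
#' @param fit A [fit_mixed_model()] result.
#' @param method Degrees-of-freedom method passed to emmeans.
#' @param family_size Bonferroni family size (fixed at 11).
#' @return Data frame: `name`, `estimate`, `se`, `df`, `t`, `p_raw`,
#'   `p_bonferroni`.
#' @export
posthoc_contrasts <- function(fit, method = c("kenward-roger", "satterthwaite"),
                              family_size = 11) {
  stopifnot(inherits(fit, "tapsync_fit"))
  method <- match.arg(method)
  em <- emmeans::emmeans(fit$fit, ~ group * condition, lmer.df = method)
  grid <- as.data.frame(em)[, c("group", "condition")]
  defs <- contrast_definitions(grid)
  stopifnot(length(defs) == family_size)
  ct <- emmeans::contrast(em, defs, adjust = "none")
  s <- as.data.frame(summary(ct))
  out <- data.frame(name = as.character(s$contrast),
                    estimate = s$estimate, se = s$SE, df = s$df,
                    t = s$t.ratio, p_raw = s$p.value,
                    p_bonferroni = pmin(1, family_size * s$p.value))
  rownames(out) <- NULL
  out
}

#' Per-participant mean consistency by condition
#'
#' @param scores Included-trials score table.
#' @return Wide data frame: `participant_id`, `group`, one column per
#'   condition with the mean `logit_R`.
#' @export
participant_condition_means <- function(scores) {
  agg <- stats::aggregate(logit_R ~ participant_id + group + condition,
                          data = scores, FUN = mean)
  wide <- stats::reshape(agg, idvar = c("participant_id", "group"),
                         timevar = "condition", direction = "wide")
  names(wide) <- sub("^logit_R\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Clinical-covariate regression in the implant group
#'
#' Ordinary least squares of a per-participant consistency outcome on a
#' deafness-history predictor, within implant users only. Outcomes are
#' the participant-mean logit consistency in the visual-only (`V`) or
#' auditory-only (`A`) condition, or the congruence effect
#' (`AVsync_minus_V`). Onset ages recorded as pre-linguistic enter as
#' 2 years.
#'
#' @param scores Included-trials score table (both groups allowed; the
#'   CI subset is used).
#' @param clinical Clinical table as from [ci_clinical_table()], with a
#'   `participant_id` column or rows in participant order.
#' @param outcome `"V"`, `"A"` or `"AVsync_minus_V"`.
#' @param predictor `"onset_age"` or `"deafness_duration"`.
#' @return Data frame: `outcome`, `predictor`, `b`, `se`, `t`, `df`,
#'   `p`, `n`.
#' @export
regress_clinical <- function(scores, clinical,
                             outcome = c("V", "A", "AVsync_minus_V"),
                             predictor = c("onset_age", "deafness_duration")) {
  outcome <- match.arg(outcome)
  predictor <- match.arg(predictor)
  means <- participant_condition_means(scores[scores$group == "CI", ])
  if (nrow(means) < 4) stop("need at least 4 implant users with usable trials")
  if (is.null(clinical$participant_id))
    clinical$participant_id <- means$participant_id[seq_len(nrow(clinical))]
  d <- merge(means, clinical, by = "participant_id")
  y <- switch(outcome,
              V = d$V, A = d$A,
              AVsync_minus_V = d$AVsync - d$V)
  x <- if (predictor == "onset_age") code_onset_age(d$onset_age) else
    as.numeric(d$deafness_duration)
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 4) stop("too few complete cases")
  if (stats::var(x) == 0) stop("zero-variance predictor")
  m <- stats::lm(y ~ x)
  s <- summary(m)$coefficients
  data.frame(outcome = outcome, predictor = predictor,
             b = s["x", "Estimate"], se = s["x", "Std. Error"],
             t = s["x", "t value"], df = length(y) - 2L,
             p = s["x", "Pr(>|t|)"], n = length(y))
}
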