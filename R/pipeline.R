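#' Assemble a run configuration
#'
#' Bundles every tunable of a full synthetic run: the study design, the
#' scoring parameters and the analysis settings. A saved configuration
#' reproduces the deterministic stages byte-identically.
#'
#' @param design A [study_design()].
#' @param scoring A [scoring_config()].
#' @param df_method Degrees-of-freedom method for the omnibus tests and
#'   contrasts.
#' @param alpha Nominal significance level recorded in the report.
#' @param family_size Bonferroni family size for the planned contrasts.
#' @param run_analysis `FALSE` stops after scoring (scores TSV only).
#' @param out_dir Output directory (created if needed).
#' @return List of class `run_config`.
#' @export
run_config <- function(design = study_design(),
                       scoring = scoring_config(),
                       df_method = c("kenward-roger", "satterthwaite"),
                       alpha = 0.05, family_size = 11,
                       run_analysis = TRUE,
                       out_dir = tempfile("tapsync_run_")) {
  structure(list(design = design, scoring = scoring,
                 df_method = match.arg(df_method),
                 alpha = alpha, family_size = family_size,
                 run_analysis = run_analysis, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulate -> write events -> score -> aggregate -> model -> omnibus ->
#' contrasts -> clinical regressions -> report, in the study's order.
#' Writes `events.tsv`, `scores.tsv`, `exclusions.tsv`, `report.json`
#' and `run_log.txt` (which records every design-decision parameter in
#' effect) under `config$out_dir`. A stage failure aborts with the stage
#' name; files already written are kept.
#'
#' @param config A [run_config()].
#' @return Named character vector of output paths, invisibly; the parsed
#'   report is attached as attribute `"report"`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(events = file.path(config$out_dir, "events.tsv"),
             scores = file.path(config$out_dir, "scores.tsv"),
             exclusions = file.path(config$out_dir, "exclusions.tsv"),
             report = file.path(config$out_dir, "report.json"),
             log = file.path(config$out_dir, "run_log.txt"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  dataset <- stage("simulate", generate_study(config$design))
  stage("write_events", write_events_table(dataset, paths[["events"]]))
  scores <- stage("score", score_study(dataset, config$scoring))
  stage("write_scores",
        write_scores_table(scores, paths[["scores"]], config$design$seed))
  agg <- stage("aggregate", suppressWarnings(aggregate_scores(scores)))
  excl_df <- as.data.frame.table(agg$exclusion_counts,
                                 responseName = "n_excluded")
  names(excl_df)[1:2] <- c("group", "condition")
  stage("write_exclusions", write_tsv(excl_df, paths[["exclusions"]],
                                      config$design$seed, ""))
  write_run_log(config, paths[["log"]])
  if (!config$run_analysis) return(invisible(paths[c("events", "scores", "log")]))

  fit <- stage("model", fit_mixed_model(agg$scores))
  omnibus <- stage("omnibus", omnibus_tests(fit, config$df_method))
  contrasts <- stage("contrasts",
                     posthoc_contrasts(fit, config$df_method,
                                       config$family_size))
  clinical <- ci_clinical_table()
  clinical$participant_id <- sprintf("CI%02d", seq_len(nrow(clinical)))
  regressions <- stage("regressions", do.call(rbind, lapply(
    c("V", "A", "AVsync_minus_V"), function(oc)
      do.call(rbind, lapply(c("onset_age", "deafness_duration"), function(pr)
        regress_clinical(agg$scores, clinical, oc, pr))))))
  report <- list(
    seed = config$design$seed,
    alpha = config$alpha,
    model = list(structure = fit$structure, singular = fit$singular,
                 df_method = config$df_method),
    omnibus = omnibus,
    contrasts = contrasts,
    regressions = regressions,
    exclusion_counts = excl_df)
  stage("report", jsonlite::write_json(report, paths[["report"]],
                                       auto_unbox = TRUE, digits = NA,
                                       dataframe = "rows"))
  out <- paths
  attr(out, "report") <- report
  invisible(out)
}

write_run_log <- function(config, path) {
  d <- config$design
  s <- config$scoring
  lines <- c(
    header_comment(d$seed, config_hash(config)),
    sprintf("design: n_ci=%d n_hc=%d trials_per_condition=%d duration=%g s",
            d$n_ci, d$n_hc, d$trials_per_condition, d$duration),
    sprintf("design: dropout_prob=%g dropout_length=%g s", d$dropout_prob,
            d$dropout_length),
    sprintf("design: wrong_rate_prob CI=%g HC=%g even_phase_prob=%g",
            d$wrong_rate_prob[["CI"]], d$wrong_rate_prob[["HC"]],
            d$even_phase_prob),
    sprintf("design: pause_prob=%g double_tap_prob=%g miss_prob=%g",
            d$pause_prob, d$double_tap_prob, d$miss_prob),
    sprintf("design: participant_log_kappa_sd=%g cell_log_kappa_sd=%g mean_phase=%g rad",
            d$participant_log_kappa_sd, d$cell_log_kappa_sd, d$mean_phase),
    sprintf("scoring: kernel_sd=%g s grid_dt=%g s refractory=%g s",
            s$kernel_sd, s$grid_dt, s$refractory),
    sprintf("scoring: n_trim=%d epsilon=%g min_taps=%d instructed_multiplier=%d",
            s$n_trim, s$epsilon, s$min_taps, s$instructed_multiplier),
    "scoring: quartile convention = type 7 (linear interpolation), pause rule single-pass",
    "scoring: guard window boundary half-open [dropout_end, dropout_end + window)",
    sprintf("analysis: df_method=%s alpha=%g bonferroni_family=%d",
            config$df_method, config$alpha, config$family_size))
  writeLines(lines, path)
  invisible(path)
}
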