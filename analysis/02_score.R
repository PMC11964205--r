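#!/usr/bin/env Rscript
# Stage 2: read the event tables back (as an analysis of real recordings
# would), run the cleaning pipeline (dropout guard, double-tap suppression,
# interval-multiple detection, wrong-rate exclusion, phase detection, initial
# trim, pause pruning) and score each trial's circular consistency.

suppressPackageStartupMessages(library(tapsync))

events <- read_events_table("results/events.tsv")
trials <- events_to_trials(events)
cat(sprintf("Scoring %d trials...\n", length(trials)))

config <- scoring_config()
grp <- ifelse(grepl("^CI", vapply(trials, `[[`, "", "participant_id")),
              "CI", "HC")
scores <- do.call(rbind, Map(function(trial, g) {
  cbind(data.frame(participant_id = trial$participant_id, group = g,
                   condition = trial$condition_name, trial = trial$trial),
        score_trial(trial, config))
}, trials, grp))
rownames(scores) <- NULL

write_scores_table(scores, "results/scores.tsv")
agg <- suppressWarnings(aggregate_scores(scores))
cat("Exclusions by group and condition:\n")
print(agg$exclusion_counts)
cat("Exclusion reasons:\n")
print(agg$exclusion_reasons)
cat("Mean logit consistency by cell:\n")
print(round(tapply(agg$scores$logit_R,
                   list(agg$scores$group, agg$scores$condition), mean), 2))
cat("Wrote results/scores.tsv\n")
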