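#!/usr/bin/env Rscript
# Stage 1: simulate the full synthetic study (20 implant users + 17 hearing
# controls, 4 metronome conditions x 10 trials, 39.5 s trials at 2.4 Hz with
# the 2.6 Hz asynchronous visual stream) and write the event-level tables.

suppressPackageStartupMessages(library(tapsync))

seed <- 20260919
dir.create("results", showWarnings = FALSE)

design <- study_design(seed = seed)
cat(sprintf("Simulating: %d CI + %d HC participants, %d trials/condition\n",
            design$n_ci, design$n_hc, design$trials_per_condition))
dataset <- generate_study(design)

write_events_table(dataset, "results/events.tsv")
write_stimulus_table(path = "results/stimuli.tsv")

ev <- events_table(dataset)
cat(sprintf("Wrote results/events.tsv: %d taps over %d trials\n",
            nrow(ev), length(dataset$trials)))
cat(sprintf("Trials carrying the 1.46 s recording dropout: %d of %d\n",
            sum(vapply(dataset$trials,
                       function(x) !is.null(x$dropout_end), logical(1))),
            length(dataset$trials)))
wrong <- sum(vapply(dataset$trials, function(x) x$truth$wrong_rate, logical(1)))
cat(sprintf("Planted wrong-rate (1x/3x) trials: %d\n", wrong))
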