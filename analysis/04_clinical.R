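#!/usr/bin/env Rscript
# Stage 4: clinical-covariate regressions within the implant-user group:
# per-participant mean consistency (visual-only, auditory-only, and the
# synchronous-congruence effect AVsync - V) against deafness onset age
# (pre-linguistic coded as 2 years) and deafness duration.

suppressPackageStartupMessages({library(tapsync); library(jsonlite)})

scores <- read_scores_table("results/scores.tsv")
agg <- suppressWarnings(aggregate_scores(scores))
clinical <- ci_clinical_table()
clinical$participant_id <- sprintf("CI%02d", seq_len(nrow(clinical)))

res <- do.call(rbind, lapply(c("V", "A", "AVsync_minus_V"), function(oc)
  do.call(rbind, lapply(c("onset_age", "deafness_duration"), function(pr)
    regress_clinical(agg$scores, clinical, oc, pr)))))

cat("Linear regressions within the CI group:\n")
for (i in seq_len(nrow(res)))
  cat(sprintf("  %-15s ~ %-18s b = %6.3f, t(%d) = %5.2f, p = %.3f\n",
              res$outcome[i], res$predictor[i], res$b[i], res$df[i],
              res$t[i], res$p[i]))

write_json(res, "results/clinical_regressions.json",
           auto_unbox = TRUE, digits = NA, dataframe = "rows")
cat("Wrote results/clinical_regressions.json\n")
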