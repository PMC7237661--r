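#!/usr/bin/env Rscript
# Screen participants on secondary-task performance (5 SD below the cohort
# mean on symmetry judgements or lexical decisions) and score the battery:
# per-task accuracy plus the combined spatial and working-memory predictors.
# Reads results/trials.csv (from 01_simulate.R), writes results/scores.csv
# and results/screen.json.

library(physep)

trials <- read_trial_table("results/trials.csv")
screen <- screen_participants(trials, k_sd = 5)
message(sprintf("screened out %d of %d participants: %s",
                length(screen$excluded_ids),
                length(unique(trials$participant_id)),
                if (length(screen$excluded_ids))
                  paste(screen$excluded_ids, collapse = ", ") else "none"))

retained <- trials[!(trials$participant_id %in% screen$excluded_ids), ]
scores <- score_primary(retained)
write.csv(scores, "results/scores.csv", row.names = FALSE)
jsonlite::write_json(
  list(excluded_ids = screen$excluded_ids,
       thresholds = as.list(screen$thresholds), k_sd = screen$k_sd),
  "results/screen.json", auto_unbox = TRUE, digits = NA)

for (task in task_names()) {
  message(sprintf("  %-16s mean %.3f sd %.3f (chance %.4f)", task,
                  mean(scores[[task]]), sd(scores[[task]]),
                  chance_level(task)))
}
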