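#!/usr/bin/env Rscript
# Split-half reliability of every task (items split into stratified halves,
# per-participant accuracy correlated across halves) and the item-level
# reliability of the towers task (participants halved, per-item accuracy
# correlated across items). Permutation p-values use 10,000 shuffles of the
# participant (resp. item) correspondence. Writes results/reliability.csv.

library(physep)

seed <- 1L
trials <- read_trial_table("results/trials.csv")
screen <- screen_participants(trials)
trials <- trials[!(trials$participant_id %in% screen$excluded_ids), ]

rows <- list()
for (i in seq_along(task_names())) {
  task <- task_names()[i]
  res <- split_half_participants(trials, task, seed = seed + i,
                                 n_iter_perm = 10000L)
  message(sprintf("%-16s participant-level r = %.3f (Spearman-Brown %.3f), p = %.4g",
                  task, res$r, res$corrected_r, res$p_perm))
  rows[[i]] <- data.frame(task = task, level = "participants", r = res$r,
                          corrected_r = res$corrected_r, p_perm = res$p_perm,
                          n_units = res$n_units)
}
items <- split_half_items(trials, "towers", seed = seed + 10L,
                          n_iter_perm = 10000L)
message(sprintf("towers item-level r = %.3f over %d items, p = %.4g",
                items$r, items$n_units, items$p_perm))
rows[[length(rows) + 1L]] <- data.frame(task = "towers", level = "items",
                                        r = items$r,
                                        corrected_r = items$corrected_r,
                                        p_perm = items$p_perm,
                                        n_units = items$n_units)
write.csv(do.call(rbind, rows), "results/reliability.csv", row.names = FALSE)
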