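# shared fixtures, built in code

.fixture_env <- new.env(parent = emptyenv())

# memoised simulated cohort so several test files can reuse one draw
cohort_fixture <- function(key = "default", config = default_config(seed = 42L)) {
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_cohort(config)
  }
  .fixture_env[[key]]
}

# hand-built trial table over the full battery schedule: `rule(i, task, j)`
# returns correctness for participant i on the j-th scheduled unit of `task`;
# secondary units are all-correct unless `secondary_rule` is given
manual_trials <- function(n, rule, secondary_rule = function(i, task, j) 1L) {
  schedule <- lapply(task_names(), default_task_schedule)
  names(schedule) <- task_names()
  ids <- sprintf("P%03d", seq_len(n))
  pieces <- list()
  for (task in task_names()) {
    sched <- schedule[[task]]
    for (i in seq_len(n)) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        participant_id = ids[i], task = task, item_id = sched$item_id,
        stratum = sched$stratum, unit_kind = "primary",
        correct = vapply(seq_len(nrow(sched)),
                         function(j) as.integer(rule(i, task, j)), integer(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  sec_items <- list(wm_spatial = sprintf("sym%03d", 1:132),
                    wm_verbal = sprintf("lex%03d", 1:132))
  for (task in names(sec_items)) {
    for (i in seq_len(n)) {
      m <- length(sec_items[[task]])
      pieces[[length(pieces) + 1L]] <- data.frame(
        participant_id = ids[i], task = task, item_id = sec_items[[task]],
        stratum = "secondary", unit_kind = "secondary",
        correct = vapply(seq_len(m),
                         function(j) as.integer(secondary_rule(i, task, j)),
                         integer(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# all permutations of 1..n, one per column (for exhaustive permutation oracles)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(ncol(sub))) {
      col <- col + 1L
      out[, col] <- c(k, rest[sub[, j]])
    }
  }
  out
}
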