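#' Write a trial table to CSV
#'
#' @param trials Trial table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a trial table from CSV
#'
#' Checks the declared header, task labels, binary correctness, duplicate
#' units, and (when a schedule is supplied) per-participant completeness of
#' the primary units.
#'
#' @param path CSV path with header `participant_id, task, item_id, stratum,
#'   unit_kind, correct`.
#' @param schedule Optional named list of per-task schedules to check
#'   completeness against.
#' @return A validated trial table.
#' @export
read_trial_table <- function(path, schedule = NULL) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(correct = "integer"))
  validate_trials(trials)
  if (!is.null(schedule)) {
    prim <- trials[trials$unit_kind == "primary", , drop = FALSE]
    participants <- unique(prim$participant_id)
    for (task in names(schedule)) {
      tt <- prim[prim$task == task, , drop = FALSE]
      counts <- table(factor(tt$participant_id, levels = participants))
      bad <- names(counts)[counts != nrow(schedule[[task]])]
      if (length(bad)) {
        stop(sprintf("participant %s has %d of %d scheduled units for task %s",
                     bad[1], counts[[bad[1]]], nrow(schedule[[task]]), task))
      }
    }
  }
  trials
}

#' Retained sample size after exclusion bookkeeping
#'
#' @param completers Number of workers who completed the battery.
#' @param exclusions Numeric vector of exclusion counts by reason (applied
#'   before screening), e.g. comprehension failures, data-saving
#'   malfunctions, location, concurrent-task violations.
#' @param screened Participants removed by the secondary-task screen.
#' @return The retained count.
#' @export
retained_n <- function(completers, exclusions = numeric(0), screened = 0) {
  if (any(c(completers, exclusions, screened) < 0)) {
    stop("counts must be non-negative")
  }
  out <- completers - sum(exclusions) - screened
  if (out < 0) stop("exclusions exceed completers: bookkeeping error")
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (when given a `cohort_config`) or load (when given a
#' CSV path) -> secondary-task screening -> scoring -> split-half
#' reliabilities (participant-level for all tasks, item-level for towers) ->
#' the 5 x 5 task intercorrelation matrix with permutation p-values -> nested
#' model comparisons (paper folding alone vs. both spatial predictors; verbal
#' WM alone vs. both WM predictors, each predicting towers accuracy) -> the
#' residual split-half separability test. All randomness derives from `seed`
#' via fixed per-stage offsets, so the report is fully reproducible and each
#' stage can be replayed independently.
#'
#' @param input A `cohort_config` or a path to a trial-table CSV.
#' @param seed Master seed. When `input` is a config, its own seed is
#'   replaced by this one so a single integer governs the whole run.
#' @param n_iter_perm Permutation iterations for every test (default 10000).
#' @param k_sd Screening threshold in SD units (default 5).
#' @return An `analysis_report` list; see [report_json()] for serialization.
#' @export
run_pipeline <- function(input, seed = 1L, n_iter_perm = 10000L, k_sd = 5) {
  seed <- as.integer(seed)
  if (inherits(input, "cohort_config")) {
    config <- input
    config$seed <- seed
    abilities <- draw_abilities(config)
    trials <- simulate_trials(abilities, config)
    source_desc <- "simulated"
    schedule <- config$schedule
  } else if (is.character(input) && length(input) == 1L) {
    trials <- read_trial_table(input)
    config <- NULL
    source_desc <- input
    schedule <- NULL
  } else {
    stop("input must be a cohort_config or a path to a trial-table CSV")
  }

  n_total <- length(unique(trials$participant_id))
  screen <- screen_participants(trials, k_sd = k_sd)
  retained <- trials[!(trials$participant_id %in% screen$excluded_ids), ,
                     drop = FALSE]
  scores <- score_primary(retained, schedule = schedule)
  tasks <- task_names()

  task_summaries <- lapply(tasks, function(task) {
    list(mean = mean(scores[[task]]), sd = stats::sd(scores[[task]]),
         chance = chance_level(task))
  })
  names(task_summaries) <- tasks

  reliability <- lapply(seq_along(tasks), function(i) {
    res <- split_half_participants(retained, tasks[i], seed = seed + 100L + i,
                                   n_iter_perm = n_iter_perm)
    list(r = res$r, p_perm = res$p_perm, corrected_r = res$corrected_r,
         n_units = res$n_units)
  })
  names(reliability) <- tasks
  towers_items <- split_half_items(retained, "towers", seed = seed + 200L,
                                   n_iter_perm = n_iter_perm)

  # full-data task intercorrelations with permutation p-values
  r_mat <- diag(1, length(tasks))
  p_mat <- matrix(NA_real_, length(tasks), length(tasks))
  dimnames(r_mat) <- dimnames(p_mat) <- list(tasks, tasks)
  pair_seed <- seed + 300L
  for (i in seq_along(tasks)) for (j in seq_along(tasks)) {
    if (j <= i) next
    pair_seed <- pair_seed + 1L
    perm <- permutation_test(scores[[tasks[i]]], scores[[tasks[j]]],
                             n_iter = n_iter_perm, seed = pair_seed)
    r_mat[i, j] <- r_mat[j, i] <- perm$observed_stat
    p_mat[i, j] <- p_mat[j, i] <- perm$p_two_tailed
  }

  # do the two spatial (resp. WM) measures capture distinct towers variance?
  cmp_spatial <- nested_f_test(
    ols_fit(scores$towers, scores[, "paper_folding", drop = FALSE]),
    ols_fit(scores$towers, scores[, c("paper_folding", "mental_rotation")])
  )
  cmp_wm <- nested_f_test(
    ols_fit(scores$towers, scores[, "wm_verbal", drop = FALSE]),
    ols_fit(scores$towers, scores[, c("wm_verbal", "wm_spatial")])
  )

  separability <- residual_separability(retained, scores,
                                        seed = seed + 400L,
                                        n_iter_perm = n_iter_perm)

  report <- list(
    cohort = list(source = source_desc, n_total = n_total,
                  n_screened_out = length(screen$excluded_ids),
                  excluded_ids = screen$excluded_ids,
                  screen_thresholds = as.list(screen$thresholds),
                  n_retained = retained_n(n_total,
                                          screened = length(screen$excluded_ids))),
    task_summaries = task_summaries,
    reliability = list(participants = reliability,
                       towers_items = list(r = towers_items$r,
                                           p_perm = towers_items$p_perm,
                                           n_units = towers_items$n_units)),
    correlations = list(r = r_mat, p_perm = p_mat),
    model_comparisons = list(
      spatial = unclass(cmp_spatial)[c("f", "df", "p", "aic_reduced",
                                       "aic_full", "evidence_ratio", "favored")],
      working_memory = unclass(cmp_wm)[c("f", "df", "p", "aic_reduced",
                                         "aic_full", "evidence_ratio", "favored")]
    ),
    residual_separability = list(r_resid = separability$r_resid,
                                 p_perm = separability$p_perm),
    parameters = list(seed = seed, n_iter_perm = n_iter_perm, k_sd = k_sd)
  )
  if (!is.null(config)) {
    report$parameters$config <- config[c("n_participants", "latent_sd",
                                         "latent_corr", "seed")]
    report$parameters$loadings <- config$loadings
  }
  class(report) <- "analysis_report"
  report
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report`.
#' @param path Optional path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Battery analysis report\n")
  cat(sprintf("  cohort: %d participants, %d screened out, %d retained\n",
              x$cohort$n_total, x$cohort$n_screened_out, x$cohort$n_retained))
  cat("  task accuracies (mean +/- sd | chance):\n")
  for (task in names(x$task_summaries)) {
    s <- x$task_summaries[[task]]
    cat(sprintf("    %-16s %.3f +/- %.3f | %.4f\n", task, s$mean, s$sd,
                s$chance))
  }
  cat("  split-half reliability (participant-level r, Spearman-Brown):\n")
  for (task in names(x$reliability$participants)) {
    r <- x$reliability$participants[[task]]
    cat(sprintf("    %-16s r = %.3f (SB %.3f), p = %.4g\n", task, r$r,
                r$corrected_r, r$p_perm))
  }
  ti <- x$reliability$towers_items
  cat(sprintf("  towers item-level split-half: r = %.3f over %d items, p = %.4g\n",
              ti$r, ti$n_units, ti$p_perm))
  for (nm in names(x$model_comparisons)) {
    m <- x$model_comparisons[[nm]]
    cat(sprintf("  %s comparison: F(%d,%d) = %.2f, p = %.3g; %s model %.1fx more likely\n",
                nm, m$df[1], m$df[2], m$f, m$p, m$favored, m$evidence_ratio))
  }
  rs <- x$residual_separability
  cat(sprintf("  residual separability: r = %.3f, permutation p = %.4g\n",
              rs$r_resid, rs$p_perm))
  invisible(x)
}
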