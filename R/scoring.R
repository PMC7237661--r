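#' Score primary task units into a participant-by-task accuracy matrix
#'
#' Each task's accuracy is the fraction of scheduled primary units answered
#' correctly: towers /48, paper folding /20, mental rotation /48 (one unit
#' per selection, so a partially correct item earns partial credit), each
#' working memory task /24 (one unit per span trial; trial-level correctness
#' must already encode the exact-set recall rule — all target positions and
#' no others). Combined predictors are the arithmetic means of the two
#' spatial and the two working memory accuracies.
#'
#' @param trials A trial table (see [simulate_trials()] for the schema).
#' @param schedule Named list of per-task schedules (`item_id`, `stratum`);
#'   defaults to the battery's standard schedule. Every participant must have
#'   exactly one record per scheduled unit.
#' @return A `score_matrix` data.frame: `participant_id`, one accuracy column
#'   per task, `combined_spatial`, `combined_wm`.
#' @export
score_primary <- function(trials, schedule = NULL) {
  validate_trials(trials)
  if (is.null(schedule)) {
    schedule <- infer_schedule(trials)
  }
  prim <- trials[trials$unit_kind == "primary", , drop = FALSE]
  participants <- sort(unique(prim$participant_id))
  out <- data.frame(participant_id = participants, stringsAsFactors = FALSE)
  for (task in task_names()) {
    sched <- schedule[[task]]
    if (is.null(sched)) stop("no schedule for task ", task)
    tt <- prim[prim$task == task, , drop = FALSE]
    counts <- table(factor(tt$participant_id, levels = participants))
    bad <- names(counts)[counts != nrow(sched)]
    if (length(bad)) {
      stop(sprintf(
        "incomplete data: participant %s has %d of %d scheduled units for task %s",
        bad[1], counts[[bad[1]]], nrow(sched), task))
    }
    unknown <- setdiff(unique(tt$item_id), sched$item_id)
    if (length(unknown)) {
      stop(sprintf("unscheduled item(s) for task %s: %s", task,
                   paste(utils::head(unknown, 3), collapse = ", ")))
    }
    acc <- tapply(tt$correct, factor(tt$participant_id, levels = participants),
                  mean)
    out[[task]] <- as.numeric(acc)
  }
  out$combined_spatial <- (out$paper_folding + out$mental_rotation) / 2
  out$combined_wm <- (out$wm_spatial + out$wm_verbal) / 2
  class(out) <- c("score_matrix", "data.frame")
  out
}

# Recover the scheduled units per task from the table itself: the union of
# primary (item_id, stratum) pairs seen across participants. Completeness is
# then checked per participant against this union.
infer_schedule <- function(trials) {
  prim <- trials[trials$unit_kind == "primary", , drop = FALSE]
  tasks <- intersect(task_names(), unique(prim$task))
  if (length(tasks) < length(task_names())) {
    stop("trial table is missing primary units for task(s): ",
         paste(setdiff(task_names(), tasks), collapse = ", "))
  }
  sched <- lapply(tasks, function(task) {
    tt <- prim[prim$task == task, c("item_id", "stratum")]
    unique(tt[order(tt$item_id), , drop = FALSE])
  })
  names(sched) <- tasks
  sched
}

validate_trials <- function(trials) {
  required <- c("participant_id", "task", "item_id", "stratum",
                "unit_kind", "correct")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(unique(trials$task), task_names())
  if (length(unknown)) {
    stop("unknown task label(s): ", paste(unknown, collapse = ", "))
  }
  if (!all(trials$correct %in% c(0L, 1L))) {
    stop("correct must be binary (0/1)")
  }
  if (!all(trials$unit_kind %in% c("primary", "secondary"))) {
    stop("unit_kind must be 'primary' or 'secondary'")
  }
  key <- paste(trials$participant_id, trials$task, trials$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate scoring unit: ", gsub("\r", " / ", dup, fixed = TRUE))
  }
  invisible(trials)
}

#' Screen participants on secondary-task performance
#'
#' Complex-span tasks interleave the memoranda with a secondary processing
#' judgement (shape symmetry for spatial WM, lexical decision for verbal WM).
#' Participants whose secondary accuracy falls more than `k_sd` standard
#' deviations below the cohort mean on either measure are flagged for
#' exclusion. Thresholds are computed once on the full cohort (single pass,
#' no iterative re-screening), so screening is idempotent. A degenerate
#' measure with zero SD excludes no one.
#'
#' @param trials A trial table containing secondary units for both WM tasks.
#' @param k_sd Number of SDs below the mean that triggers exclusion
#'   (default 5).
#' @return A `screen_result` list: `excluded_ids`, per-participant
#'   `secondary` accuracies, and the `thresholds` used.
#' @export
screen_participants <- function(trials, k_sd = 5) {
  validate_trials(trials)
  sec <- trials[trials$unit_kind == "secondary", , drop = FALSE]
  measures <- c(symmetry = "wm_spatial", lexical = "wm_verbal")
  absent <- setdiff(measures, unique(sec$task))
  if (length(absent)) {
    stop("no secondary units for task(s): ", paste(absent, collapse = ", "))
  }
  participants <- sort(unique(trials$participant_id))
  acc <- data.frame(participant_id = participants, stringsAsFactors = FALSE)
  thresholds <- numeric(0)
  flagged <- character(0)
  for (mi in seq_along(measures)) {
    mname <- names(measures)[mi]
    tt <- sec[sec$task == measures[[mi]], , drop = FALSE]
    a <- tapply(tt$correct, factor(tt$participant_id, levels = participants),
                mean)
    acc[[mname]] <- as.numeric(a)
    mu <- mean(acc[[mname]])
    sdev <- stats::sd(acc[[mname]])
    thr <- mu - k_sd * sdev
    thresholds[mname] <- thr
    if (is.finite(sdev) && sdev > 0) {
      flagged <- union(flagged, participants[acc[[mname]] < thr])
    }
  }
  res <- list(excluded_ids = sort(flagged), secondary = acc,
              thresholds = thresholds, k_sd = k_sd)
  class(res) <- "screen_result"
  res
}

#' Analytic chance level of each task
#'
#' The accuracy expected from uniform random responding, which differs by
#' response format: a two-alternative side judgement (towers) gives 1/2;
#' one-of-five selection (paper folding) gives 1/5; picking 2 of 4 options
#' when exactly 2 are correct (mental rotation, scored per selection) gives
#' an expected 1 correct of 2 selected, i.e. 1/2 — computed here by
#' enumerating the six unordered option pairs; exact-set recall on a 12-cell
#' grid (working memory) requires a uniformly random subset to equal the
#' target set, probability 2^-12 (0.024%).
#'
#' @param task One of the five battery task names.
#' @return The guessing probability.
#' @export
chance_level <- function(task) {
  task <- match.arg(task, task_names())
  switch(task,
    towers = 0.5,
    paper_folding = 1 / 5,
    mental_rotation = {
      pairs <- utils::combn(4L, 2L)          # candidate selections
      correct <- c(TRUE, TRUE, FALSE, FALSE) # exactly two options are rotations
      mean(apply(pairs, 2L, function(sel) sum(correct[sel]) / 2))
    },
    wm_spatial = ,
    wm_verbal = 0.5^12
  )
}
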