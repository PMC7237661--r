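#' Draw a stratified split of a task's items into two halves
#'
#' Items are assigned to half A or half B at random, with balance enforced
#' within every stratum (trial type): strata of even size split exactly in
#' half; odd strata place the extra item in a randomly chosen half. The same
#' plan is applied to all participants (the split is over items, not drawn
#' per participant).
#'
#' @param trials Trial table.
#' @param task Task whose primary items are split.
#' @param seed Integer seed; identical seeds give identical plans.
#' @return A `split_plan` data.frame: `item_id`, `stratum`, `half` ("A"/"B").
#' @export
stratified_split <- function(trials, task, seed) {
  validate_trials(trials)
  task <- match.arg(task, task_names())
  prim <- trials[trials$unit_kind == "primary" & trials$task == task,
                 c("item_id", "stratum")]
  items <- unique(prim)
  if (!nrow(items)) stop("no primary units for task ", task)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  parts <- split(items, items$stratum)
  out <- lapply(parts, function(st) {
    m <- nrow(st)
    if (m < 2L) stop("stratum '", st$stratum[1], "' has fewer than 2 items; ",
                     "a balanced split is impossible")
    shuffled <- st[sample.int(m), , drop = FALSE]
    halves <- rep(sample(c("A", "B")), length.out = m)
    shuffled$half <- halves
    shuffled
  })
  plan <- do.call(rbind, out)
  plan <- plan[order(plan$item_id), , drop = FALSE]
  rownames(plan) <- NULL
  attr(plan, "task") <- task
  attr(plan, "seed") <- seed
  class(plan) <- c("split_plan", "data.frame")
  plan
}

# per-participant accuracy on each half of a split plan
half_accuracies <- function(trials, plan, participants = NULL) {
  task <- attr(plan, "task")
  prim <- trials[trials$unit_kind == "primary" & trials$task == task, ,
                 drop = FALSE]
  if (is.null(participants)) participants <- sort(unique(prim$participant_id))
  fac <- factor(prim$participant_id, levels = participants)
  half <- plan$half[match(prim$item_id, plan$item_id)]
  if (anyNA(half)) stop("trial table contains items absent from the split plan")
  list(
    A = as.numeric(tapply(prim$correct[half == "A"], fac[half == "A"], mean)),
    B = as.numeric(tapply(prim$correct[half == "B"], fac[half == "B"], mean)),
    participants = participants
  )
}

new_split_half_result <- function(r, p_perm, n_units, halves, n_iter,
                                  mode, task) {
  res <- list(r = r, p_perm = p_perm, n_units = n_units, halves = halves,
              corrected_r = spearman_brown(r), n_iter = n_iter,
              mode = mode, task = task)
  class(res) <- "split_half_result"
  res
}

#' Participant-level split-half reliability
#'
#' Splits a task's items into stratified halves, computes every participant's
#' accuracy on each half, and correlates the two accuracy vectors across
#' participants (Pearson). Significance comes from a permutation test that
#' shuffles the correspondence between participants' half-A and half-B
#' scores. With `n_plans > 1` the correlation is averaged over independent
#' split plans for stability (the permutation p is computed on the first
#' plan); the default single plan mirrors a single randomized split.
#'
#' @param trials Trial table.
#' @param task Task name.
#' @param seed Integer seed controlling the split plan(s) and permutations.
#' @param n_iter_perm Permutation iterations (default 10000).
#' @param n_plans Number of independent split plans to average over.
#' @return A `split_half_result`: `r`, `p_perm`, `n_units` (participants),
#'   the two half-accuracy vectors, and the Spearman-Brown `corrected_r`.
#' @export
split_half_participants <- function(trials, task, seed, n_iter_perm = 10000L,
                                    n_plans = 1L) {
  rs <- numeric(n_plans)
  first <- NULL
  for (i in seq_len(n_plans)) {
    plan <- stratified_split(trials, task, seed + (i - 1L))
    halves <- half_accuracies(trials, plan)
    rs[i] <- pearson_r(halves$A, halves$B)
    if (i == 1L) first <- halves
  }
  perm <- permutation_test(first$A, first$B, n_iter = n_iter_perm,
                           seed = seed + n_plans)
  new_split_half_result(mean(rs), perm$p_two_tailed,
                        length(first$participants), first,
                        n_iter_perm, mode = "participants", task = task)
}

#' Item-level split-half reliability
#'
#' Participants are randomly divided into two groups (no stratification) and
#' each item's accuracy is computed within each group; the correlation across
#' items indexes how reliably easy or difficult each item is across
#' independent sets of observers.
#'
#' @inheritParams split_half_participants
#' @return A `split_half_result` with `n_units` = number of items.
#' @export
split_half_items <- function(trials, task, seed, n_iter_perm = 10000L) {
  validate_trials(trials)
  task <- match.arg(task, task_names())
  prim <- trials[trials$unit_kind == "primary" & trials$task == task, ,
                 drop = FALSE]
  participants <- sort(unique(prim$participant_id))
  n <- length(participants)
  if (n < 4L) stop("need at least 2 participants per group")
  items <- sort(unique(prim$item_id))
  if (length(items) < 3L) stop("need at least 3 items")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grp_a <- sample(participants, floor(n / 2))
  in_a <- prim$participant_id %in% grp_a
  ifac <- factor(prim$item_id, levels = items)
  acc_a <- as.numeric(tapply(prim$correct[in_a], ifac[in_a], mean))
  acc_b <- as.numeric(tapply(prim$correct[!in_a], ifac[!in_a], mean))
  r <- pearson_r(acc_a, acc_b)
  perm <- permutation_test(acc_a, acc_b, n_iter = n_iter_perm, seed = seed + 1L)
  new_split_half_result(r, perm$p_two_tailed, length(items),
                        list(A = acc_a, B = acc_b, items = items),
                        n_iter_perm, mode = "items", task = task)
}

#' Spearman-Brown prophecy correction
#'
#' Predicted full-length reliability from a half-length reliability `r`:
#' `2 r / (1 + r)`. The raw split-half correlation is a lower bound on the
#' full-test reliability; this correction estimates the latter.
#'
#' @param r A correlation in (-1, 1].
#' @return The corrected reliability.
#' @export
spearman_brown <- function(r) {
  if (!is.finite(r) || r <= -1 || r > 1) {
    stop("r must lie in (-1, 1]")
  }
  2 * r / (1 + r)
}

#' @export
print.split_half_result <- function(x, ...) {
  cat(sprintf("Split-half reliability (%s-level), task '%s'\n", x$mode, x$task))
  cat(sprintf("  r = %.3f over %d %s (Spearman-Brown %.3f)\n",
              x$r, x$n_units, x$mode, x$corrected_r))
  cat(sprintf("  permutation p = %.4g (%d iterations)\n", x$p_perm, x$n_iter))
  invisible(x)
}
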