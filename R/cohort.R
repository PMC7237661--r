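#' Task identifiers for the five-task battery
#'
#' The battery pairs an unstable-towers physical-prediction task with two
#' spatial reasoning tests (paper folding, mental rotation) and two
#' complex-span working memory tasks (spatial, verbal).
#'
#' @return Character vector of the five task names, in canonical order.
#' @export
task_names <- function() {
  c("towers", "paper_folding", "mental_rotation", "wm_spatial", "wm_verbal")
}

# Scheduled primary units for one task: data.frame(item_id, stratum).
# towers: 48 videos in 12 strata (6 block counts x 2 landing sides, 4 each);
# paper folding: 20 items; mental rotation: 24 items scored as 48 selections;
# each WM task: 24 span trials, 4 per set size 3..8.
default_task_schedule <- function(task) {
  switch(task,
    towers = {
      blocks <- c(11L, 13L, 15L, 17L, 19L, 21L)
      grid <- expand.grid(rep = 1:4, side = c("gray", "white"), blocks = blocks,
                          stringsAsFactors = FALSE)
      data.frame(
        item_id = sprintf("tw%02d", seq_len(nrow(grid))),
        stratum = sprintf("b%02d_%s", grid$blocks, grid$side),
        stringsAsFactors = FALSE
      )
    },
    paper_folding = data.frame(
      item_id = sprintf("pf%02d", 1:20),
      stratum = "all",
      stringsAsFactors = FALSE
    ),
    mental_rotation = data.frame(
      item_id = sprintf("mr%02d_%s", rep(1:24, each = 2), c("a", "b")),
      stratum = "all",
      stringsAsFactors = FALSE
    ),
    wm_spatial = ,
    wm_verbal = {
      prefix <- if (task == "wm_spatial") "ws" else "wv"
      grid <- expand.grid(trial = 1:4, set_size = 3:8)
      data.frame(
        item_id = sprintf("%s_s%d_t%d", prefix, grid$set_size, grid$trial),
        stratum = sprintf("set%d", grid$set_size),
        stringsAsFactors = FALSE
      )
    },
    stop("unknown task: ", task)
  )
}

#' Default synthetic cohort configuration
#'
#' Returns the generative specification for a simulated cohort matching the
#' battery's design: 100 participants; 48 towers trials in 12 strata of 4
#' (six block counts, two landing sides); 20 paper-folding items; 24
#' mental-rotation items scored as 48 selections; 24 complex-span trials per
#' working memory task (4 per set size 3-8); 132 secondary symmetry
#' judgements and 132 matched lexical decisions.
#'
#' Abilities are latent factors: spatial (S), working memory (W), and a
#' physics-unique component (U) that, by construction, loads only on the
#' towers task, so "unique variance" has an unambiguous generative meaning.
#' S and W are correlated (`latent_corr`); U is independent of both. Each
#' task's true ability is `theta = loadings %*% c(s, w, u)` and unit-level
#' correctness follows a guessing-floor logistic response model
#' `P(correct) = c + (1 - c) * plogis(theta - b)` with per-item difficulty
#' `b ~ N(mean_task, sd_task)`. Chance floors are the analytic guessing
#' probabilities of each response format: 1/2 (towers, mental rotation),
#' 1/5 (paper folding), 2^-12 (exact-set working memory recall).
#'
#' @param n_participants Cohort size (default 100).
#' @param latent_corr Correlation between the S and W factors (default 0.3).
#' @param loading_u Towers loading on the physics-unique factor U
#'   (default 0.6 latent-SD units; set 0 for a cohort with no separable
#'   physics-specific variance).
#' @param seed Integer seed; the entire trial table is a deterministic
#'   function of the configuration, including this seed.
#' @param schedule_multiplier Named numeric vector of per-task factors that
#'   replicate the primary schedule (e.g. `c(paper_folding = 10)` gives 200
#'   paper-folding items). Used for asymptotic calibration studies; defaults
#'   to 1 for every task.
#' @return A `cohort_config` list; see fields in the source.
#' @export
default_config <- function(n_participants = 100L, latent_corr = 0.3,
                           loading_u = 0.6, seed = 1L,
                           schedule_multiplier = NULL) {
  tasks <- task_names()
  loadings <- rbind(
    towers          = c(s = 0.45, w = 0.00, u = loading_u),
    paper_folding   = c(s = 1.00, w = 0.00, u = 0),
    mental_rotation = c(s = 1.00, w = 0.00, u = 0),
    wm_spatial      = c(s = 0.00, w = 0.60, u = 0),
    wm_verbal       = c(s = 0.00, w = 0.60, u = 0)
  )
  schedule <- lapply(tasks, default_task_schedule)
  names(schedule) <- tasks
  if (!is.null(schedule_multiplier)) {
    for (task in names(schedule_multiplier)) {
      m <- as.integer(schedule_multiplier[[task]])
      if (m > 1L) {
        base <- schedule[[task]]
        schedule[[task]] <- data.frame(
          item_id = sprintf("%s_r%02d", rep(base$item_id, m),
                            rep(seq_len(m), each = nrow(base))),
          stratum = rep(base$stratum, m),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    latent_sd = c(s = 1, w = 1, u = 1),
    latent_corr = latent_corr,
    loadings = loadings,
    # difficulty location/scale on the latent (logit) scale; towers location
    # targets the high-accuracy regime typical of the task, the spreads give
    # items ranging from near-chance to near-ceiling
    item_difficulty_mean = c(towers = -0.32, paper_folding = 0,
                             mental_rotation = 0, wm_spatial = 0,
                             wm_verbal = 0),
    item_difficulty_sd = c(towers = 0.8, paper_folding = 1.0,
                           mental_rotation = 1.0, wm_spatial = 0.5,
                           wm_verbal = 0.5),
    # longer spans are harder: linear shift on b per set-size step, centred
    # on the mean set size 5.5
    wm_setsize_slope = 0.25,
    chance_floor = c(towers = 0.5, paper_folding = 0.2,
                     mental_rotation = 0.5, wm_spatial = 2^-12,
                     wm_verbal = 2^-12),
    schedule = schedule,
    secondary = list(n_units = 132L, mean_accuracy = 0.95,
                     n_outliers = 0L, outlier_accuracy = 0.05),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_participants < 1L) stop("n_participants must be positive")
  if (abs(config$latent_corr) > 1) stop("latent_corr must lie in [-1, 1]")
  if (any(config$latent_sd < 0)) stop("latent_sd must be non-negative")
  probs <- c(config$chance_floor, config$secondary$mean_accuracy,
             config$secondary$outlier_accuracy)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  u_load <- config$loadings[, "u"]
  if (any(u_load[setdiff(rownames(config$loadings), "towers")] != 0)) {
    stop("only the towers task may load on the physics-unique factor U")
  }
  tasks <- task_names()
  missing <- setdiff(tasks, rownames(config$loadings))
  if (length(missing)) stop("loadings missing for task(s): ",
                            paste(missing, collapse = ", "))
  missing <- setdiff(tasks, names(config$schedule))
  if (length(missing)) stop("schedule missing for task(s): ",
                            paste(missing, collapse = ", "))
  invisible(config)
}

#' Draw latent abilities for a simulated cohort
#'
#' Samples one row per participant: (s, w) from the bivariate normal implied
#' by `latent_sd` and `latent_corr`, u independently, and the per-task true
#' abilities `theta_<task> = loadings %*% c(s, w, u)`.
#'
#' @param config A `cohort_config` from [default_config()].
#' @return A data.frame with columns `participant_id`, `s`, `w`, `u`, and one
#'   `theta_<task>` column per task.
#' @export
draw_abilities <- function(config) {
  validate_config(config)
  sd <- config$latent_sd
  rho <- config$latent_corr
  cov_sw <- rho * sd["s"] * sd["w"]
  sigma <- matrix(c(sd["s"]^2, cov_sw, cov_sw, sd["w"]^2), 2, 2)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) stop("latent covariance is not positive semi-definite")
  n <- config$n_participants
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  z <- matrix(stats::rnorm(2L * n), n, 2L)
  ch <- chol(sigma, pivot = FALSE)
  sw <- z %*% ch
  u <- stats::rnorm(n, 0, sd["u"])
  out <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    s = sw[, 1], w = sw[, 2], u = u,
    stringsAsFactors = FALSE
  )
  theta <- cbind(out$s, out$w, out$u) %*% t(config$loadings)
  colnames(theta) <- paste0("theta_", rownames(config$loadings))
  cbind(out, as.data.frame(theta))
}

# save/restore the global RNG state so seeded draws inside package functions
# do not perturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a trial-level table from latent abilities
#'
#' For every participant x scheduled primary unit, correctness is Bernoulli
#' with `P(correct) = c_task + (1 - c_task) * plogis(theta_task - b_item)`,
#' where `b_item` is a fixed per-item difficulty drawn once per cohort from
#' `N(mean_task, sd_task)` (working memory items additionally shift with set
#' size). Secondary units (symmetry judgements for spatial WM, lexical
#' decisions for verbal WM) are Bernoulli at the configured secondary
#' accuracy, with optional planted low-performing participants for screening
#' studies. The result is byte-identical for identical configurations.
#'
#' @param abilities Output of [draw_abilities()].
#' @param config The same `cohort_config` used to draw the abilities.
#' @return A long-format trial table: `participant_id`, `task`, `item_id`,
#'   `stratum`, `unit_kind` ("primary"/"secondary"), `correct` (0/1).
#' @export
simulate_trials <- function(abilities, config) {
  validate_config(config)
  tasks <- task_names()
  missing <- setdiff(paste0("theta_", tasks), names(abilities))
  if (length(missing)) stop("abilities table lacks columns: ",
                            paste(missing, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)

  n <- nrow(abilities)
  pieces <- vector("list", length(tasks) + 2L)
  for (ti in seq_along(tasks)) {
    task <- tasks[ti]
    sched <- config$schedule[[task]]
    m <- nrow(sched)
    b <- stats::rnorm(m, config$item_difficulty_mean[[task]],
                      config$item_difficulty_sd[[task]])
    if (task %in% c("wm_spatial", "wm_verbal")) {
      set_size <- as.integer(sub("^set", "", sched$stratum))
      b <- b + config$wm_setsize_slope * (set_size - mean(3:8))
    }
    theta <- abilities[[paste0("theta_", task)]]
    cf <- config$chance_floor[[task]]
    # participants vary along rows, items along columns
    p <- cf + (1 - cf) * stats::plogis(outer(theta, b, `-`))
    correct <- matrix(stats::rbinom(n * m, 1L, p), n, m)
    pieces[[ti]] <- data.frame(
      participant_id = rep(abilities$participant_id, times = m),
      task = task,
      item_id = rep(sched$item_id, each = n),
      stratum = rep(sched$stratum, each = n),
      unit_kind = "primary",
      correct = as.integer(correct),
      stringsAsFactors = FALSE
    )
  }

  # secondary judgements: per-participant accuracy is the configured mean,
  # except for planted outliers (the last n_outliers participants)
  sec <- config$secondary
  acc <- rep(sec$mean_accuracy, n)
  if (sec$n_outliers > 0L) {
    idx <- seq.int(n - sec$n_outliers + 1L, n)
    acc[idx] <- sec$outlier_accuracy
  }
  sec_spec <- list(
    wm_spatial = sprintf("sym%03d", seq_len(sec$n_units)),
    wm_verbal  = sprintf("lex%03d", seq_len(sec$n_units))
  )
  for (si in seq_along(sec_spec)) {
    task <- names(sec_spec)[si]
    ids <- sec_spec[[si]]
    m <- length(ids)
    correct <- matrix(stats::rbinom(n * m, 1L, rep(acc, times = m)), n, m)
    pieces[[length(tasks) + si]] <- data.frame(
      participant_id = rep(abilities$participant_id, times = m),
      task = task,
      item_id = rep(ids, each = n),
      stratum = "secondary",
      unit_kind = "secondary",
      correct = as.integer(correct),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper: draws abilities and simulates the trial table.
#'
#' @inheritParams simulate_trials
#' @return List with elements `abilities` and `trials`.
#' @export
simulate_cohort <- function(config = default_config()) {
  abilities <- draw_abilities(config)
  list(abilities = abilities, trials = simulate_trials(abilities, config))
}
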