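test_that("default configuration matches the battery design", {
  cfg <- default_config()
  expect_equal(cfg$n_participants, 100L)
  expect_equal(nrow(cfg$schedule$towers), 48L)
  strata <- table(cfg$schedule$towers$stratum)
  expect_length(strata, 12L)
  expect_true(all(strata == 4L))
  expect_equal(nrow(cfg$schedule$paper_folding), 20L)
  expect_equal(nrow(cfg$schedule$mental_rotation), 48L)
  expect_equal(nrow(cfg$schedule$wm_spatial), 24L)
  expect_true(all(table(cfg$schedule$wm_verbal$stratum) == 4L))
  expect_equal(cfg$secondary$n_units, 132L)
  expect_equal(unname(cfg$chance_floor["paper_folding"]), 0.20)
  expect_equal(unname(cfg$chance_floor["towers"]), 0.5)
  expect_equal(unname(cfg$chance_floor["wm_spatial"]), 2^-12)
  # U is the physics-unique factor: only towers may load on it
  expect_true(cfg$loadings["towers", "u"] > 0)
  expect_true(all(cfg$loadings[-1, "u"] == 0))
  expect_true(all(cfg$loadings[c("paper_folding", "mental_rotation"), "s"] > 0))
  expect_true(all(cfg$loadings[c("wm_spatial", "wm_verbal"), "w"] > 0))
  expect_error(default_config(latent_corr = 1.5), "latent_corr")
})

test_that("ability draws respect the latent covariance and the seed", {
  cfg <- default_config(n_participants = 50000L, latent_corr = 0, seed = 11L)
  ab <- draw_abilities(cfg)
  expect_lt(abs(cor(ab$s, ab$w)), 0.02)
  expect_lt(abs(cor(ab$s, ab$u)), 0.02)

  cfg6 <- default_config(n_participants = 50000L, latent_corr = 0.6, seed = 12L)
  ab6 <- draw_abilities(cfg6)
  expect_lt(abs(cor(ab6$s, ab6$w) - 0.6), 0.02)

  # theta is a deterministic linear function of the latents
  theta <- as.matrix(ab6[, c("s", "w", "u")]) %*% t(cfg6$loadings)
  expect_equal(unname(theta[, 1]), ab6$theta_towers)

  expect_identical(draw_abilities(cfg), draw_abilities(cfg))
})

test_that("identical configurations give byte-identical trial tables", {
  cfg <- default_config(n_participants = 20L, seed = 5L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$trials, co2$trials)
  # and a different seed gives a different table
  co3 <- simulate_cohort(default_config(n_participants = 20L, seed = 6L))
  expect_false(identical(co1$trials, co3$trials))
})

test_that("response model is calibrated to c + (1-c) * logistic(theta - b)", {
  # theta = 0 for everyone, b = 0, c = 0.5 -> P(correct) = 0.75
  cfg <- default_config(n_participants = 400L, seed = 21L)
  cfg$loadings["towers", ] <- 0
  cfg$item_difficulty_mean["towers"] <- 0
  cfg$item_difficulty_sd["towers"] <- 0
  trials <- simulate_trials(draw_abilities(cfg), cfg)
  tow <- trials[trials$task == "towers" & trials$unit_kind == "primary", ]
  n_units <- nrow(tow)
  se <- sqrt(0.75 * 0.25 / n_units)
  expect_lt(abs(mean(tow$correct) - 0.75), 3 * se)

  # saturation: items far below every ability -> all correct
  cfg$item_difficulty_mean["towers"] <- -50
  trials <- simulate_trials(draw_abilities(cfg), cfg)
  tow <- trials[trials$task == "towers" & trials$unit_kind == "primary", ]
  expect_true(all(tow$correct == 1L))

  # guessing floor: theta - b -> -Inf leaves the WM chance level 2^-12
  cfg2 <- default_config(n_participants = 500L, seed = 22L)
  cfg2$item_difficulty_mean["wm_spatial"] <- 50
  cfg2$item_difficulty_sd["wm_spatial"] <- 0
  trials2 <- simulate_trials(draw_abilities(cfg2), cfg2)
  wm <- trials2[trials2$task == "wm_spatial" & trials2$unit_kind == "primary", ]
  p0 <- 2^-12
  se <- sqrt(p0 * (1 - p0) / nrow(wm))
  expect_lt(abs(mean(wm$correct) - p0), 3 * se + 1e-12)
})

test_that("physics-unique variance in theta is exactly the planted component", {
  cfg0 <- default_config(n_participants = 200L, loading_u = 0, seed = 31L)
  ab0 <- draw_abilities(cfg0)
  # zero unique loading: towers theta is an exact linear function of (s, w)
  lin <- as.matrix(ab0[, c("s", "w")]) %*% cfg0$loadings["towers", c("s", "w")]
  expect_equal(unname(lin[, 1]), ab0$theta_towers, tolerance = 1e-12)

  cfg1 <- default_config(n_participants = 200L, loading_u = 0.6, seed = 31L)
  ab1 <- draw_abilities(cfg1)
  resid <- ab1$theta_towers -
    as.matrix(ab1[, c("s", "w")]) %*% cfg1$loadings["towers", c("s", "w")]
  # what remains is exactly loading_u * u, so its variance is loading_u^2 var(u)
  expect_equal(unname(resid[, 1]), 0.6 * ab1$u, tolerance = 1e-12)
  expect_equal(var(resid[, 1]), 0.36 * var(ab1$u), tolerance = 1e-12)
})
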