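test_that("GDP simulator honours degenerate noise and determinism", {
  yrs <- 2000:2010
  flat <- simulate_gdp_series(yrs, "USA", mean_growth = 2.0,
                              ar_coefficient = 0, innovation_sd = 0, seed = 7)
  expect_true(all(flat$growth_pct == 2.0))
  a <- simulate_gdp_series(yrs, c("USA", "ENG"), seed = 11)
  b <- simulate_gdp_series(yrs, c("USA", "ENG"), seed = 11)
  expect_identical(a, b)
  expect_error(simulate_gdp_series(integer(0), "USA"), "non-empty")
  expect_error(simulate_gdp_series(yrs, character(0)), "non-empty")
})

test_that("GDP simulator matches AR(1) closed-form moments", {
  g <- simulate_gdp_series(1:10000, "X", mean_growth = 2.0,
                           ar_coefficient = 0.5, innovation_sd = 1.0,
                           seed = 123)$growth_pct
  n <- length(g)
  # stationary sd and the long-run variance of the mean of an AR(1)
  sd_x <- 1 / sqrt(1 - 0.5^2)
  se_mean <- sd_x * sqrt((1 + 0.5) / (1 - 0.5)) / sqrt(n)
  expect_lt(abs(mean(g) - 2.0), 3 * se_mean)
  ac1 <- cor(g[-1], g[-n])
  expect_lt(abs(ac1 - 0.5), 0.05)
})

test_that("zero effects with a cutpoint below the support give zero prevalence", {
  dl <- survey_dialect("HRS")
  cfg <- sim_config(
    n_individuals = 2000, cohort_effect = rep(0, 8), age_effect = rep(0, 6),
    period_coupling = 0, individual_sd = 0, noise_sd = 1,
    diagnosis_cutpoints = c(-30, -29), seed = 5
  )
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 5)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  expect_true(all(pan$true_dementia == 0L))
  expect_true(all(pan$true_class == "normal"))
})

test_that("with all effects zero and kappa1 = 0, every cell has prevalence 1/2", {
  cfg <- sim_config(
    n_individuals = 20000, cohort_effect = rep(0, 8), age_effect = rep(0, 6),
    period_coupling = 0, individual_sd = 0.5, noise_sd = 1,
    diagnosis_cutpoints = c(0, 1), seed = 99
  )
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 99)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  # P(latent < 0) = 0.5 exactly; check overall and per well-populated cell
  expect_lt(abs(mean(pan$true_dementia) - 0.5), 0.02)
  cells <- split(pan$true_dementia, list(pan$age_group, pan$cohort), drop = TRUE)
  for (cell in cells[vapply(cells, length, 0L) >= 400]) {
    p <- mean(cell)
    expect_lt(abs(p - 0.5), 4 * sqrt(0.25 / length(cell)) + 0.01)
  }
})

test_that("latent structure is reproducible and responds only to its own streams", {
  cfg <- sim_config(n_individuals = 500, seed = 21)
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 21)
  p1 <- suppressMessages(simulate_panel(cfg, gdp))
  p2 <- suppressMessages(simulate_panel(cfg, gdp))
  expect_identical(p1, p2)

  # with period_coupling = 0, swapping the GDP draw changes nothing
  cfg0 <- sim_config(n_individuals = 500, period_coupling = 0, seed = 21)
  gdp_b <- simulate_gdp_series(cfg0$survey_years, cfg0$countries, seed = 777)
  a <- suppressMessages(simulate_panel(cfg0, gdp))
  b <- suppressMessages(simulate_panel(cfg0, gdp_b))
  expect_identical(a$latent_cognition, b$latent_cognition)
  expect_identical(a$true_dementia, b$true_dementia)
})

test_that("prevalence rises with age group under a decreasing age effect", {
  cfg <- sim_config(n_individuals = 20000, cohort_effect = rep(0, 8), seed = 31)
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 31)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  by_age <- vapply(split(pan$true_dementia, pan$age_group), mean, 0)
  expect_true(all(diff(by_age) > -0.005))
  expect_gt(by_age[[length(by_age)]], by_age[[1]])
})

test_that("observables are truncated affine maps of latent cognition", {
  cfg <- sim_config(n_individuals = 4000, seed = 13)
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 13)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  obs <- degrade_to_observables(pan, cfg)

  # declared ranges respected
  expect_true(all(obs$score_recall >= 0 & obs$score_recall <= 20, na.rm = TRUE))
  expect_true(all(obs$score_serial7 >= 0 & obs$score_serial7 <= 5, na.rm = TRUE))
  expect_true(all(obs$score_orientation >= 0 & obs$score_orientation <= 4,
                  na.rm = TRUE))
  expect_true(all(obs$informant_score >= 1 & obs$informant_score <= 5,
                  na.rm = TRUE))
  expect_true(all(obs$adl_count %in% 0:5))
  expect_true(all(obs$iadl_count %in% 0:5))

  # proxy pattern: informant score iff proxy; self scores missing iff proxy
  expect_true(all(is.na(obs$score_recall[obs$proxy])))
  expect_true(all(!is.na(obs$score_recall[!obs$proxy])))
  expect_true(all(!is.na(obs$informant_score[obs$proxy])))
  expect_true(all(is.na(obs$informant_score[!obs$proxy])))

  # zero observation noise: score is the deterministic truncated affine value
  cfg0 <- sim_config(n_individuals = 1000, seed = 13,
                     observation = list(score_recall = list(
                       intercept = 10, slope = 3, sd = 0,
                       range = c(0, 20), integer = TRUE)))
  obs0 <- degrade_to_observables(pan[1:1000, ], cfg0)
  sel <- !obs0$proxy
  expect_equal(obs0$score_recall[sel],
               pmin(pmax(round(10 + 3 * pan$latent_cognition[1:1000][sel]), 0), 20))
})

test_that("score-latent correlation matches the bivariate-normal value", {
  # all systematic effects off so latent is exactly normal and truncation is mild
  cfg <- sim_config(n_individuals = 12000, cohort_effect = rep(0, 8),
                    age_effect = rep(0, 6), period_coupling = 0,
                    individual_sd = 0.5, noise_sd = 1, seed = 17)
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 17)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  obs <- degrade_to_observables(pan, cfg)
  sel <- !obs$proxy
  got <- cor(obs$score_recall[sel], obs$latent_cognition[sel])
  s_lat <- sqrt(0.5^2 + 1)
  expected <- 3 * s_lat / sqrt((3 * s_lat)^2 + 2^2)
  expect_gt(got, 0)
  expect_lt(abs(got - expected), 0.05)
})

test_that("gold-standard sampling is a labeled per-person census at fraction 1", {
  cfg <- sim_config(n_individuals = 300, seed = 3)
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 3)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  gold <- assign_gold_standard(pan, 1, seed = 3)
  expect_setequal(gold$person_id, unique(pan$person_id))
  expect_identical(anyDuplicated(gold$person_id), 0L)
  # labels equal the true class at the sampled wave
  key_g <- paste(gold$person_id, gold$wave)
  key_p <- paste(pan$person_id, pan$wave)
  expect_identical(gold$label, pan$true_class[match(key_g, key_p)])
  # both split halves present and disjoint by construction
  expect_setequal(unique(gold$split), c("calibration", "validation"))

  g1 <- assign_gold_standard(pan, 0.5, seed = 8)
  g2 <- assign_gold_standard(pan, 0.5, seed = 8)
  expect_identical(g1, g2)
  expect_warning(assign_gold_standard(pan, 0.02, seed = 8), "unstable")
})

test_that("gold label distribution tracks the true class distribution", {
  cfg <- sim_config(n_individuals = 8000, seed = 41)
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 41)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  gold <- assign_gold_standard(pan, 0.5, seed = 41)
  # oracle: persons are sampled uniformly and the labeled wave is uniform
  # within person, so the expected label distribution is the average of the
  # per-person wave-uniform class distributions
  per_person <- lapply(split(pan$true_class, pan$person_id), function(cl) {
    table(factor(cl, levels = c("dementia", "cind", "normal"))) / length(cl)
  })
  expected <- Reduce(`+`, per_person) / length(per_person)
  got <- table(factor(gold$label, levels = names(expected))) / nrow(gold)
  for (k in names(expected)) {
    se <- sqrt(expected[[k]] * (1 - expected[[k]]) / nrow(gold))
    expect_lt(abs(got[[k]] - expected[[k]]), 4 * se)
  }
})
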