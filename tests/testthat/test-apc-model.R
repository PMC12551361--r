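test_that("dummy designs have the documented column counts", {
  # two age groups x two cohorts in gdp mode: intercept + 1 + 1 + 1
  dl2 <- apcdem:::new_dialect("two", data.frame(
    label = c("1930-1934", "1935-1939"), start = c(1930L, 1935L),
    end = c(1934L, 1939L)))
  rec <- data.frame(
    person_id = sprintf("P%d", 1:8), birth_year = rep(c(1932L, 1937L), 4),
    gender = "female", interview_year = rep(c(2005L, 2010L), each = 4),
    gdp_growth = 2, dementia_hat = rep(c(0L, 1L), 4)
  )
  d2 <- suppressMessages(suppressWarnings(build_design(rec, dl2, mode = "gdp")))
  expect_identical(ncol(d2$X), 4L)

  # full HRS dialect: intercept + 5 age + 7 cohort + gdp = 14
  # 4-bin MC dialect spans ages 71-91 only: intercept + 4 age + 3 cohort + gdp
  des <- mc_design(800, seed = 1)
  expect_identical(ncol(des$X), 1L + 4L + 3L + 1L)
  hrs_des <- local({
    cfg <- sim_config(n_individuals = 1500, seed = 2)
    gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 2)
    pan <- suppressMessages(simulate_panel(cfg, gdp))
    build_design(pan, cfg$dialect, mode = "gdp", outcome = "true_dementia")
  })
  expect_identical(ncol(hrs_des$X), 14L)
  expect_true("gdp_growth" %in% colnames(hrs_des$X))
})

test_that("continuous age+year+cohort is rank deficient with null vector (1,-1,1)", {
  cfg <- sim_config(n_individuals = 500, seed = 3)
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 3)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  pan$dementia_hat <- pan$true_dementia
  des <- build_design(pan, cfg$dialect, mode = "year", encode = "continuous")
  rep <- check_identifiability(des)
  expect_true(rep$deficient)
  expect_identical(rep$rank, ncol(des$X) - 1L)
  v <- rep$null_space[[1]]
  expect_setequal(names(v), c("age", "year", "cohort"))
  # proportional to (1, -1, 1) on (age, year, cohort)
  expect_equal(v[["age"]] / v[["cohort"]], 1, tolerance = 1e-6)
  expect_equal(v[["year"]] / v[["cohort"]], -1, tolerance = 1e-6)

  # the categorical gdp-mode design from the same panel is full rank
  cat_des <- build_design(pan, cfg$dialect, mode = "gdp")
  expect_false(check_identifiability(cat_des)$deficient)

  # duplicated column named in the null space
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, a_copy = X[, "a"])
  repd <- check_identifiability(X)
  expect_true(repd$deficient)
  expect_setequal(names(repd$null_space[[1]]), c("a", "a_copy"))
})

test_that("rank-deficient designs are refused by the fitter", {
  cfg <- sim_config(n_individuals = 300, seed = 4)
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 4)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  des <- build_design(pan, cfg$dialect, mode = "year", encode = "continuous",
                      outcome = "true_dementia")
  expect_error(fit_glmm(des), "rank deficient")
})

test_that("the GLM path matches an independent IRLS probit to 1e-6", {
  withr::local_seed(8)
  n <- 200
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- as.integer(runif(n) < pnorm(drop(X %*% c(-0.5, 0.7, -0.4))))
  des <- structure(list(y = y, X = X, cluster = sprintf("c%d", 1:n),
                        mode = "gdp", outcome = "y", n_obs = n, n_persons = n),
                   class = "apc_design")
  fit <- fit_glmm(des, re = "none")
  oracle <- irls_probit(X, y)
  expect_lt(max(abs(fit$coefficients - oracle)), 1e-6)
})

test_that("one observation per cluster makes clustered SEs equal HC0", {
  withr::local_seed(9)
  n <- 150
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- as.integer(runif(n) < pnorm(drop(X %*% c(-0.2, 0.5))))
  des <- structure(list(y = y, X = X, cluster = sprintf("c%d", 1:n),
                        mode = "gdp", outcome = "y", n_obs = n, n_persons = n),
                   class = "apc_design")
  fit <- fit_glmm(des, re = "none")
  df <- data.frame(V1 = X[, 1], V2 = X[, 2], .y = y)
  ref <- glm(.y ~ . - 1, data = df, family = binomial("probit"))
  hc0 <- sqrt(diag(sandwich::vcovHC(ref, type = "HC0")))
  expect_lt(max(abs(fit$se - hc0)), 1e-8)
})

test_that("zero simulated intercept variance collapses to the GLM", {
  des <- mc_design(1500, seed = 10, individual_sd = 0)
  mixed <- fit_glmm(des, nodes = 9)
  plain <- fit_glmm(des, re = "none")
  expect_lt(mixed$random_intercept_sd, 0.08)
  expect_true(all(abs(mixed$coefficients - plain$coefficients) <
                    2 * plain$se + 1e-8))
})

test_that("the AGQ fitter agrees with lme4::glmer on a shared fixture", {
  des <- mc_design(250, seed = 12)
  fit <- fit_glmm(des, nodes = 9, se = "model")
  df <- data.frame(y = des$y, des$X[, -1, drop = FALSE], cl = des$cluster,
                   check.names = TRUE)
  ref <- suppressWarnings(lme4::glmer(y ~ . - cl + (1 | cl), data = df,
                                      family = binomial("probit"), nAGQ = 9))
  expect_lt(max(abs(fit$coefficients - lme4::fixef(ref))), 0.02)
  expect_lt(abs(fit$random_intercept_sd -
                  sqrt(unlist(lme4::VarCorr(ref)))), 0.02)
  # our fixed point should be at least as good a maximum
  expect_gte(fit$loglik, as.numeric(stats::logLik(ref)) - 1e-3)
})

test_that("probit and logit links both fit and order effects identically", {
  des <- mc_design(1200, seed = 14)
  fp <- fit_glmm(des, link = "probit", re = "none")
  fl <- fit_glmm(des, link = "logit", re = "none")
  coh <- grep("^cohort_", names(fp$coefficients))
  expect_identical(order(fp$coefficients[coh]), order(fl$coefficients[coh]))
  # logit coefficients are larger in magnitude by the usual scale factor
  expect_gt(median(abs(fl$coefficients[coh] / fp$coefficients[coh])), 1.3)
})

test_that("gender strata with equal effects give compatible estimates", {
  withr::local_seed(15)
  cfg <- sim_config(n_individuals = 4000, dialect = mc_dialect(),
                    birth_year_range = c(1929, 1948),
                    cohort_effect = c(0, 0.2, 0.3, 0.5),
                    diagnosis_cutpoints = c(-1.2, -0.4), seed = 15)
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 15)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  pan$dementia_hat <- pan$true_dementia
  fits <- suppressWarnings(
    stratified_fit(pan, mc_dialect(), mode = "gdp", re = "none"))
  expect_setequal(names(fits), c("female", "male"))
  last <- "cohort_1944-1948"
  diff <- fits$female$coefficients[[last]] - fits$male$coefficients[[last]]
  se_diff <- sqrt(fits$female$se[[last]]^2 + fits$male$se[[last]]^2)
  expect_lt(abs(diff), 2.5 * se_diff)

  pan_miss <- pan
  pan_miss$gender[1:50] <- NA
  expect_message(
    suppressWarnings(stratified_fit(pan_miss, mc_dialect(), mode = "gdp",
                                    re = "none")),
    "missing gender")
})

test_that("null cohort effects are covered by the 95% CIs at nominal rate", {
  # zero true cohort effects: each cohort coefficient's cluster-robust CI
  # should cover 0 at close to the nominal rate (fixed-effect path; the
  # mixed-model coverage under a nonzero gradient is checked end to end in
  # the acceptance suite)
  covered <- logical(0)
  for (r in 1:200) {
    des <- mc_design(2000, seed = 80000 + r, cohort_effect = rep(0, 4))
    f <- fit_glmm(des, re = "none")
    co <- grep("^cohort_", names(f$coefficients))
    covered <- c(covered, f$ci95[co, "low"] <= 0 & 0 <= f$ci95[co, "high"])
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("a steeper female cohort gradient is detected across replicates", {
  # women simulated with a stronger favourable shift in the latest cohort
  # (latent +0.6 vs +0.2 for men); the stratified fits should order the
  # latest-cohort estimates accordingly in nearly every replicate
  hits <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    cfg_f <- sim_config(n_individuals = 1000, dialect = mc_dialect(),
                        birth_year_range = c(1929, 1948),
                        cohort_effect = c(0, 0.25, 0.4, 0.6),
                        diagnosis_cutpoints = c(-1.2, -0.4), seed = 5000 + r)
    cfg_m <- sim_config(n_individuals = 1000, dialect = mc_dialect(),
                        birth_year_range = c(1929, 1948),
                        cohort_effect = c(0, 0.1, 0.15, 0.2),
                        diagnosis_cutpoints = c(-1.2, -0.4), seed = 6000 + r)
    gdp <- simulate_gdp_series(cfg_f$survey_years, cfg_f$countries,
                               seed = 7000 + r)
    pan_f <- suppressMessages(simulate_panel(cfg_f, gdp))
    pan_m <- suppressMessages(simulate_panel(cfg_m, gdp))
    pan_f$gender <- "female"; pan_m$gender <- "male"
    pan_m$person_id <- paste0("M", pan_m$person_id)
    pan <- rbind(pan_f, pan_m)
    pan$dementia_hat <- pan$true_dementia
    fits <- suppressWarnings(
      stratified_fit(pan, mc_dialect(), mode = "gdp", re = "none"))
    last <- "cohort_1944-1948"
    if (fits$female$coefficients[[last]] < fits$male$coefficients[[last]]) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.90)
})
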