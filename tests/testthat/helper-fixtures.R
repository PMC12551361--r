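# Shared fixtures and independent oracles for the test suite.

# Reduced four-cohort dialect for Monte-Carlo designs: keeps the regression
# small while exercising the full cohort-gradient machinery.
mc_dialect <- function() {
  apcdem:::new_dialect("MC4", data.frame(
    label = c("1929-1933", "1934-1938", "1939-1943", "1944-1948"),
    start = c(1929L, 1934L, 1939L, 1944L),
    end   = c(1933L, 1938L, 1943L, 1948L)
  ))
}

# Simulated gdp-mode design with the monotone cohort gradient
# (0, -0.2, -0.3, -0.5 on the dementia probit scale).
mc_design <- function(n_persons, seed, mode = "gdp", outcome = "true_dementia",
                      cohort_effect = c(0, 0.2, 0.3, 0.5),
                      individual_sd = 0.5) {
  dl <- mc_dialect()
  cfg <- sim_config(
    n_individuals = n_persons, birth_year_range = c(1929, 1948),
    dialect = dl, cohort_effect = cohort_effect,
    diagnosis_cutpoints = c(-1.2, -0.4), individual_sd = individual_sd,
    seed = seed
  )
  gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries,
                             ar_coefficient = 0.5, innovation_sd = 1.5,
                             seed = seed)
  pan <- suppressMessages(simulate_panel(cfg, gdp))
  suppressWarnings(build_design(pan, dl, mode = mode, outcome = outcome))
}

# True parameter vector (with log sigma) matching mc_design's generator, for
# warm-starting Monte-Carlo fits; order must match the design columns.
mc_truth <- function(design, individual_sd = 0.5) {
  nm <- colnames(design$X)
  truth <- c(
    "(Intercept)" = -1.2, age_2 = 0.25, age_3 = 0.5, age_4 = 0.75,
    age_5 = 1.0, age_6 = 1.25,
    "cohort_1934-1938" = -0.2, "cohort_1939-1943" = -0.3,
    "cohort_1944-1948" = -0.5, gdp_growth = -0.05
  )
  th <- truth[nm]
  th[is.na(th)] <- 0  # year dummies etc. have no closed-form truth
  names(th) <- nm
  c(th, log_sigma = log(individual_sd))
}

# draw labels from the ordered-probit data-generating process
# P(dementia) = pnorm(k1 + eta), P(dementia or CIND) = pnorm(k2 + eta)
draw_oprobit <- function(eta, k1, k2) {
  u <- runif(length(eta))
  ifelse(u < pnorm(k1 + eta), "dementia",
         ifelse(u < pnorm(k2 + eta), "cind", "normal"))
}

# Independent probit GLM oracle: Fisher-scoring IRLS written directly from
# the normal-equations updates, sharing no code with the package fitter.
irls_probit <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- pnorm(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    phi <- dnorm(eta)
    W <- phi^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / phi
    XtW <- t(X * W)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}

# Ordered-probit log-likelihood evaluated directly from the class
# probabilities (oracle-side formula, shared with nothing in the package).
oprobit_loglik <- function(beta, k1, k2, x, cls) {
  eta <- x * beta
  p1 <- pnorm(k1 + eta)
  p2 <- pnorm(k2 + eta) - pnorm(k1 + eta)
  p3 <- 1 - pnorm(k2 + eta)
  p <- ifelse(cls == 1, p1, ifelse(cls == 2, p2, p3))
  sum(log(pmax(p, 1e-300)))
}

# Two-stage exhaustive grid search over (beta, kappa1, kappa2) for a
# single-feature ordered probit; refines around the coarse optimum.
oprobit_grid_search <- function(x, cls, coarse = 0.05, fine = 0.002) {
  stage <- function(bs, k1s, gaps) {
    best <- c(-Inf, NA, NA, NA)
    for (b in bs) {
      for (k1 in k1s) {
        for (g in gaps) {
          ll <- oprobit_loglik(b, k1, k1 + g, x, cls)
          if (ll > best[1]) best <- c(ll, b, k1, k1 + g)
        }
      }
    }
    best
  }
  b1 <- stage(seq(-3, 3, coarse), seq(-3, 2, coarse), seq(coarse, 4, coarse))
  b2 <- stage(seq(b1[2] - coarse, b1[2] + coarse, fine),
              seq(b1[3] - coarse, b1[3] + coarse, fine),
              seq(max(b1[4] - b1[3] - coarse, fine),
                  b1[4] - b1[3] + coarse, fine))
  list(loglik = b2[1], beta = b2[2], kappa = b2[3:4])
}

# Small hand-writable panel data frame with all required columns.
make_panel_df <- function(n = 10, proxy = rep(FALSE, n)) {
  data.frame(
    person_id = sprintf("H%03d", seq_len(n)),
    country = "USA",
    birth_year = rep(1930L, n),
    gender = rep(c("female", "male"), length.out = n),
    education_years = 12L,
    wave = 1L,
    interview_year = 2010L,
    proxy = proxy,
    score_recall = ifelse(proxy, NA_real_, 10),
    score_serial7 = ifelse(proxy, NA_real_, 3),
    score_orientation = ifelse(proxy, NA_real_, 4),
    adl_count = 0L,
    iadl_count = 0L,
    informant_score = ifelse(proxy, 3, NA_real_),
    stringsAsFactors = FALSE
  )
}
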