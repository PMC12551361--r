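#' Simulation configuration for synthetic multi-wave cohort panels
#'
#' Builds the configuration object consumed by [simulate_panel()],
#' [degrade_to_observables()] and [assign_gold_standard()].  The generator
#' emulates the structure of harmonized aging panels (HRS/SHARE/ELSA-like):
#' persons with fixed birth year, gender, education and country are observed
#' at biennial survey waves; latent cognition is
#' \deqn{c_{i,t} = \lambda_{age}(a_{i,t}) + \lambda_{coh}(c_i) +
#'   \gamma \, g_{k(i),t} + u_i + \varepsilon_{i,t}}
#' with a person-level random intercept \eqn{u_i \sim N(0,\sigma_u^2)} and
#' occasion noise \eqn{\varepsilon \sim N(0,\sigma_e^2)}; lower latent
#' cognition is worse.  Clinical three-class status is assigned by two
#' ordered cutpoints on the latent scale: below \eqn{\kappa_1} is dementia,
#' between \eqn{\kappa_1} and \eqn{\kappa_2} is cognitively impaired, not
#' demented (CIND), above \eqn{\kappa_2} is normal.
#'
#' Default effects are calibrated to the regime the method targets: dementia
#' prevalence around 5-10% in the youngest eligible age group rising past 30%
#' beyond age 90, a monotone favourable trend for more recent cohorts with a
#' latent shift reaching +0.55 for the 1944-1948 cohort, a small positive
#' loading of annual GDP growth on cognition, and roughly one person-wave in
#' ten answered by a proxy informant.
#'
#' @param n_individuals number of simulated persons.
#' @param survey_years ordered calendar years of the waves (biennial default).
#' @param birth_year_range closed interval of birth years sampled uniformly.
#' @param dialect the [survey_dialect()] whose cohort bins index
#'   `cohort_effect`.
#' @param cohort_effect latent-scale shift per cohort bin (length =
#'   number of bins, first bin is the reference and conventionally 0).
#' @param age_effect latent-scale shift per age group 1-6.
#' @param period_coupling loading of the GDP growth rate (percent per annum)
#'   on latent cognition.
#' @param individual_sd standard deviation of the person random intercept.
#' @param noise_sd standard deviation of the occasion noise (> 0).
#' @param diagnosis_cutpoints `c(kappa1, kappa2)` with `kappa1 < kappa2`.
#' @param proxy_intercept,proxy_slope parameters of the monotone proxy
#'   mechanism: a person-wave is proxy-answered with probability
#'   `plogis(proxy_intercept - proxy_slope * latent)`, so the probability
#'   rises as cognition falls.
#' @param gold_fraction fraction of persons receiving a gold-standard
#'   clinical adjudication (in (0, 1]).
#' @param attrition_rate_per_wave probability of permanent exit at each wave
#'   after the first, in [0, 1).
#' @param attrition_latent_slope optional link between the person intercept
#'   and attrition (0 = attrition independent of cognition, the default;
#'   positive values make low-cognition persons likelier to exit, the
#'   mechanism by which panels underestimate prevalence).
#' @param countries country labels assigned uniformly to persons.
#' @param observation observation-model parameters; see
#'   [degrade_to_observables()].  Override individual entries by name.
#' @param seed root integer seed; every stochastic operation draws a named
#'   substream from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 10000,
                       survey_years = seq(2010, 2020, by = 2),
                       birth_year_range = c(1910, 1948),
                       dialect = survey_dialect("HRS"),
                       cohort_effect = default_cohort_effect(dialect),
                       age_effect = c(0, -0.25, -0.5, -0.75, -1.0, -1.25),
                       period_coupling = 0.05,
                       individual_sd = 0.5,
                       noise_sd = 1,
                       diagnosis_cutpoints = c(-1.65, -0.65),
                       proxy_intercept = -2.8,
                       proxy_slope = 0.9,
                       gold_fraction = 0.1,
                       attrition_rate_per_wave = 0.05,
                       attrition_latent_slope = 0,
                       countries = "USA",
                       observation = list(),
                       seed = 20260101) {
  stopifnot(
    n_individuals >= 1,
    length(survey_years) >= 1, !is.unsorted(survey_years, strictly = TRUE),
    length(birth_year_range) == 2, birth_year_range[1] <= birth_year_range[2],
    length(age_effect) == 6,
    length(cohort_effect) == nrow(dialect$cohort_bins),
    individual_sd >= 0, noise_sd > 0,
    length(diagnosis_cutpoints) == 2,
    diagnosis_cutpoints[1] < diagnosis_cutpoints[2],
    gold_fraction > 0, gold_fraction <= 1,
    attrition_rate_per_wave >= 0, attrition_rate_per_wave < 1,
    length(countries) >= 1
  )
  obs <- utils::modifyList(default_observation_model(), observation)
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      survey_years = as.integer(survey_years),
      birth_year_range = as.integer(birth_year_range),
      dialect = dialect,
      cohort_effect = cohort_effect,
      age_effect = age_effect,
      period_coupling = period_coupling,
      individual_sd = individual_sd,
      noise_sd = noise_sd,
      diagnosis_cutpoints = diagnosis_cutpoints,
      proxy_intercept = proxy_intercept,
      proxy_slope = proxy_slope,
      gold_fraction = gold_fraction,
      attrition_rate_per_wave = attrition_rate_per_wave,
      attrition_latent_slope = attrition_latent_slope,
      countries = countries,
      observation = obs,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Favourable latent shifts for recent cohorts, on the scale of the probit
# coefficients the cohort model estimates (reference bin 0, most recent about
# +0.55); intermediate bins interpolate a monotone gradient.
default_cohort_effect <- function(dialect) {
  k <- nrow(dialect$cohort_bins)
  five_year <- c("1919-1923" = 0.18, "1924-1928" = 0.27, "1929-1933" = 0.32,
                 "1934-1938" = 0.36, "1939-1943" = 0.46, "1944-1948" = 0.55)
  eff <- rep(0, k)
  names(eff) <- dialect$cohort_bins$label
  hit <- names(eff) %in% names(five_year)
  eff[hit] <- five_year[names(eff)[hit]]
  if ("1914-1918" %in% names(eff)) eff["1914-1918"] <- 0.09
  eff
}

default_observation_model <- function() {
  list(
    score_recall = list(intercept = 10, slope = 3, sd = 2,
                        range = c(0, 20), integer = TRUE),
    score_serial7 = list(intercept = 3.5, slope = 1.1, sd = 0.9,
                         range = c(0, 5), integer = TRUE),
    score_orientation = list(intercept = 3.6, slope = 0.6, sd = 0.5,
                             range = c(0, 4), integer = TRUE),
    informant_score = list(intercept = 3.3, slope = -0.8, sd = 0.4,
                           range = c(1, 5), integer = FALSE),
    adl = list(intercept = -2.2, slope = -0.9, trials = 5),
    iadl = list(intercept = -2.0, slope = -1.1, trials = 5),
    education_mean = 12, education_sd = 3
  )
}

#' Simulate an annual GDP-growth series as a stationary AR(1)
#'
#' One independent series per country: \eqn{g_t = m + \rho (g_{t-1} - m) +
#' e_t}, \eqn{e_t \sim N(0, s^2)}, initialized from the stationary
#' distribution \eqn{N(m, s^2 / (1 - \rho^2))}.  Growth is in percent per
#' annum; this is the period proxy joined onto panels by [attach_gdp()].
#'
#' @param years calendar years (non-empty).
#' @param countries country labels (non-empty).
#' @param mean_growth long-run mean growth, percent.
#' @param ar_coefficient AR(1) coefficient in (-1, 1).
#' @param innovation_sd innovation standard deviation (>= 0).
#' @param seed integer seed.
#' @return a `gdp_series` data frame with columns `country`, `year`,
#'   `growth_pct`.
#' @export
simulate_gdp_series <- function(years, countries, mean_growth = 2,
                                ar_coefficient = 0.5, innovation_sd = 1,
                                seed = 1) {
  if (!length(years)) stop("years must be non-empty")
  if (!length(countries)) stop("countries must be non-empty")
  stopifnot(innovation_sd >= 0, abs(ar_coefficient) < 1)
  years <- sort(unique(as.integer(years)))
  n <- length(years)
  out <- with_seed(substream_seed(seed, "gdp"), {
    do.call(rbind, lapply(countries, function(ct) {
      x <- numeric(n)
      s0 <- innovation_sd / sqrt(1 - ar_coefficient^2)
      x[1] <- mean_growth + stats::rnorm(1, 0, s0)
      if (n > 1) {
        e <- stats::rnorm(n - 1, 0, innovation_sd)
        for (t in 2:n) {
          x[t] <- mean_growth + ar_coefficient * (x[t - 1] - mean_growth) + e[t - 1]
        }
      }
      data.frame(country = ct, year = years, growth_pct = x,
                 stringsAsFactors = FALSE)
    }))
  })
  as_gdp_series(out)
}

#' Simulate a true panel with known age, cohort and period effects
#'
#' Draws persons, their random intercepts and wave-level noise, builds latent
#' cognition from the configured age-group, cohort and GDP effects, assigns
#' three-class clinical truth by the diagnosis cutpoints, and applies
#' permanent per-wave attrition.  Only eligible person-waves (age at
#' interview 71 or older, birth year inside a cohort bin) enter the output;
#' persons never eligible at any retained wave are excluded and counted in
#' the `"n_excluded_persons"` attribute.
#'
#' @param config a [sim_config()].
#' @param gdp a GDP series covering every (country, survey year) pair.
#' @return a data frame (the "true panel") with one row per eligible,
#'   non-attrited person-wave: identifiers, demographics, `age`, `age_group`,
#'   `cohort`, `gdp_growth`, `latent_cognition`, `true_class`
#'   (`"dementia"`, `"cind"`, `"normal"`) and binary `true_dementia`.
#' @export
simulate_panel <- function(config, gdp) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  np <- cfg$n_individuals
  yrs <- cfg$survey_years
  nw <- length(yrs)

  persons <- with_seed(substream_seed(cfg$seed, "persons"), {
    data.frame(
      person_id = sprintf("P%06d", seq_len(np)),
      birth_year = sample(seq(cfg$birth_year_range[1], cfg$birth_year_range[2]),
                          np, replace = TRUE),
      gender = sample(c("female", "male"), np, replace = TRUE,
                      prob = c(0.56, 0.44)),
      education_years = pmin(pmax(round(stats::rnorm(
        np, cfg$observation$education_mean, cfg$observation$education_sd)), 0), 20),
      country = sample(cfg$countries, np, replace = TRUE),
      u = stats::rnorm(np, 0, cfg$individual_sd),
      stringsAsFactors = FALSE
    )
  })

  # permanent attrition: survival to each wave; optional cognition link via
  # the person intercept (lower u -> higher exit hazard when slope > 0)
  present <- matrix(TRUE, np, nw)
  if (nw > 1 && (cfg$attrition_rate_per_wave > 0 || cfg$attrition_latent_slope > 0)) {
    present <- with_seed(substream_seed(cfg$seed, "attrition"), {
      p_exit <- stats::plogis(stats::qlogis(pmax(cfg$attrition_rate_per_wave, 1e-12)) +
                                cfg$attrition_latent_slope * (-persons$u))
      m <- matrix(TRUE, np, nw)
      for (w in 2:nw) {
        m[, w] <- m[, w - 1] & (stats::runif(np) >= p_exit)
      }
      m
    })
  }

  idx_p <- rep(seq_len(np), each = nw)
  idx_w <- rep(seq_len(nw), times = np)
  long <- persons[idx_p, c("person_id", "birth_year", "gender",
                           "education_years", "country")]
  long$wave <- idx_w
  long$interview_year <- yrs[idx_w]
  long$u <- persons$u[idx_p]
  long <- long[present[cbind(idx_p, idx_w)], , drop = FALSE]

  long$age <- compute_age(long$interview_year, long$birth_year)
  long$age_group <- bin_age_group(long$age)
  long$cohort <- bin_cohort(long$birth_year, cfg$dialect)
  eligible <- !is.na(long$age_group) & !is.na(long$cohort)
  long <- long[eligible, , drop = FALSE]

  long <- attach_gdp(long, gdp)

  coh_eff <- cfg$cohort_effect
  if (is.null(names(coh_eff))) names(coh_eff) <- cfg$dialect$cohort_bins$label
  eps <- with_seed(substream_seed(cfg$seed, "noise"),
                   stats::rnorm(nrow(long), 0, cfg$noise_sd))
  long$latent_cognition <- cfg$age_effect[long$age_group] +
    unname(coh_eff[long$cohort]) +
    cfg$period_coupling * long$gdp_growth +
    long$u + eps

  k <- cfg$diagnosis_cutpoints
  long$true_class <- ifelse(long$latent_cognition < k[1], "dementia",
                            ifelse(long$latent_cognition < k[2], "cind", "normal"))
  long$true_dementia <- as.integer(long$true_class == "dementia")
  long$u <- NULL
  rownames(long) <- NULL

  kept_persons <- unique(long$person_id)
  n_excluded <- np - length(kept_persons)
  attr(long, "n_excluded_persons") <- n_excluded
  if (n_excluded > 0) {
    message("simulate_panel: ", n_excluded,
            " person(s) had no eligible person-wave and were excluded")
  }
  long
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Degrade a true panel to survey observables
#'
#' Replaces latent cognition with what a survey actually measures: cognitive
#' test scores (word recall 0-20, serial 7s 0-5, orientation 0-4) as noisy
#' affine transforms of latent cognition, rounded and truncated to their
#' declared ranges; ADL/IADL limitation counts with rates decreasing in
#' latent cognition; a proxy flag whose probability rises as cognition falls;
#' and, for proxy person-waves, an IQCODE-like informant score (1-5,
#' decreasing in latent cognition) with the self-test scores marked missing.
#' Self-respondent person-waves have the informant score missing.
#'
#' The true panel's `latent_cognition`, `true_class` and `true_dementia`
#' columns are retained so simulation studies can score against truth; they
#' are not written by [write_panel()]'s standard column set and are never
#' visible to the classifier.
#'
#' @param panel a true panel from [simulate_panel()].
#' @param config the same [sim_config()].
#' @param seed optional seed override (defaults to the config root seed).
#' @return the panel with observable columns appended.
#' @export
degrade_to_observables <- function(panel, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  obs <- config$observation
  n <- nrow(panel)
  lat <- panel$latent_cognition
  out <- panel

  out <- with_seed(substream_seed(seed, "observables"), {
    for (sc in c("score_recall", "score_serial7", "score_orientation",
                 "informant_score")) {
      p <- obs[[sc]]
      v <- p$intercept + p$slope * lat + stats::rnorm(n, 0, p$sd)
      if (isTRUE(p$integer)) v <- round(v)
      out[[sc]] <- clamp(v, p$range[1], p$range[2])
    }
    out$adl_count <- stats::rbinom(
      n, obs$adl$trials, stats::plogis(obs$adl$intercept + obs$adl$slope * lat))
    out$iadl_count <- stats::rbinom(
      n, obs$iadl$trials, stats::plogis(obs$iadl$intercept + obs$iadl$slope * lat))
    out$proxy <- stats::runif(n) <
      stats::plogis(config$proxy_intercept - config$proxy_slope * lat)
    out
  })

  out$score_recall[out$proxy] <- NA_real_
  out$score_serial7[out$proxy] <- NA_real_
  out$score_orientation[out$proxy] <- NA_real_
  out$informant_score[!out$proxy] <- NA_real_
  out
}

#' Draw a gold-standard clinical subsample
#'
#' Emulates a one-time clinical adjudication substudy: a simple random sample
#' of persons (not person-waves) of the stated fraction, each labeled with
#' the true three-class status at one randomly chosen observed wave, split
#' 50/50 by person into disjoint calibration and validation halves.
#'
#' @param panel a true panel (needs `person_id`, `wave`, `true_class`).
#' @param gold_fraction fraction of persons sampled, in (0, 1].
#' @param seed integer seed.
#' @return a data frame with `person_id`, `wave`, `label`
#'   (`dementia`/`cind`/`normal`) and `split` (`"calibration"` or
#'   `"validation"`).
#' @export
assign_gold_standard <- function(panel, gold_fraction, seed = 1) {
  stopifnot(gold_fraction > 0, gold_fraction <= 1)
  persons <- unique(panel$person_id)
  n_gold <- max(1L, round(length(persons) * gold_fraction))
  with_seed(substream_seed(seed, "gold"), {
    chosen <- sample(persons, n_gold)
    rows <- vapply(chosen, function(p) {
      cand <- which(panel$person_id == p)
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, integer(1))
    split <- sample(rep_len(c("calibration", "validation"), n_gold))
    out <- data.frame(
      person_id = panel$person_id[rows],
      wave = panel$wave[rows],
      label = panel$true_class[rows],
      split = split,
      stringsAsFactors = FALSE
    )
    if (n_gold < 50) {
      warning("gold-standard subsample has only ", n_gold,
              " persons; calibration may be unstable")
    }
    out
  })
}
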