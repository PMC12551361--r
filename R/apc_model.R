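#' Build the age-period-cohort regression design
#'
#' Constructs the design matrix of the cohort models: an intercept, age-group
#' dummies (reference: youngest group, 71-75), cohort dummies (reference: the
#' dialect's first cohort), and a period block that is either survey-year
#' dummies (reference: first year present; `mode = "year"`) or the single
#' continuous GDP growth column (`mode = "gdp"`), the proxy that breaks the
#' exact age = year - birth-year collinearity.  Declared age or cohort cells
#' with zero observations have their dummy dropped with a warning naming the
#' cell.  Rows with an ineligible age or out-of-range cohort are excluded
#' with logged counts.
#'
#' `encode = "continuous"` is a diagnostic path that instead enters age,
#' year and birth year as continuous columns; the resulting design is
#' exactly rank deficient and exists to demonstrate the identification
#' problem via [check_identifiability()].
#'
#' @param records classified panel rows carrying the outcome column,
#'   `age_group`, `cohort`, `interview_year`, `person_id`, and (gdp mode)
#'   `gdp_growth`.
#' @param dialect a [survey_dialect()].
#' @param mode `"gdp"` or `"year"`.
#' @param outcome name of the binary outcome column (default
#'   `"dementia_hat"`, the imputed status; simulation studies may fit on
#'   `"true_dementia"`).
#' @param encode `"dummy"` (the model design) or `"continuous"` (diagnostic).
#' @return an object of class `apc_design`: list with `y`, `X`, `cluster`
#'   (person ids), `mode`, `n_obs`, `n_persons`.
#' @export
build_design <- function(records, dialect, mode = c("gdp", "year"),
                         outcome = "dementia_hat",
                         encode = c("dummy", "continuous")) {
  mode <- match.arg(mode)
  encode <- match.arg(encode)
  stopifnot(inherits(dialect, "survey_dialect"))
  if (!outcome %in% names(records)) {
    stop("records lack outcome column '", outcome, "'")
  }
  drop_n <- sum(is.na(records[[outcome]]))
  records <- records[!is.na(records[[outcome]]), , drop = FALSE]
  if (!"age_group" %in% names(records) || !"cohort" %in% names(records)) {
    records <- filter_eligible(records, dialect)
  }
  y <- as.integer(records[[outcome]])
  stopifnot(all(y %in% c(0L, 1L)))

  if (encode == "continuous") {
    X <- cbind(
      `(Intercept)` = 1,
      age = compute_age(records$interview_year, records$birth_year),
      year = records$interview_year,
      cohort = records$birth_year
    )
    if (mode == "gdp") X <- cbind(X, gdp_growth = records$gdp_growth)
  } else {
    X <- matrix(1, nrow(records), 1, dimnames = list(NULL, "(Intercept)"))
    ag_levels <- dialect$age_groups$group
    for (g in ag_levels[-1L]) {
      col <- as.numeric(records$age_group == g)
      if (!any(col == 1)) {
        warning("age group ", g, " has zero observations; dummy dropped")
        next
      }
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("age_", g)
    }
    coh_levels <- dialect$cohort_bins$label
    for (cb in coh_levels[-1L]) {
      col <- as.numeric(records$cohort == cb)
      if (!any(col == 1)) {
        warning("cohort ", cb, " has zero observations; dummy dropped")
        next
      }
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("cohort_", cb)
    }
    if (mode == "gdp") {
      if (!"gdp_growth" %in% names(records)) {
        stop("gdp mode requires a gdp_growth column; see attach_gdp()")
      }
      X <- cbind(X, gdp_growth = records$gdp_growth)
    } else {
      yrs <- sort(unique(records$interview_year))
      for (yr in yrs[-1L]) {
        X <- cbind(X, as.numeric(records$interview_year == yr))
        colnames(X)[ncol(X)] <- paste0("year_", yr)
      }
    }
  }

  structure(
    list(y = y, X = X, cluster = records$person_id, mode = mode,
         outcome = outcome, n_obs = length(y),
         n_persons = length(unique(records$person_id)),
         n_dropped_missing_outcome = drop_n),
    class = "apc_design"
  )
}

#' Diagnose age-period-cohort collinearity in a design
#'
#' Singular-value analysis of the column-standardized design matrix.  The
#' design is flagged rank deficient when the smallest singular value falls
#' below 1e-8 times the largest; the (near-)null combinations are mapped
#' back to the raw column scale and reported with the implicated columns.
#' The canonical failure is the exact identity age - year + birth-year = 0
#' when all three enter as continuous columns, whose null vector is
#' proportional to (1, -1, 1).
#'
#' @param design an `apc_design` or a plain numeric matrix.
#' @return an object of class `collinearity_report`: list with `rank`,
#'   `n_columns`, `deficient`, and `null_space` (list of named normalized
#'   coefficient vectors over the implicated columns).
#' @export
check_identifiability <- function(design) {
  X <- if (inherits(design, "apc_design")) design$X else as.matrix(design)
  p <- ncol(X)
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  const <- sdev == 0
  Xs <- X
  Xs[, !const] <- sweep(sweep(X[, !const, drop = FALSE], 2, mu[!const]),
                        2, sdev[!const], "/")
  Xs[, const] <- sweep(X[, const, drop = FALSE], 2,
                       pmax(abs(mu[const]), 1), "/")
  sv <- svd(Xs)
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  deficient <- rank < p
  null_space <- list()
  if (deficient) {
    scale_back <- ifelse(const, pmax(abs(mu), 1), sdev)
    for (j in (rank + 1L):p) {
      v <- sv$v[, j] / scale_back
      v <- v / max(abs(v))
      names(v) <- colnames(X)
      null_space[[length(null_space) + 1L]] <- v[abs(v) > 1e-6]
    }
  }
  structure(
    list(rank = rank, n_columns = p, deficient = deficient,
         null_space = null_space,
         condition = sv$d[1] / sv$d[length(sv$d)]),
    class = "collinearity_report"
  )
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Design rank ", x$rank, " of ", x$n_columns, " columns",
      if (x$deficient) "  [RANK DEFICIENT]", "\n", sep = "")
  for (v in x$null_space) {
    cat("  null combination: ",
        paste(sprintf("%+.3f*%s", v, names(v)), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Fit the cohort model
#'
#' Binary-outcome regression of dementia status on age group, cohort and the
#' period block.  With `re = "individual_intercept"` (the default) the model
#' is a generalized linear mixed model with a person-level normal random
#' intercept, fitted by maximizing the marginal likelihood with adaptive
#' Gauss-Hermite quadrature (default 9 nodes, configurable); with
#' `re = "none"` it is an ordinary GLM.  In both paths cluster-robust
#' (sandwich) standard errors clustered on person are available and are the
#' default (`se = "cluster"`, the convention of the reported tables);
#' `se = "model"` gives model-based standard errors.  No small-sample
#' cluster adjustment is applied, so with one observation per cluster the
#' clustered covariance coincides with the heteroskedasticity-robust (HC0)
#' one.  95% CIs are estimate +/- 1.96 SE with two-sided normal p-values.
#'
#' @param design an [build_design()] result (must be full rank).
#' @param link `"probit"` (default; coefficients on the latent-normal scale)
#'   or `"logit"`.
#' @param re `"individual_intercept"` or `"none"`.
#' @param nodes quadrature node count (>= 1; default 9).
#' @param se `"cluster"`, `"model"`, or `"none"` (point estimates only;
#'   skips the covariance computation, useful in simulation loops).
#' @param start optional starting values `c(beta, log sigma)` for the
#'   mixed-model path (default: the no-RE GLM fit).
#' @return an object of class `apc_fit`: coefficient table plus
#'   `random_intercept_sd`, `loglik`, `n_obs`, `n_persons`, `link`, `mode`,
#'   `converged`.
#' @export
fit_glmm <- function(design, link = c("probit", "logit"),
                     re = c("individual_intercept", "none"),
                     nodes = 9, se = c("cluster", "model", "none"),
                     start = NULL) {
  link <- match.arg(link)
  re <- match.arg(re)
  se <- match.arg(se)
  stopifnot(inherits(design, "apc_design"))
  ident <- check_identifiability(design)
  if (ident$deficient) {
    stop("design is rank deficient (rank ", ident$rank, " of ",
         ident$n_columns, "); see check_identifiability()")
  }

  if (re == "none") {
    df <- as.data.frame(design$X)
    names(df) <- paste0("V", seq_len(ncol(df)))   # syntactic, remapped below
    df$.y <- design$y
    fit <- stats::glm(.y ~ . - 1, data = df, family = stats::binomial(link = link))
    est <- stats::coef(fit)
    V_model <- stats::vcov(fit)
    V_cluster <- sandwich::vcovCL(fit, cluster = design$cluster,
                                  type = "HC0", cadjust = FALSE)
    names(est) <- colnames(design$X)
    dimnames(V_model) <- dimnames(V_cluster) <- list(names(est), names(est))
    sd_u <- 0
    loglik <- as.numeric(stats::logLik(fit))
    converged <- fit$converged
  } else {
    core <- fit_glmm_core(design$y, design$X, design$cluster, link = link,
                          nodes = nodes, start = start,
                          compute_vcov = se != "none")
    est <- core$coefficients
    pidx <- seq_along(est)
    V_model <- core$vcov_model[pidx, pidx, drop = FALSE]
    V_cluster <- core$vcov_cluster[pidx, pidx, drop = FALSE]
    sd_u <- core$sigma
    loglik <- core$loglik
    converged <- core$converged
  }

  V <- if (se == "cluster") V_cluster else V_model
  se_vec <- suppressWarnings(sqrt(diag(V)))
  lo <- est - 1.96 * se_vec
  hi <- est + 1.96 * se_vec
  pval <- 2 * stats::pnorm(-abs(est / se_vec))

  structure(
    list(
      coefficients = est,
      se = se_vec,
      ci95 = cbind(low = lo, high = hi),
      p_values = pval,
      se_type = se,
      vcov_model = V_model,
      vcov_cluster = V_cluster,
      random_intercept_sd = sd_u,
      loglik = loglik,
      n_obs = design$n_obs,
      n_persons = design$n_persons,
      link = link,
      re = re,
      mode = design$mode,
      nodes = if (re == "none") NA_integer_ else nodes,
      converged = converged
    ),
    class = "apc_fit"
  )
}

#' @export
print.apc_fit <- function(x, ...) {
  cat("Cohort model (", x$link, " link, period = ", x$mode,
      ", RE = ", x$re, ")", if (!x$converged) "  [NOT CONVERGED]", "\n",
      sep = "")
  cat("  n_obs = ", x$n_obs, ", n_persons = ", x$n_persons,
      ", random intercept SD = ", format(x$random_intercept_sd, digits = 4),
      "\n", sep = "")
  stars <- ifelse(x$p_values < 0.01, "**",
                  ifelse(x$p_values < 0.05, "*", ""))
  tab <- data.frame(
    estimate = round(x$coefficients, 4),
    se = round(x$se, 4),
    ci_low = round(x$ci95[, "low"], 4),
    ci_high = round(x$ci95[, "high"], 4),
    p = signif(x$p_values, 3),
    sig = stars
  )
  print(tab)
  cat("  (SEs: ", x$se_type, "; * P<.05, ** P<.01, two-sided)\n", sep = "")
  invisible(x)
}

#' Gender-stratified cohort models
#'
#' Independent fits per gender stratum with identical design construction
#' within stratum.  Rows with missing gender are excluded with a logged
#' count.
#'
#' @param records classified panel rows (see [build_design()]).
#' @param dialect a [survey_dialect()].
#' @param mode,outcome,link,re,nodes,se passed through to [build_design()]
#'   and [fit_glmm()].
#' @return named list of `apc_fit` objects (one per stratum).
#' @export
stratified_fit <- function(records, dialect, mode = c("gdp", "year"),
                           outcome = "dementia_hat",
                           link = c("probit", "logit"),
                           re = c("individual_intercept", "none"),
                           nodes = 9, se = c("cluster", "model", "none")) {
  mode <- match.arg(mode)
  link <- match.arg(link)
  re <- match.arg(re)
  se <- match.arg(se)
  miss <- is.na(records$gender) | !(records$gender %in% c("female", "male"))
  if (any(miss)) {
    message("stratified_fit: excluded ", sum(miss),
            " record(s) with missing gender")
    records <- records[!miss, , drop = FALSE]
  }
  strata <- split(records, records$gender)
  if (length(strata) < 2L) stop("both gender strata must be non-empty")
  lapply(strata, function(r) {
    fit_glmm(build_design(r, dialect, mode = mode, outcome = outcome),
             link = link, re = re, nodes = nodes, se = se)
  })
}

#' Export a fitted cohort model as delimited text
#'
#' @param fit an `apc_fit`.
#' @param path output path (CSV: term, estimate, ci_low, ci_high, p, stars).
#' @export
write_apc_fit <- function(fit, path) {
  stars <- ifelse(fit$p_values < 0.01, "**",
                  ifelse(fit$p_values < 0.05, "*", ""))
  utils::write.csv(
    data.frame(term = names(fit$coefficients),
               estimate = fit$coefficients,
               ci_low = fit$ci95[, "low"],
               ci_high = fit$ci95[, "high"],
               p = fit$p_values,
               stars = stars,
               row.names = NULL),
    path, row.names = FALSE)
  invisible(path)
}
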