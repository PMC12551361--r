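default_feature_lists <- list(
  self = c("age", "female", "education_years", "adl_count", "iadl_count",
           "score_recall", "score_serial7", "score_orientation"),
  proxy = c("age", "female", "education_years", "adl_count", "iadl_count",
            "informant_score")
)

# features that get a between-wave change companion (the cognitive
# instruments; demographics and limitation counts do not)
change_features <- c("score_recall", "score_serial7", "score_orientation",
                     "informant_score")

#' Build classifier feature vectors for one respondent kind
#'
#' Assembles, for every person-wave of the requested kind, the feature vector
#' the imputation models use: demographics (age, gender, education),
#' ADL/IADL limitation counts, and the kind's cognitive instruments (test
#' scores for self-respondents, the informant score for proxy respondents),
#' plus a between-wave change feature for each cognitive instrument (current
#' minus the same person's most recent prior wave of the same kind).  Change
#' features are zero at a person's first observed wave of the kind, with a
#' companion `first_wave` indicator.  Missing feature values are imputed by
#' the within-kind sample mean with a companion `miss_*` indicator (added
#' only for features with any missingness in the sample).
#'
#' The feature list is configuration: surveys lacking an instrument simply
#' omit it from `features`, mirroring how the algorithm is adapted across
#' surveys by dropping variables not collected in all waves.
#'
#' @param records eligible panel data frame (needs `person_id`, `wave`,
#'   `proxy`, `gender`, and the feature columns; `age` is computed from the
#'   year columns if absent).
#' @param kind `"self"` or `"proxy"`.
#' @param features base feature columns; defaults to the kind's standard
#'   list.  Unknown names are a hard error.
#' @return an object of class `feature_set`: list with `kind`, `X` (numeric
#'   matrix), `meta` (data frame `person_id`, `wave`), `feature_names`.
#' @export
build_features <- function(records, kind = c("self", "proxy"),
                           features = NULL) {
  kind <- match.arg(kind)
  features <- features %||% default_feature_lists[[kind]]
  rec <- records
  if (!"age" %in% names(rec)) {
    rec$age <- compute_age(rec$interview_year, rec$birth_year)
  }
  rec$female <- as.numeric(rec$gender == "female")
  unknown <- setdiff(features, names(rec))
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  rec <- rec[order(rec$person_id, rec$wave), , drop = FALSE]
  keep <- if (kind == "proxy") rec$proxy else !rec$proxy
  sub <- rec[keep, , drop = FALSE]
  n <- nrow(sub)

  X <- matrix(NA_real_, n, 0)
  for (f in features) X <- cbind(X, as.numeric(sub[[f]]))
  colnames(X) <- features

  # change features against the most recent prior wave of the same kind
  chg <- intersect(features, change_features)
  prev_idx <- c(NA_integer_, seq_len(max(n - 1L, 0L)))
  same_person <- if (n > 1L) {
    c(FALSE, sub$person_id[-1L] == sub$person_id[-n])
  } else {
    logical(n)
  }
  first_wave <- as.numeric(!same_person)
  for (f in chg) {
    cur <- as.numeric(sub[[f]])
    prev <- rep(NA_real_, n)
    if (n > 1L) prev[same_person] <- cur[prev_idx[same_person]]
    d <- cur - prev
    d[!same_person] <- 0
    X <- cbind(X, d)
    colnames(X)[ncol(X)] <- paste0("chg_", f)
  }
  X <- cbind(X, first_wave = first_wave)

  # mean-impute with missingness indicators
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) {
      m <- mean(X[!miss, j])
      if (!is.finite(m)) m <- 0
      ind <- as.numeric(miss)
      X[miss, j] <- m
      X <- cbind(X, ind)
      colnames(X)[ncol(X)] <- paste0("miss_", colnames(X)[j])
    }
  }

  structure(
    list(kind = kind, X = X,
         meta = data.frame(person_id = sub$person_id, wave = sub$wave,
                           stringsAsFactors = FALSE),
         feature_names = colnames(X)),
    class = "feature_set"
  )
}

match_gold_rows <- function(meta, gold) {
  match(paste(gold$person_id, gold$wave, sep = "\r"),
        paste(meta$person_id, meta$wave, sep = "\r"))
}

#' Calibrate the decision rule and classify dementia status
#'
#' Applies the per-kind ordered-probit models to every person-wave and
#' converts the predicted dementia probability into a binary status.  Under
#' `rule = "argmax"` a person-wave is classified as dementia when
#' `p_dementia` is the largest of the three class probabilities.  Under the
#' default `rule = "cutoff"` a grid of thresholds on `p_dementia` (step
#' 0.005) is scanned and the threshold maximizing binary accuracy on the
#' gold calibration split is chosen, ties broken toward the lower threshold;
#' dementia is assigned when `p_dementia >= cutoff`.
#'
#' @param models named list of [fit_ordered_probit()] fits (`self`, `proxy`).
#' @param features named list of matching [build_features()] sets.
#' @param gold gold-standard labels (calibration split rows are used), as
#'   from [assign_gold_standard()]; required for `rule = "cutoff"`.
#' @param rule `"cutoff"` (default) or `"argmax"`.
#' @return a data frame with `person_id`, `wave`, `kind`, `p_dementia`,
#'   `dementia_hat`, with the chosen `rule` and `cutoff` as attributes.
#' @export
calibrate_and_classify <- function(models, features, gold = NULL,
                                   rule = c("cutoff", "argmax")) {
  rule <- match.arg(rule)
  kinds <- names(features)
  preds <- lapply(kinds, function(kd) {
    fs <- features[[kd]]
    if (is.null(fs) || nrow(fs$X) == 0L) return(NULL)
    pr <- predict_probs(models[[kd]], fs$X)
    data.frame(person_id = fs$meta$person_id, wave = fs$meta$wave,
               kind = kd, p_dementia = pr$p_dementia,
               argmax_dementia = as.integer(
                 pr$p_dementia >= pr$p_cind & pr$p_dementia >= pr$p_normal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, preds)
  if (is.null(out)) {
    out <- data.frame(person_id = character(0), wave = integer(0),
                      kind = character(0), p_dementia = numeric(0),
                      dementia_hat = integer(0))
    attr(out, "rule") <- rule
    return(out)
  }

  cutoff <- NA_real_
  if (rule == "argmax") {
    out$dementia_hat <- out$argmax_dementia
  } else {
    if (is.null(gold)) stop("rule = 'cutoff' requires gold calibration labels")
    cal <- gold[gold$split == "calibration", , drop = FALSE]
    if (!nrow(cal)) stop("gold calibration split is empty")
    idx <- match_gold_rows(out, cal)
    ok <- !is.na(idx)
    p_cal <- out$p_dementia[idx[ok]]
    truth <- as.integer(cal$label[ok] == "dementia")
    grid <- seq(0, 1, by = 0.005)
    acc <- vapply(grid, function(t) mean(as.integer(p_cal >= t) == truth), 0)
    cutoff <- grid[which.max(acc)]   # which.max takes the first (lowest) tie
    out$dementia_hat <- as.integer(out$p_dementia >= cutoff)
  }
  out$argmax_dementia <- NULL
  attr(out, "rule") <- rule
  attr(out, "cutoff") <- cutoff
  out
}

#' Validity of imputed dementia status against the gold standard
#'
#' Validity is the percentage of gold-standard person-waves for whom the
#' predicted binary dementia status equals the clinically adjudicated status,
#' reported to one decimal, with the 2x2 confusion table and a per-kind
#' breakdown.  The validation split must be disjoint from the calibration
#' split used to choose the cutoff; out-of-sample validity is what is
#' reported.
#'
#' @param predicted classification output from [calibrate_and_classify()]
#'   (or any data frame with `person_id`, `wave`, `kind`, `dementia_hat`).
#' @param gold gold-standard labels; rows with `split == "validation"` are
#'   used (all rows if there is no `split` column).
#' @return an object of class `validation_report`: list with `accuracy`
#'   (percent, one decimal), `confusion` (2x2 table), `n`, `by_kind`.
#' @export
compute_validity <- function(predicted, gold) {
  if ("split" %in% names(gold)) {
    gold <- gold[gold$split == "validation", , drop = FALSE]
  }
  if (!nrow(gold)) stop("validation split is empty")
  idx <- match_gold_rows(predicted, gold)
  ok <- !is.na(idx)
  if (!any(ok)) stop("no gold validation rows matched the predictions")
  pred <- predicted$dementia_hat[idx[ok]]
  kind <- predicted$kind[idx[ok]]
  truth <- as.integer(gold$label[ok] == "dementia")
  n <- length(truth)
  agree <- pred == truth
  confusion <- table(
    predicted = factor(pred, levels = c(0, 1), labels = c("no dementia", "dementia")),
    gold = factor(truth, levels = c(0, 1), labels = c("no dementia", "dementia"))
  )
  by_kind <- vapply(split(agree, kind), function(a) {
    round_half_away(100 * mean(a), 1)
  }, 0)
  structure(
    list(
      accuracy = round_half_away(100 * mean(agree), 1),
      confusion = confusion,
      n = n,
      by_kind = by_kind
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validity: ", formatC(x$accuracy, format = "f", digits = 1),
      "% agreement with gold standard (n = ", x$n, ")\n", sep = "")
  if (length(x$by_kind)) {
    for (k in names(x$by_kind)) {
      cat("  ", k, ": ", formatC(x$by_kind[[k]], format = "f", digits = 1),
          "%\n", sep = "")
    }
  }
  print(x$confusion)
  invisible(x)
}

#' End-to-end dementia imputation on an observed panel
#'
#' Convenience wrapper tying the classifier stages together: builds per-kind
#' feature sets, fits the per-kind ordered-probit models on the gold
#' calibration split, classifies every person-wave, and scores out-of-sample
#' validity on the gold validation split.
#'
#' @param records eligible observed panel (see [filter_eligible()] and
#'   [degrade_to_observables()]).
#' @param gold gold-standard labels from [assign_gold_standard()].
#' @param rule decision rule, see [calibrate_and_classify()].
#' @param feature_lists optional named list (`self`, `proxy`) of base feature
#'   columns.
#' @return list with `models`, `predictions` (classified panel rows),
#'   `validity` (a `validation_report`), `cutoff`, `records` (input with
#'   `p_dementia` and `dementia_hat` columns appended).
#' @export
classify_dementia <- function(records, gold, rule = c("cutoff", "argmax"),
                              feature_lists = NULL) {
  rule <- match.arg(rule)
  kinds <- c("self", "proxy")
  features <- list()
  models <- list()
  cal <- gold[gold$split == "calibration", , drop = FALSE]
  for (kd in kinds) {
    fs <- build_features(records, kd, features = feature_lists[[kd]])
    if (!nrow(fs$X)) next
    features[[kd]] <- fs
    idx <- match_gold_rows(fs$meta, cal)
    ok <- !is.na(idx)
    if (sum(ok) < ncol(fs$X) + 5L) {
      stop("too few gold calibration person-waves of kind '", kd,
           "' to fit the model (", sum(ok), " for ", ncol(fs$X),
           " features); increase gold_fraction or the sample size")
    }
    models[[kd]] <- tryCatch(
      fit_ordered_probit(fs$X[idx[ok], , drop = FALSE], cal$label[ok],
                         kind = kd),
      error = function(e) {
        if (!grepl("separation", conditionMessage(e))) stop(e)
        # quasi-separation in a small calibration sample: refit with a weak
        # ridge on the standardized coefficients (documented stabilizer)
        message("classify_dementia: ", kd, " model shows separation; ",
                "refitting with ridge = 1")
        fit_ordered_probit(fs$X[idx[ok], , drop = FALSE], cal$label[ok],
                           kind = kd, ridge = 1)
      })
  }
  predictions <- calibrate_and_classify(models, features, gold, rule = rule)
  validity <- compute_validity(predictions, gold)

  key_p <- paste(predictions$person_id, predictions$wave, sep = "\r")
  key_r <- paste(records$person_id, records$wave, sep = "\r")
  idx <- match(key_r, key_p)
  records$p_dementia <- predictions$p_dementia[idx]
  records$dementia_hat <- predictions$dementia_hat[idx]

  list(models = models, predictions = predictions, validity = validity,
       cutoff = attr(predictions, "cutoff"), records = records)
}
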