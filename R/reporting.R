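#' Percentage with the tables' printing convention
#'
#' `100 * numerator / denominator`, rounded half away from zero to one
#' decimal — the convention under which every printed percentage in the
#' descriptive tables recomputes exactly from its printed counts.
#'
#' @param numerator count, `0 <= numerator <= denominator`.
#' @param denominator positive count.
#' @return the percentage to one decimal.
#' @examples
#' percentage(58883, 99420) # 59.2
#' @export
percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0 | numerator > denominator)) {
    stop("numerator must lie in [0, denominator]")
  }
  round_half_away(100 * numerator / denominator, 1)
}

#' Dementia prevalence by age group and birth cohort
#'
#' The descriptive age x cohort grid behind the prevalence figure: for every
#' non-empty (age group, cohort) cell, the number of person-waves, the
#' number classified as dementia, and the prevalence in percent to one
#' decimal.  Empty cells are absent, not zero.  Margins by age group and by
#' cohort are included.
#'
#' @param records classified panel rows with `age_group`, `cohort` and the
#'   outcome column.
#' @param outcome binary outcome column name (default `"dementia_hat"`).
#' @return an object of class `prevalence_table`: list with `cells` (data
#'   frame `age_group`, `cohort`, `n`, `n_dementia`, `prevalence_pct`) and
#'   `margins` (list of data frames `by_age_group`, `by_cohort`).
#' @export
prevalence_table <- function(records, outcome = "dementia_hat") {
  if (!nrow(records)) {
    return(structure(list(
      cells = data.frame(age_group = integer(0), cohort = character(0),
                         n = integer(0), n_dementia = integer(0),
                         prevalence_pct = numeric(0)),
      margins = list()
    ), class = "prevalence_table"))
  }
  y <- records[[outcome]]
  agg <- function(by) {
    n <- as.data.frame(stats::aggregate(y, by = by, FUN = length))
    d <- as.data.frame(stats::aggregate(y, by = by, FUN = sum))
    out <- n
    names(out)[ncol(out)] <- "n"
    out$n_dementia <- d$x
    out$prevalence_pct <- percentage(out$n_dementia, out$n)
    out
  }
  cells <- agg(list(age_group = records$age_group, cohort = records$cohort))
  cells <- cells[order(cells$age_group, cells$cohort), , drop = FALSE]
  rownames(cells) <- NULL
  structure(
    list(cells = cells,
         margins = list(by_age_group = agg(list(age_group = records$age_group)),
                        by_cohort = agg(list(cohort = records$cohort)))),
    class = "prevalence_table"
  )
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat("Dementia prevalence by age group and cohort (%", ", n cells = ",
      nrow(x$cells), ")\n", sep = "")
  if (nrow(x$cells)) {
    wide <- stats::reshape(
      x$cells[c("age_group", "cohort", "prevalence_pct")],
      idvar = "age_group", timevar = "cohort", direction = "wide")
    names(wide) <- sub("^prevalence_pct\\.", "", names(wide))
    print(wide, row.names = FALSE)
  }
  invisible(x)
}

#' Export / re-read a prevalence table (round-trip exact)
#'
#' @param ptab a `prevalence_table`.
#' @param path output path (CSV of the cells).
#' @export
write_prevalence_table <- function(ptab, path) {
  utils::write.csv(ptab$cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prevalence_table
#' @export
read_prevalence_table <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(cells = cells, margins = list()), class = "prevalence_table")
}

#' Summary statistics table
#'
#' Counts and one-decimal percentages of the survey column total for the
#' gender, age-group and cohort blocks, in the style of a panel survey's
#' descriptive table.  Within each block the counts sum to the survey total.
#'
#' @param records eligible panel rows (with `gender`, `age_group`, `cohort`).
#' @param dialect a [survey_dialect()] (fixes the block level ordering).
#' @return an object of class `summary_table`: data frame with `block`,
#'   `level`, `n`, `pct`, plus the total row count as attribute `"total"`.
#' @export
summary_table <- function(records, dialect) {
  total <- nrow(records)
  one_block <- function(block, values, levels) {
    values <- factor(values, levels = levels)
    tab <- table(values)
    data.frame(block = block, level = names(tab), n = as.integer(tab),
               pct = if (total > 0) percentage(as.integer(tab), total) else
                 rep(NA_real_, length(tab)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one_block("gender", records$gender, c("female", "male")),
    one_block("age_group", records$age_group, dialect$age_groups$group),
    one_block("cohort", records$cohort, dialect$cohort_bins$label)
  )
  structure(out, total = total, class = c("summary_table", "data.frame"))
}

#' @export
print.summary_table <- function(x, ...) {
  cat("Summary statistics (n = ", attr(x, "total"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

fmt_coef_ci <- function(estimate, lo, hi) {
  paste0(fmt_fixed(estimate, 2), " (", fmt_fixed(lo, 2), " to ",
         fmt_fixed(hi, 2), ")")
}

#' Formatted cohort-coefficient table across regions
#'
#' One row per cohort, one column per region: the estimate to two decimals
#' with its 95% CI as "(low to high)", marked `**` when P < .01 and `*` when
#' .01 <= P < .05 (two-sided), plus an observation-count row.  Only cohort
#' terms are shown (age-group and period controls are in the fit objects).
#'
#' @param fits named list (region -> `apc_fit`).  Entries that are not
#'   `apc_fit` objects are omitted with a warning.
#' @return a data frame of formatted strings, cohorts in rows, regions in
#'   columns.
#' @export
coefficient_table <- function(fits) {
  ok <- vapply(fits, inherits, TRUE, what = "apc_fit")
  if (any(!ok)) {
    warning("omitting unfitted region(s): ",
            paste(names(fits)[!ok], collapse = ", "))
    fits <- fits[ok]
  }
  if (!length(fits)) stop("no fitted regions")
  cohort_terms <- unique(unlist(lapply(fits, function(f) {
    grep("^cohort_", names(f$coefficients), value = TRUE)
  })))
  rows <- c(sub("^cohort_", "", cohort_terms), "No. of observations")
  out <- data.frame(cohort = rows, stringsAsFactors = FALSE)
  for (rg in names(fits)) {
    f <- fits[[rg]]
    col <- character(length(rows))
    for (i in seq_along(cohort_terms)) {
      idx <- match(cohort_terms[i], names(f$coefficients))
      if (!is.na(idx)) {
        p <- f$p_values[[idx]]
        star <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
        col[i] <- paste0(
          fmt_coef_ci(f$coefficients[[idx]], f$ci95[idx, "low"],
                      f$ci95[idx, "high"]),
          star)
      } else {
        col[i] <- ""
      }
    }
    col[length(rows)] <- format(f$n_obs)
    out[[rg]] <- col
  }
  out
}

#' Plot prevalence trajectories by cohort
#'
#' Base-graphics line plot of cell prevalence against age group, one line
#' per birth cohort — the standard visual for generational prevalence
#' trends.
#'
#' @param ptab a [prevalence_table()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_prevalence <- function(ptab, ...) {
  cells <- ptab$cells
  if (!nrow(cells)) {
    warning("empty prevalence table; nothing to plot")
    return(invisible(NULL))
  }
  wide <- stats::reshape(cells[c("age_group", "cohort", "prevalence_pct")],
                         idvar = "age_group", timevar = "cohort",
                         direction = "wide")
  wide <- wide[order(wide$age_group), , drop = FALSE]
  m <- as.matrix(wide[, -1, drop = FALSE])
  graphics::matplot(wide$age_group, m, type = "b", pch = 16, lty = 1,
                    xlab = "Age group", ylab = "Dementia prevalence (%)", ...)
  graphics::legend("topleft", legend = sub("^prevalence_pct\\.", "",
                                           colnames(wide)[-1]),
                   col = seq_len(ncol(m)), lty = 1, pch = 16, cex = 0.7,
                   bty = "n")
  invisible(ptab)
}

#' Append lines to a structured run log
#'
#' Line-oriented `key=value` log used by the pipeline wrappers to record
#' seeds, exclusion counts, chosen rules and cutoffs.
#'
#' @param path log file path.
#' @param ... named atomic values.
#' @export
log_run <- function(path, ...) {
  vals <- list(...)
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  lines <- vapply(names(vals), function(k) {
    paste0(stamp, " ", k, "=", paste(vals[[k]], collapse = ","))
  }, "")
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
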