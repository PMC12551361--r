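#' Survey dialects: cohort bins, age groups and eligibility
#'
#' A dialect describes how one harmonized panel survey is mapped onto the
#' common analysis frame: its ordered closed birth-year cohort bins (the first
#' bin is the reference cohort of the regression models), the minimum eligible
#' age (71: respondents older than 70 at interview), and the six five-year
#' age groups 71-75, 76-80, 81-85, 86-90, 91-95 and 96+.
#'
#' The three built-in dialects differ only in their cohort bins.  The HRS
#' (United States) has 8 bins with reference cohort 1890-1913; SHARE (ten
#' pooled European countries) and ELSA (England) each have 7 bins with
#' reference cohorts 1901-1918 and 1908-1918 respectively.  All later bins
#' are the five-year cohorts 1919-1923 through 1944-1948.  Bins are closed on
#' both ends, so 1919-1923 contains both 1919 and 1923.
#'
#' @param name one of `"HRS"`, `"SHARE"`, `"ELSA"`.
#' @return an object of class `survey_dialect`: a list with elements `name`,
#'   `cohort_bins` (data frame with `label`, `start`, `end`), `min_age`,
#'   and `age_groups` (data frame with `group`, `start`, `end`).
#' @examples
#' survey_dialect("HRS")$cohort_bins
#' @export
survey_dialect <- function(name = c("HRS", "SHARE", "ELSA")) {
  name <- match.arg(name)
  first <- switch(name,
    HRS   = c(1890L, 1913L),
    SHARE = c(1901L, 1918L),
    ELSA  = c(1908L, 1918L)
  )
  starts <- seq(1919L, 1944L, by = 5L)
  bins <- data.frame(
    label = c(paste0(first[1], "-", first[2]),
              paste0(starts, "-", starts + 4L)),
    start = c(first[1], starts),
    end   = c(first[2], starts + 4L),
    stringsAsFactors = FALSE
  )
  if (name == "HRS") {
    # HRS additionally splits 1914-1918 out of the reference cohort
    bins <- rbind(
      data.frame(label = "1890-1913", start = 1890L, end = 1913L),
      data.frame(label = "1914-1918", start = 1914L, end = 1918L),
      bins[-1L, ]
    )
  }
  rownames(bins) <- NULL
  new_dialect(name, bins)
}

new_dialect <- function(name, bins) {
  stopifnot(is.data.frame(bins), all(c("label", "start", "end") %in% names(bins)))
  bins <- bins[order(bins$start), , drop = FALSE]
  if (any(bins$end < bins$start)) {
    stop("cohort bins must have start <= end")
  }
  if (nrow(bins) > 1L && any(bins$start[-1L] <= bins$end[-nrow(bins)])) {
    stop("cohort bins must be disjoint and ordered")
  }
  structure(
    list(
      name = name,
      cohort_bins = bins,
      reference_cohort = bins$label[1L],
      min_age = 71L,
      age_groups = data.frame(
        group = 1:6,
        start = c(71L, 76L, 81L, 86L, 91L, 96L),
        end   = c(75L, 80L, 85L, 90L, 95L, NA_integer_)
      )
    ),
    class = "survey_dialect"
  )
}

#' Read a cohort-bin descriptor file as a survey dialect
#'
#' New surveys can be added without code changes by describing their cohort
#' bins in a comma-separated file with a header row and columns `label`,
#' `start`, `end` (closed birth-year intervals, ordered, disjoint).
#'
#' @param path path to the descriptor file.
#' @param name label for the dialect.
#' @return a `survey_dialect` object.
#' @export
read_dialect <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("dialect descriptor not found: ", path)
  bins <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_dialect(name, bins)
}

#' @export
print.survey_dialect <- function(x, ...) {
  cat("Survey dialect:", x$name, "\n")
  cat("  minimum eligible age:", x$min_age, "\n")
  cat("  reference cohort:", x$reference_cohort, "\n")
  cat("  cohort bins:", paste(x$cohort_bins$label, collapse = ", "), "\n")
  invisible(x)
}

#' Age at interview
#'
#' Age is the exact calendar-year difference `interview_year - birth_year`
#' (no birth-month adjustment): the identity age = year - birth year holds at
#' year resolution, which is also what makes simultaneous linear age, period
#' and cohort effects unidentifiable.
#'
#' @param interview_year,birth_year calendar years (vectorized).
#' @return integer ages.
#' @examples
#' compute_age(1994, 1923) # 71
#' @export
compute_age <- function(interview_year, birth_year) {
  age <- as.integer(interview_year) - as.integer(birth_year)
  if (any(age < 0, na.rm = TRUE)) {
    stop("interview_year precedes birth_year for ", sum(age < 0, na.rm = TRUE),
         " record(s)")
  }
  age
}

#' Five-year age groups for respondents older than 70
#'
#' Ages 71-75 map to group 1, 76-80 to 2, 81-85 to 3, 86-90 to 4, 91-95 to 5
#' and 96 or older to group 6.  Ages of 70 or below are ineligible and return
#' `NA`; they are excluded downstream.
#'
#' @param age integer ages (vectorized).
#' @return integer group codes 1-6, or `NA` for ineligible ages.
#' @export
bin_age_group <- function(age) {
  if (any(!is.finite(age) & !is.na(age))) stop("age must be finite")
  ok <- !is.na(age)
  if (any(ok & (age[ok] < 0 | age[ok] != floor(age[ok])))) {
    stop("age must be a non-negative integer")
  }
  g <- rep(NA_integer_, length(age))
  idx <- ok & age >= 71
  g[idx] <- as.integer(pmin((age[idx] - 71) %/% 5 + 1, 6))
  g
}

#' Assign birth years to a dialect's cohort bins
#'
#' @param birth_year birth years (vectorized).
#' @param dialect a [survey_dialect()].
#' @return character cohort labels; `NA` for birth years outside every bin
#'   (excluded downstream with a logged count).
#' @export
bin_cohort <- function(birth_year, dialect) {
  stopifnot(inherits(dialect, "survey_dialect"))
  bins <- dialect$cohort_bins
  out <- rep(NA_character_, length(birth_year))
  for (i in seq_len(nrow(bins))) {
    hit <- !is.na(birth_year) & birth_year >= bins$start[i] & birth_year <= bins$end[i]
    out[hit] <- bins$label[i]
  }
  out
}

panel_columns <- c(
  "person_id", "country", "birth_year", "gender", "education_years",
  "wave", "interview_year", "proxy",
  "score_recall", "score_serial7", "score_orientation",
  "adl_count", "iadl_count", "informant_score"
)

score_ranges <- list(
  score_recall = c(0, 20),      # immediate + delayed word recall
  score_serial7 = c(0, 5),      # serial-7 subtractions
  score_orientation = c(0, 4),  # orientation to date
  informant_score = c(1, 5)     # IQCODE-style informant rating
)

MISSING_SENTINEL <- "."

#' Read and validate a harmonized panel file
#'
#' Panels are comma-separated UTF-8 text with a header row naming every
#' required column (`person_id, country, birth_year, gender, education_years,
#' wave, interview_year, proxy, score_recall, score_serial7,
#' score_orientation, adl_count, iadl_count, informant_score`), one row per
#' person-wave.  Missing values are the explicit sentinel token `"."`, never
#' an empty string.
#'
#' Each row is validated: the interview year may not precede the birth year;
#' proxy person-waves must carry an informant score (and may have missing
#' self-test scores); self-respondent rows must not carry an informant score;
#' gender must be `female` or `male`; counts and scores must lie in their
#' declared ranges.  Rows failing validation are collected into a
#' machine-readable rejection report (row number + reason) rather than
#' silently dropped; more than 50% rejected rows is treated as a corrupt
#' file and raises an error.
#'
#' @param path path to a panel file.
#' @param dialect a [survey_dialect()].
#' @return a list with `records` (validated data frame) and `rejections`
#'   (data frame with `row`, `reason`).
#' @seealso [write_panel()]
#' @export
read_panel <- function(path, dialect) {
  stopifnot(inherits(dialect, "survey_dialect"))
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = MISSING_SENTINEL, colClasses = NA)
  missing_cols <- setdiff(panel_columns, names(raw))
  if (length(missing_cols)) {
    stop("panel file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$proxy <- as.logical(raw$proxy)
  validate_panel(raw)
}

validate_panel <- function(raw) {
  n <- nrow(raw)
  reject <- character(n)
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reject[bad & !nzchar(reject)] <<- why
  }
  if (n) {
    flag(is.na(raw$person_id) | !nzchar(as.character(raw$person_id)),
         "missing person id")
    flag(is.na(raw$birth_year) | is.na(raw$interview_year),
         "missing birth or interview year")
    flag(!is.na(raw$birth_year) & !is.na(raw$interview_year) &
           raw$interview_year < raw$birth_year,
         "interview year precedes birth year")
    flag(!(raw$gender %in% c("female", "male")), "invalid gender")
    flag(is.na(raw$proxy), "missing proxy flag")
    flag(!is.na(raw$proxy) & raw$proxy & is.na(raw$informant_score),
         "proxy without informant score")
    flag(!is.na(raw$proxy) & !raw$proxy & !is.na(raw$informant_score),
         "informant score on self-respondent")
    for (sc in names(score_ranges)) {
      rng <- score_ranges[[sc]]
      flag(!is.na(raw[[sc]]) & (raw[[sc]] < rng[1] | raw[[sc]] > rng[2]),
           paste(sc, "out of range"))
    }
    flag(!is.na(raw$adl_count) & (raw$adl_count < 0 | raw$adl_count > 5),
         "adl_count out of range")
    flag(!is.na(raw$iadl_count) & (raw$iadl_count < 0 | raw$iadl_count > 5),
         "iadl_count out of range")
  }
  bad <- nzchar(reject)
  rejections <- data.frame(row = which(bad), reason = reject[bad],
                           stringsAsFactors = FALSE)
  if (n > 0 && nrow(rejections) > n / 2) {
    stop("more than 50% of rows rejected (", nrow(rejections), " of ", n,
         "); refusing to continue")
  }
  records <- raw[!bad, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, rejections = rejections)
}

#' Write a panel file in the package's dialect
#'
#' @param records a panel data frame.
#' @param path output path.
#' @export
write_panel <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = MISSING_SENTINEL,
                   quote = FALSE)
  invisible(path)
}

#' Read an annual GDP-growth series
#'
#' Comma-separated text with columns `country`, `year`, `growth_pct` (annual
#' real GDP growth in percent).  At most one entry per country-year.
#'
#' @param path path to the series file.
#' @return a data frame of class `gdp_series`.
#' @export
read_gdp_series <- function(path) {
  if (!file.exists(path)) stop("GDP series file not found: ", path)
  g <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = MISSING_SENTINEL)
  need <- c("country", "year", "growth_pct")
  if (!all(need %in% names(g))) {
    stop("GDP series must have columns: ", paste(need, collapse = ", "))
  }
  as_gdp_series(g)
}

as_gdp_series <- function(g) {
  if (anyDuplicated(g[c("country", "year")])) {
    stop("GDP series has duplicate country-year entries")
  }
  class(g) <- c("gdp_series", "data.frame")
  g
}

#' Join the period proxy onto a panel
#'
#' Each person-wave receives the GDP growth rate of its own country in its
#' own interview year (pooled multi-country panels use the per-country value,
#' not a cross-country average).  Coverage must be complete: a missing
#' country-year pair is a hard error naming the uncovered pairs.
#'
#' @param records a panel data frame.
#' @param gdp a GDP series (see [read_gdp_series()] or [simulate_gdp_series()]).
#' @return `records` with a `gdp_growth` column appended.
#' @export
attach_gdp <- function(records, gdp) {
  key_r <- paste(records$country, records$interview_year, sep = "\r")
  key_g <- paste(gdp$country, gdp$year, sep = "\r")
  idx <- match(key_r, key_g)
  if (anyNA(idx)) {
    miss <- unique(records[is.na(idx), c("country", "interview_year")])
    stop("GDP series does not cover: ",
         paste(miss$country, miss$interview_year, sep = ":", collapse = ", "))
  }
  records$gdp_growth <- gdp$growth_pct[idx]
  records
}

#' Restrict a panel to eligible person-waves
#'
#' Keeps person-waves aged 71 or older whose birth year falls in one of the
#' dialect's cohort bins, and appends the derived `age`, `age_group` and
#' `cohort` columns.  Exclusion counts by reason are recorded in the
#' `"exclusions"` attribute and reported via `message()`.
#'
#' @param records a panel data frame.
#' @param dialect a [survey_dialect()].
#' @return the eligible subset with derived columns.
#' @export
filter_eligible <- function(records, dialect) {
  if (!nrow(records)) {
    records$age <- integer(0)
    records$age_group <- integer(0)
    records$cohort <- character(0)
    attr(records, "exclusions") <- c(underage = 0L, out_of_range_cohort = 0L)
    return(records)
  }
  age <- compute_age(records$interview_year, records$birth_year)
  grp <- bin_age_group(age)
  coh <- bin_cohort(records$birth_year, dialect)
  underage <- is.na(grp)
  no_cohort <- !underage & is.na(coh)
  keep <- !underage & !no_cohort
  out <- records[keep, , drop = FALSE]
  out$age <- age[keep]
  out$age_group <- grp[keep]
  out$cohort <- coh[keep]
  rownames(out) <- NULL
  excl <- c(underage = sum(underage), out_of_range_cohort = sum(no_cohort))
  attr(out, "exclusions") <- excl
  if (sum(excl) > 0) {
    message("filter_eligible: excluded ", excl[["underage"]],
            " underage and ", excl[["out_of_range_cohort"]],
            " out-of-range-cohort person-waves")
  }
  out
}
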