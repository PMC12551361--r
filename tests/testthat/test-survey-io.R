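test_that("age is the exact calendar-year difference", {
  expect_identical(compute_age(1994, 1923), 71L)
  expect_identical(compute_age(2004, 1919), 85L)
  expect_identical(compute_age(2000, 2000), 0L)
  expect_error(compute_age(1990, 1995), "precedes")
})

test_that("age groups partition the eligible ages and exclude 70 and below", {
  expect_identical(bin_age_group(71), 1L)
  expect_identical(bin_age_group(70), NA_integer_)
  expect_identical(bin_age_group(103), 6L)
  expect_identical(bin_age_group(c(75, 76, 85, 86, 95, 96)),
                   c(1L, 2L, 3L, 4L, 5L, 6L))
  # partition: every age >= 71 maps to exactly one group
  ages <- 71:130
  groups <- bin_age_group(ages)
  expect_false(anyNA(groups))
  expect_true(all(diff(groups) >= 0))
  expect_error(bin_age_group(-3), "non-negative")
  expect_error(bin_age_group(71.5), "integer")
})

test_that("dialects carry the documented cohort bins", {
  hrs <- survey_dialect("HRS")
  share <- survey_dialect("SHARE")
  elsa <- survey_dialect("ELSA")
  expect_identical(nrow(hrs$cohort_bins), 8L)
  expect_identical(nrow(share$cohort_bins), 7L)
  expect_identical(nrow(elsa$cohort_bins), 7L)
  expect_identical(hrs$reference_cohort, "1890-1913")
  expect_identical(share$reference_cohort, "1901-1918")
  expect_identical(elsa$reference_cohort, "1908-1918")
  expect_identical(utils::tail(hrs$cohort_bins$label, 1), "1944-1948")
})

test_that("cohort binning returns the unique containing bin", {
  hrs <- survey_dialect("HRS")
  share <- survey_dialect("SHARE")
  expect_identical(bin_cohort(1890, hrs), "1890-1913")
  expect_identical(bin_cohort(1918, share), "1901-1918")
  expect_identical(bin_cohort(1950, hrs), NA_character_)
  expect_identical(bin_cohort(1950, share), NA_character_)
  # closed intervals: both endpoints inside
  expect_identical(bin_cohort(1919, hrs), "1919-1923")
  expect_identical(bin_cohort(1923, hrs), "1919-1923")
  # partition over each dialect's covered range
  for (dl in list(hrs, share)) {
    yrs <- dl$cohort_bins$start[1]:utils::tail(dl$cohort_bins$end, 1)
    hits <- bin_cohort(yrs, dl)
    expect_false(anyNA(hits))
  }
})

test_that("age-group x year cells reproduce the five-year cohort diagonal", {
  hrs <- survey_dialect("HRS")
  # in reference year y, age group g (1..5) spans births y-70-5g .. y-66-5g;
  # walking y in 5-year steps shifts each cohort one group down the diagonal
  for (y in seq(1994, 2019, by = 5)) {
    for (g in 1:5) {
      births <- (y - 70 - 5 * g):(y - 66 - 5 * g)
      expect_true(all(bin_age_group(compute_age(y, births)) == g))
      labels <- bin_cohort(births, hrs)
      in_five_year <- births >= 1919 & births <= 1948
      if (any(in_five_year)) {
        expect_identical(unique(labels[in_five_year]),
                         paste0(min(births[in_five_year]), "-",
                                min(births[in_five_year]) + 4))
      }
    }
  }
})

test_that("panel reading validates rows into records plus a rejection report", {
  dl <- survey_dialect("HRS")
  df <- make_panel_df(10)
  # two deliberate defects: informant score on a self-respondent and an
  # interview predating birth
  df$informant_score[3] <- 4.2
  df$interview_year[7] <- 1900L
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(df, path)
  got <- read_panel(path, dl)
  expect_identical(nrow(got$records), 8L)
  expect_identical(got$rejections$row, c(3L, 7L))
  expect_match(got$rejections$reason[1], "informant score on self-respondent")

  # empty data section: no records, no rejections
  empty <- df[0, ]
  write_panel(empty, path)
  got0 <- read_panel(path, dl)
  expect_identical(nrow(got0$records), 0L)
  expect_identical(nrow(got0$rejections), 0L)

  # a mostly-corrupt file is a hard error
  bad <- make_panel_df(10)
  bad$informant_score <- 3  # informant score on every self-respondent
  write_panel(bad, path)
  expect_error(read_panel(path, dl), "50%")
})

test_that("panel write/read round-trips records through the sentinel format", {
  dl <- survey_dialect("HRS")
  df <- make_panel_df(6, proxy = c(rep(FALSE, 4), TRUE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(df, path)
  raw <- readLines(path)
  expect_false(any(grepl(",,", raw)))  # missing is the sentinel, never empty
  got <- read_panel(path, dl)$records
  expect_identical(nrow(got), 6L)
  expect_identical(got$proxy, df$proxy)
  expect_true(all(is.na(got$score_recall[got$proxy])))
  expect_equal(got$informant_score[got$proxy], df$informant_score[df$proxy])
})

test_that("GDP joining is by own country and year, with hard coverage errors", {
  rec <- make_panel_df(6)
  rec$country <- rep(c("USA", "ENG"), 3)
  rec$interview_year <- c(2010L, 2010L, 2012L, 2012L, 2014L, 2014L)
  gdp <- apcdem:::as_gdp_series(data.frame(
    country = rep(c("USA", "ENG"), each = 3),
    year = rep(c(2010L, 2012L, 2014L), 2),
    growth_pct = c(1.1, 2.2, 3.3, -1.1, -2.2, -3.3)
  ))
  got <- attach_gdp(rec, gdp)
  expect_equal(got$gdp_growth, c(1.1, -1.1, 2.2, -2.2, 3.3, -3.3))

  const <- apcdem:::as_gdp_series(data.frame(
    country = "USA", year = c(2010L, 2012L, 2014L), growth_pct = 2.0))
  rec_usa <- rec[rec$country == "USA", ]
  expect_true(all(attach_gdp(rec_usa, const)$gdp_growth == 2.0))

  rec_bad <- rec
  rec_bad$interview_year[1] <- 1999L
  expect_error(attach_gdp(rec_bad, gdp), "USA:1999")
})

test_that("eligibility filtering keeps ages >= 71 in covered cohorts", {
  dl <- survey_dialect("HRS")
  df <- make_panel_df(10)
  df$birth_year <- rep(1935L, 10)
  df$interview_year <- c(rep(2010L, 7), rep(2000L, 3))  # 3 aged 65
  got <- suppressMessages(filter_eligible(df, dl))
  expect_identical(nrow(got), 7L)
  expect_identical(attr(got, "exclusions")[["underage"]], 3L)
  expect_true(all(got$age >= 71))
  expect_true(all(got$age_group == 1L))  # age 75
  expect_true(all(got$cohort == "1934-1938"))

  all_ok <- df[df$interview_year == 2010L, ]
  kept <- filter_eligible(all_ok, dl)
  expect_identical(nrow(kept), nrow(all_ok))

  empty <- filter_eligible(df[0, ], dl)
  expect_identical(nrow(empty), 0L)
})

test_that("a cohort descriptor file defines a usable dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(label = c("1920-1929", "1930-1939"),
                              start = c(1920L, 1930L), end = c(1929L, 1939L)),
                   path, row.names = FALSE)
  dl <- read_dialect(path, name = "custom")
  expect_identical(bin_cohort(1925, dl), "1920-1929")
  expect_identical(dl$reference_cohort, "1920-1929")
  expect_identical(dl$min_age, 71L)
})
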