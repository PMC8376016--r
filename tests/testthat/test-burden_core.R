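lt_std <- load_standard_life_table()

test_that("durations convert to fractional years by 12/52/365", {
  expect_equal(parse_duration(6, "months"), 0.5)
  expect_equal(parse_duration(26, "weeks"), 0.5)
  expect_equal(parse_duration(365, "days"), 1.0)
  expect_equal(parse_duration(2, "years"), 2)
  expect_error(parse_duration(-1, "days"), ">= 0")
  expect_error(parse_duration(1, "continuing"), "unit")
})

test_that("classification follows outcome, duration and care", {
  expect_equal(classify(make_record(outcome = "death_related",
                                    age_at_death = 25)), "death")
  expect_equal(classify(make_record(duration_value = 6,
                                    duration_unit = "months")), "short_term")
  expect_equal(classify(make_record(duration_unit = "continuing",
                                    care = "none")), "permanent_untreated")
  expect_equal(classify(make_record(duration_unit = "continuing")),
               "permanent_treated")
  expect_equal(classify(make_record(duration_value = 2,
                                    duration_unit = "years",
                                    care = "clinic")),
               "long_term_recovered_treated")
  # exactly one year is long-term by the under-one-year rule
  expect_equal(classify(make_record(duration_value = 52,
                                    duration_unit = "weeks", care = "none")),
               "long_term_recovered_untreated")
  expect_equal(classify(make_record(duration_value = 3,
                                    duration_unit = "years",
                                    care = "unknown"),
                        unknown_care = "untreated"),
               "long_term_recovered_untreated")
})

test_that("YLLs arise only from definitive deaths", {
  dead <- make_record(outcome = "death_related", age_at_death = 20,
                      disability_flag = FALSE)
  expect_equal(compute_yll(dead, lt_std), 66.35)
  old <- make_record(outcome = "death_related", age_at_death = 200,
                     disability_flag = FALSE)
  expect_equal(compute_yll(old, lt_std),
               remaining_life_expectancy(200, lt_std))
  expect_error(compute_yll(make_record(), lt_std), "definitive")
  expect_error(
    compute_yll(make_record(outcome = "death_possibly_related"), lt_std),
    "definitive")
  expect_error(compute_yll(make_record(outcome = "death_related"), lt_std),
               "age_at_death")
})

test_that("incidence YLDs: DW times duration, or DW times remaining LE", {
  perm <- make_record(age_at_injury = 20, duration_unit = "continuing")
  expect_equal(compute_yld_incidence(perm, "permanent_treated", 0.2, lt_std),
               0.2 * 66.35)
  expect_equal(compute_yld_incidence(perm, "permanent_treated", 0, lt_std), 0)
  rec <- make_record(duration_value = 2, duration_unit = "years")
  expect_equal(
    compute_yld_incidence(rec, "long_term_recovered_treated", 0.3, lt_std),
    0.6)
  perm$age_at_injury <- NA_real_
  expect_error(compute_yld_incidence(perm, "permanent_treated", 0.2, lt_std),
               "age_at_injury")
})

test_that("prevalence allocation matches the year-by-year oracle and caps at study end", {
  perm <- make_record(age_at_injury = 20, injury_year = 2011L,
                      duration_unit = "continuing")
  # start-of-year convention: 0.2 per whole calendar year
  a0 <- compute_yld_prevalence(perm, "permanent_treated", 0.2, lt_std,
                               study_end = 2014.0, injury_offset = 0)
  expect_equal(sum(a0), 0.6)
  expect_equal(unname(a0), rep(0.2, 3))
  expect_equal(names(a0), c("2011", "2012", "2013"))
  # mid-year default: half a year lived in the injury year
  a5 <- compute_yld_prevalence(perm, "permanent_treated", 0.2, lt_std,
                               study_end = 2014.0)
  expect_equal(sum(a5), 0.5)
  expect_equal(unname(a5[1]), 0.1)
  # study end before the injury -> empty allocation
  expect_length(compute_yld_prevalence(perm, "permanent_treated", 0.2,
                                       lt_std, study_end = 2010.0), 0)
})

test_that("short-term recovery inside the injury year stays in that year", {
  rec <- make_record(injury_year = 2007L, duration_value = 10,
                     duration_unit = "weeks")
  a <- compute_yld_prevalence(rec, "short_term", 0.1, lt_std)
  expect_equal(names(a), "2007")
  expect_equal(sum(a),
               compute_yld_incidence(rec, "short_term", 0.1, lt_std))
})

test_that("unbounded prevalence equals incidence for randomized records", {
  set.seed(404)
  for (k in 1:60) {
    kind <- sample(c("short", "long", "perm"), 1)
    rec <- switch(kind,
      short = make_record(injury_year = sample(2003:2014, 1),
                          duration_value = sample(1:300, 1),
                          duration_unit = sample(c("days", "weeks",
                                                   "months"), 1)),
      long = make_record(injury_year = sample(2003:2014, 1),
                         duration_value = sample(1:40, 1),
                         duration_unit = "years"),
      perm = make_record(injury_year = sample(2003:2014, 1),
                         age_at_injury = sample(0:95, 1),
                         duration_unit = "continuing"))
    pattern <- classify(rec)
    dw <- stats::runif(1)
    off <- stats::runif(1)
    inc <- compute_yld_incidence(rec, pattern, dw, lt_std)
    prev <- compute_yld_prevalence(rec, pattern, dw, lt_std,
                                   study_end = Inf, injury_offset = off)
    expect_equal(sum(prev), inc, tolerance = 1e-9)
  }
})

test_that("YLD is monotone in DW and duration; untreated dominates treated", {
  rec <- make_record(duration_value = 30, duration_unit = "weeks")
  v <- vapply(c(0, 0.1, 0.4, 0.9), function(dw)
    compute_yld_incidence(rec, "short_term", dw, lt_std), numeric(1))
  expect_true(all(diff(v) >= 0))
  d <- vapply(c(1, 5, 20, 52), function(w) {
    r <- rec; r$duration_value <- w
    compute_yld_incidence(r, "short_term", 0.2, lt_std)
  }, numeric(1))
  expect_true(all(diff(d) >= 0))
  # untreated DW >= treated DW implies untreated YLD >= treated YLD
  reg <- tiny_registry()
  long_rec <- make_record(duration_value = 4, duration_unit = "years",
                          dw_code = "lt")
  tr <- match_dw(long_rec, "long_term_recovered_treated", reg)
  un <- match_dw(within(long_rec, care <- "none"),
                 "long_term_recovered_untreated", reg)
  expect_gte(un$mean, tr$mean)
  expect_gte(
    compute_yld_incidence(long_rec, "long_term_recovered_untreated",
                          un$mean, lt_std),
    compute_yld_incidence(long_rec, "long_term_recovered_treated",
                          tr$mean, lt_std))
})

test_that("per-record table: DALY = YLL + YLD exactly, one pathway each", {
  cc <- small_complete_cohort(seed = 31)
  pb <- person_burden(cc$complete, cc$registry, cc$table,
                      study_end = 2014.42)
  expect_equal(pb$daly, pb$yll + pb$yld_incidence)
  expect_true(all(pb$yll == 0 | pb$yld_incidence == 0))
  expect_true(all(pb$pattern %in% c("death", "short_term",
                                    "long_term_recovered_treated",
                                    "long_term_recovered_untreated",
                                    "permanent_treated",
                                    "permanent_untreated")))
  expect_true(all(pb$yld_prevalence <= pb$yld_incidence + 1e-9))
})
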