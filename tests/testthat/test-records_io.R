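test_that("an empty CSV yields an empty list and an all-zero report", {
  path <- write_toy_csv(empty_records())
  rd <- read_records(path)
  expect_equal(nrow(rd$records), 0)
  expect_equal(rd$report$n_total, 0L)
  expect_equal(rd$report$n_complete, 0L)
  expect_equal(rd$report$n_missing_age_or_duration, 0L)
  expect_equal(rd$report$n_missing_dw_info, 0L)
})

test_that("toy CSV: valid rows parse, incomplete rows are itemized", {
  df <- rbind(
    make_record("a", outcome = "death_related", age_at_death = 25,
                disability_flag = FALSE),
    make_record("b", duration_value = 6, duration_unit = "months",
                dw_code = "st"),
    make_record("c", duration_unit = "continuing", dw_code = "lt"),
    # missing both age and duration
    make_record("d", age_at_injury = NA, dw_code = "lt")
  )
  rd <- read_records(write_toy_csv(df))
  expect_equal(nrow(rd$records), 4)
  expect_equal(nrow(rd$complete), 3)
  expect_equal(rd$report$n_missing_age_or_duration, 1L)
  expect_equal(rd$excluded$person_id, "d")
  expect_match(rd$excluded$reason, "missing age/duration")
})

test_that("unknown enum values are per-row exclusions with a reason", {
  df <- rbind(make_record("ok", duration_value = 2, duration_unit = "weeks",
                          dw_code = "st"),
              make_record("bad", duration_value = 2, duration_unit = "weeks",
                          dw_code = "st", mechanism = "trebuchet"),
              make_record("late", duration_value = 2, duration_unit = "weeks",
                          dw_code = "st", injury_year = 2019L))
  rd <- read_records(write_toy_csv(df))
  expect_equal(rd$records$person_id, "ok")
  expect_setequal(rd$excluded$person_id, c("bad", "late"))
  expect_match(rd$excluded$reason[rd$excluded$person_id == "bad"],
               "mechanism")
  expect_match(rd$excluded$reason[rd$excluded$person_id == "late"],
               "study window")
  expect_error(read_records(tempfile()), "not found")
})

test_that("completeness rules follow the burden pathways", {
  reg <- tiny_registry()
  df <- rbind(
    # permanent with age and DW -> retained
    make_record("keep1", duration_unit = "continuing", dw_code = "lt"),
    # recovered with duration absent -> missing age/duration
    make_record("drop1", duration_value = NA, duration_unit = NA,
                dw_code = "lt"),
    # survivor with duration but nothing to pair a DW -> missing DW info
    make_record("drop2", duration_value = 2, duration_unit = "years"),
    # DW code that does not resolve in the registry -> missing DW info
    make_record("drop3", duration_value = 2, duration_unit = "years",
                dw_code = "unregistered"),
    # definitive death without age at death -> missing age/duration
    make_record("drop4", outcome = "death_related", disability_flag = FALSE),
    # non-definitive death goes down the YLD pathway with its duration
    make_record("keep2", outcome = "death_possibly_related",
                duration_value = 4, duration_unit = "months", dw_code = "st")
  )
  flt <- apply_completeness_filter(df, reg)
  expect_setequal(flt$complete$person_id, c("keep1", "keep2"))
  expect_equal(flt$report$n_missing_age_or_duration, 2L)
  expect_equal(flt$report$n_missing_dw_info, 2L)
  expect_setequal(flt$report$excluded_ids,
                  c("drop1", "drop2", "drop3", "drop4"))
})

test_that("reader + filter partition records; counts are order-invariant", {
  sv <- generate_survey(synthetic_survey_config(seed = 5,
                                                n_households = 200))
  reg <- tiny_registry()
  path <- write_toy_csv(sv$records)
  rd <- read_records(path)
  expect_equal(nrow(rd$complete) + nrow(rd$excluded), nrow(sv$records))
  expect_length(intersect(rd$complete$person_id, rd$excluded$person_id), 0)
  # permutation invariance of the report
  shuffled <- sv$records[sample.int(nrow(sv$records)), ]
  rd2 <- read_records(write_toy_csv(shuffled))
  expect_equal(rd2$report$n_complete, rd$report$n_complete)
  expect_equal(rd2$report$n_missing_age_or_duration,
               rd$report$n_missing_age_or_duration)
  expect_equal(rd2$report$n_missing_dw_info, rd$report$n_missing_dw_info)
  expect_setequal(rd2$report$excluded_ids, rd$report$excluded_ids)
})

test_that("a YAML dialect map remaps columns and enum spellings", {
  df <- data.frame(id = c("x1", "x2"), age = c(30, 40),
                   yr = c(2008, 2010), cause = c("GSW", "shelling"),
                   status = c("alive", "alive"), dead_age = c(NA, NA),
                   tx = c("hosp", "none"), disabled = c("yes", "yes"),
                   dur = c(6, 2), dur_u = c("months", "years"),
                   gbd = c("st", "lt"), stringsAsFactors = FALSE)
  csv <- write_toy_csv(df)
  dpath <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    columns = list(person_id = "id", age_at_injury = "age",
                   injury_year = "yr", mechanism = "cause",
                   outcome = "status", age_at_death = "dead_age",
                   care = "tx", disability_flag = "disabled",
                   duration_value = "dur", duration_unit = "dur_u",
                   dw_code = "gbd"),
    values = list(mechanism = list(GSW = "gunshot"),
                  outcome = list(alive = "survived"),
                  care = list(hosp = "hospital"))
  ), dpath)
  rd <- read_records(csv, dialect = read_dialect(dpath))
  expect_equal(rd$records$mechanism, c("gunshot", "shelling"))
  expect_equal(rd$records$care, c("hospital", "none"))
  expect_equal(rd$report$n_complete, 2L)
})

test_that("a continuing disability never carries a finite duration", {
  df <- make_record("p", duration_value = 5, duration_unit = "continuing",
                    dw_code = "lt")
  rd <- read_records(write_toy_csv(df))
  expect_true(is.na(rd$records$duration_value))
  expect_equal(rd$records$duration_unit, "continuing")
})

test_that("burden reports round-trip through JSON and agree with CSV", {
  cc <- small_complete_cohort(seed = 21)
  res <- bootstrap_burden(cc$complete, cc$registry, cc$table,
                          bootstrap_config(n_iterations = 50, seed = 2),
                          study_end = 2014.42,
                          n_persons = cc$survey$n_persons)
  res$by_cause <- cause_specific_burden(
    cc$complete, cc$registry, cc$table,
    bootstrap_config(n_iterations = 50, seed = 2), study_end = 2014.42)
  jpath <- tempfile(fileext = ".json")
  write_report(res, jpath, "json")
  back <- read_report(jpath)
  expect_equal(back$summary, res$summary, tolerance = 1e-12)
  expect_equal(back$by_year, res$by_year, tolerance = 1e-12)
  expect_equal(back$by_cause, res$by_cause, tolerance = 1e-12)
  expect_equal(back$meta$seed, res$meta$seed)
  expect_equal(back$meta$n_iterations, res$meta$n_iterations)
  expect_equal(back$meta$life_table, res$meta$life_table)
  expect_equal(back$meta$study_end, res$meta$study_end)
  # CSV rendering carries the same point estimates
  cpath <- tempfile(fileext = ".csv")
  write_report(res, cpath, "csv")
  csv <- utils::read.csv(cpath, comment.char = "#")
  expect_equal(csv$point, res$summary$point, tolerance = 1e-12)
  expect_equal(csv$quantity, res$summary$quantity)
})

test_that("an empty cohort reports zero totals with flagged intervals", {
  reg <- tiny_registry()
  res <- direct_burden(empty_records(), reg, load_standard_life_table())
  expect_equal(res$summary$point, rep(0, 4))
  expect_true(all(is.na(res$summary$ui_lower)))
  jpath <- tempfile(fileext = ".json")
  write_report(res, jpath, "json")
  back <- read_report(jpath)
  expect_equal(back$summary$point, rep(0, 4))
  expect_error(write_report(res, file.path(tempdir(), "no/such/dir/x.json")),
               "could not write")
})
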