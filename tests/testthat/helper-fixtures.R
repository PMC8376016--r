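# Builders for tiny in-code fixtures shared across test files.

make_record <- function(person_id = "p1", age_at_injury = 30,
                        injury_year = 2008L, mechanism = "gunshot",
                        outcome = "survived", age_at_death = NA_real_,
                        care = "hospital", disability_flag = TRUE,
                        duration_value = NA_real_,
                        duration_unit = NA_character_,
                        dw_code = NA_character_) {
  data.frame(person_id = person_id, age_at_injury = age_at_injury,
             injury_year = as.integer(injury_year), mechanism = mechanism,
             outcome = outcome, age_at_death = age_at_death, care = care,
             disability_flag = disability_flag,
             duration_value = duration_value, duration_unit = duration_unit,
             dw_code = dw_code, stringsAsFactors = FALSE)
}

# registry with one long-term code (treated 0.2 / untreated 0.4) and one
# short-term code (0.1); strictly ordered bounds for beta fitting
tiny_registry <- function() {
  dw_registry(data.frame(
    code = c("lt", "lt", "st"),
    description = "test state",
    variant = c("treated", "untreated", "single"),
    mean = c(0.2, 0.4, 0.1),
    ui_lower = c(0.1, 0.3, 0.05),
    ui_upper = c(0.35, 0.55, 0.2),
    stringsAsFactors = FALSE
  ))
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# standard-survey fixture at reduced size, complete cases ready for burden
small_complete_cohort <- function(seed = 11, n_households = 150,
                                  missingness = 0) {
  cfg <- synthetic_survey_config(seed = seed, n_households = n_households,
                                 missingness = missingness)
  sv <- generate_survey(cfg)
  reg <- generate_draws(load_dw_registry(), n_draws = 200, seed = seed)
  flt <- apply_completeness_filter(sv$records, reg)
  list(survey = sv, registry = reg, complete = flt$complete,
       report = flt$report, table = load_standard_life_table())
}
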