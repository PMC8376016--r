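#' Injury patterns and per-record burden arithmetic
#'
#' Each complete record falls into exactly one of six injury patterns:
#' death; short-term disability (resolved in under a year); long-term
#' disability with recovery, treated or untreated; and permanent disability
#' (still present at survey), treated or untreated. Deaths contribute years
#' of life lost (YLLs): the remaining life expectancy at the age of death.
#' Survivors contribute years lived with disability (YLDs): disability
#' weight times duration, where a permanent disability runs for the full
#' remaining life expectancy at the age of injury. A record contributes to
#' exactly one of YLL or YLD, and DALY = YLL + YLD.
#'
#' @name burden_core
NULL

.patterns <- c("death", "short_term", "long_term_recovered_treated",
               "long_term_recovered_untreated", "permanent_treated",
               "permanent_untreated")

#' Convert a reported disability duration to fractional years
#'
#' Months, weeks and days are divided by 12, 52 and 365 respectively; years
#' pass through.
#'
#' @param value nonnegative duration value.
#' @param unit one of `"years"`, `"months"`, `"weeks"`, `"days"`.
#' @return duration in years.
#' @export
parse_duration <- function(value, unit) {
  if (any(is.na(value)) || any(value < 0)) stop("duration must be >= 0")
  div <- c(years = 1, months = 12, weeks = 52, days = 365)[unit]
  if (any(is.na(div)))
    stop("duration unit must be years/months/weeks/days, not: ",
         paste(unique(unit[is.na(div)]), collapse = ", "))
  unname(value / div)
}

#' Classify a complete record into its injury pattern
#'
#' Definitive deaths map to `death`. A continuing disability is permanent;
#' otherwise the parsed duration splits short-term (< 1 year) from long-term
#' recovered (>= 1 year). Long-term and permanent patterns carry a
#' treated/untreated suffix from care status (any care = treated, none =
#' untreated, unknown per `unknown_care`).
#'
#' @param record one-row record data frame.
#' @param unknown_care routing for unknown care status.
#' @return pattern string.
#' @export
classify <- function(record, unknown_care = c("treated", "untreated")) {
  unknown_care <- match.arg(unknown_care)
  if (record$outcome == "death_related") return("death")
  variant <- care_variant(record$care, unknown_care)
  if (!is.na(record$duration_unit) && record$duration_unit == "continuing")
    return(paste0("permanent_", variant))
  dur <- parse_duration(record$duration_value, record$duration_unit)
  if (dur < 1) "short_term"
  else paste0("long_term_recovered_", variant)
}

#' Years of life lost for a definitive death
#'
#' Only records whose outcome is `death_related` yield YLLs; deaths deemed
#' possibly related or unrelated to the injury are routed to the YLD pathway
#' for their documented disability instead (conservative practice, since
#' YLLs dominate DALY totals).
#'
#' @param record one-row record with outcome `death_related` and
#'   `age_at_death` present.
#' @param table a `life_table`.
#' @return YLL in years: remaining life expectancy at the age of death.
#' @export
compute_yll <- function(record, table) {
  if (record$outcome != "death_related")
    stop("YLLs are computed only for definitive deaths (outcome death_related)")
  if (is.na(record$age_at_death))
    stop("death record lacks age_at_death")
  remaining_life_expectancy(record$age_at_death, table)
}

#' Incidence-based years lived with disability for one record
#'
#' Short-term and recovered long-term disabilities contribute DW times the
#' parsed duration. Permanent disabilities contribute DW times the full
#' remaining life expectancy at the age of injury (such individuals are
#' assumed to live out a normal life span without recovering). The whole
#' amount is attributed to the injury year.
#'
#' @param record one-row record.
#' @param pattern its injury pattern (not `"death"`).
#' @param dw_value disability weight in \[0, 1\].
#' @param table a `life_table` (used for permanent patterns).
#' @return YLD in years.
#' @export
compute_yld_incidence <- function(record, pattern, dw_value, table) {
  stopifnot(pattern %in% .patterns, pattern != "death",
            dw_value >= 0, dw_value <= 1)
  if (startsWith(pattern, "permanent")) {
    if (is.na(record$age_at_injury))
      stop("permanent disability requires age_at_injury")
    dw_value * remaining_life_expectancy(record$age_at_injury, table)
  } else {
    dw_value * parse_duration(record$duration_value, record$duration_unit)
  }
}

# Years lived with the disability inside the study window: overlap of
# [start, start + duration) with (-Inf, study_end), where start is the
# injury year plus injury_offset (mid-year by default) and duration is the
# full remaining LE for permanent patterns.
disability_span <- function(record, pattern, table,
                            injury_offset = 0.5) {
  start <- record$injury_year + injury_offset
  dur <- if (startsWith(pattern, "permanent")) {
    if (is.na(record$age_at_injury))
      stop("permanent disability requires age_at_injury")
    remaining_life_expectancy(record$age_at_injury, table)
  } else {
    parse_duration(record$duration_value, record$duration_unit)
  }
  c(start = start, end = start + dur)
}

#' Prevalence-based YLD allocation across calendar years
#'
#' Allocates `dw_value` per person-year actually lived with the disability
#' to each calendar year between the injury and the earlier of recovery or
#' `study_end`, with fractional first and last years. The injury is placed
#' at `injury_year + injury_offset` (mid-year by default, the standard
#' demographic convention when no finer date exists). Over an unbounded
#' horizon (`study_end = Inf`) the allocation sums exactly to the
#' incidence-based YLD.
#'
#' @inheritParams compute_yld_incidence
#' @param study_end decimal calendar year ending the observation window
#'   (e.g. `2014.42` for 1 June 2014); `Inf` for an unbounded horizon.
#' @param injury_offset fraction of the injury year elapsed at injury
#'   (default 0.5).
#' @return named numeric vector: calendar year -> years lived with
#'   disability times DW. Empty when `study_end` precedes the injury.
#' @export
compute_yld_prevalence <- function(record, pattern, dw_value,
                                   table, study_end = Inf,
                                   injury_offset = 0.5) {
  stopifnot(pattern %in% .patterns, pattern != "death",
            dw_value >= 0, dw_value <= 1)
  span <- disability_span(record, pattern, table, injury_offset)
  start <- span[["start"]]
  end <- min(span[["end"]], study_end)
  if (end <= start) return(stats::setNames(numeric(0), character(0)))
  years <- seq.int(floor(start), ceiling(end) - 1L)
  lived <- pmin(end, years + 1) - pmax(start, years)
  keep <- lived > 0
  stats::setNames(dw_value * lived[keep], years[keep])
}

# Per-record burden table used by the direct pass and the bootstrap.
# Columns: pattern, yll, yld_base (duration or remaining LE multiplying the
# DW), prev_base (study-window-capped lived years), dw_index / dw_mean.
prepare_burden <- function(records, registry, table, study_end = Inf,
                           unknown_care = "treated", injury_offset = 0.5) {
  n <- nrow(records)
  pattern <- character(n)
  yll <- numeric(n); yld_base <- numeric(n); prev_base <- numeric(n)
  dw_index <- rep(NA_integer_, n); dw_mean <- numeric(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    p <- classify(r, unknown_care)
    pattern[i] <- p
    if (p == "death") {
      yll[i] <- compute_yll(r, table)
      next
    }
    m <- match_dw(r, p, registry, unknown_care)
    if (is.na(m$index))
      stop("record ", r$person_id, " has no resolvable DW entry; ",
           "run apply_completeness_filter() with the registry first")
    dw_index[i] <- m$index
    dw_mean[i] <- m$mean
    yld_base[i] <- compute_yld_incidence(r, p, 1, table)
    span <- disability_span(r, p, table, injury_offset)
    prev_base[i] <- max(0, min(span[["end"]], study_end) - span[["start"]])
  }
  data.frame(person_id = records$person_id, mechanism = records$mechanism,
             injury_year = records$injury_year, pattern = pattern,
             yll = yll, yld_base = yld_base, prev_base = prev_base,
             dw_index = dw_index, dw_mean = dw_mean,
             stringsAsFactors = FALSE)
}

#' Per-record burden at DW point estimates
#'
#' A single deterministic pass: each complete record's YLL, incidence YLD
#' and study-window prevalence YLD at the mean disability weights.
#'
#' @param records complete record frame (see [apply_completeness_filter()]).
#' @param registry a `dw_registry`.
#' @param table a `life_table`.
#' @param study_end decimal year capping prevalence YLDs (default
#'   `Inf` = unbounded).
#' @param unknown_care routing for unknown care status.
#' @param injury_offset within-year timing of the injury (default mid-year).
#' @return data frame with one row per record: `person_id`, `mechanism`,
#'   `injury_year`, `pattern`, `yll`, `yld_incidence`, `yld_prevalence`,
#'   `daly`.
#' @export
person_burden <- function(records, registry, table, study_end = Inf,
                          unknown_care = c("treated", "untreated"),
                          injury_offset = 0.5) {
  unknown_care <- match.arg(unknown_care)
  prep <- prepare_burden(records, registry, table, study_end, unknown_care,
                         injury_offset)
  out <- prep[c("person_id", "mechanism", "injury_year", "pattern", "yll")]
  out$yld_incidence <- prep$dw_mean * prep$yld_base
  out$yld_prevalence <- prep$dw_mean * prep$prev_base
  out$daly <- out$yll + out$yld_incidence
  out
}
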