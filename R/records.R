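#' Injury-record data model and survey-CSV reader
#'
#' One record describes one surveyed person-injury: demographics, mechanism,
#' outcome, care received, duration of any disability, and a
#' disability-weight code. Records are held in an ordinary data frame with a
#' fixed column inventory; [read_records()] parses a survey CSV into that
#' shape through a configurable dialect map, and
#' [apply_completeness_filter()] partitions records into those usable for
#' burden computation and itemized exclusions.
#'
#' @name records
NULL

#' Enumerations of the injury-record data model
#'
#' @return Character vectors of allowed values.
#' @export
injury_mechanisms <- function() {
  c("gunshot", "shelling", "blast_explosion", "stabbing", "burn",
    "torture", "other")
}

#' @rdname injury_mechanisms
#' @export
injury_outcomes <- function() {
  c("death_related", "death_possibly_related", "death_unrelated", "survived")
}

#' @rdname injury_mechanisms
#' @export
care_levels <- function() {
  c("hospital", "clinic", "workplace", "none", "unknown")
}

#' @rdname injury_mechanisms
#' @export
duration_units <- function() {
  c("years", "months", "weeks", "days", "continuing")
}

.record_cols <- c("person_id", "age_at_injury", "injury_year", "mechanism",
                  "outcome", "age_at_death", "care", "disability_flag",
                  "duration_value", "duration_unit", "dw_code")

#' Empty, correctly-typed injury-record frame
#'
#' @return zero-row data frame with the canonical record columns.
#' @export
empty_records <- function() {
  data.frame(person_id = character(0), age_at_injury = numeric(0),
             injury_year = integer(0), mechanism = character(0),
             outcome = character(0), age_at_death = numeric(0),
             care = character(0), disability_flag = logical(0),
             duration_value = numeric(0), duration_unit = character(0),
             dw_code = character(0), stringsAsFactors = FALSE)
}

#' Default CSV dialect map
#'
#' A dialect maps the package's internal column names to the CSV header
#' names, and optionally remaps enum spellings
#' (`values$<field>$<csv value> = <internal value>`). Survey datasets vary;
#' editing a YAML dialect file (see [read_dialect()]) adapts the reader
#' without code changes.
#'
#' @return A dialect list with elements `columns` and `values`.
#' @export
default_dialect <- function() {
  list(
    columns = stats::setNames(as.list(.record_cols), .record_cols),
    values = list()
  )
}

#' Read a dialect map from a YAML file
#'
#' @param path YAML file with top-level keys `columns` (internal name ->
#'   CSV header) and optionally `values` (field -> CSV value -> internal
#'   value).
#' @return A dialect list; unspecified columns fall back to the default map.
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) stop("dialect file not found: ", path)
  d <- yaml::read_yaml(path)
  base <- default_dialect()
  if (!is.null(d$columns)) base$columns[names(d$columns)] <- d$columns
  if (!is.null(d$values)) base$values <- d$values
  base
}

# Map raw CSV values of an enum field through the dialect, returning internal
# values; unknown values come back unchanged for the validator to reject.
map_enum <- function(x, field, dialect) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  vm <- dialect$values[[field]]
  if (!is.null(vm)) {
    hit <- match(x, names(vm))
    x[!is.na(hit)] <- unlist(vm)[hit[!is.na(hit)]]
  }
  x
}

as_num <- function(x) suppressWarnings(as.numeric(x))

#' Read and validate injury records from a survey CSV
#'
#' Every CSV row either becomes a validated record or an itemized exclusion
#' with a reason; nothing is silently dropped. Parse-level exclusions
#' (unknown enum values, years outside the study window, negative ages)
#' are distinct from the downstream completeness filter, which the returned
#' report summarises (see [apply_completeness_filter()]).
#'
#' @param path CSV file (comma-separated, UTF-8, header row).
#' @param dialect dialect map (see [default_dialect()], [read_dialect()]).
#' @param study_window two integers, first and last admissible injury year
#'   (default 2003--2014).
#' @param registry optional `dw_registry`; when supplied, completeness
#'   additionally requires that the record's DW code resolves in it.
#' @param unknown_care how unknown care status is routed when matching DWs.
#' @return list with `records` (all parse-valid records), `complete`,
#'   `excluded` (records + `reason` column, covering both parse and
#'   completeness exclusions), and `report` (a `completeness_report`).
#' @export
read_records <- function(path, dialect = default_dialect(),
                         study_window = c(2003L, 2014L),
                         registry = NULL,
                         unknown_care = c("treated", "untreated")) {
  unknown_care <- match.arg(unknown_care)
  if (!file.exists(path)) stop("records file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character"),
    error = function(e) stop("unparseable records file: ", conditionMessage(e))
  )
  cols <- dialect$columns
  get_col <- function(internal) {
    nm <- cols[[internal]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]]
    else rep(NA_character_, nrow(raw))
  }
  n <- nrow(raw)
  if (n == 0L) {
    rec <- empty_records()
    flt <- apply_completeness_filter(rec, registry, unknown_care)
    return(list(records = rec, complete = flt$complete,
                excluded = flt$excluded, report = flt$report))
  }

  pid <- get_col("person_id")
  pid[is.na(pid) | pid == ""] <- paste0("row", which(is.na(pid) | pid == ""))
  df <- data.frame(
    person_id = pid,
    age_at_injury = as_num(get_col("age_at_injury")),
    injury_year = as_num(get_col("injury_year")),
    mechanism = map_enum(get_col("mechanism"), "mechanism", dialect),
    outcome = map_enum(get_col("outcome"), "outcome", dialect),
    age_at_death = as_num(get_col("age_at_death")),
    care = map_enum(get_col("care"), "care", dialect),
    disability_flag = tolower(trimws(get_col("disability_flag"))) %in%
      c("true", "t", "yes", "y", "1"),
    duration_value = as_num(get_col("duration_value")),
    duration_unit = map_enum(get_col("duration_unit"), "duration_unit",
                             dialect),
    dw_code = {
      x <- trimws(get_col("dw_code")); x[x == ""] <- NA_character_; x
    },
    stringsAsFactors = FALSE
  )
  # absent disability column: assume survivors in scope carry disability
  if (is.null(cols$disability_flag) ||
      !(cols$disability_flag %in% names(raw)))
    df$disability_flag <- df$outcome == "survived" | startsWith(
      ifelse(is.na(df$outcome), "", df$outcome), "death_")
  # missing mechanism is tolerated as 'other'; unknown spellings are rejected
  df$mechanism[is.na(df$mechanism)] <- "other"
  df$care[is.na(df$care)] <- "unknown"

  reason <- rep(NA_character_, n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(!df$mechanism %in% injury_mechanisms(),
       "unknown mechanism value")
  flag(is.na(df$outcome) | !df$outcome %in% injury_outcomes(),
       "missing or unknown outcome value")
  flag(!df$care %in% care_levels(), "unknown care value")
  flag(!is.na(df$duration_unit) & !df$duration_unit %in% duration_units(),
       "unknown duration unit")
  flag(is.na(df$injury_year) | df$injury_year < study_window[1] |
         df$injury_year > study_window[2],
       "injury year missing or outside study window")
  flag(!is.na(df$age_at_injury) & df$age_at_injury < 0, "negative age")
  flag(!is.na(df$duration_value) & df$duration_value < 0,
       "negative duration")
  flag(df$outcome == "survived" & !df$disability_flag,
       "survivor without reported disability (no burden pathway)")
  # invariant: a continuing disability has no finite duration value
  cont <- !is.na(df$duration_unit) & df$duration_unit == "continuing"
  df$duration_value[cont] <- NA_real_
  df$injury_year <- as.integer(round(df$injury_year))

  parse_excluded <- df[!is.na(reason), , drop = FALSE]
  if (nrow(parse_excluded)) parse_excluded$reason <- reason[!is.na(reason)]
  else parse_excluded$reason <- character(0)
  records <- df[is.na(reason), , drop = FALSE]
  rownames(records) <- NULL

  flt <- apply_completeness_filter(records, registry, unknown_care)
  excluded <- rbind(parse_excluded, flt$excluded)
  rownames(excluded) <- NULL
  list(records = records, complete = flt$complete, excluded = excluded,
       report = flt$report)
}

#' Partition records into complete cases and itemized exclusions
#'
#' A record can enter the burden computation when it carries everything its
#' pathway needs: a definitive death needs the age at death; a continuing
#' (permanent) disability needs the age at injury; a recovered disability
#' needs its duration; and every non-death record needs enough information to
#' pair a disability weight (a DW code, resolvable in `registry` when one is
#' given). Exclusions are itemized with reasons, mirroring how incomplete
#' survey cases are dropped before bootstrapping.
#'
#' @inheritParams read_records
#' @param records validated record frame.
#' @return list with `complete`, `excluded` (with `reason`), and `report`.
#' @export
apply_completeness_filter <- function(records, registry = NULL,
                                      unknown_care = c("treated",
                                                       "untreated")) {
  unknown_care <- match.arg(unknown_care)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (r$outcome == "death_related") {
      if (is.na(r$age_at_death)) reason[i] <- "missing age/duration"
      next
    }
    # non-definitive deaths and survivors go down the YLD pathway
    permanent <- !is.na(r$duration_unit) && r$duration_unit == "continuing"
    if (permanent) {
      if (is.na(r$age_at_injury)) { reason[i] <- "missing age/duration"; next }
    } else {
      if (is.na(r$duration_value) || is.na(r$duration_unit)) {
        reason[i] <- "missing age/duration"; next
      }
    }
    if (is.na(r$dw_code)) { reason[i] <- "missing DW info"; next }
    if (!is.null(registry)) {
      pat <- classify(r, unknown_care)
      m <- match_dw(r, pat, registry, unknown_care)
      if (is.na(m$index)) reason[i] <- "missing DW info"
    }
  }
  complete <- records[is.na(reason), , drop = FALSE]
  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!is.na(reason)]
  else excluded$reason <- character(0)
  rownames(complete) <- NULL
  rownames(excluded) <- NULL
  report <- completeness_report(
    n_total = n,
    n_complete = nrow(complete),
    n_missing_age_or_duration = sum(excluded$reason == "missing age/duration"),
    n_missing_dw_info = sum(excluded$reason == "missing DW info"),
    excluded_ids = excluded$person_id
  )
  list(complete = complete, excluded = excluded, report = report)
}

#' Completeness report
#'
#' @param n_total,n_complete,n_missing_age_or_duration,n_missing_dw_info
#'   counts; the three parts must sum to `n_total`.
#' @param excluded_ids identifiers of excluded records.
#' @return object of class `completeness_report`.
#' @export
completeness_report <- function(n_total, n_complete,
                                n_missing_age_or_duration,
                                n_missing_dw_info, excluded_ids = character(0)) {
  if (n_total != n_complete + n_missing_age_or_duration + n_missing_dw_info)
    stop("completeness counts do not partition n_total")
  structure(
    list(n_total = as.integer(n_total), n_complete = as.integer(n_complete),
         n_missing_age_or_duration = as.integer(n_missing_age_or_duration),
         n_missing_dw_info = as.integer(n_missing_dw_info),
         excluded_ids = as.character(excluded_ids)),
    class = "completeness_report"
  )
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf(paste0("<completeness_report: %d records, %d complete, ",
                     "%d missing age/duration, %d missing DW info>\n"),
              x$n_total, x$n_complete, x$n_missing_age_or_duration,
              x$n_missing_dw_info))
  invisible(x)
}
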