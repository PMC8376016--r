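#' Life tables: remaining life expectancy by age
#'
#' A life table here is a lookup from exact age to remaining life expectancy
#' (both in years). Years of life lost (YLLs) for a death at age `a` are the
#' remaining life expectancy at `a`, so the choice of table is the choice of
#' how a death is valued. Two tables are supported out of the box: the
#' standard (aspirational) reference table bundled with the package, and a
#' flat country-specific table in which remaining life expectancy is simply
#' life expectancy at birth minus current age.
#'
#' @name life_tables
NULL

#' Construct a life table
#'
#' @param age numeric vector of exact ages in years; strictly increasing,
#'   starting at 0.
#' @param remaining_le numeric vector of remaining life expectancies at those
#'   ages, in years; all nonnegative. `age + remaining_le` must be
#'   non-decreasing (total-longevity consistency); remaining LE itself is not
#'   required to be monotone, so infant-mortality artifacts are allowed.
#' @param name label for the table.
#' @return An object of class `life_table`.
#' @export
life_table <- function(age, remaining_le, name = "custom") {
  if (!is.numeric(age) || !is.numeric(remaining_le))
    stop("age and remaining_le must be numeric")
  if (length(age) != length(remaining_le) || length(age) < 1L)
    stop("age and remaining_le must have equal, positive length")
  if (anyNA(age) || anyNA(remaining_le))
    stop("life table entries must not contain NA")
  if (age[1] != 0)
    stop("life table must start at age 0")
  if (any(diff(age) <= 0))
    stop("life table ages must be strictly increasing")
  if (any(remaining_le < 0))
    stop("remaining life expectancy must be nonnegative")
  total <- age + remaining_le
  if (any(diff(total) < -1e-9))
    stop("age + remaining_le must be non-decreasing (incoherent life table)")
  structure(
    list(name = as.character(name)[1], age = as.numeric(age),
         remaining_le = as.numeric(remaining_le)),
    class = "life_table"
  )
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table '%s': %d knots, ages %g-%g, LE at birth %.2f>\n",
              x$name, length(x$age), min(x$age), max(x$age),
              x$remaining_le[1]))
  invisible(x)
}

#' Load the bundled standard reference life table
#'
#' The standard (aspirational) table values every death identically
#' regardless of country: it is built from the lowest observed age-specific
#' death rates among countries of more than 5 million population. The bundled
#' 2010/2013-era reference has a life expectancy at birth of 86.02 years and
#' a remaining life expectancy at age 20 of 66.35 years.
#'
#' @return A `life_table`.
#' @export
#' @examples
#' lt <- load_standard_life_table()
#' remaining_life_expectancy(20, lt) # about 67 years
load_standard_life_table <- function() {
  path <- system.file("extdata", "gbd_standard_life_table.csv",
                      package = "injuryburden")
  if (!nzchar(path) || !file.exists(path))
    stop("bundled standard life table resource is missing")
  read_life_table(path, name = "standard")
}

#' Read a life table from a two-column CSV
#'
#' @param path CSV with header columns `age` and `remaining_le`; lines
#'   starting with `#` are comments.
#' @param name label for the table (default: file name).
#' @return A `life_table`.
#' @export
read_life_table <- function(path, name = NULL) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("age", "remaining_le") %in% names(df)))
    stop("life table CSV must have columns 'age' and 'remaining_le'")
  if (is.null(name)) name <- basename(path)
  life_table(df$age, df$remaining_le, name = name)
}

#' Flat country-specific life table
#'
#' Remaining life expectancy is `max(0, le_at_birth - age)`: every person is
#' assumed to live to exactly `le_at_birth`. Used for country-specific
#' sensitivity analyses when only life expectancy at birth is available
#' (e.g. 69.4 years for Iraq in 2013).
#'
#' @param le_at_birth life expectancy at birth in years; must be positive.
#' @return A `life_table` with knots at ages 0 and `le_at_birth`.
#' @export
make_flat_life_table <- function(le_at_birth) {
  if (!is.numeric(le_at_birth) || length(le_at_birth) != 1L ||
      is.na(le_at_birth) || le_at_birth <= 0)
    stop("le_at_birth must be a single positive number")
  life_table(c(0, le_at_birth), c(le_at_birth, 0),
             name = sprintf("flat:%g", le_at_birth))
}

#' Remaining life expectancy at an exact age
#'
#' Linear interpolation between bracketing knots; beyond the last tabulated
#' age the final entry's value is carried forward (never below zero).
#'
#' @param age numeric vector of nonnegative ages in years.
#' @param table a `life_table`.
#' @return numeric vector of remaining life expectancies in years.
#' @export
remaining_life_expectancy <- function(age, table) {
  stopifnot(inherits(table, "life_table"))
  if (!is.numeric(age) || anyNA(age)) stop("age must be numeric and non-NA")
  if (any(age < 0)) stop("age must be nonnegative")
  out <- stats::approx(table$age, table$remaining_le, xout = age,
                       method = "linear", rule = 2)$y
  pmax(out, 0)
}
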