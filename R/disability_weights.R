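#' Disability-weight registry with draw-level uncertainty
#'
#' Disability weights (DWs) are severity factors on \[0, 1\] (0 = full
#' health, 1 = equivalent to death) published with a mean and a 95%
#' uncertainty interval. Long-term-capable health states carry `treated` and
#' `untreated` variants; short-term states carry a `single` variant.
#' Uncertainty is propagated by attaching to each entry a vector of draws
#' from a beta distribution fitted to the published mean and interval.
#'
#' @name disability_weights
NULL

.dw_variants <- c("treated", "untreated", "single")

#' Load a disability-weight registry
#'
#' With `path = NULL`, loads the small synthetic starter registry bundled
#' with the package: illustrative injury weights covering all six injury
#' patterns (three short-term states plus five long-term states, each with
#' treated and untreated variants). For real analyses, supply the published
#' DW appendix as a CSV with columns `code, description, variant, mean,
#' ui_lower, ui_upper`.
#'
#' @param path CSV path, or `NULL` for the bundled starter registry.
#' @return A `dw_registry`: entries validated, draws not yet generated
#'   (see [generate_draws()]).
#' @export
load_dw_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dw_registry_starter.csv",
                        package = "injuryburden")
    if (!nzchar(path)) stop("bundled starter DW registry is missing")
  }
  if (!file.exists(path)) stop("DW registry file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("code", "variant", "mean", "ui_lower", "ui_upper")
  if (!all(need %in% names(df)))
    stop("DW registry CSV must have columns: ",
         paste(c(need, "description"), collapse = ", "))
  if (!"description" %in% names(df)) df$description <- ""
  dw_registry(df)
}

#' Construct a DW registry from a data frame
#'
#' @param entries data frame with columns `code`, `description`, `variant`,
#'   `mean`, `ui_lower`, `ui_upper`.
#' @return A `dw_registry` object.
#' @export
dw_registry <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  entries$variant <- as.character(entries$variant)
  bad_var <- setdiff(unique(entries$variant), .dw_variants)
  if (length(bad_var))
    stop("unknown DW variant(s): ", paste(bad_var, collapse = ", "))
  for (col in c("mean", "ui_lower", "ui_upper")) {
    v <- entries[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1))
      stop("DW column '", col, "' must lie in [0, 1]")
  }
  bad <- entries$ui_lower > entries$mean | entries$mean > entries$ui_upper
  if (any(bad))
    stop("DW ordering ui_lower <= mean <= ui_upper violated for code(s): ",
         paste(unique(entries$code[bad]), collapse = ", "))
  key <- paste(entries$code, entries$variant, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (code, variant) pairs in DW registry")
  structure(
    list(entries = entries, key = key, draws = NULL,
         n_draws = 0L, seed = NA_integer_),
    class = "dw_registry"
  )
}

#' @export
print.dw_registry <- function(x, ...) {
  cat(sprintf("<dw_registry: %d entries, %d codes, draws: %s>\n",
              nrow(x$entries), length(unique(x$entries$code)),
              if (is.null(x$draws)) "none" else
                sprintf("%d per entry (seed %d)", x$n_draws, x$seed)))
  invisible(x)
}

#' Fit a beta distribution to a mean and 95% interval
#'
#' The concentration `c` of a Beta(mean * c, (1 - mean) * c) distribution is
#' chosen to minimise the squared error of the 2.5th and 97.5th percentiles
#' against `(lower, upper)`; the analytic mean therefore matches the target
#' mean exactly for any concentration. Degenerate inputs
#' (`lower == mean == upper`, or mean at 0 or 1) yield a point mass.
#'
#' @param mean,lower,upper target mean and 95% bounds, all in \[0, 1\] with
#'   `lower <= mean <= upper`.
#' @return list with `shape1`, `shape2` (NA for a point mass), `mean`, and
#'   `degenerate` flag.
#' @export
fit_beta_dw <- function(mean, lower, upper) {
  stopifnot(lower <= mean, mean <= upper, lower >= 0, upper <= 1)
  if (lower == upper || mean <= 0 || mean >= 1) {
    return(list(shape1 = NA_real_, shape2 = NA_real_, mean = mean,
                degenerate = TRUE))
  }
  obj <- function(logc) {
    cc <- exp(logc)
    q <- stats::qbeta(c(0.025, 0.975), mean * cc, (1 - mean) * cc)
    (q[1] - lower)^2 + (q[2] - upper)^2
  }
  opt <- stats::optimize(obj, interval = c(log(1e-2), log(1e6)))
  cc <- exp(opt$minimum)
  list(shape1 = mean * cc, shape2 = (1 - mean) * cc, mean = mean,
       degenerate = FALSE)
}

#' Generate uncertainty draws for every registry entry
#'
#' Each entry receives `n_draws` samples from its fitted beta distribution.
#' Entries are sampled from independent sub-seeds derived from `seed`, so the
#' draw matrix is reproducible and entry draws are mutually independent.
#'
#' @param registry a `dw_registry`.
#' @param n_draws draws per entry (default 1000).
#' @param seed integer seed.
#' @return The registry with a `draws` matrix (entries x draws) attached.
#' @export
generate_draws <- function(registry, n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(registry, "dw_registry"))
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) stop("n_draws must be >= 1")
  e <- registry$entries
  draws <- matrix(NA_real_, nrow = nrow(e), ncol = n_draws)
  for (i in seq_len(nrow(e))) {
    fit <- fit_beta_dw(e$mean[i], e$ui_lower[i], e$ui_upper[i])
    if (fit$degenerate) {
      draws[i, ] <- e$mean[i]
    } else {
      set.seed((as.integer(seed) + 7919L * i) %% .Machine$integer.max)
      draws[i, ] <- stats::rbeta(n_draws, fit$shape1, fit$shape2)
    }
  }
  registry$draws <- draws
  registry$n_draws <- n_draws
  registry$seed <- as.integer(seed)
  registry
}

# Row index of (code, variant) in the registry, or NA if absent.
dw_index <- function(registry, code, variant) {
  match(paste(code, variant, sep = "|"), registry$key)
}

#' Match a record to its disability-weight entry
#'
#' Long-term and permanent patterns resolve to the `treated` or `untreated`
#' variant of the record's DW code according to care received: any post-injury
#' care (hospital, clinic, workplace) counts as treated, `none` as untreated,
#' and `unknown` follows `unknown_care` (default treated). Short-term
#' patterns resolve to the `single` variant, falling back to the care-based
#' variant if no single-variant entry exists for the code.
#'
#' @param record one-row data frame (an injury record; see [read_records()]).
#' @param pattern injury pattern string from [classify()]; must not be
#'   `"death"`.
#' @param registry a `dw_registry`.
#' @param unknown_care `"treated"` or `"untreated"`: how to treat unknown
#'   care status.
#' @return list with `index` (registry row), `code`, `variant`, `mean`.
#'   Unresolvable codes return `index = NA` (callers count these as
#'   missing-DW exclusions rather than errors).
#' @export
match_dw <- function(record, pattern, registry,
                     unknown_care = c("treated", "untreated")) {
  unknown_care <- match.arg(unknown_care)
  stopifnot(inherits(registry, "dw_registry"))
  if (identical(pattern, "death")) stop("death records carry no DW")
  code <- record$dw_code
  if (is.null(code) || is.na(code) || !nzchar(code))
    return(list(index = NA_integer_, code = NA_character_,
                variant = NA_character_, mean = NA_real_))
  variant <- care_variant(record$care, unknown_care)
  idx <- if (startsWith(pattern, "short_term")) {
    i <- dw_index(registry, code, "single")
    if (is.na(i)) dw_index(registry, code, variant) else i
  } else {
    dw_index(registry, code, variant)
  }
  if (is.na(idx))
    return(list(index = NA_integer_, code = code, variant = variant,
                mean = NA_real_))
  list(index = idx, code = code,
       variant = registry$entries$variant[idx],
       mean = registry$entries$mean[idx])
}

# Collapse care status to a DW variant: any care -> treated, none ->
# untreated, unknown -> configurable (all levels of care are treated alike).
care_variant <- function(care, unknown_care = "treated") {
  if (is.na(care) || care == "unknown") return(unknown_care)
  if (care == "none") "untreated" else "treated"
}
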