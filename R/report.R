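#' Write a burden result to disk
#'
#' JSON reports round-trip losslessly through [read_report()] and carry the
#' full structure (summary, by-year series, cause table, metadata including
#' seed, iteration count, life-table choice and study window). CSV reports
#' render the summary table with metadata as `#`-prefixed comment lines;
#' both formats agree on all point estimates.
#'
#' @param result a `burden_result`.
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "burden_result"))
  payload <- list(summary = result$summary, by_year = result$by_year,
                  by_cause = result$by_cause, meta = result$meta)
  if (format == "json") {
    ok <- tryCatch({
      jsonlite::write_json(payload, path, dataframe = "columns",
                           auto_unbox = TRUE, digits = NA, na = "null",
                           null = "null")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(path)) stop("could not write report to: ", path)
  } else {
    meta <- result$meta
    hdr <- vapply(names(meta), function(k)
      sprintf("# %s=%s", k, paste(format(meta[[k]]), collapse = ",")),
      character(1))
    ok <- tryCatch({
      con <- file(path, "w"); on.exit(close(con))
      writeLines(hdr, con)
      utils::write.csv(result$summary, con, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("could not write report to: ", path)
  }
  invisible(path)
}

#' Read back a JSON burden report
#'
#' @param path a JSON file written by [write_report()].
#' @return A `burden_result` (without the raw iteration matrix).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_df <- function(x) if (is.null(x)) NULL else
    as.data.frame(x, stringsAsFactors = FALSE)
  meta <- p$meta
  # scalars that jsonlite may have widened or nulled
  for (k in names(meta)) if (is.null(meta[[k]])) meta[[k]] <- NA
  meta$study_end <- if (is.character(meta$study_end) &&
                        identical(meta$study_end, "Inf")) Inf
                    else as.numeric(meta$study_end)
  new_burden_result(to_df(p$summary), to_df(p$by_year), meta,
                    by_cause = to_df(p$by_cause))
}
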