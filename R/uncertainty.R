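#' Bootstrap uncertainty, cause decomposition and population extrapolation
#'
#' Uncertainty is propagated by repeating the whole burden computation
#' (default 1,000 times): each iteration resamples the complete records with
#' replacement and maps a randomly selected set of disability-weight draws
#' onto the sample. Point estimates are the means over iterations and 95%
#' uncertainty intervals (UIs) are the 2.5th/97.5th percentiles of the
#' iteration totals. Cause-specific decomposition resamples but holds DWs at
#' their means (varying them would not alter the totals' allocation), and
#' extrapolation scales the per-person mean burden to a target population.
#'
#' @name uncertainty
NULL

#' Bootstrap configuration
#'
#' @param n_iterations number of bootstrap iterations (default 1000).
#' @param seed integer seed; the run is deterministic given the seed.
#' @param vary_dws draw a new set of disability weights each iteration from
#'   the registry's draw distributions.
#' @param resample resample records with replacement each iteration.
#' @param draw_mode `"shared"` selects one draw index per iteration applied
#'   to every DW entry; `"per_record"` selects an independent index per
#'   resampled record.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_iterations = 1000L, seed = 1L,
                             vary_dws = TRUE, resample = TRUE,
                             draw_mode = c("shared", "per_record")) {
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("n_iterations must be >= 1")
  structure(list(n_iterations = n_iterations, seed = as.integer(seed),
                 vary_dws = isTRUE(vary_dws), resample = isTRUE(resample),
                 draw_mode = match.arg(draw_mode)),
            class = "bootstrap_config")
}

new_burden_result <- function(summary, by_year, meta, by_cause = NULL,
                              iterations = NULL) {
  structure(list(summary = summary, by_year = by_year, by_cause = by_cause,
                 meta = meta, iterations = iterations),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("<burden_result: %s%s>\n",
              if (isTRUE(x$meta$extrapolated)) "population-scale, " else "",
              paste0(x$meta$n_iterations, " iterations, seed ",
                     x$meta$seed)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

summary_row <- function(quantity, point, lo = NA_real_, hi = NA_real_) {
  data.frame(quantity = quantity, point = point, ui_lower = lo,
             ui_upper = hi, stringsAsFactors = FALSE)
}

# Direct (no-bootstrap) totals and by-year series from a prepared table.
direct_totals <- function(prep, registry, table, study_end, injury_offset) {
  yld_inc <- prep$dw_mean * prep$yld_base
  yld_prev <- prep$dw_mean * prep$prev_base
  years <- sort(unique(prep$injury_year))
  by_year <- data.frame(
    year = years,
    yll = as.numeric(rowsum(prep$yll, prep$injury_year)[, 1]),
    yld_incidence = as.numeric(rowsum(yld_inc, prep$injury_year)[, 1])
  )
  prev_by_year <- numeric(0)
  for (i in seq_len(nrow(prep))) {
    if (is.na(prep$dw_index[i])) next
    r <- prep[i, ]
    span_end <- min(r$injury_year + injury_offset + r$prev_base, study_end)
    alloc <- allocate_years(r$injury_year + injury_offset, span_end,
                            prep$dw_mean[i])
    prev_by_year <- merge_alloc(prev_by_year, alloc)
  }
  all_years <- sort(unique(c(by_year$year, as.integer(names(prev_by_year)))))
  out <- data.frame(year = all_years)
  out$yll <- by_year$yll[match(all_years, by_year$year)]
  out$yld_incidence <- by_year$yld_incidence[match(all_years, by_year$year)]
  out$yll[is.na(out$yll)] <- 0
  out$yld_incidence[is.na(out$yld_incidence)] <- 0
  out$yld_prevalence <- prev_by_year[as.character(all_years)]
  out$yld_prevalence[is.na(out$yld_prevalence)] <- 0
  out$daly <- out$yll + out$yld_incidence
  list(yll = sum(prep$yll), yld_incidence = sum(yld_inc),
       yld_prevalence = sum(yld_prev), by_year = out)
}

allocate_years <- function(start, end, value_per_year) {
  if (end <= start) return(stats::setNames(numeric(0), character(0)))
  years <- seq.int(floor(start), ceiling(end) - 1L)
  lived <- pmin(end, years + 1) - pmax(start, years)
  keep <- lived > 0
  stats::setNames(value_per_year * lived[keep], years[keep])
}

merge_alloc <- function(a, b) {
  if (!length(b)) return(a)
  nm <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(nm)), nm)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out
}

#' Direct single-pass burden result (no bootstrap)
#'
#' Totals at mean disability weights with no resampling; uncertainty
#' intervals are undefined (NA). Handles an empty cohort (all totals zero).
#' This is the deterministic reference the bootstrap converges to.
#'
#' @inheritParams person_burden
#' @param n_persons number of persons surveyed (denominator for per-person
#'   means); NA if unknown.
#' @return A `burden_result` with NA uncertainty intervals.
#' @export
direct_burden <- function(records, registry, table, study_end = Inf,
                          n_persons = NA_integer_,
                          unknown_care = c("treated", "untreated"),
                          injury_offset = 0.5) {
  unknown_care <- match.arg(unknown_care)
  meta <- list(seed = NA_integer_, n_iterations = 0L, resample = FALSE,
               vary_dws = FALSE, draw_mode = "none",
               life_table = table$name, study_end = study_end,
               injury_offset = injury_offset, unknown_care = unknown_care,
               n_records = nrow(records), n_persons = n_persons,
               n_deaths = sum(records$outcome == "death_related"),
               extrapolated = FALSE, population = NA_real_)
  if (nrow(records) == 0L) {
    s <- rbind(summary_row("total_yll", 0), summary_row("total_yld_incidence", 0),
               summary_row("total_yld_prevalence", 0), summary_row("total_daly", 0))
    by_year <- data.frame(year = integer(0), yll = numeric(0),
                          yld_incidence = numeric(0),
                          yld_prevalence = numeric(0), daly = numeric(0))
    return(new_burden_result(s, by_year, meta))
  }
  prep <- prepare_burden(records, registry, table, study_end, unknown_care,
                         injury_offset)
  d <- direct_totals(prep, registry, table, study_end, injury_offset)
  s <- rbind(
    summary_row("total_yll", d$yll),
    summary_row("total_yld_incidence", d$yld_incidence),
    summary_row("total_yld_prevalence", d$yld_prevalence),
    summary_row("total_daly", d$yll + d$yld_incidence)
  )
  new_burden_result(s, d$by_year, meta)
}

#' Bootstrap the cohort burden with disability-weight uncertainty
#'
#' Each iteration resamples the complete records with replacement (if
#' `config$resample`) and, if `config$vary_dws`, substitutes a randomly
#' selected draw of each matched disability weight; totals of YLL,
#' incidence YLD, study-window prevalence YLD and DALY are recorded. Point
#' estimates are iteration means; 95% UIs are percentile intervals of the
#' iteration totals. Per-person means divide the totals by `n_persons`
#' (all persons surveyed), per-injury means by the number of complete
#' injury records, and per-death YLL means by the number of definitive
#' deaths.
#'
#' @inheritParams person_burden
#' @param config a [bootstrap_config()].
#' @param n_persons persons surveyed, the per-person denominator (NA to
#'   skip per-person means).
#' @return A `burden_result`: `summary` (point and UI per quantity),
#'   `by_year` (direct-pass series), `meta`, and the raw `iterations`
#'   matrix.
#' @export
bootstrap_burden <- function(records, registry, table,
                             config = bootstrap_config(),
                             study_end = Inf, n_persons = NA_integer_,
                             unknown_care = c("treated", "untreated"),
                             injury_offset = 0.5) {
  unknown_care <- match.arg(unknown_care)
  stopifnot(inherits(config, "bootstrap_config"))
  if (nrow(records) == 0L)
    stop("cannot bootstrap an empty record list")
  if (config$vary_dws && is.null(registry$draws))
    stop("config$vary_dws requires draws; call generate_draws() first")
  prep <- prepare_burden(records, registry, table, study_end, unknown_care,
                         injury_offset)
  n <- nrow(prep)
  n_iter <- config$n_iterations
  has_dw <- !is.na(prep$dw_index)
  idx_dw <- ifelse(has_dw, prep$dw_index, 1L)

  tot <- matrix(NA_real_, n_iter, 3,
                dimnames = list(NULL, c("yll", "yld_incidence",
                                        "yld_prevalence")))
  set.seed(config$seed)
  for (b in seq_len(n_iter)) {
    idx <- if (config$resample) sample.int(n, n, replace = TRUE)
           else seq_len(n)
    if (config$vary_dws) {
      j <- if (config$draw_mode == "shared")
        rep.int(sample.int(registry$n_draws, 1L), n)
      else sample.int(registry$n_draws, n, replace = TRUE)
      dw <- registry$draws[cbind(idx_dw[idx], j)]
    } else {
      dw <- prep$dw_mean[idx]
    }
    dw[!has_dw[idx]] <- 0
    tot[b, ] <- c(sum(prep$yll[idx]),
                  sum(dw * prep$yld_base[idx]),
                  sum(dw * prep$prev_base[idx]))
  }
  daly <- tot[, "yll"] + tot[, "yld_incidence"]

  n_deaths <- sum(prep$pattern == "death")
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  row_of <- function(name, x, denom = 1) {
    q <- qs(x) / denom
    summary_row(name, mean(x) / denom, q[1], q[2])
  }
  s <- rbind(
    row_of("total_yll", tot[, "yll"]),
    row_of("total_yld_incidence", tot[, "yld_incidence"]),
    row_of("total_yld_prevalence", tot[, "yld_prevalence"]),
    row_of("total_daly", daly),
    row_of("per_person_daly", daly, n_persons),
    row_of("per_person_yll", tot[, "yll"], n_persons),
    row_of("per_person_yld_incidence", tot[, "yld_incidence"], n_persons),
    row_of("per_injury_daly", daly, n),
    if (n_deaths > 0) row_of("per_death_yll", tot[, "yll"], n_deaths)
  )
  d <- direct_totals(prep, registry, table, study_end, injury_offset)
  meta <- list(seed = config$seed, n_iterations = n_iter,
               resample = config$resample, vary_dws = config$vary_dws,
               draw_mode = config$draw_mode, life_table = table$name,
               study_end = study_end, injury_offset = injury_offset,
               unknown_care = unknown_care, n_records = n,
               n_persons = n_persons, n_deaths = n_deaths,
               extrapolated = FALSE, population = NA_real_)
  new_burden_result(s, d$by_year, meta, iterations = tot)
}

#' Cause-specific DALY decomposition
#'
#' Bootstraps cause (mechanism) DALY totals with resampling but with
#' disability weights held at their means: varying the DWs would not alter
#' how the total splits across causes. Proportions are computed from the
#' unresampled direct point estimates, so they sum to one. Causes with no
#' records report zero with a degenerate interval.
#'
#' @inheritParams bootstrap_burden
#' @return data frame: `mechanism`, `daly` (bootstrap mean), `ui_lower`,
#'   `ui_upper`, `proportion`.
#' @export
cause_specific_burden <- function(records, registry, table,
                                  config = bootstrap_config(),
                                  study_end = Inf,
                                  unknown_care = c("treated", "untreated"),
                                  injury_offset = 0.5) {
  unknown_care <- match.arg(unknown_care)
  if (nrow(records) == 0L)
    stop("cannot decompose an empty record list")
  prep <- prepare_burden(records, registry, table, study_end, unknown_care,
                         injury_offset)
  n <- nrow(prep)
  daly_i <- prep$yll + prep$dw_mean * prep$yld_base
  mech <- factor(prep$mechanism, levels = injury_mechanisms())
  direct <- as.numeric(tapply(daly_i, mech, sum, default = 0))

  n_iter <- config$n_iterations
  totals <- matrix(0, n_iter, nlevels(mech),
                   dimnames = list(NULL, levels(mech)))
  set.seed(config$seed)
  for (b in seq_len(n_iter)) {
    idx <- if (config$resample) sample.int(n, n, replace = TRUE)
           else seq_len(n)
    totals[b, ] <- as.numeric(tapply(daly_i[idx], mech[idx], sum,
                                     default = 0))
  }
  out <- data.frame(
    mechanism = levels(mech),
    daly = unname(colMeans(totals)),
    ui_lower = unname(apply(totals, 2, stats::quantile, 0.025,
                            names = FALSE)),
    ui_upper = unname(apply(totals, 2, stats::quantile, 0.975,
                            names = FALSE)),
    proportion = direct / sum(direct),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Extrapolate a sample burden result to a population
#'
#' Multiplies the sample per-person mean (total divided by the number of
#' sampled persons) by the population size, applied separately to the point
#' estimate and to each end of the uncertainty interval. Totals, the
#' by-year series and any cause table scale linearly; per-person and
#' per-event means are population-invariant and are left unchanged.
#'
#' @param result a `burden_result`.
#' @param n_sampled_persons persons in the sample (denominator).
#' @param population target population size.
#' @return A population-scale `burden_result`.
#' @export
extrapolate <- function(result, n_sampled_persons, population) {
  stopifnot(inherits(result, "burden_result"),
            n_sampled_persons > 0, population > 0)
  f <- population / n_sampled_persons
  s <- result$summary
  scale_rows <- startsWith(s$quantity, "total_")
  s[scale_rows, c("point", "ui_lower", "ui_upper")] <-
    s[scale_rows, c("point", "ui_lower", "ui_upper")] * f
  by_year <- result$by_year
  num <- setdiff(names(by_year), "year")
  by_year[num] <- by_year[num] * f
  by_cause <- result$by_cause
  if (!is.null(by_cause))
    by_cause[c("daly", "ui_lower", "ui_upper")] <-
      by_cause[c("daly", "ui_lower", "ui_upper")] * f
  meta <- result$meta
  meta$extrapolated <- TRUE
  meta$population <- population
  meta$n_sampled_persons <- n_sampled_persons
  new_burden_result(s, by_year, meta, by_cause = by_cause)
}
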