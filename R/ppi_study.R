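# The central analysis constructor: runs exclusions, classification and all
# cohort metrics over the study years, returning one classed object.

#' Chronic-PPI-use study analysis
#'
#' Runs the full drug-utilization analysis on a claims dataset: applies the
#' age and parenteral-only exclusions, classifies every patient at each
#' January 1 anchor (chronic / incident / discontinued, with death
#' accounting), segments treatment episodes, and aggregates yearly cohort
#' summaries (counts, incidence/prevalence/discontinuation rates,
#' demographics, median annual DDD, dispensation mix), prescriber
#' attribution, coverage-threshold sensitivity and across-year trend tests.
#'
#' @param claims a [claims_data] object.
#' @param years integer anchor years to analyse; default: all anchors covered
#'   by the data period except the first (kept as burn-in so new-user status
#'   is assessable).
#' @param threshold coverage threshold for chronic status (default 0.80, i.e.
#'   74 doses over the 92-day trailing quarter).
#' @param gap_days uncovered-run length that splits episodes (default 61).
#' @param sensitivity_thresholds thresholds for the chronic-count sensitivity
#'   table.
#' @param decimals decimal places for published-style rates.
#' @return An object of class `ppi_study`: a list with `years`, `status`,
#'   `episodes`, `summary` (one row per year), `mix` (per year),
#'   `prescribers`, `sensitivity`, `trend`, `exclusions` and the call.
#' @seealso [summary.ppi_study()], [plot.ppi_study()], [render_tables()]
#' @export
#' @examples
#' sim <- simulate_claims(claims_config(n_patients = 300, seed = 42))
#' fit <- ppi_study(sim$claims, years = 2017:2020)
#' fit
ppi_study <- function(claims, years = NULL, threshold = 0.80, gap_days = 61L,
                      sensitivity_thresholds = c(0.75, 0.80, 0.85),
                      decimals = 1) {
  stopifnot(inherits(claims, "claims_data"))
  period <- attr(claims, "period")
  if (is.null(years)) {
    anch <- anchor_years(period[1], period[2])
    years <- if (length(anch) > 1L) anch[-1] else anch
  }
  years <- sort(as.integer(years))

  claims <- apply_exclusions(claims, anchor_year = years[1])
  status <- chronic_status_table(claims, years, threshold = threshold)
  episodes <- episode_table(claims, gap_days = gap_days)

  pts <- claims$patients
  den <- claims$denominators
  rows <- vector("list", length(years))
  mix <- vector("list", length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    prev_ids <- prevalent_chronic(status, y)
    inc_ids <- incident_chronic(status, y)
    pop <- den$count[match(y, den$year)]
    disc <- if (length(prev_ids))
      discontinuation_summary(status, y, decimals = decimals)
    else list(count = 0L, deaths_before_cutoff = 0L, prevalent = 0L,
              proportion_pct = NA_real_)

    prev_demo <- if (length(prev_ids))
      demographics_summary(pts[pts$patient_id %in% prev_ids, ], y, decimals)
    else NULL
    inc_demo <- if (length(inc_ids))
      demographics_summary(pts[pts$patient_id %in% inc_ids, ], y, decimals)
    else NULL

    med_ddd <- if (length(prev_ids))
      median_annual_ddd(claims$dispensings, y, claims$drug_reference, prev_ids)
    else NA_real_
    mix[[k]] <- if (length(prev_ids))
      tryCatch(cbind(year = y, dispensation_mix(claims$dispensings, y, prev_ids)),
               error = function(e) NULL)
    else NULL

    rows[[k]] <- data.frame(
      year = y,
      prevalent_count = length(prev_ids),
      incident_count = length(inc_ids),
      discontinuation_count = disc$count,
      deaths_before_cutoff = disc$deaths_before_cutoff,
      general_population = pop,
      incidence_rate_pct = if (is.na(pop)) NA_real_ else rate_pct(length(inc_ids), pop, decimals),
      prevalence_rate_pct = if (is.na(pop)) NA_real_ else rate_pct(length(prev_ids), pop, decimals),
      discontinuation_pct = disc$proportion_pct,
      discontinuation_pct_2dp = if (disc$prevalent > 0)
        rate_pct(disc$count, disc$prevalent, 2) else NA_real_,
      prev_age_mean = prev_demo$age_mean %||% NA_real_,
      prev_age_sd = prev_demo$age_sd %||% NA_real_,
      prev_age_median = prev_demo$age_median %||% NA_real_,
      prev_age_iqr = prev_demo$age_iqr %||% NA_real_,
      prev_male_n = prev_demo$male_n %||% 0L,
      prev_male_pct = prev_demo$male_pct %||% NA_real_,
      inc_age_mean = inc_demo$age_mean %||% NA_real_,
      inc_age_sd = inc_demo$age_sd %||% NA_real_,
      inc_age_median = inc_demo$age_median %||% NA_real_,
      inc_age_iqr = inc_demo$age_iqr %||% NA_real_,
      inc_male_n = inc_demo$male_n %||% 0L,
      inc_male_pct = inc_demo$male_pct %||% NA_real_,
      median_ddd_per_patient = med_ddd
    )
  }
  summary_df <- do.call(rbind, rows)
  mix_df <- do.call(rbind, mix[!vapply(mix, is.null, NA)])

  prescribers <- if (nrow(claims$dispensings))
    prescriber_attribution(claims$dispensings, decimals) else NULL

  sens <- do.call(rbind, lapply(years, function(y)
    cbind(year = y, threshold_sensitivity(claims, y, sensitivity_thresholds))))

  trend <- list(incidence = NULL, prevalence = NULL)
  ok <- !is.na(summary_df$general_population)
  if (sum(ok) >= 2L) {
    trend$incidence <- trend_test(summary_df$incident_count[ok],
                                  summary_df$general_population[ok],
                                  years = summary_df$year[ok])
    trend$prevalence <- trend_test(summary_df$prevalent_count[ok],
                                   summary_df$general_population[ok],
                                   years = summary_df$year[ok])
  }

  structure(list(
    call = match.call(),
    years = years, threshold = threshold, gap_days = gap_days,
    status = status, episodes = episodes,
    summary = summary_df, mix = mix_df, prescribers = prescribers,
    sensitivity = sens, trend = trend,
    exclusions = list(log = attr(claims, "exclusion_log"),
                      counts = attr(claims, "exclusion_counts"),
                      dropped_out_of_region = attr(claims, "dropped_out_of_region")),
    n_patients = nrow(claims$patients)
  ), class = "ppi_study")
}

#' @export
print.ppi_study <- function(x, ...) {
  cat("Chronic PPI use study\n")
  cat(sprintf("  years %s-%s, coverage threshold %.0f%% (%d doses / 92 days), episode gap %d days\n",
              min(x$years), max(x$years), 100 * x$threshold,
              chronic_dose_threshold(x$threshold), x$gap_days))
  cat(sprintf("  %d patients after exclusions\n\n", x$n_patients))
  cols <- c("year", "prevalent_count", "incident_count", "discontinuation_count",
            "incidence_rate_pct", "prevalence_rate_pct", "discontinuation_pct")
  print(x$summary[, cols], row.names = FALSE)
  if (!is.null(x$trend$incidence))
    cat(sprintf("\nIncidence trend across years: chi-sq = %.2f, p = %.3g\n",
                x$trend$incidence$statistic, x$trend$incidence$p_value))
  invisible(x)
}

#' Summarize a chronic-PPI-use study
#'
#' @param object a `ppi_study`.
#' @param ... unused.
#' @return object of class `summary.ppi_study` wrapping the yearly summary,
#'   mix, prescriber attribution and trend tests.
#' @export
summary.ppi_study <- function(object, ...) {
  structure(list(summary = object$summary, mix = object$mix,
                 prescribers = object$prescribers, trend = object$trend,
                 sensitivity = object$sensitivity,
                 exclusions = object$exclusions),
            class = "summary.ppi_study")
}

#' @export
print.summary.ppi_study <- function(x, ...) {
  cat("Yearly cohort summary:\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$prescribers)) {
    cat("\nTreatment initiations by specialty:\n")
    print(x$prescribers$initiations, row.names = FALSE)
    cat("\nFirst renewals by specialty:\n")
    print(x$prescribers$first_renewals, row.names = FALSE)
  }
  cat("\nChronic count by coverage threshold:\n")
  print(x$sensitivity, row.names = FALSE)
  invisible(x)
}

#' Plot yearly rates of a chronic-PPI-use study
#'
#' Base-graphics panel: incidence and prevalence rates (left axis, % of the
#' general population) and the discontinuation proportion among chronic
#' users, by year.
#'
#' @param x a `ppi_study`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ppi_study <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(s$year, cbind(s$incidence_rate_pct, s$prevalence_rate_pct),
                    type = "b", pch = c(1, 16), lty = 1,
                    col = c("steelblue", "darkred"),
                    xlab = "year", ylab = "% of general population",
                    main = "Chronic PPI use", ...)
  graphics::legend("topleft", c("incidence", "prevalence"), pch = c(1, 16),
                   col = c("steelblue", "darkred"), bty = "n")
  graphics::plot(s$year, s$discontinuation_pct, type = "b", pch = 16,
                 xlab = "year", ylab = "% of chronic users",
                 main = "Discontinuation")
  invisible(x)
}

#' Render published-style report tables
#'
#' Formats the yearly summaries the way drug-utilization reports print them:
#' an incident-cohort demographics table, a prevalent-cohort table, a
#' consumption-evolution table whose discontinuation column carries the
#' death tally as `"count (d +)"`, and the per-year dispensation-mix table.
#'
#' @param study a `ppi_study`.
#' @return named list of data.frames (`incident`, `prevalent`,
#'   `consumption`, `mix`).
#' @export
render_tables <- function(study) {
  s <- study$summary
  if (nrow(s) == 0L) stop("no years to render", call. = FALSE)
  fmt <- function(v) format(v, big.mark = ",", trim = TRUE)
  incident <- data.frame(
    year = s$year,
    incident_population = fmt(s$incident_count),
    age_mean_sd = sprintf("%s; %s", s$inc_age_mean, s$inc_age_sd),
    age_median_iqr = sprintf("%s; %s", s$inc_age_median, s$inc_age_iqr),
    male_n_pct = sprintf("%s (%s%%)", fmt(s$inc_male_n), s$inc_male_pct),
    general_population = fmt(s$general_population),
    incidence_rate = sprintf("%s%%", s$incidence_rate_pct)
  )
  prevalent <- data.frame(
    year = s$year,
    prevalent_population = fmt(s$prevalent_count),
    age_mean_sd = sprintf("%s; %s", s$prev_age_mean, s$prev_age_sd),
    age_median_iqr = sprintf("%s; %s", s$prev_age_median, s$prev_age_iqr),
    male_n_pct = sprintf("%s (%s%%)", fmt(s$prev_male_n), s$prev_male_pct),
    general_population = fmt(s$general_population),
    prevalence_rate = sprintf("%s%%", s$prevalence_rate_pct)
  )
  consumption <- data.frame(
    year = s$year,
    chronic_on_jan1 = fmt(s$prevalent_count),
    no_refill_nov_dec = sprintf("%s (%s +)", fmt(s$discontinuation_count),
                                s$deaths_before_cutoff),
    discontinuation_pct = sprintf("%.2f%%", s$discontinuation_pct_2dp)
  )
  list(incident = incident, prevalent = prevalent, consumption = consumption,
       mix = study$mix)
}
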