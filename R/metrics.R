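# Cohort-level quantities: prevalent/incident sets, rates, discontinuation
# with death accounting, DDD statistics, dispensation mix, prescriber
# attribution, trend test, demographics.

#' Prevalent chronic patient set of a year
#'
#' All patients chronic at January 1 of `year`.
#'
#' @param status a chronic-status table from [chronic_status_table()].
#' @param year integer anchor year.
#' @return character vector of patient ids.
#' @export
prevalent_chronic <- function(status, year) {
  if (!year %in% status$year)
    stop(sprintf("year %d not covered by the status table", year), call. = FALSE)
  status$patient_id[status$year == year & status$chronic]
}

#' Incident (new) chronic patient set of a year
#'
#' @inheritParams prevalent_chronic
#' @return character vector of patient ids (always a subset of the prevalent
#'   set of the same year).
#' @export
incident_chronic <- function(status, year) {
  if (!year %in% status$year)
    stop(sprintf("year %d not covered by the status table", year), call. = FALSE)
  sel <- status$year == year & status$chronic & !is.na(status$incident) & status$incident
  status$patient_id[sel]
}

#' Percentage with configurable rounding
#'
#' `100 * count / population`, rounded half away from zero to `decimals`
#' places, as published rates are.
#'
#' @param count numerator (>= 0).
#' @param population denominator (> 0).
#' @param decimals decimal places (default 1).
#' @return percentage.
#' @export
#' @examples
#' rate_pct(46308, 3757600) # 1.2
#' rate_pct(167751, 3801800) # 4.4
rate_pct <- function(count, population, decimals = 1) {
  if (any(population <= 0)) stop("population must be > 0", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  round_half_up(100 * count / population, decimals)
}

#' Discontinuation summary of a year
#'
#' Chronic users of `year` with no refill in November-December, including
#' those who died before the October 31 cutoff (tallied separately, as the
#' yearly consumption table footnotes them). The proportion is over the
#' year's prevalent set.
#'
#' @inheritParams prevalent_chronic
#' @param decimals decimal places of the proportion (default 1; published
#'   tables also print 2).
#' @return list: `count`, `deaths_before_cutoff`, `prevalent`,
#'   `proportion_pct`.
#' @export
discontinuation_summary <- function(status, year, decimals = 1) {
  prev <- prevalent_chronic(status, year)
  if (length(prev) == 0L)
    stop(sprintf("no prevalent chronic patients in %d: proportion undefined", year),
         call. = FALSE)
  sel <- status$year == year & status$chronic & status$discontinued
  cnt <- sum(sel)
  deaths <- sum(sel & status$died_before_cutoff)
  list(count = cnt, deaths_before_cutoff = deaths, prevalent = length(prev),
       proportion_pct = rate_pct(cnt, length(prev), decimals))
}

#' Annual DDD consumption per patient
#'
#' Sum over a year's oral dispensings of `units * dosage_mg / ddd_mg`
#' (defined daily doses). A patient taking one DDD-strength unit daily for a
#' year accumulates 365 DDD.
#'
#' @param dispensings dispensing records (any number of patients).
#' @param year calendar year to account.
#' @param drug_reference DDD reference table (`inn`, `dosage_mg`, `ddd_mg`).
#' @return named numeric vector: DDD total per patient id present in the
#'   year's oral dispensings.
#' @export
annual_ddd_per_patient <- function(dispensings, year, drug_reference) {
  d <- oral_only(dispensings)
  d <- d[date_year(d$dispense_date) == year, , drop = FALSE]
  if (nrow(d) == 0L) return(stats::setNames(numeric(0), character(0)))
  m <- match(paste(d$inn, d$dosage_mg), paste(drug_reference$inn, drug_reference$dosage_mg))
  if (anyNA(m))
    stop(sprintf("missing DDD entry for %s %g mg", d$inn[which(is.na(m))[1]],
                 d$dosage_mg[which(is.na(m))[1]]), call. = FALSE)
  ddd <- d$units_dispensed * d$dosage_mg / drug_reference$ddd_mg[m]
  v <- rowsum(ddd, d$patient_id)
  stats::setNames(as.numeric(v), rownames(v))
}

#' Median annual DDD over a patient set
#'
#' Patients in the set without any oral dispensing that year count 0 DDD.
#'
#' @inheritParams annual_ddd_per_patient
#' @param patient_set character vector of patient ids (e.g. the prevalent
#'   set).
#' @return median DDD.
#' @export
median_annual_ddd <- function(dispensings, year, drug_reference, patient_set) {
  if (length(patient_set) == 0L) stop("empty patient set", call. = FALSE)
  v <- annual_ddd_per_patient(dispensings, year, drug_reference)
  out <- stats::setNames(rep(0, length(patient_set)), patient_set)
  hit <- intersect(names(v), patient_set)
  out[hit] <- v[hit]
  stats::median(out)
}

#' Dispensation mix among a year's chronic users
#'
#' Share of dispensing events (rows, not units) per INN x dosage among the
#' oral dispensings of the year's chronic patients; two-decimal percentages
#' summing to ~100.
#'
#' @inheritParams annual_ddd_per_patient
#' @param patient_set ids of the year's chronic users.
#' @return data.frame `inn`, `dosage_mg`, `n_events`, `pct`, ordered by INN
#'   and dosage.
#' @export
dispensation_mix <- function(dispensings, year, patient_set) {
  d <- oral_only(dispensings)
  d <- d[date_year(d$dispense_date) == year & d$patient_id %in% patient_set, ,
         drop = FALSE]
  if (nrow(d) == 0L)
    stop(sprintf("no dispensings among chronic users in %d", year), call. = FALSE)
  tab <- stats::aggregate(list(n_events = d$units_dispensed),
                          by = list(inn = d$inn, dosage_mg = d$dosage_mg),
                          FUN = length)
  tab <- tab[order(tab$inn, tab$dosage_mg), , drop = FALSE]
  tab$pct <- round_half_up(100 * tab$n_events / sum(tab$n_events), 2)
  rownames(tab) <- NULL
  tab
}

#' Prescriber attribution of initiations and first renewals
#'
#' Initiation: the prescriber of a patient's earliest dispensing anywhere in
#' the data (the data span is the lookback). First renewal: the prescriber of
#' the earliest dispensing bearing a prescription id different from the
#' initiation prescription; patients whose dispensings all share one
#' prescription contribute no renewal.
#'
#' @param dispensings dispensing records.
#' @param decimals decimal places for percentages.
#' @return list of two data.frames (`initiations`, `first_renewals`) with
#'   `specialty`, `n`, `pct`.
#' @export
prescriber_attribution <- function(dispensings, decimals = 1) {
  d <- dispensings
  if (nrow(d) == 0L) stop("no dispensings", call. = FALSE)
  d <- d[order(d$patient_id, d$dispense_date, d$prescription_id), , drop = FALSE]
  first_idx <- !duplicated(d$patient_id)
  init <- d[first_idx, c("patient_id", "prescription_id", "prescriber_specialty")]

  m <- match(d$patient_id, init$patient_id)
  different <- d$prescription_id != init$prescription_id[m]
  dr <- d[different, , drop = FALSE]
  ren <- dr[!duplicated(dr$patient_id), , drop = FALSE]

  tally <- function(spec) {
    n <- vapply(SPECIALTIES, function(s) sum(spec == s), 1L)
    data.frame(specialty = SPECIALTIES, n = as.integer(n),
               pct = if (sum(n) > 0) rate_pct(n, sum(n), decimals) else NA_real_)
  }
  list(initiations = tally(init$prescriber_specialty),
       first_renewals = tally(ren$prescriber_specialty))
}

#' Trend test for proportions across ordered years
#'
#' Cochran-Armitage score test for a linear trend in yearly proportions
#' (via [stats::prop.trend.test()] with the years as scores); two-sided
#' p-value.
#'
#' @param counts integer vector of yearly event counts.
#' @param populations corresponding denominators.
#' @param years the ordered years (scores); defaults to `1:length(counts)`.
#' @return list with `statistic` (chi-squared, 1 df) and `p_value`.
#' @export
trend_test <- function(counts, populations, years = seq_along(counts)) {
  if (length(counts) < 2L) stop("need at least two years", call. = FALSE)
  if (any(populations <= 0)) stop("populations must be > 0", call. = FALSE)
  # flat proportions are a legitimate degenerate input (statistic 0, p = 1);
  # prop.trend.test's internal ANOVA warns about the perfect fit there
  ht <- suppressWarnings(stats::prop.trend.test(counts, populations, score = years))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Demographic summary of a patient set at a January 1 anchor
#'
#' Ages are completed years at January 1 of `anchor_year`. Median uses the
#' midpoint convention for even counts; quartiles use the inclusive
#' (type 7) method, and the IQR is reported as a single width `q3 - q1`,
#' matching published cohort tables.
#'
#' @param patients patient table rows for the set.
#' @param anchor_year integer year.
#' @param decimals decimal places for means/percentages.
#' @return list: `n`, `age_mean`, `age_sd`, `age_median`, `age_iqr`,
#'   `male_n`, `male_pct`, `female_n`, `female_pct`.
#' @export
demographics_summary <- function(patients, anchor_year, decimals = 1) {
  if (nrow(patients) == 0L) stop("empty patient set", call. = FALSE)
  age <- age_at_jan1(patients$birth_date, anchor_year)
  q <- stats::quantile(age, c(0.25, 0.75), type = 7, names = FALSE)
  male <- sum(patients$sex == "male")
  list(
    n = nrow(patients),
    age_mean = round_half_up(mean(age), decimals),
    age_sd = round_half_up(stats::sd(age), decimals),
    age_median = stats::median(age),
    age_iqr = q[2] - q[1],
    male_n = male,
    male_pct = rate_pct(male, nrow(patients), decimals),
    female_n = nrow(patients) - male,
    female_pct = rate_pct(nrow(patients) - male, nrow(patients), decimals)
  )
}

#' Size-weighted pooled mean
#'
#' Pooled mean of per-year means weighted by cohort sizes; with equal weights
#' this is the plain arithmetic mean.
#'
#' @param means numeric vector of group means.
#' @param weights corresponding group sizes.
#' @return the pooled mean (unrounded).
#' @export
pooled_mean <- function(means, weights) {
  if (length(means) != length(weights) || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative, same length as means, not all zero",
         call. = FALSE)
  sum(means * weights) / sum(weights)
}

#' Maximum whole-day duration of a course shorter than a week bound
#'
#' Guideline arithmetic for acute-course durations: a treatment of "less than
#' `weeks` weeks" lasts at most `7 * (weeks - 1)` days in whole weeks - 56
#' days for the usual under-9-weeks acute indications, well below the 74-dose
#' chronic threshold.
#'
#' @param weeks exclusive upper bound in weeks.
#' @return days.
#' @export
#' @examples
#' acute_course_max_days(9) # 56
acute_course_max_days <- function(weeks) {
  if (weeks < 1) stop("weeks must be >= 1", call. = FALSE)
  as.integer(7 * (weeks - 1))
}
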