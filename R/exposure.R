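# Exposure algebra: supply intervals, dose-based temporal coverage, chronic
# classification at January 1 anchors, discontinuation, episode segmentation.
#
# Conventions (all documented in the methods vignette):
#   * 1 dispensed unit = 1 day of treatment ("dose").
#   * All date windows are closed intervals; a dispensing dated on a window
#     boundary counts.
#   * The canonical chronic window for anchor year y is Oct 1 - Dec 31 of
#     y - 1 (92 days); the dose threshold at coverage t is ceiling(t * 92),
#     i.e. 74 doses at the default 80%.

#' Coverage window
#'
#' A closed calendar interval used for dose counting. The canonical chronic
#' window for anchor year `y` is October 1 to December 31 of `y - 1`
#' (92 days); see [chronic_window()].
#'
#' @param start_date,end_date `Date` scalars, `start_date <= end_date`.
#' @return An object of class `coverage_window`: a list with `start_date`,
#'   `end_date` and `n_days = end - start + 1`.
#' @export
#' @examples
#' coverage_window(as.Date("2016-10-01"), as.Date("2016-12-31"))$n_days # 92
coverage_window <- function(start_date, end_date) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (length(start_date) != 1L || length(end_date) != 1L || is.na(start_date) || is.na(end_date))
    stop("coverage_window() needs scalar, non-missing dates", call. = FALSE)
  if (end_date < start_date) stop("end_date must be >= start_date", call. = FALSE)
  structure(
    list(start_date = start_date, end_date = end_date,
         n_days = as.integer(end_date - start_date) + 1L),
    class = "coverage_window"
  )
}

#' Canonical trailing-quarter window for an anchor year
#'
#' @param year integer anchor year (chronic status is assessed at Jan 1 of
#'   this year).
#' @return the `coverage_window` Oct 1 - Dec 31 of `year - 1` (92 days).
#' @export
chronic_window <- function(year) {
  coverage_window(ymd(year - 1L, 10L, 1L), ymd(year - 1L, 12L, 31L))
}

#' Dose threshold implied by a coverage fraction
#'
#' The smallest integer dose count whose coverage of an `n_days` window
#' reaches `threshold`: `ceiling(threshold * n_days)`. At the default 80%
#' over the 92-day quarter this is 74 doses.
#'
#' @param threshold coverage fraction in (0, 1].
#' @param n_days window length in days (default 92).
#' @return integer dose threshold.
#' @export
#' @examples
#' chronic_dose_threshold(0.80) # 74
#' chronic_dose_threshold(0.75) # 69
chronic_dose_threshold <- function(threshold, n_days = 92L) {
  if (any(!is.finite(threshold)) || any(threshold <= 0) || any(threshold > 1))
    stop("coverage `threshold` must lie in (0, 1]", call. = FALSE)
  # round() guards binary-representation error (0.8 * 92 = 73.60000000000001)
  as.integer(ceiling(round(threshold * n_days, 9)))
}

#' Supply interval of a dispensing
#'
#' With one unit covering one day, a dispensing of `units` on day `d` covers
#' the closed interval `[d, d + units - 1]`.
#'
#' @param dispense_date `Date` vector.
#' @param units_dispensed positive integer vector (recycled against dates).
#' @param route optional route vector; parenteral records are a contract
#'   violation (they never enter coverage).
#' @return a data.frame with `Date` columns `start` and `end`.
#' @export
#' @examples
#' supply_interval(as.Date("2016-12-15"), 30) # ends 2017-01-13, covers Jan 1
supply_interval <- function(dispense_date, units_dispensed, route = NULL) {
  dispense_date <- as.Date(dispense_date)
  if (!is.null(route) && any(route != "oral"))
    stop("supply_interval() is defined for oral dispensings only", call. = FALSE)
  if (any(units_dispensed < 1)) stop("units_dispensed must be >= 1", call. = FALSE)
  data.frame(start = dispense_date,
             end = dispense_date + as.integer(units_dispensed) - 1L)
}

oral_only <- function(records) records[records$route == "oral", , drop = FALSE]

#' Doses dispensed inside a window
#'
#' Sum of `units_dispensed` over oral records whose *dispense date* falls
#' inside the closed window. Dose counting is by dispensing date, not by
#' supply overlap: a box dispensed the day before the window contributes
#' nothing even if its supply runs into it.
#'
#' @param records dispensing records of a single patient (data.frame with at
#'   least `dispense_date`, `units_dispensed`, `route`).
#' @param window a [coverage_window()].
#' @return integer dose count.
#' @export
doses_in_window <- function(records, window) {
  stopifnot(inherits(window, "coverage_window"))
  r <- oral_only(records)
  inside <- r$dispense_date >= window$start_date & r$dispense_date <= window$end_date
  as.integer(sum(r$units_dispensed[inside]))
}

#' Temporal coverage of a window
#'
#' Dose-count coverage, capped at 1: `min(1, doses / n_days)`. 74 doses over
#' the 92-day quarter give 74/92 = 0.804, just above the 80% chronic
#' threshold.
#'
#' @inheritParams doses_in_window
#' @return fraction in \[0, 1\].
#' @export
temporal_coverage <- function(records, window) {
  min(1, doses_in_window(records, window) / window$n_days)
}

check_year_in_range <- function(year, data_range, what) {
  if (is.null(data_range)) return(invisible(TRUE))
  data_range <- as.Date(data_range)
  w <- chronic_window(year)
  if (w$start_date < data_range[1] || ymd(year, 1L, 1L) > data_range[2])
    stop(sprintf("%s: year %d lies outside the data period %s..%s",
                 what, year, data_range[1], data_range[2]), call. = FALSE)
  invisible(TRUE)
}

#' Chronic-user classification at a January 1 anchor
#'
#' A patient is a chronic user in year `y` when the trailing quarter
#' (Oct 1 - Dec 31 of `y - 1`) contains at least `ceiling(threshold * 92)`
#' dispensed doses - 74 at the default 80% coverage.
#'
#' @param records oral dispensing records of one patient.
#' @param year integer anchor year.
#' @param threshold coverage fraction in (0, 1], default 0.80.
#' @param data_range optional `Date` length-2 vector; when supplied, an anchor
#'   whose window falls outside it is an error.
#' @return logical scalar.
#' @export
#' @examples
#' r <- data.frame(dispense_date = as.Date("2016-10-10"), units_dispensed = 74L,
#'                 route = "oral")
#' classify_chronic(r, 2017) # TRUE: 74 doses in Oct-Dec 2016
classify_chronic <- function(records, year, threshold = 0.80, data_range = NULL) {
  check_year_in_range(year, data_range, "classify_chronic")
  w <- chronic_window(year)
  doses_in_window(records, w) >= chronic_dose_threshold(threshold, w$n_days)
}

#' Was the patient a user on a given date?
#'
#' TRUE when some oral supply interval contains `date`.
#'
#' @param records oral dispensing records of one patient.
#' @param date `Date` scalar.
#' @return logical scalar.
#' @export
user_on <- function(records, date) {
  r <- oral_only(records)
  if (nrow(r) == 0L) return(FALSE)
  iv <- supply_interval(r$dispense_date, r$units_dispensed)
  any(iv$start <= date & date <= iv$end)
}

#' Incident (new) chronic-user classification
#'
#' Chronic in year `y` while not a PPI user on January 1 of `y - 1`: no
#' supply interval covers that date and the patient was not a chronic user of
#' year `y - 1` (a chronic user is by definition a user on its January 1
#' anchor, even when a refill gap happens to straddle the date).
#'
#' @inheritParams classify_chronic
#' @return logical scalar.
#' @export
classify_incident <- function(records, year, threshold = 0.80, data_range = NULL) {
  if (!is.null(data_range) && ymd(year - 1L, 1L, 1L) < as.Date(data_range)[1])
    stop(sprintf(
      "classify_incident: Jan 1 of year %d precedes the data period; new-user status not assessable",
      year - 1L), call. = FALSE)
  classify_chronic(records, year, threshold, data_range) &&
    !user_on(records, ymd(year - 1L, 1L, 1L)) &&
    !classify_chronic(records, year - 1L, threshold)
}

#' Discontinuation detection for a chronic patient-year
#'
#' A chronic user of year `y` discontinues when no oral dispensing is dated
#' in November-December of `y` (no more refills). Deaths before the
#' October 31 cutoff are flagged so they can be tallied separately in the
#' yearly consumption table.
#'
#' @param records oral dispensing records of one patient.
#' @param year integer anchor year; the patient must be chronic in it.
#' @param death_date `Date` scalar or `NA`.
#' @param threshold coverage fraction used for the chronic precondition.
#' @return list with logical `discontinued` and `died_before_cutoff`.
#' @export
detect_discontinuation <- function(records, year, death_date = as.Date(NA),
                                   threshold = 0.80) {
  if (!classify_chronic(records, year, threshold))
    stop("detect_discontinuation() called for a non-chronic patient-year",
         call. = FALSE)
  r <- oral_only(records)
  nov_dec <- r$dispense_date >= ymd(year, 11L, 1L) &
    r$dispense_date <= ymd(year, 12L, 31L)
  list(
    discontinued = !any(nov_dec),
    died_before_cutoff = !is.na(death_date) && death_date <= ymd(year, 10L, 31L)
  )
}

#' Segment dispensings into episodes of use
#'
#' Supply intervals are merged into maximal exposure runs; an uncovered run of
#' at least `gap_days` days (default 61, the length of a November-December
#' "two months") ends an episode, and the next dispensing starts a new one.
#'
#' @param records oral dispensing records of one patient, any order.
#' @param gap_days minimum uncovered run that splits episodes.
#' @return data.frame with `start_date`, `end_date`, `n_doses`, ordered and
#'   disjoint; zero rows when the patient has no oral dispensing.
#' @export
#' @examples
#' r <- data.frame(
#'   dispense_date = as.Date(c("2017-03-02", "2017-06-01")),
#'   units_dispensed = c(30L, 30L), route = "oral")
#' segment_episodes(r) # supply ends Mar 31; 61 uncovered days -> 2 episodes
segment_episodes <- function(records, gap_days = 61L) {
  r <- oral_only(records)
  if (nrow(r) == 0L)
    return(data.frame(start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      n_doses = integer()))
  r <- r[order(r$dispense_date, r$units_dispensed), , drop = FALSE]
  iv <- supply_interval(r$dispense_date, r$units_dispensed)
  start <- iv$start[1]; end <- iv$end[1]; doses <- r$units_dispensed[1]
  out <- list()
  if (nrow(r) > 1L) for (k in 2:nrow(r)) {
    uncovered <- as.integer(iv$start[k] - end) - 1L
    if (uncovered >= gap_days) {
      out[[length(out) + 1L]] <- list(start, end, doses)
      start <- iv$start[k]; end <- iv$end[k]; doses <- r$units_dispensed[k]
    } else {
      end <- max(end, iv$end[k])
      doses <- doses + r$units_dispensed[k]
    }
  }
  out[[length(out) + 1L]] <- list(start, end, doses)
  data.frame(
    start_date = as.Date(vapply(out, function(e) as.character(e[[1]]), "")),
    end_date = as.Date(vapply(out, function(e) as.character(e[[2]]), "")),
    n_doses = vapply(out, function(e) as.integer(e[[3]]), 1L)
  )
}

#' Chronic-status table for a dataset
#'
#' Vectorized classification of every included patient at every requested
#' January 1 anchor: chronic, incident, discontinued and died-before-cutoff
#' flags. Patients dead before Jan 1 of a year are not chronic for it.
#' Incident status is `NA` for anchors whose year-before January 1 precedes
#' the data period (new-user status not assessable).
#'
#' @param claims a [claims_data] object (exclusions already applied).
#' @param years integer vector of anchor years.
#' @param threshold coverage fraction, default 0.80.
#' @return data.frame: `patient_id`, `year`, `chronic`, `incident`,
#'   `discontinued`, `died_before_cutoff` (one row per patient-year).
#' @export
chronic_status_table <- function(claims, years, threshold = 0.80) {
  stopifnot(inherits(claims, "claims_data"))
  years <- sort(as.integer(years))
  rng <- attr(claims, "period")
  for (y in years) check_year_in_range(y, rng, "chronic_status_table")

  pts <- claims$patients
  d <- oral_only(claims$dispensings)
  thr <- chronic_dose_threshold(threshold)

  mo <- date_month(d$dispense_date)
  yr <- date_year(d$dispense_date)
  # doses per (patient, anchor year fed by the Oct-Dec window)
  feed <- mo >= 10L
  wkey <- paste(d$patient_id[feed], yr[feed] + 1L)
  wdoses <- rowsum(as.numeric(d$units_dispensed[feed]), wkey)
  # patient-years with any Nov-Dec dispensing
  nd <- mo >= 11L
  ndkey <- unique(paste(d$patient_id[nd], yr[nd]))

  death <- pts$death_date[match(pts$patient_id, pts$patient_id)]
  res <- vector("list", length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    jan1 <- ymd(y, 1L, 1L)
    doses <- wdoses[match(paste(pts$patient_id, y), rownames(wdoses))]
    doses[is.na(doses)] <- 0
    alive <- is.na(pts$death_date) | pts$death_date >= jan1
    chronic <- doses >= thr & alive

    incident <- rep(NA, nrow(pts))
    prev_jan <- ymd(y - 1L, 1L, 1L)
    assessable <- is.null(rng) || prev_jan >= as.Date(rng)[1]
    if (assessable) {
      incident <- chronic
      prev_doses <- wdoses[match(paste(pts$patient_id, y - 1L), rownames(wdoses))]
      prev_doses[is.na(prev_doses)] <- 0
      prev_alive <- is.na(pts$death_date) | pts$death_date >= prev_jan
      prev_chronic <- prev_doses >= thr & prev_alive
      idx <- which(chronic)
      if (length(idx)) {
        sub <- d[d$patient_id %in% pts$patient_id[idx], , drop = FALSE]
        iv <- supply_interval(sub$dispense_date, sub$units_dispensed)
        covers <- iv$start <= prev_jan & prev_jan <= iv$end
        users <- unique(sub$patient_id[covers])
        incident[idx] <- !(pts$patient_id[idx] %in% users) & !prev_chronic[idx]
      }
    }

    discontinued <- chronic & !(paste(pts$patient_id, y) %in% ndkey)
    died_cut <- chronic & !is.na(pts$death_date) & pts$death_date <= ymd(y, 10L, 31L)

    res[[k]] <- data.frame(
      patient_id = pts$patient_id, year = y,
      chronic = chronic, incident = incident,
      discontinued = discontinued, died_before_cutoff = died_cut,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Episode table for a dataset
#'
#' [segment_episodes()] applied per patient over all oral dispensings.
#'
#' @inheritParams chronic_status_table
#' @param gap_days minimum uncovered run (days) that splits episodes.
#' @return data.frame: `patient_id`, `start_date`, `end_date`, `n_doses`.
#' @export
episode_table <- function(claims, gap_days = 61L) {
  stopifnot(inherits(claims, "claims_data"))
  d <- oral_only(claims$dispensings)
  if (nrow(d) == 0L)
    return(data.frame(patient_id = character(), start_date = as.Date(character()),
                      end_date = as.Date(character()), n_doses = integer()))
  parts <- split(d, d$patient_id)
  out <- lapply(names(parts), function(pid) {
    ep <- segment_episodes(parts[[pid]], gap_days)
    cbind(patient_id = pid, ep)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Chronic counts across coverage thresholds
#'
#' Sensitivity of the chronic-user count to the coverage threshold: the count
#' is non-increasing in the threshold because the implied dose cutoff
#' `ceiling(t * 92)` is non-decreasing.
#'
#' @inheritParams chronic_status_table
#' @param year integer anchor year.
#' @param thresholds numeric vector of coverage fractions in (0, 1].
#' @return data.frame with `threshold`, `dose_threshold`, `chronic_count`.
#' @export
threshold_sensitivity <- function(claims, year, thresholds = c(0.75, 0.80, 0.85)) {
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  counts <- vapply(thresholds, function(t) {
    st <- chronic_status_table(claims, year, threshold = t)
    sum(st$chronic)
  }, 1L)
  data.frame(threshold = thresholds,
             dose_threshold = chronic_dose_threshold(thresholds),
             chronic_count = counts)
}
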