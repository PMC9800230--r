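# Data model and flat-file I/O for dispensing-claims datasets.
#
# File schemas (ISO-8601 dates, comma-separated, header row):
#   patients.csv       patient_id,birth_date,sex,death_date,in_region
#   dispensings.csv    patient_id,dispense_date,inn,dosage_mg,units_dispensed,
#                      route,prescription_id,prescriber_specialty
#   drug_reference.csv inn,dosage_mg,ddd_mg
#   population.csv     year,count

PPI_INNS <- c("esomeprazole", "lansoprazole", "omeprazole", "pantoprazole",
              "rabeprazole")
SPECIALTIES <- c("general_practitioner", "specialist", "institution")

#' Assemble and validate a claims dataset
#'
#' Bundles the four tables of a drug-utilization dataset into a validated
#' `claims_data` object. Out-of-region patients (`in_region = FALSE`) are
#' dropped at construction with a logged count, mirroring a regional study
#' population.
#'
#' @param patients data.frame: `patient_id`, `birth_date`, `sex`
#'   (male/female), `death_date` (`NA` if alive), `in_region` (logical).
#' @param dispensings data.frame: `patient_id`, `dispense_date`, `inn`,
#'   `dosage_mg`, `units_dispensed`, `route` (oral/parenteral),
#'   `prescription_id`, `prescriber_specialty`.
#' @param drug_reference data.frame: `inn`, `dosage_mg`, `ddd_mg`.
#' @param denominators data.frame: `year`, `count` - yearly general-population
#'   denominators for rates.
#' @param period optional `Date` length-2 data-coverage period; defaults to
#'   the range of dispensing dates.
#' @return A `claims_data` object (list of the four validated tables) with a
#'   `period` attribute and a `dropped_out_of_region` count attribute.
#' @export
claims_data <- function(patients, dispensings, drug_reference, denominators,
                        period = NULL) {
  patients$birth_date <- as.Date(patients$birth_date)
  patients$death_date <- as.Date(patients$death_date)
  dispensings$dispense_date <- as.Date(dispensings$dispense_date)
  orphan <- !dispensings$patient_id %in% patients$patient_id
  if (any(orphan))
    validation_error("dispensings.csv", which(orphan)[1], "patient_id",
                     sprintf("patient_id '%s' absent from patients.csv",
                             dispensings$patient_id[which(orphan)[1]]))
  dropped <- 0L
  if ("in_region" %in% names(patients)) {
    patients$in_region <- as.logical(patients$in_region)
    dropped <- sum(!patients$in_region)
    keep <- patients$patient_id[patients$in_region]
    patients <- patients[patients$in_region, , drop = FALSE]
    dispensings <- dispensings[dispensings$patient_id %in% keep, , drop = FALSE]
  }
  obj <- structure(
    list(patients = patients, dispensings = dispensings,
         drug_reference = drug_reference, denominators = denominators),
    class = "claims_data"
  )
  if (is.null(period)) {
    period <- if (nrow(dispensings)) range(dispensings$dispense_date) else NULL
  } else period <- as.Date(period)
  attr(obj, "period") <- period
  attr(obj, "dropped_out_of_region") <- dropped
  validate_claims(obj)
  obj
}

validation_error <- function(file, row, field, msg) {
  stop(sprintf("validation error [%s%s%s]: %s",
               file,
               if (is.na(row)) "" else sprintf(", row %d", row),
               if (is.na(field)) "" else sprintf(", field `%s`", field),
               msg),
       call. = FALSE)
}

require_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    validation_error(file, NA, miss[1], "missing column")
}

#' Validate a claims dataset
#'
#' Checks column presence, parseable dates, category levels, positivity,
#' referential integrity (every dispensing's `patient_id` exists; every
#' dispensed `(inn, dosage_mg)` has a DDD entry) and uniqueness of
#' `patient_id`. Errors name the file, row and field at fault.
#'
#' @param claims a `claims_data` object.
#' @return the object, invisibly, when valid.
#' @export
validate_claims <- function(claims) {
  p <- claims$patients; d <- claims$dispensings
  ref <- claims$drug_reference; den <- claims$denominators
  require_columns(p, c("patient_id", "birth_date", "sex", "death_date"), "patients.csv")
  require_columns(d, c("patient_id", "dispense_date", "inn", "dosage_mg",
                       "units_dispensed", "route", "prescription_id",
                       "prescriber_specialty"), "dispensings.csv")
  require_columns(ref, c("inn", "dosage_mg", "ddd_mg"), "drug_reference.csv")
  require_columns(den, c("year", "count"), "population.csv")

  if (anyNA(p$birth_date))
    validation_error("patients.csv", which(is.na(p$birth_date))[1], "birth_date",
                     "unparseable or missing date")
  if (anyDuplicated(p$patient_id))
    validation_error("patients.csv", anyDuplicated(p$patient_id), "patient_id",
                     "duplicated patient_id")
  bad_sex <- !p$sex %in% c("male", "female")
  if (any(bad_sex))
    validation_error("patients.csv", which(bad_sex)[1], "sex",
                     "must be 'male' or 'female'")
  bad_death <- !is.na(p$death_date) & p$death_date < p$birth_date
  if (any(bad_death))
    validation_error("patients.csv", which(bad_death)[1], "death_date",
                     "death_date precedes birth_date")

  if (nrow(d)) {
    if (anyNA(d$dispense_date))
      validation_error("dispensings.csv", which(is.na(d$dispense_date))[1],
                       "dispense_date", "unparseable or missing date")
    orphan <- !d$patient_id %in% p$patient_id
    if (any(orphan))
      validation_error("dispensings.csv", which(orphan)[1], "patient_id",
                       sprintf("patient_id '%s' absent from patients.csv",
                               d$patient_id[which(orphan)[1]]))
    bad_inn <- !d$inn %in% PPI_INNS
    if (any(bad_inn))
      validation_error("dispensings.csv", which(bad_inn)[1], "inn",
                       sprintf("unknown INN '%s'", d$inn[which(bad_inn)[1]]))
    if (any(d$units_dispensed < 1))
      validation_error("dispensings.csv", which(d$units_dispensed < 1)[1],
                       "units_dispensed", "must be >= 1")
    if (any(d$dosage_mg <= 0))
      validation_error("dispensings.csv", which(d$dosage_mg <= 0)[1],
                       "dosage_mg", "must be > 0")
    bad_route <- !d$route %in% c("oral", "parenteral")
    if (any(bad_route))
      validation_error("dispensings.csv", which(bad_route)[1], "route",
                       "must be 'oral' or 'parenteral'")
    bad_spec <- !d$prescriber_specialty %in% SPECIALTIES
    if (any(bad_spec))
      validation_error("dispensings.csv", which(bad_spec)[1],
                       "prescriber_specialty",
                       sprintf("must be one of %s",
                               paste(SPECIALTIES, collapse = ", ")))
    key <- paste(d$inn, d$dosage_mg)
    refkey <- paste(ref$inn, ref$dosage_mg)
    no_ddd <- !key %in% refkey
    if (any(no_ddd))
      validation_error("dispensings.csv", which(no_ddd)[1], "inn",
                       sprintf("no DDD entry in drug_reference.csv for %s %g mg",
                               d$inn[which(no_ddd)[1]], d$dosage_mg[which(no_ddd)[1]]))
  }
  if (any(ref$ddd_mg <= 0))
    validation_error("drug_reference.csv", which(ref$ddd_mg <= 0)[1], "ddd_mg",
                     "must be > 0")
  if (nrow(den) && any(den$count <= 0))
    validation_error("population.csv", which(den$count <= 0)[1], "count",
                     "must be > 0")
  invisible(claims)
}

#' Read a claims dataset from a directory of CSV files
#'
#' Expects `patients.csv`, `dispensings.csv`, `drug_reference.csv` and
#' `population.csv` in `dir` (see the schemas in [claims_data()]). Dates are
#' ISO-8601 strings; empty `death_date` means alive.
#'
#' @param dir directory containing the four files.
#' @param period optional data-coverage period passed to [claims_data()].
#' @return a validated `claims_data` object.
#' @export
read_claims <- function(dir, period = NULL) {
  path <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop(sprintf("missing input file: %s", fp), call. = FALSE)
    fp
  }
  pat <- utils::read.csv(path("patients.csv"), colClasses = c(
    patient_id = "character", birth_date = "character", sex = "character",
    death_date = "character", in_region = "logical"))
  pat$death_date[pat$death_date == ""] <- NA
  disp <- utils::read.csv(path("dispensings.csv"), colClasses = c(
    patient_id = "character", dispense_date = "character", inn = "character",
    dosage_mg = "numeric", units_dispensed = "integer", route = "character",
    prescription_id = "character", prescriber_specialty = "character"))
  ref <- utils::read.csv(path("drug_reference.csv"), colClasses = c(
    inn = "character", dosage_mg = "numeric", ddd_mg = "numeric"))
  den <- utils::read.csv(path("population.csv"), colClasses = c(
    year = "integer", count = "numeric"))
  claims_data(pat, disp, ref, den, period = period)
}

#' Write a claims dataset to a directory of CSV files
#'
#' Inverse of [read_claims()]; a write-then-read round trip reproduces the
#' dataset exactly.
#'
#' @param claims a `claims_data` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(claims, dir) {
  stopifnot(inherits(claims, "claims_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- claims$patients
  p$birth_date <- as.character(p$birth_date)
  p$death_date <- ifelse(is.na(p$death_date), "", as.character(p$death_date))
  if (!"in_region" %in% names(p)) p$in_region <- TRUE
  d <- claims$dispensings
  d$dispense_date <- as.character(d$dispense_date)
  utils::write.csv(p, file.path(dir, "patients.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(d, file.path(dir, "dispensings.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(claims$drug_reference, file.path(dir, "drug_reference.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(claims$denominators, file.path(dir, "population.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Apply the study inclusion and exclusion rules
#'
#' Removes patients younger than 18 completed years at January 1 of
#' `anchor_year` and patients whose every dispensing is parenteral.
#' Patients with both routes are retained, but their parenteral rows are
#' dropped from the dispensing stream so that hospital parenteral doses never
#' enter coverage or DDD accounting. Idempotent.
#'
#' @param claims a `claims_data` object.
#' @param anchor_year year whose January 1 anchors the age rule.
#' @return a `claims_data` object with an `exclusion_log` attribute
#'   (data.frame `patient_id`, `rule`) and an `exclusion_counts` attribute.
#' @export
apply_exclusions <- function(claims, anchor_year) {
  stopifnot(inherits(claims, "claims_data"))
  p <- claims$patients; d <- claims$dispensings

  age <- age_at_jan1(p$birth_date, anchor_year)
  under18 <- p$patient_id[age < 18L]

  with_disp <- unique(d$patient_id)
  oral_pat <- unique(d$patient_id[d$route == "oral"])
  parenteral_only <- setdiff(with_disp, oral_pat)
  parenteral_only <- setdiff(parenteral_only, under18) # log each patient once

  log <- rbind(
    if (length(under18)) data.frame(patient_id = under18, rule = "age_under_18"),
    if (length(parenteral_only)) data.frame(patient_id = parenteral_only,
                                            rule = "parenteral_only")
  )
  if (is.null(log)) log <- data.frame(patient_id = character(), rule = character())

  drop <- c(under18, parenteral_only)
  p2 <- p[!p$patient_id %in% drop, , drop = FALSE]
  d2 <- d[!d$patient_id %in% drop & d$route == "oral", , drop = FALSE]

  out <- structure(
    list(patients = p2, dispensings = d2,
         drug_reference = claims$drug_reference,
         denominators = claims$denominators),
    class = "claims_data"
  )
  attr(out, "period") <- attr(claims, "period")
  attr(out, "dropped_out_of_region") <- attr(claims, "dropped_out_of_region")
  attr(out, "exclusion_log") <- log
  attr(out, "exclusion_counts") <- c(
    age_under_18 = length(under18),
    parenteral_only = length(parenteral_only),
    parenteral_rows_dropped = sum(d$route == "parenteral" &
                                    !d$patient_id %in% drop)
  )
  out
}

#' @export
print.claims_data <- function(x, ...) {
  per <- attr(x, "period")
  cat("<claims_data>\n")
  cat(sprintf("  patients:     %d\n", nrow(x$patients)))
  cat(sprintf("  dispensings:  %d\n", nrow(x$dispensings)))
  cat(sprintf("  drug_reference entries: %d\n", nrow(x$drug_reference)))
  if (!is.null(per))
    cat(sprintf("  period:       %s .. %s\n", per[1], per[2]))
  invisible(x)
}
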