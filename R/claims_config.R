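# Generator configuration for the synthetic claims simulator.

#' Default dispensed-product mix
#'
#' Event shares per INN x dosage used by the simulator, patterned on the
#' product distribution observed among chronic users of a French regional
#' claims population (esomeprazole-dominated, all five oral PPIs present);
#' normalized to sum to 1.
#'
#' @return named numeric vector, names `"<inn>_<dosage>mg"`.
#' @export
default_drug_mix <- function() {
  m <- c(
    esomeprazole_10mg = 0.12, esomeprazole_20mg = 22.31, esomeprazole_40mg = 17.88,
    lansoprazole_15mg = 6.75, lansoprazole_30mg = 5.84,
    omeprazole_10mg = 3.66, omeprazole_20mg = 14.73,
    pantoprazole_20mg = 12.02, pantoprazole_40mg = 7.57,
    rabeprazole_10mg = 3.74, rabeprazole_20mg = 5.39
  )
  m / sum(m)
}

parse_drug_mix <- function(mix) {
  nm <- names(mix)
  inn <- sub("_.*$", "", nm)
  dos <- as.numeric(sub("mg$", "", sub("^.*_", "", nm)))
  data.frame(inn = inn, dosage_mg = dos, p = as.numeric(mix))
}

#' Synthetic claims generator configuration
#'
#' Parameters of the seeded synthetic dispensing-claims generator. Defaults
#' emulate the study conditions of a regional adult chronic-PPI-use cohort
#' observed October 2015 - December 2020: an elderly, slightly female-majority
#' user population, a ~12.5% annual discontinuation hazard among chronic
#' users, high refill adherence, general-practitioner-dominated prescribing
#' and the default product mix of [default_drug_mix()].
#'
#' @param n_patients number of patients to simulate.
#' @param study_start,study_end data-coverage period (`Date`).
#' @param annual_new_chronic_probability probability per anchor year that a
#'   non-chronic patient initiates chronic use (becomes chronic at that
#'   anchor).
#' @param annual_discontinuation_probability probability per chronic
#'   patient-year of discontinuing (no refill in November-December).
#' @param adherence_coverage_range uniform bounds for the per-patient refill
#'   coverage fraction; governs inter-box gaps.
#' @param resumption_probability probability that a discontinuer resumes
#'   treatment (a new episode, after a gap of at least two months).
#' @param annual_death_probability per-year death probability.
#' @param age_distribution named vector `c(mean=, sd=)`, years; truncated at
#'   18 at `study_start`.
#' @param female_fraction probability of female sex.
#' @param drug_mix named probability vector over `"<inn>_<dosage>mg"` keys.
#' @param prescriber_mix named probability vector over
#'   `general_practitioner`, `specialist`, `institution`.
#' @param occasional_user_fraction fraction of patients who, outside any
#'   chronic period, receive sporadic short courses (1-2 boxes in a year) and
#'   never qualify as chronic from them.
#' @param parenteral_fraction per-dispensing probability of a parenteral
#'   route record; 0 by default (parenteral rows exist for exclusion tests,
#'   not the main process).
#' @param seed integer RNG seed; every draw derives from it.
#' @return validated object of class `claims_config`.
#' @export
claims_config <- function(n_patients = 10000L,
                          study_start = as.Date("2015-10-01"),
                          study_end = as.Date("2020-12-31"),
                          annual_new_chronic_probability = 0.015,
                          annual_discontinuation_probability = 0.125,
                          adherence_coverage_range = c(0.85, 0.98),
                          resumption_probability = 0.30,
                          annual_death_probability = 0.03,
                          age_distribution = c(mean = 70, sd = 15),
                          female_fraction = 0.544,
                          drug_mix = default_drug_mix(),
                          prescriber_mix = c(general_practitioner = 0.88,
                                             specialist = 0.015,
                                             institution = 0.105),
                          occasional_user_fraction = 0.10,
                          parenteral_fraction = 0,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    annual_new_chronic_probability = annual_new_chronic_probability,
    annual_discontinuation_probability = annual_discontinuation_probability,
    adherence_coverage_range = as.numeric(adherence_coverage_range),
    resumption_probability = resumption_probability,
    annual_death_probability = annual_death_probability,
    age_distribution = age_distribution,
    female_fraction = female_fraction,
    drug_mix = drug_mix,
    prescriber_mix = prescriber_mix,
    occasional_user_fraction = occasional_user_fraction,
    parenteral_fraction = parenteral_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "claims_config"
  validate_claims_config(cfg)
  cfg
}

validate_claims_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1)
    stop_field("n_patients", "must be a positive integer")
  if (is.na(cfg$study_start) || is.na(cfg$study_end) ||
      cfg$study_end <= cfg$study_start)
    stop_field("study_end", "must be a date after study_start")
  probs <- c("annual_new_chronic_probability",
             "annual_discontinuation_probability", "resumption_probability",
             "annual_death_probability", "female_fraction",
             "occasional_user_fraction", "parenteral_fraction")
  for (f in probs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_field(f, "must be a probability in [0, 1]")
  }
  acr <- cfg$adherence_coverage_range
  if (length(acr) != 2L || any(acr <= 0 | acr > 1) || acr[1] > acr[2])
    stop_field("adherence_coverage_range", "must be bounds within (0, 1]")
  ad <- cfg$age_distribution
  if (!all(c("mean", "sd") %in% names(ad)) || ad[["sd"]] <= 0)
    stop_field("age_distribution", "needs named mean and positive sd")
  if (abs(sum(cfg$drug_mix) - 1) > 1e-9 || any(cfg$drug_mix < 0))
    stop_field("drug_mix", "probabilities must be non-negative and sum to 1")
  pm <- cfg$prescriber_mix
  if (!setequal(names(pm), SPECIALTIES) || abs(sum(pm) - 1) > 1e-9 || any(pm < 0))
    stop_field("prescriber_mix",
               "needs general_practitioner/specialist/institution summing to 1")
  if (is.na(cfg$seed)) stop_field("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.claims_config <- function(x, ...) {
  cat("<claims_config>\n")
  cat(sprintf("  %d patients, %s .. %s, seed %d\n",
              x$n_patients, x$study_start, x$study_end, x$seed))
  cat(sprintf("  new-chronic %.3f/yr, discontinuation %.3f/yr, resumption %.2f, death %.3f/yr\n",
              x$annual_new_chronic_probability,
              x$annual_discontinuation_probability,
              x$resumption_probability, x$annual_death_probability))
  invisible(x)
}

#' Anchor years covered by a data period
#'
#' Years `y` whose full trailing quarter (Oct 1 - Dec 31 of `y - 1`) and
#' January 1 both lie inside `[start, end]`.
#'
#' @param start,end `Date` scalars.
#' @return integer vector of anchor years.
#' @export
anchor_years <- function(start, end) {
  ys <- (date_year(start)):(date_year(end) + 1L)
  ys[vapply(ys, function(y) ymd(y - 1L, 10L, 1L) >= start && ymd(y, 1L, 1L) <= end,
            NA)]
}
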