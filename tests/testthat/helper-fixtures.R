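# Fixture builders used across test files. All data is generated in code.

# A dispensing row with sensible defaults.
disp_row <- function(patient_id, date, units = 28L, route = "oral",
                     inn = "omeprazole", dosage_mg = 20,
                     prescription_id = "rx1",
                     prescriber_specialty = "general_practitioner") {
  data.frame(patient_id = patient_id, dispense_date = as.Date(date), inn = inn,
             dosage_mg = dosage_mg, units_dispensed = as.integer(units),
             route = route, prescription_id = prescription_id,
             prescriber_specialty = prescriber_specialty,
             stringsAsFactors = FALSE)
}

patient_row <- function(patient_id, birth = "1950-06-15", sex = "female",
                        death = NA, in_region = TRUE) {
  data.frame(patient_id = patient_id, birth_date = as.Date(birth), sex = sex,
             death_date = as.Date(death), in_region = in_region,
             stringsAsFactors = FALSE)
}

fixture_claims <- function(patients, dispensings,
                           period = as.Date(c("2015-10-01", "2020-12-31"))) {
  claims_data(patients, dispensings,
              drug_reference = default_drug_reference(),
              denominators = data.frame(year = 2016:2020, count = 1000),
              period = period)
}

# Random mini-dataset for oracle comparisons: up to `n_pat` patients with 0-12
# dispensings each at arbitrary dates/quantities, occasional deaths.
random_mini_claims <- function(n_pat = sample(2:20, 1)) {
  dates <- seq(as.Date("2015-10-01"), as.Date("2018-12-31"), by = "day")
  pats <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    death <- if (runif(1) < 0.15) sample(dates[dates >= as.Date("2016-06-01")], 1) else NA
    patient_row(sprintf("M%03d", i), birth = as.Date("1940-01-01") + sample(0:15000, 1),
                sex = sample(c("male", "female"), 1), death = death)
  }))
  disp <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    k <- sample(0:12, 1)
    if (k == 0) return(NULL)
    death <- pats$death_date[i]
    ok <- if (is.na(death)) dates else dates[dates <= death]
    if (!length(ok)) return(NULL)
    disp_row(sprintf("M%03d", i), sample(ok, k, replace = TRUE),
             units = sample(1:40, k, replace = TRUE),
             prescription_id = sprintf("rx%d", sample(1:4, k, replace = TRUE)))
  }))
  if (is.null(disp)) disp <- disp_row("M001", "2016-01-01")[0, ]
  fixture_claims(pats, disp, period = as.Date(c("2015-10-01", "2018-12-31")))
}

# Shared large simulation (expensive; built once per session).
.sim_cache <- new.env(parent = emptyenv())
big_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_claims(claims_config(
      n_patients = 10000L, seed = 424243L,
      annual_new_chronic_probability = 0.05,
      annual_death_probability = 0))
  }
  .sim_cache$sim
}
big_status <- function() {
  if (is.null(.sim_cache$status))
    .sim_cache$status <- chronic_status_table(big_sim()$claims, 2016:2020)
  .sim_cache$status
}
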