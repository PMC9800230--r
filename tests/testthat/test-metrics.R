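# Cohort metrics: sets, rates, DDD, mix, prescribers, trend, demographics.

test_that("rate_pct rounds half away from zero and is homogeneous", {
  expect_equal(rate_pct(46308, 3757600), 1.2)
  expect_equal(rate_pct(167751, 3801800), 4.4)
  expect_equal(rate_pct(0, 100), 0)
  expect_equal(rate_pct(100, 100), 100)
  expect_equal(rate_pct(125, 1000, 1), rate_pct(250, 2000, 1))
  expect_equal(rate_pct(1, 16, 1), 6.3) # 6.25 rounds up, not to even
  expect_error(rate_pct(1, 0), "population")
})

test_that("discontinuation proportions reproduce published arithmetic", {
  expect_equal(rate_pct(19551, 156721, 1), 12.5)
  expect_equal(rate_pct(20809, 167751, 1), 12.4)
  # at two decimals the count arithmetic gives 12.48 / 12.40; published
  # two-decimal figures are not recoverable from the printed counts
  expect_equal(rate_pct(19551, 156721, 2), 12.48)
  expect_equal(rate_pct(20809, 167751, 2), 12.40)
})

test_that("prevalent/incident sets obey set algebra on simulated data", {
  st <- big_status()
  for (y in 2017:2020) {
    prev <- prevalent_chronic(st, y)
    inc <- incident_chronic(st, y)
    expect_true(all(inc %in% prev))
    disc <- st$patient_id[st$year == y & st$discontinued]
    expect_true(all(disc %in% prev))
    deaths <- st$patient_id[st$year == y & st$discontinued & st$died_before_cutoff]
    expect_lte(length(deaths), length(disc))
  }
  # chronic in consecutive years is incident at most once
  both <- intersect(prevalent_chronic(st, 2018), prevalent_chronic(st, 2019))
  expect_length(intersect(both, incident_chronic(st, 2019)), 0)
  expect_error(prevalent_chronic(st, 1999), "not covered")
})

test_that("planted prevalence is recovered within 3 binomial SEs at n = 10,000", {
  sim <- simulate_claims(claims_config(
    n_patients = 10000, seed = 52025, annual_new_chronic_probability = 0.044,
    annual_death_probability = 0))
  st <- chronic_status_table(sim$claims, 2016)
  share <- length(prevalent_chronic(st, 2016)) / 10000
  se <- sqrt(0.044 * (1 - 0.044) / 10000)
  expect_lt(abs(share - 0.044), 3 * se)
})

test_that("DDD accounting multiplies units by dosage over DDD strength", {
  ref <- data.frame(inn = "omeprazole", dosage_mg = c(20, 10), ddd_mg = 20)
  daily <- disp_row("A", seq(as.Date("2017-01-01"), as.Date("2017-12-31"), by = "day"),
                    units = 1L)
  expect_equal(unname(annual_ddd_per_patient(daily, 2017, ref)["A"]), 365)
  half <- disp_row("A", "2017-03-01", units = 100, dosage_mg = 10)
  expect_equal(unname(annual_ddd_per_patient(half, 2017, ref)["A"]), 50)
  expect_length(annual_ddd_per_patient(daily, 2019, ref), 0)
  expect_equal(median_annual_ddd(daily, 2017, ref, c("A", "B")), 365 / 2) # B has 0
  expect_error(median_annual_ddd(daily, 2017, ref, character(0)), "empty")
})

test_that("dispensation mix gives event shares summing to ~100", {
  one <- disp_row("A", c("2017-01-10", "2017-02-10"), units = 28)
  m1 <- dispensation_mix(one, 2017, "A")
  expect_equal(m1$pct, 100)
  two <- rbind(disp_row("A", "2017-01-10"),
               disp_row("A", "2017-02-10", inn = "pantoprazole", dosage_mg = 40))
  m2 <- dispensation_mix(two, 2017, "A")
  expect_equal(m2$pct, c(50, 50))
  mix <- dispensation_mix(big_sim()$claims$dispensings, 2019,
                          prevalent_chronic(big_status(), 2019))
  expect_true(all(mix$pct >= 0))
  expect_lt(abs(sum(mix$pct) - 100), 0.06)
  p <- unname(default_drug_mix()["esomeprazole_20mg"])
  n <- sum(mix$n_events)
  got <- mix$pct[mix$inn == "esomeprazole" & mix$dosage_mg == 20] / 100
  expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n))
  expect_error(dispensation_mix(one, 2019, "A"), "no dispensings")
})

test_that("prescriber attribution distinguishes initiation from first renewal", {
  pa <- prescriber_attribution(rbind(
    disp_row("A", "2017-01-05", prescription_id = "r1",
             prescriber_specialty = "general_practitioner"),
    disp_row("A", "2017-02-05", prescription_id = "r1",
             prescriber_specialty = "general_practitioner"),
    disp_row("A", "2017-03-05", prescription_id = "r2",
             prescriber_specialty = "specialist"),
    disp_row("B", "2017-06-01", prescription_id = "r9",
             prescriber_specialty = "institution")))
  init <- pa$initiations
  expect_equal(init$n[init$specialty == "general_practitioner"], 1L)
  expect_equal(init$n[init$specialty == "institution"], 1L)
  ren <- pa$first_renewals
  expect_equal(sum(ren$n), 1L) # B never renews: single prescription id
  expect_equal(ren$n[ren$specialty == "specialist"], 1L)

  solo <- prescriber_attribution(disp_row("C", "2017-01-01",
                                          prescriber_specialty = "general_practitioner"))
  expect_equal(solo$initiations$pct[solo$initiations$specialty == "general_practitioner"],
               100)
  expect_equal(sum(solo$first_renewals$n), 0L)
})

test_that("renewal share arithmetic reproduces published percentages", {
  n <- c(general_practitioner = 2402263, institution = 281311, specialist = 5221)
  tot <- sum(n)
  expect_equal(rate_pct(n[["general_practitioner"]], tot), 89.3)
  expect_equal(rate_pct(n[["institution"]], tot), 10.5)
  expect_equal(rate_pct(n[["specialist"]], tot), 0.2)
})

test_that("trend test is null on flat proportions and agrees with a permutation oracle", {
  flat <- trend_test(c(50, 100, 150), c(1000, 2000, 3000))
  expect_lt(flat$statistic, 1e-9)
  expect_equal(flat$p_value, 1)

  counts <- c(5, 9, 14); pops <- c(60, 55, 50)
  tt <- trend_test(counts, pops)
  # Monte-Carlo permutation of the pooled successes over year slots
  set.seed(4242)
  nsim <- 4000
  slots <- rep.int(seq_along(pops), pops)
  pool <- sum(counts)
  stat_of <- function(x) trend_test(x, pops)$statistic
  obs <- stat_of(counts)
  hits <- 0L
  for (b in seq_len(nsim)) {
    assign_to <- sample(slots, pool)
    x <- tabulate(assign_to, nbins = length(pops))
    if (stat_of(x) >= obs - 1e-12) hits <- hits + 1L
  }
  p_perm <- hits / nsim
  mc_se <- sqrt(p_perm * (1 - p_perm) / nsim)
  expect_lt(abs(tt$p_value - p_perm), 4 * mc_se + 0.01)
  expect_error(trend_test(c(1, 2), c(0, 10)), "populations")
})

test_that("demographics use completed age at Jan 1 with documented conventions", {
  one <- patient_row("A", birth = "1967-01-01", sex = "male")
  d1 <- demographics_summary(one, 2017)
  expect_equal(d1$age_mean, 50); expect_equal(d1$age_median, 50)
  expect_true(is.na(d1$age_sd)) # sd undefined for a single patient
  two <- rbind(patient_row("A", birth = "1956-06-15"),
               patient_row("B", birth = "1946-06-15"))
  d2 <- demographics_summary(two, 2017)
  expect_equal(d2$age_mean, 65); expect_equal(d2$age_median, 65)
  expect_equal(d2$male_pct, 0); expect_equal(d2$female_pct, 100)
  expect_error(demographics_summary(two[0, ], 2017), "empty")
})

test_that("pooled mean is weight-consistent", {
  expect_equal(pooled_mean(c(2, 4, 6), c(1, 1, 1)), 4)
  expect_equal(round_half_up(pooled_mean(
    c(67.6, 68, 68.2, 66.4), c(46308, 47684, 47931, 77222)), 1), 67.4)
  expect_error(pooled_mean(1:2, c(0, 0)), "weights")
})

test_that("estimated incidence matches planted truth on the large simulation", {
  sim <- big_sim(); st <- big_status()
  gt <- sim$ground_truth$status
  for (y in 2017:2020) {
    expect_equal(sort(incident_chronic(st, y)),
                 sort(gt$patient_id[gt$year == y & gt$true_incident %in% TRUE]))
  }
})
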