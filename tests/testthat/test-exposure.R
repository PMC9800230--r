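# Exposure algebra: supply intervals, dose counting, chronic/incident/
# discontinuation classification, episode segmentation, threshold sensitivity.

test_that("supply intervals follow 1 unit = 1 day arithmetic", {
  iv <- supply_interval(as.Date("2016-12-15"), 30L)
  expect_equal(iv$end, as.Date("2017-01-13")) # carries over Jan 1
  iv1 <- supply_interval(as.Date("2017-05-05"), 1L)
  expect_equal(iv1$start, iv1$end)
  iv92 <- supply_interval(as.Date("2016-10-01"), 92L)
  expect_equal(iv92$end, as.Date("2016-12-31"))
  expect_error(supply_interval(as.Date("2017-01-01"), 10L, route = "parenteral"),
               "oral")
})

test_that("dose counting respects closed window boundaries", {
  w <- chronic_window(2017)
  expect_identical(w$n_days, 92L)
  expect_equal(doses_in_window(disp_row("A", "2016-01-01")[0, ], w), 0L)
  expect_equal(doses_in_window(disp_row("A", "2016-11-05", units = 74), w), 74L)
  expect_equal(doses_in_window(disp_row("A", "2016-09-30", units = 50), w), 0L)
  edge <- rbind(disp_row("A", "2016-10-01", units = 3),
                disp_row("A", "2016-12-31", units = 5))
  expect_equal(doses_in_window(edge, w), 8L)
})

test_that("temporal coverage matches the 74-dose / 80% identity and caps at 1", {
  w <- chronic_window(2017)
  expect_equal(temporal_coverage(disp_row("A", "2016-10-10", units = 74), w), 74 / 92)
  expect_true(temporal_coverage(disp_row("A", "2016-10-10", units = 74), w) >= 0.80)
  expect_lt(temporal_coverage(disp_row("A", "2016-10-10", units = 73), w), 0.80)
  expect_equal(temporal_coverage(disp_row("A", "2016-10-10", units = 120), w), 1)
})

test_that("chronic classification thresholds at exactly 74 doses", {
  expect_true(classify_chronic(disp_row("A", "2016-10-15", units = 74), 2017))
  expect_false(classify_chronic(disp_row("A", "2016-10-15", units = 73), 2017))
  daily <- disp_row("A", seq(as.Date("2016-10-01"), as.Date("2016-12-31"), by = "day"),
                    units = 1L, prescription_id = "rx1")
  expect_true(classify_chronic(daily, 2017))
  expect_error(
    classify_chronic(disp_row("A", "2016-10-15", units = 74), 2015,
                     data_range = as.Date(c("2015-10-01", "2020-12-31"))),
    "outside")
})

test_that("incident status requires not being a user on Jan 1 of the year before", {
  first_ever <- disp_row("A", "2016-10-01", units = 74)
  expect_true(classify_incident(first_ever, 2017))
  # a December box whose supply covers Jan 1 of year-1 blocks incident status
  carry <- rbind(disp_row("A", "2015-12-20", units = 30),
                 disp_row("A", "2016-10-01", units = 74))
  expect_true(classify_chronic(carry, 2017))
  expect_false(classify_incident(carry, 2017))
  expect_error(
    classify_incident(first_ever, 2016,
                      data_range = as.Date(c("2015-10-01", "2020-12-31"))),
    "precedes")
})

test_that("discontinuation = no refill in November-December, deaths flagged", {
  stop_oct <- rbind(disp_row("A", "2016-10-15", units = 80),
                    disp_row("A", "2017-10-15", units = 28))
  d <- detect_discontinuation(stop_oct, 2017)
  expect_true(d$discontinued); expect_false(d$died_before_cutoff)

  refill_dec <- rbind(stop_oct, disp_row("A", "2017-12-05", units = 28))
  d2 <- detect_discontinuation(refill_dec, 2017)
  expect_false(d2$discontinued)

  dead <- rbind(disp_row("A", "2016-10-15", units = 80),
                disp_row("A", "2017-08-20", units = 14))
  d3 <- detect_discontinuation(dead, 2017, death_date = as.Date("2017-09-01"))
  expect_true(d3$discontinued); expect_true(d3$died_before_cutoff)

  expect_error(detect_discontinuation(disp_row("A", "2017-01-01", units = 5), 2017),
               "non-chronic")
})

test_that("episode segmentation splits at >= 61 uncovered days, not below", {
  one <- disp_row("A", "2017-03-02", units = 30) # supply Mar 2 - Mar 31
  expect_equal(nrow(segment_episodes(one)), 1L)
  expect_equal(segment_episodes(one)$n_doses, 30L)

  split <- rbind(one, disp_row("A", "2017-06-01", units = 30)) # 61 uncovered
  expect_equal(nrow(segment_episodes(split)), 2L)

  merged <- rbind(one, disp_row("A", "2017-05-31", units = 30)) # 60 uncovered
  expect_equal(nrow(segment_episodes(merged)), 1L)
  expect_equal(segment_episodes(merged)$n_doses, 60L)
})

test_that("episode output is invariant to record order", {
  set.seed(31)
  for (rep in 1:20) {
    cl <- random_mini_claims(4)
    d <- cl$dispensings
    if (nrow(d) < 2) next
    for (pid in unique(d$patient_id)) {
      sub <- d[d$patient_id == pid, ]
      shuf <- sub[sample(nrow(sub)), ]
      expect_equal(segment_episodes(shuf), segment_episodes(sub))
    }
  }
})

test_that("sensitivity counts use ceil(t * 92) dose cutoffs and are monotone", {
  pats <- rbind(patient_row("A"), patient_row("B"), patient_row("C"))
  disp <- rbind(disp_row("A", "2016-11-01", units = 65),
                disp_row("B", "2016-11-01", units = 74),
                disp_row("C", "2016-11-01", units = 79))
  cl <- fixture_claims(pats, disp)
  sens <- threshold_sensitivity(cl, 2017, c(0.75, 0.80, 0.85))
  expect_equal(sens$dose_threshold, c(69L, 74L, 79L))
  expect_equal(sens$chronic_count, c(2L, 2L, 1L))
  same <- threshold_sensitivity(cl, 2017, c(0.8, 0.8))
  expect_equal(same$chronic_count[1], same$chronic_count[2])
  expect_error(threshold_sensitivity(cl, 2017, c(0, 0.5)), "\\(0, 1\\]")
})

test_that("adding a dispensing never destroys chronic status nor creates a discontinuation", {
  set.seed(77)
  for (rep in 1:25) {
    cl <- random_mini_claims(5)
    st <- chronic_status_table(cl, 2017)
    extra_date <- sample(seq(as.Date("2016-10-01"), as.Date("2017-12-31"), by = "day"), 1)
    pid <- sample(cl$patients$patient_id, 1)
    if (!is.na(cl$patients$death_date[cl$patients$patient_id == pid]) &&
        extra_date > cl$patients$death_date[cl$patients$patient_id == pid]) next
    cl2 <- cl
    cl2$dispensings <- rbind(cl$dispensings, disp_row(pid, extra_date, units = 10))
    st2 <- chronic_status_table(cl2, 2017)
    m <- match(paste(st$patient_id, st$year), paste(st2$patient_id, st2$year))
    expect_true(all(st2$chronic[m] >= st$chronic))          # monotone in data
    expect_true(all(st2$discontinued[m] <= st$discontinued |
                      st2$chronic[m] > st$chronic))         # no new disc among same chronic
  }
})

test_that("vectorized status table agrees with per-patient classification", {
  set.seed(5)
  cl <- random_mini_claims(12)
  st <- chronic_status_table(cl, 2017:2018)
  for (i in seq_len(nrow(cl$patients))) {
    pid <- cl$patients$patient_id[i]
    rec <- cl$dispensings[cl$dispensings$patient_id == pid, ]
    death <- cl$patients$death_date[i]
    for (y in 2017:2018) {
      row <- st[st$patient_id == pid & st$year == y, ]
      alive <- is.na(death) || death >= as.Date(sprintf("%d-01-01", y))
      expect_identical(row$chronic, classify_chronic(rec, y) && alive)
      if (row$chronic) {
        expect_identical(row$incident, classify_incident(rec, y))
        dd <- detect_discontinuation(rec, y, death)
        expect_identical(row$discontinued, dd$discontinued)
        expect_identical(row$died_before_cutoff, dd$died_before_cutoff)
      }
    }
  }
})
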