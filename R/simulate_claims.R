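# Seeded synthetic dispensing-claims generator with planted ground truth.
#
# The behavioural model (see the methods vignette):
#   * each patient owns two RNG sub-streams derived from (seed, index), so
#     adding patients never perturbs existing ones;
#   * dispensings are "boxes" (mostly 28, sometimes 14 units; 1 unit = 1 day
#     of supply) chained with geometric inter-box gaps set by a per-patient
#     adherence coverage, truncated at 20 days so refill delays never split
#     an episode;
#   * a non-chronic patient initiates chronic use at an anchor year with the
#     configured probability (first box in early October of the previous
#     year); a chronic patient-year discontinues with the configured hazard
#     (refills stop by late October, none in November-December); a
#     discontinuer may resume the following spring, which makes a new episode
#     after a >= 61-day uncovered gap;
#   * every planted chronic anchor is guaranteed >= 74 units dated inside its
#     Oct-Dec window by an early-refill top-up step;
#   * deaths truncate the schedule; labels for death years are derived from
#     the truncated schedule so generated data and labels always agree.

GEN_MULT <- 507468114 # 2654435761 mod 2^31-1; 2^31-1 is prime so i -> i*m is injective

patient_stream_seed <- function(seed, i, k) {
  as.integer((as.numeric(seed) %% 2147483647 + i * GEN_MULT + k * 97531) %% 2147483647)
}

#' Example DDD reference table
#'
#' Per-dosage defined-daily-dose values for the five oral PPIs, used by the
#' simulator and shipped as `inst/extdata/drug_reference.csv`. These are
#' plausible example maintenance-dose values for a synthetic dataset, not an
#' asserted transcription of the WHO ATC/DDD index; real studies must supply
#' their own reference table.
#'
#' @return data.frame `inn`, `dosage_mg`, `ddd_mg`.
#' @export
default_drug_reference <- function() {
  ddd <- c(esomeprazole = 30, lansoprazole = 30, omeprazole = 20,
           pantoprazole = 40, rabeprazole = 20)
  mix <- parse_drug_mix(default_drug_mix())
  data.frame(inn = mix$inn, dosage_mg = mix$dosage_mg,
             ddd_mg = unname(ddd[mix$inn]))
}

#' Simulate the patient table
#'
#' Draws `n_patients` adults: ages normal (truncated at 18 at `study_start`),
#' sex Bernoulli(`female_fraction`), yearly deaths with
#' `annual_death_probability`. Fully determined by `config$seed`.
#'
#' @param config a [claims_config()].
#' @return data.frame `patient_id`, `birth_date`, `sex`, `death_date`,
#'   `in_region`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "claims_config"))
  n <- config$n_patients
  mu <- config$age_distribution[["mean"]]; sdv <- config$age_distribution[["sd"]]
  p_lo <- stats::pnorm(18, mu, sdv)
  yrs <- date_year(config$study_start):date_year(config$study_end)

  birth <- numeric(n); sex <- character(n); death <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    set.seed(patient_stream_seed(config$seed, i, 1L))
    age <- stats::qnorm(p_lo + stats::runif(1) * (1 - p_lo), mu, sdv)
    birth[i] <- as.numeric(config$study_start) - round(age * 365.25)
    sex[i] <- if (stats::runif(1) < config$female_fraction) "female" else "male"
    for (yy in yrs) {
      if (stats::runif(1) < config$annual_death_probability) {
        lo <- max(ymd(yy, 1L, 1L), config$study_start)
        hi <- min(ymd(yy, 12L, 31L), config$study_end)
        death[i] <- as.numeric(lo) + sample.int(as.integer(hi - lo) + 1L, 1L) - 1L
        break
      }
    }
  }
  data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    birth_date = as.Date(birth, origin = "1970-01-01"),
    sex = sex,
    death_date = as.Date(death, origin = "1970-01-01"),
    in_region = TRUE
  )
}

# Merge one patient's boxes (numeric day vectors) into episode intervals
# under the >= gap_days uncovered-run rule.
boxes_to_episodes <- function(dates, units, gap_days = 61L) {
  if (!length(dates)) return(NULL)
  o <- order(dates, units)
  dates <- dates[o]; units <- units[o]
  ends <- dates + units - 1
  s <- dates[1]; e <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(dates) > 1L) for (k in 2:length(dates)) {
    if (dates[k] - e - 1 >= gap_days) {
      out_s <- c(out_s, s); out_e <- c(out_e, e)
      s <- dates[k]; e <- ends[k]
    } else e <- max(e, ends[k])
  }
  cbind(start = c(out_s, s), end = c(out_e, e))
}

#' Simulate the dispensing stream with planted ground truth
#'
#' Generates the dispensing claims of `patients` under `config` and the
#' ground-truth labels the trajectories imply: per patient-year chronic /
#' incident / discontinued flags and per-patient episode intervals.
#' Incident truth is `NA` for the first anchor when January 1 of the year
#' before precedes the data period.
#'
#' @param patients the table produced by [simulate_population()] under the
#'   same `config`.
#' @param config a [claims_config()].
#' @return list with `dispensings` (data.frame in the dispensings.csv schema)
#'   and `ground_truth` (list of `status` and `episodes` data.frames).
#' @export
simulate_dispensings <- function(patients, config) {
  stopifnot(inherits(config, "claims_config"))
  n <- config$n_patients
  if (nrow(patients) != n || !identical(patients$patient_id, sprintf("P%06d", seq_len(n))))
    stop("`patients` was not produced by simulate_population() under this config",
         call. = FALSE)

  anchors <- anchor_years(config$study_start, config$study_end)
  nA <- length(anchors)
  end_num <- as.numeric(config$study_end)
  start_num <- as.numeric(config$study_start)
  mixdf <- parse_drug_mix(config$drug_mix)
  pm <- config$prescriber_mix[SPECIALTIES]
  p_new <- config$annual_new_chronic_probability
  p_disc <- config$annual_discontinuation_probability
  p_res <- config$resumption_probability
  acr <- config$adherence_coverage_range
  jan1s <- vapply(anchors, function(y) as.numeric(ymd(y, 1L, 1L)), 1)
  wstarts <- vapply(anchors, function(y) as.numeric(ymd(y - 1L, 10L, 1L)), 1)
  dec31s <- vapply(anchors, function(y) as.numeric(ymd(y, 12L, 31L)), 1)
  all_years <- date_year(config$study_start):date_year(config$study_end)

  disp_acc <- vector("list", n)
  status_acc <- vector("list", n)
  epi_acc <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(patient_stream_seed(config$seed, i, 2L))
    pid <- patients$patient_id[i]
    death_num <- if (is.na(patients$death_date[i])) Inf
                 else as.numeric(patients$death_date[i])
    bound <- min(end_num, death_num)
    occasional <- stats::runif(1) < config$occasional_user_fraction
    cov <- stats::runif(1, acr[1], acr[2])

    bdates <- numeric(0); bunits <- integer(0) # oral boxes
    chronic <- logical(nA); disc <- logical(nA)

    emit_chain <- function(from, until) {
      cursor <- from
      while (cursor <= min(until, bound)) {
        u <- if (stats::runif(1) < 0.85) 28L else 14L
        bdates <<- c(bdates, cursor); bunits <<- c(bunits, u)
        g_mean <- u * (1 - cov) / cov
        gap <- min(stats::rgeom(1L, 1 / (1 + g_mean)), 20L)
        cursor <- cursor + u + gap
      }
      cursor
    }
    topup_window <- function(aidx) {
      w0 <- wstarts[aidx]; w1 <- w0 + 91
      repeat {
        have <- sum(bunits[bdates >= w0 & bdates <= w1])
        if (have >= 74L) break
        bdates <<- c(bdates, w0 + sample.int(92L, 1L) - 1L)
        bunits <<- c(bunits, 28L)
      }
    }

    a <- 1L
    next_eligible <- 1L
    resume_date <- NA_real_; resume_idx <- NA_integer_
    while (a <= nA) {
      if (death_num < jan1s[a]) break
      start_date <- NA_real_
      if (!is.na(resume_idx) && a == resume_idx) {
        start_date <- resume_date; resume_date <- NA_real_; resume_idx <- NA_integer_
      } else if (is.na(resume_idx) && a >= next_eligible &&
                 stats::runif(1) < p_new) {
        start_date <- wstarts[a] + (sample.int(5L, 1L) - 1L)
      }
      if (is.na(start_date)) { a <- a + 1L; next }

      # pre-anchor run, then guarantee the anchor's Oct-Dec window
      cursor <- emit_chain(start_date, jan1s[a] - 1)
      topup_window(a)
      repeat { # chronic years of this period
        if (a > nA || death_num < jan1s[a]) break
        y <- anchors[a]
        chronic[a] <- TRUE
        dies <- death_num <= dec31s[a]
        if (!dies && stats::runif(1) < p_disc) {
          stop_bound <- as.numeric(ymd(y, 2L, 1L)) + sample.int(260L, 1L) - 1L
          cursor <- emit_chain(cursor, stop_bound)
          disc[a] <- TRUE
          if (stats::runif(1) < p_res) {
            resume_date <- as.numeric(ymd(y + 1L, 2L, 1L)) + sample.int(120L, 1L) - 1L
            resume_idx <- a + 2L
          }
          next_eligible <- a + 2L
          a <- a + 1L
          break
        }
        cursor <- emit_chain(cursor, dec31s[a])
        if (dies) {
          disc[a] <- !any(bdates >= as.numeric(ymd(y, 11L, 1L)) &
                            bdates <= dec31s[a])
          a <- a + 1L
          break
        }
        if (a < nA) topup_window(a + 1L)
        a <- a + 1L
      }
    }
    # resumption scheduled past the last anchor: dispense it, no labels
    if (!is.na(resume_date) && resume_date <= bound)
      emit_chain(resume_date, end_num)

    # sporadic short courses in years free of period activity (<= 2 boxes a
    # year, at most 56 units in any quarter: can never reach the 74-dose bar)
    if (occasional) {
      busy <- unique(date_year(as.Date(bdates, origin = "1970-01-01")))
      for (yy in all_years) {
        if (yy %in% busy || stats::runif(1) >= 0.5) next
        lo <- max(as.numeric(ymd(yy, 1L, 1L)), start_num)
        hi <- min(as.numeric(ymd(yy, 12L, 31L)), bound)
        if (hi < lo) next
        for (j in seq_len(sample.int(2L, 1L))) {
          bdates <- c(bdates, lo + sample.int(as.integer(hi - lo) + 1L, 1L) - 1L)
          bunits <- c(bunits, if (stats::runif(1) < 0.5) 14L else 28L)
        }
      }
    }

    if (length(bdates)) {
      o <- order(bdates, bunits)
      bdates <- bdates[o]; bunits <- bunits[o]

      epi <- boxes_to_episodes(bdates, bunits)
      epi_acc[[i]] <- epi

      # prescriptions: runs of 1-3 boxes within an episode share one id
      epi_id <- findInterval(bdates, epi[, "start"])
      rx <- integer(length(bdates)); rx_counter <- 0L
      for (e in unique(epi_id)) {
        idx <- which(epi_id == e)
        pos <- 1L
        while (pos <= length(idx)) {
          run <- sample.int(3L, 1L)
          rx_counter <- rx_counter + 1L
          take <- idx[pos:min(pos + run - 1L, length(idx))]
          rx[take] <- rx_counter
          pos <- pos + run
        }
      }
      rx_spec <- sample(SPECIALTIES, rx_counter, replace = TRUE, prob = pm)
      prod <- sample.int(nrow(mixdf), length(bdates), replace = TRUE, prob = mixdf$p)

      rec_dates <- bdates; rec_units <- bunits
      rec_route <- rep("oral", length(bdates))
      rec_rx <- rx; rec_prod <- prod
      if (config$parenteral_fraction > 0 &&
          stats::runif(1) < config$parenteral_fraction) {
        # one extra parenteral record; oral boxes and labels stay untouched
        rec_dates <- c(rec_dates, bdates[1]); rec_units <- c(rec_units, 1L)
        rec_route <- c(rec_route, "parenteral")
        rec_rx <- c(rec_rx, rx_counter); rec_prod <- c(rec_prod, 3L)
      }

      disp_acc[[i]] <- data.frame(
        patient_id = pid,
        dispense_date = as.Date(rec_dates, origin = "1970-01-01"),
        inn = mixdf$inn[rec_prod],
        dosage_mg = mixdf$dosage_mg[rec_prod],
        units_dispensed = as.integer(rec_units),
        route = rec_route,
        prescription_id = sprintf("%s-rx%04d", pid, rec_rx),
        prescriber_specialty = rx_spec[rec_rx],
        stringsAsFactors = FALSE
      )
    }

    # incident truth from the assembled oral boxes; NA when Jan 1 of the
    # year before precedes the data period (new-user status not assessable)
    incident <- rep(FALSE, nA)
    for (k in seq_len(nA)) {
      prev_jan <- as.numeric(ymd(anchors[k] - 1L, 1L, 1L))
      if (prev_jan < start_num) { incident[k] <- NA; next }
      if (chronic[k])
        incident[k] <- !(k > 1L && chronic[k - 1L]) &&
          !any(bdates <= prev_jan & prev_jan <= bdates + bunits - 1)
    }
    status_acc[[i]] <- cbind(i = i, year = anchors, chronic = chronic,
                             incident = incident, discontinued = disc)
  }

  dispensings <- do.call(rbind, disp_acc[!vapply(disp_acc, is.null, NA)])
  if (is.null(dispensings))
    dispensings <- data.frame(
      patient_id = character(), dispense_date = as.Date(character()),
      inn = character(), dosage_mg = numeric(), units_dispensed = integer(),
      route = character(), prescription_id = character(),
      prescriber_specialty = character())
  rownames(dispensings) <- NULL

  st <- do.call(rbind, status_acc)
  status <- data.frame(
    patient_id = sprintf("P%06d", st[, "i"]),
    year = as.integer(st[, "year"]),
    true_chronic = st[, "chronic"] == 1,
    true_incident = ifelse(is.na(st[, "incident"]), NA, st[, "incident"] == 1),
    true_discontinued = st[, "discontinued"] == 1
  )

  eps <- lapply(seq_len(n), function(i) {
    e <- epi_acc[[i]]
    if (is.null(e)) return(NULL)
    data.frame(patient_id = sprintf("P%06d", i),
               start_date = as.Date(e[, "start"], origin = "1970-01-01"),
               end_date = as.Date(e[, "end"], origin = "1970-01-01"))
  })
  eps <- do.call(rbind, eps[!vapply(eps, is.null, NA)])
  if (is.null(eps))
    eps <- data.frame(patient_id = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()))
  rownames(eps) <- NULL

  list(dispensings = dispensings,
       ground_truth = list(status = status, episodes = eps))
}

#' Simulate a complete claims dataset
#'
#' Runs [simulate_population()] and [simulate_dispensings()] and assembles a
#' validated [claims_data] object together with its ground truth. The
#' population denominator for every anchor year is `n_patients`.
#'
#' @param config a [claims_config()].
#' @return list with `claims` (a `claims_data`), `ground_truth` and the
#'   `config` used.
#' @export
#' @examples
#' sim <- simulate_claims(claims_config(n_patients = 50, seed = 7))
#' sim$claims
simulate_claims <- function(config) {
  stopifnot(inherits(config, "claims_config"))
  patients <- simulate_population(config)
  gen <- simulate_dispensings(patients, config)
  anchors <- anchor_years(config$study_start, config$study_end)
  claims <- claims_data(
    patients, gen$dispensings,
    drug_reference = default_drug_reference(),
    denominators = data.frame(year = anchors, count = config$n_patients),
    period = c(config$study_start, config$study_end)
  )
  list(claims = claims, ground_truth = gen$ground_truth, config = config)
}

#' Write a simulated dataset (claims, ground truth, config) to disk
#'
#' Writes the four claims CSVs via [write_claims()] plus `ground_truth.csv`
#' (the per patient-year labels), `ground_truth_episodes.csv` and the
#' generating configuration as `config.yaml`.
#'
#' @param sim the list returned by [simulate_claims()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_claims(sim$claims, dir)
  utils::write.csv(sim$ground_truth$status, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  ep <- sim$ground_truth$episodes
  ep$start_date <- as.character(ep$start_date)
  ep$end_date <- as.character(ep$end_date)
  utils::write.csv(ep, file.path(dir, "ground_truth_episodes.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg_list <- unclass(sim$config)
  cfg_list$study_start <- as.character(cfg_list$study_start)
  cfg_list$study_end <- as.character(cfg_list$study_end)
  cfg_list$drug_mix <- as.list(cfg_list$drug_mix)
  cfg_list$prescriber_mix <- as.list(cfg_list$prescriber_mix)
  cfg_list$age_distribution <- as.list(cfg_list$age_distribution)
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  invisible(dir)
}
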