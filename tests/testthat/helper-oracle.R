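# Brute-force day-grid oracle: materializes one value per calendar day and
# re-derives chronic status, discontinuation and episodes by direct scanning.
# Deliberately loop-based and independent of the package's vectorized
# implementation.

oracle_chronic <- function(records, year, death_date = as.Date(NA),
                           threshold = 0.8) {
  if (!is.na(death_date) && death_date < as.Date(sprintf("%d-01-01", year)))
    return(FALSE)
  days <- seq(as.Date(sprintf("%d-10-01", year - 1)),
              as.Date(sprintf("%d-12-31", year - 1)), by = "day")
  r <- records[records$route == "oral", , drop = FALSE]
  total <- 0
  for (d in days) total <- total + sum(r$units_dispensed[as.numeric(r$dispense_date) == d])
  total >= ceiling(threshold * length(days))
}

oracle_discontinued <- function(records, year) {
  days <- seq(as.Date(sprintf("%d-11-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  r <- records[records$route == "oral", , drop = FALSE]
  hit <- FALSE
  for (d in days) if (any(as.numeric(r$dispense_date) == d)) hit <- TRUE
  !hit
}

oracle_episodes <- function(records, gap_days = 61) {
  r <- records[records$route == "oral", , drop = FALSE]
  if (nrow(r) == 0L) return(NULL)
  covered <- sort(unique(unlist(lapply(seq_len(nrow(r)), function(k)
    as.numeric(r$dispense_date[k]) + 0:(r$units_dispensed[k] - 1L)))))
  brk <- which(diff(covered) - 1 >= gap_days)
  starts <- covered[c(1, brk + 1)]
  ends <- covered[c(brk, length(covered))]
  data.frame(
    start_date = as.Date(starts, origin = "1970-01-01"),
    end_date = as.Date(ends, origin = "1970-01-01"),
    n_doses = vapply(seq_along(starts), function(j)
      as.integer(sum(r$units_dispensed[as.numeric(r$dispense_date) >= starts[j] &
                                         as.numeric(r$dispense_date) <= ends[j]])), 1L)
  )
}
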