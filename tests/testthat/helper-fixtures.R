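# In-code fixtures shared across tests. Everything is generated; nothing is
# read from disk.

# Minimal 4-state space: one sex, one band, one location, all statuses.
micro_stock <- function(ft = 100, pt = 50, tmp = 10, prm = 0, year = 2004) {
  tibble::tibble(
    year = year, sex = "male", age_band = "45_54", location = "urban",
    status = c("full_time", "part_time", "temporary_exit",
               "permanent_exit"),
    headcount = c(ft, pt, tmp, prm)
  )
}

# Random valid transition table on the micro space; probabilities scaled so
# outbound sums stay below 1.
micro_transitions <- function(p = NULL) {
  moves <- tibble::tibble(
    from_status = c("full_time", "part_time", "full_time", "part_time",
                    "full_time", "part_time", "temporary_exit",
                    "temporary_exit", "temporary_exit"),
    to_status = c("part_time", "full_time", "temporary_exit",
                  "temporary_exit", "permanent_exit", "permanent_exit",
                  "full_time", "part_time", "permanent_exit")
  )
  if (is.null(p)) p <- runif(nrow(moves), 0, 0.3)
  tibble::tibble(
    sex = "male", age_band = "45_54", from_location = "urban",
    from_status = moves$from_status, to_location = "urban",
    to_status = moves$to_status, probability = p
  )
}

random_micro_multipliers <- function(tr) {
  dplyr::mutate(
    tr[, c("sex", "age_band", "from_location", "from_status",
           "to_location", "to_status")],
    multiplier = runif(nrow(tr), -0.1, 0.1)
  )
}

micro_entry_stream <- function(grad = 10, migr = 5) {
  entry_stream(
    tibble::tibble(type = c("graduate", "migrant"), count = c(grad, migr)),
    tibble::tibble(
      type = rep(c("graduate", "migrant"), each = 2),
      sex = "male", age_band = "45_54", location = "urban",
      status = rep(c("full_time", "part_time"), 2),
      fraction = c(0.7, 0.3, 0.6, 0.4)
    )
  )
}

flat_hours <- function(ft = 40, pt = 20, standard = 40, weeks = 44) {
  hours_profile(
    tibble::tibble(status = c("full_time", "part_time"),
                   weekly_hours = c(ft, pt)),
    standard_week = standard, working_weeks = weeks
  )
}

active_total <- function(stock) {
  sum(stock$headcount[stock$status %in% c("full_time", "part_time")])
}

grand_total <- function(stock) sum(stock$headcount)
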