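# Deterministic annual state-transition cohort projection of the GP stock.
#
# Within each sex x age-band stratum, GPs move between full-time and
# part-time work, urban and rural practice, and temporary or permanent exit;
# permanent exit is absorbing. Counts are continuous expected flows, never
# stochastic realisations: with 100 full-time urban GPs and an annual
# full->part probability of 0.05, exactly 5 move in that year. The within-year
# event order is fixed: entries, then transitions, then aging.

allowed_move <- function(from_location, from_status, to_location, to_status) {
  active_f <- from_status %in% gp_active_statuses
  active_t <- to_status %in% gp_active_statuses
  same_loc <- from_location == to_location
  (active_f & active_t & from_status != to_status & same_loc) |      # full<->part
    (active_f & active_t & from_status == to_status & !same_loc) |   # urban<->rural
    (active_f & to_status %in% gp_exit_statuses & same_loc) |        # active->exit
    (from_status == "temporary_exit" & active_t & same_loc) |        # re-entry
    (from_status == "temporary_exit" & to_status == "permanent_exit" & same_loc)
}

#' Validate an annual transition table
#'
#' A transition table gives, per sex and age band, annual movement
#' probabilities between states. Allowed moves: full-time <-> part-time
#' (same location), urban <-> rural (same status), active -> temporary or
#' permanent exit, temporary exit -> active, and temporary exit -> permanent
#' exit. Permanent exit is absorbing. The residual `1 - sum(outbound)` is the
#' stay probability.
#'
#' @param transitions Data frame with columns `sex`, `age_band`,
#'   `from_location`, `from_status`, `to_location`, `to_status`,
#'   `probability`.
#' @return The validated tibble, invisibly usable in pipes.
#' @export
transition_table <- function(transitions) {
  tr <- tibble::as_tibble(transitions)
  req <- c("sex", "age_band", "from_location", "from_status",
           "to_location", "to_status", "probability")
  miss <- setdiff(req, names(tr))
  if (length(miss)) {
    abort(paste0("Transition table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "gp_schema_error")
  }
  lv <- gp_levels()
  for (cl in c("from_location", "to_location")) {
    bad <- setdiff(unique(tr[[cl]]), lv$location)
    if (length(bad)) abort(paste0("Unknown location label(s): ",
                                  paste(bad, collapse = ", ")),
                           class = "gp_schema_error")
  }
  for (cl in c("from_status", "to_status")) {
    bad <- setdiff(unique(tr[[cl]]), lv$status)
    if (length(bad)) abort(paste0("Unknown status label(s): ",
                                  paste(bad, collapse = ", ")),
                           class = "gp_schema_error")
  }
  validate_categories(tr, c("sex", "age_band"), "transition table")
  if (any(!is.finite(tr$probability)) ||
      any(tr$probability < 0) || any(tr$probability > 1)) {
    abort("Transition probabilities must lie in [0, 1].",
          class = "gp_parameter_error")
  }
  ok <- allowed_move(tr$from_location, tr$from_status,
                     tr$to_location, tr$to_status)
  if (any(!ok)) {
    ex <- tr[!ok, ][1, ]
    abort(sprintf(
      "Disallowed transition: %s/%s -> %s/%s (sex %s, age %s).",
      ex$from_location, ex$from_status, ex$to_location, ex$to_status,
      ex$sex, ex$age_band), class = "gp_schema_error")
  }
  dup <- duplicated(tr[, setdiff(req, "probability")])
  if (any(dup)) {
    abort("Duplicate transition rows for the same (stratum, move).",
          class = "gp_schema_error")
  }
  tr
}

#' Transition probability after k years of compound annual change
#'
#' Each transition probability `p` carries an annual percentage-change
#' multiplier `m`; after `k` years since the base year the effective
#' probability is `p * (1 + m)^k`, clamped to `[0, 1]`.
#'
#' @param p Base annual probability, in `[0, 1]`.
#' @param m Annual change (e.g. `0.02` for +2%/year); vectorised with `p`.
#' @param k Whole years since the base year, `>= 0`.
#' @return Effective probabilities, clamped to `[0, 1]`.
#' @examples
#' effective_probability(0.05, 0.10, 2) # 0.0605
#' @export
effective_probability <- function(p, m, k) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("`p` must lie in [0, 1].", class = "gp_parameter_error")
  }
  if (any(k < 0) || any(k != floor(k))) {
    abort("`k` must be a non-negative integer.", class = "gp_parameter_error")
  }
  pmin(pmax(p * (1 + m)^k, 0), 1)
}

#' Rescale a from-state's outbound probabilities to a proper distribution
#'
#' If the outbound probabilities of one from-state sum above 1 they are
#' rescaled proportionally so they sum to exactly 1 (stay probability 0),
#' with a warning; otherwise they are returned unchanged and the residual is
#' the stay probability. An empty vector is an absorbing state (stay 1).
#'
#' @param probs Numeric vector of outbound probabilities for one from-state.
#' @return Numeric vector of adjusted probabilities with attribute `stay`.
#' @examples
#' normalize_outflows(c(0.2, 0.3)) # unchanged, stay 0.5
#' @export
normalize_outflows <- function(probs) {
  if (any(probs < 0, na.rm = TRUE) || any(!is.finite(probs) & length(probs))) {
    abort("Outbound probabilities must be non-negative and finite.",
          class = "gp_parameter_error")
  }
  s <- sum(probs)
  if (s > 1) {
    warn("Outbound probabilities sum above 1; rescaled proportionally.")
    probs <- probs / s
    s <- 1
  }
  attr(probs, "stay") <- 1 - s
  probs
}

#' Aging rule: annual graduation fractions between age bands
#'
#' Each year a fraction of every non-terminal band's survivors (active and
#' temporary-exit states) moves to the next band, state otherwise preserved.
#' The default fraction is `1/10` per band (the band width in years), a
#' steady-state flow approximation; the terminal band's fraction is 0.
#'
#' @param fractions Optional named numeric vector, names from
#'   `age_bands()$label`, overriding the default per-band fractions.
#' @return Tibble with columns `age_band` and `fraction`.
#' @export
aging_rule <- function(fractions = NULL) {
  bands <- age_bands()$label
  fr <- setNames(c(rep(0.1, length(bands) - 1L), 0), bands)
  if (!is.null(fractions)) {
    bad <- setdiff(names(fractions), bands)
    if (length(bad)) abort(paste0("Unknown age band(s): ",
                                  paste(bad, collapse = ", ")),
                           class = "gp_schema_error")
    fr[names(fractions)] <- fractions
  }
  if (any(fr < 0 | fr > 1)) {
    abort("Aging fractions must lie in [0, 1].", class = "gp_parameter_error")
  }
  if (fr[[length(fr)]] != 0) {
    abort("The terminal age band must have aging fraction 0.",
          class = "gp_parameter_error")
  }
  tibble::tibble(age_band = bands, fraction = unname(fr))
}

#' Construct an entry stream
#'
#' Entries are new graduates of vocational training and in-migrants from
#' interstate or overseas. Counts are held constant at their base-year values
#' unless a per-year series is supplied; the allocation spreads each entry
#' type across active states with fractions summing to 1.
#'
#' @param entries Data frame with columns `type` (`graduate` or `migrant`)
#'   and `count`, optionally `year` for a per-year series.
#' @param allocation Data frame with columns `type`, `sex`, `age_band`,
#'   `location`, `status`, `fraction`; per type the fractions must sum to 1.
#'   See [default_entry_allocation()].
#' @return An object of class `entry_stream`.
#' @export
entry_stream <- function(entries, allocation) {
  entries <- tibble::as_tibble(entries)
  allocation <- tibble::as_tibble(allocation)
  if (!all(c("type", "count") %in% names(entries))) {
    abort("`entries` needs columns `type` and `count`.",
          class = "gp_schema_error")
  }
  bad <- setdiff(unique(entries$type), c("graduate", "migrant"))
  if (length(bad)) abort(paste0("Unknown entry type(s): ",
                                paste(bad, collapse = ", ")),
                         class = "gp_schema_error")
  if (any(entries$count < 0)) {
    abort("Entry counts must be non-negative.", class = "gp_schema_error")
  }
  validate_categories(allocation,
                      c("type", "sex", "age_band", "location", "status"),
                      "entry allocation")
  if (!all(allocation$status %in% gp_active_statuses)) {
    abort("Entries may only be allocated to active states.",
          class = "gp_schema_error")
  }
  sums <- tapply(allocation$fraction, allocation$type, sum)
  if (any(abs(sums - 1) > 1e-8)) {
    abort("Allocation fractions must sum to 1 per entry type.",
          class = "gp_schema_error")
  }
  structure(list(entries = entries, allocation = allocation),
            class = "entry_stream")
}

#' Default allocation of entries across active states
#'
#' Graduates enter the two youngest bands (70/30 by default) with sex,
#' location and work-status shares matching the base-year active stock's
#' marginal distributions; in-migrants follow the base-year stock's full
#' joint distribution over active states.
#'
#' @param base_stock Base-year stock table (active rows are used).
#' @param grad_age_split Named fractions over entry age bands for graduates.
#' @return Allocation tibble suitable for [entry_stream()].
#' @export
default_entry_allocation <- function(base_stock,
                                     grad_age_split = c(under_35 = 0.7,
                                                        "35_44" = 0.3)) {
  stock <- dplyr::filter(tibble::as_tibble(base_stock),
                         .data$status %in% gp_active_statuses,
                         .data$headcount > 0)
  if (!nrow(stock)) {
    abort("Base stock has no active headcount to derive allocations from.",
          class = "gp_schema_error")
  }
  if (abs(sum(grad_age_split) - 1) > 1e-8) {
    abort("`grad_age_split` must sum to 1.", class = "gp_config_error")
  }
  tot <- sum(stock$headcount)
  marg <- function(col) {
    m <- dplyr::summarise(dplyr::group_by(stock, .data[[col]]),
                          share = sum(.data$headcount) / tot,
                          .groups = "drop")
    setNames(m$share, m[[col]])
  }
  sex_sh <- marg("sex"); loc_sh <- marg("location"); st_sh <- marg("status")
  grads <- tidyr::expand_grid(
    sex = names(sex_sh), age_band = names(grad_age_split),
    location = names(loc_sh), status = names(st_sh)
  )
  grads$fraction <- unname(sex_sh[grads$sex] *
                             grad_age_split[grads$age_band] *
                             loc_sh[grads$location] * st_sh[grads$status])
  grads <- dplyr::mutate(grads, type = "graduate", .before = 1)
  migr <- dplyr::transmute(stock, type = "migrant", sex = .data$sex,
                           age_band = .data$age_band,
                           location = .data$location, status = .data$status,
                           fraction = .data$headcount / tot)
  dplyr::bind_rows(grads, migr)
}

# ---------------------------------------------------------------------------
# Internal engine: integer-indexed state vectors for speed. The state space
# is the cross of the sexes, age bands, locations present in the base stock
# with all four statuses; stocks are dense numeric vectors over it.

make_state_space <- function(stock) {
  lv <- gp_levels()
  states <- tidyr::expand_grid(
    sex = intersect(lv$sex, unique(stock$sex)),
    age_band = intersect(lv$age_band, unique(stock$age_band)),
    location = intersect(lv$location, unique(stock$location)),
    status = lv$status
  )
  states$idx <- seq_len(nrow(states))
  states
}

state_match <- function(states, sex, age_band, location, status, what) {
  key_s <- paste(states$sex, states$age_band, states$location, states$status)
  key_q <- paste(sex, age_band, location, status)
  idx <- match(key_q, key_s)
  if (anyNA(idx)) {
    abort(paste0(what, " references state(s) outside the stock's state ",
                 "space: ", paste(unique(key_q[is.na(idx)]), collapse = "; ")),
          class = "gp_schema_error")
  }
  idx
}

sum_by_index <- function(v, idx, n) {
  out <- numeric(n)
  if (length(v)) {
    t <- rowsum(v, idx)
    out[as.integer(rownames(t))] <- t[, 1L]
  }
  out
}

stock_to_vector <- function(stock, states) {
  idx <- state_match(states, stock$sex, stock$age_band, stock$location,
                     stock$status, "stock")
  sum_by_index(stock$headcount, idx, nrow(states))
}

vector_to_stock <- function(x, states, year) {
  tibble::tibble(year = year, sex = states$sex, age_band = states$age_band,
                 location = states$location, status = states$status,
                 headcount = x)
}

build_engine <- function(base_stock, transitions, entries = NULL,
                         aging = NULL, multipliers = NULL) {
  states <- make_state_space(base_stock)
  n <- nrow(states)
  tr <- transition_table(transitions)
  tr_from <- state_match(states, tr$sex, tr$age_band, tr$from_location,
                         tr$from_status, "transition table")
  tr_to <- state_match(states, tr$sex, tr$age_band, tr$to_location,
                       tr$to_status, "transition table")
  m <- multiplier_vector(multipliers, tr)
  ag <- NULL
  if (!is.null(aging)) {
    aging <- tibble::as_tibble(aging)
    validate_categories(aging, c("age_band"), "aging rule")
    bands <- intersect(age_bands()$label, unique(states$age_band))
    frac <- setNames(rep(0, length(bands)), bands)
    hit <- intersect(aging$age_band, bands)
    frac[hit] <- aging$fraction[match(hit, aging$age_band)]
    # terminal band (last present) never ages out
    frac[[length(frac)]] <- 0
    agers <- states[states$age_band != bands[length(bands)] &
                      states$status != "permanent_exit", ]
    if (nrow(agers)) {
      nxt <- bands[match(agers$age_band, bands) + 1L]
      ag <- list(
        from = agers$idx,
        to = state_match(states, agers$sex, nxt, agers$location,
                         agers$status, "aging rule"),
        frac = unname(frac[agers$age_band])
      )
    }
  }
  ef <- NULL
  if (!is.null(entries)) {
    stopifnot(inherits(entries, "entry_stream"))
    al <- entries$allocation
    al_idx <- state_match(states, al$sex, al$age_band, al$location,
                          al$status, "entry allocation")
    etab <- entries$entries
    if (!"year" %in% names(etab)) etab$year <- NA_integer_
    base_count <- vapply(c("graduate", "migrant"), function(tp) {
      r <- etab[etab$type == tp, ]
      if (!nrow(r)) return(0)
      if (all(is.na(r$year))) return(sum(r$count))
      y0 <- min(r$year, na.rm = TRUE)
      sum(r$count[!is.na(r$year) & r$year == y0])
    }, numeric(1))
    ef <- function(year) {
      counts <- vapply(c("graduate", "migrant"), function(tp) {
        if (is.na(year)) return(base_count[[tp]])
        r <- etab[etab$type == tp & !is.na(etab$year) & etab$year == year, ]
        if (nrow(r)) sum(r$count) else base_count[[tp]]
      }, numeric(1))
      sum_by_index(counts[al$type] * al$fraction, al_idx, n)
    }
  }
  list(states = states, n = n, tr_from = tr_from, tr_to = tr_to,
       p = tr$probability, m = m, aging = ag, entry_fun = ef,
       transitions = tr)
}

multiplier_vector <- function(multipliers, tr) {
  if (is.null(multipliers)) return(rep(0, nrow(tr)))
  if (is.numeric(multipliers) && length(multipliers) == 1L) {
    return(rep(multipliers, nrow(tr)))
  }
  mu <- tibble::as_tibble(multipliers)
  req <- c("sex", "age_band", "from_location", "from_status",
           "to_location", "to_status", "multiplier")
  miss <- setdiff(req, names(mu))
  if (length(miss)) {
    abort(paste0("Multiplier table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "gp_schema_error")
  }
  key <- function(d) paste(d$sex, d$age_band, d$from_location, d$from_status,
                           d$to_location, d$to_status)
  i <- match(key(tr), key(mu))
  out <- ifelse(is.na(i), 0, mu$multiplier[i])
  out
}

engine_step <- function(x, eng, k, year) {
  if (!is.null(eng$entry_fun)) x <- x + eng$entry_fun(year)
  x <- engine_transitions(x, eng, k)
  if (!is.null(eng$aging)) {
    mv <- x[eng$aging$from] * eng$aging$frac
    x[eng$aging$from] <- x[eng$aging$from] - mv
    x[eng$aging$to] <- x[eng$aging$to] + mv
  }
  x
}

engine_transitions <- function(x, eng, k) {
  if (!length(eng$tr_from)) return(x)
  p_eff <- pmin(pmax(eng$p * (1 + eng$m)^k, 0), 1)
  s <- sum_by_index(p_eff, eng$tr_from, eng$n)
  if (any(s > 1 + 1e-12)) {
    warn("Outbound probabilities sum above 1 for some states; rescaled.")
    fac <- pmax(s, 1)
    p_eff <- p_eff / fac[eng$tr_from]
  }
  out <- x[eng$tr_from] * p_eff
  x - sum_by_index(out, eng$tr_from, eng$n) +
    sum_by_index(out, eng$tr_to, eng$n)
}

# ---------------------------------------------------------------------------

#' Advance the stock by one year
#'
#' Applies, in order: (1) entries allocated across active states; (2) annual
#' transitions as expected flows at their effective (multiplier-compounded)
#' probabilities; (3) aging of active and temporary-exit survivors to the
#' next band. Headcount is conserved: the total over active plus exit states
#' afterwards equals the prior total plus entries.
#'
#' @param stock Stock table for one year (columns `sex`, `age_band`,
#'   `location`, `status`, `headcount`, optionally `year`).
#' @param transitions Transition table, see [transition_table()].
#' @param entries Optional [entry_stream()].
#' @param aging Optional aging rule tibble, see [aging_rule()]; `NULL`
#'   disables aging.
#' @param multipliers Optional annual-change multipliers: a single number
#'   applied to every transition or a table keyed like `transitions` with a
#'   `multiplier` column. Missing transitions get 0.
#' @param k Whole years since the base year (drives the compounding).
#' @return Stock tibble for the next year.
#' @examples
#' stock <- tibble::tibble(year = 2004, sex = "male", age_band = "45_54",
#'   location = "urban", status = "full_time", headcount = 100)
#' tr <- tibble::tibble(sex = "male", age_band = "45_54",
#'   from_location = "urban", from_status = "full_time",
#'   to_location = "urban", to_status = "part_time", probability = 0.05)
#' out <- step_year(stock, tr)
#' out$headcount[out$status == "part_time"] # 5
#' @export
step_year <- function(stock, transitions, entries = NULL, aging = NULL,
                      multipliers = NULL, k = 0) {
  stock <- tibble::as_tibble(stock)
  validate_categories(stock, c("sex", "age_band", "location", "status"),
                      "stock")
  year <- if ("year" %in% names(stock)) unique(stock$year) else NA_integer_
  if (length(year) != 1L) {
    abort("`stock` must contain a single year.", class = "gp_schema_error")
  }
  eng <- build_engine(stock, transitions, entries, aging, multipliers)
  x <- stock_to_vector(stock, eng$states)
  x1 <- engine_step(x, eng, k, year + 1L)
  vector_to_stock(x1, eng$states, if (is.na(year)) NA_integer_ else year + 1L)
}

#' Project the GP stock over a horizon
#'
#' Iterates [step_year()] from the base year, compounding the annual-change
#' multipliers: the step into year `base_year + j` uses
#' `k = j - 1` years since base. Returns the full per-state headcount series
#' including the base year.
#'
#' @inheritParams step_year
#' @param stock_base Base-year stock table; its `year` column (default 2004)
#'   anchors the series.
#' @param horizon Number of years to project, `>= 1`.
#' @param base_year Overrides the base year when `stock_base` has no `year`.
#' @return A `gp_supply_projection` tibble with columns `year`, `sex`,
#'   `age_band`, `location`, `status`, `headcount` for `horizon + 1` years.
#' @seealso [supply_summary()] to reduce to per-year headcount and FTE.
#' @export
project_supply <- function(stock_base, transitions, entries = NULL,
                           aging = NULL, multipliers = NULL, horizon,
                           base_year = NULL) {
  if (horizon < 1) abort("`horizon` must be >= 1.", class = "gp_config_error")
  stock_base <- tibble::as_tibble(stock_base)
  validate_categories(stock_base, c("sex", "age_band", "location", "status"),
                      "base stock")
  if (is.null(base_year)) {
    base_year <- if ("year" %in% names(stock_base)) {
      unique(stock_base$year)
    } else 2004L
  }
  if (length(base_year) != 1L) {
    abort("Base stock must contain a single year.", class = "gp_schema_error")
  }
  eng <- build_engine(stock_base, transitions, entries, aging, multipliers)
  x <- stock_to_vector(stock_base, eng$states)
  res <- matrix(0, eng$n, horizon + 1L)
  res[, 1L] <- x
  for (j in seq_len(horizon)) {
    x <- engine_step(x, eng, k = j - 1L, year = base_year + j)
    res[, j + 1L] <- x
  }
  out <- purrr::map_dfr(seq_len(horizon + 1L), function(j) {
    vector_to_stock(res[, j], eng$states, base_year + j - 1L)
  })
  class(out) <- c("gp_supply_projection", class(out))
  attr(out, "base_year") <- base_year
  attr(out, "horizon") <- horizon
  out
}

#' Per-year headcount and FTE of a supply projection
#'
#' @param projection Output of [project_supply()] (or any multi-year stock
#'   table).
#' @param profile An [hours_profile()] for the FTE conversion.
#' @return Tibble with `year`, active `headcount`, `total_headcount`
#'   (including exits) and `fte`.
#' @export
supply_summary <- function(projection, profile) {
  ft <- headcount_to_fte(projection, profile)
  dplyr::summarise(
    dplyr::group_by(ft, .data$year),
    total_headcount = sum(.data$headcount),
    fte = sum(.data$fte),
    headcount = sum(.data$headcount[.data$status %in% gp_active_statuses]),
    .groups = "drop"
  )[, c("year", "headcount", "total_headcount", "fte")]
}
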