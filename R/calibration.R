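# Accept-reject calibration of the supply sub-model.
#
# Candidate parameter sets (base transition probabilities from beta priors,
# annual-change multipliers from uniform priors) are sampled, the cohort
# model is projected, and every candidate whose predictions deviate by less
# than the tolerance (default 5%) from the smoothed observed stock across
# ALL calibration targets is retained, representing the joint uncertainty
# around the inputs.

#' Validate a prior specification
#'
#' One row per transition: the beta shape parameters for its base annual
#' probability and the uniform range (default -0.10 to +0.10) for its annual
#' percentage-change multiplier.
#'
#' @param priors Data frame with the six transition key columns (`sex`,
#'   `age_band`, `from_location`, `from_status`, `to_location`, `to_status`)
#'   plus `alpha`, `beta`, `mult_low`, `mult_high`.
#' @return The validated tibble.
#' @export
prior_spec <- function(priors) {
  if (isTRUE(attr(priors, "gp_validated"))) return(priors)
  pr <- tibble::as_tibble(priors)
  req <- c("sex", "age_band", "from_location", "from_status",
           "to_location", "to_status", "alpha", "beta",
           "mult_low", "mult_high")
  miss <- setdiff(req, names(pr))
  if (length(miss)) {
    abort(paste0("Prior table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "gp_schema_error")
  }
  if (any(pr$alpha <= 0) || any(pr$beta <= 0)) {
    abort("Beta shape parameters must be positive.",
          class = "gp_config_error")
  }
  if (any(pr$mult_low > pr$mult_high)) {
    abort("`mult_low` must not exceed `mult_high`.",
          class = "gp_config_error")
  }
  # key columns must describe allowed moves: reuse the transition validator
  transition_table(dplyr::mutate(
    pr[, req[1:6]], probability = pr$alpha / (pr$alpha + pr$beta)))
  attr(pr, "gp_validated") <- TRUE
  pr
}

#' Sample one candidate parameter set from the priors
#'
#' Each base probability is drawn from its beta prior and each multiplier
#' from its uniform range; the draw is reproducible given `seed` and leaves
#' the global random-number state untouched.
#'
#' @param priors A [prior_spec()] table.
#' @param seed Integer seed for this draw.
#' @return A `gp_parameter_set`: list with `transitions` (a transition
#'   table), `multipliers` (keyed multiplier table), and `seed`.
#' @export
sample_parameter_set <- function(priors, seed) {
  pr <- prior_spec(priors)
  n <- nrow(pr)
  draw <- withr::with_seed(as.integer(seed), {
    list(p = rbeta(n, pr$alpha, pr$beta),
         m = runif(n, pr$mult_low, pr$mult_high))
  })
  keys <- pr[, c("sex", "age_band", "from_location", "from_status",
                 "to_location", "to_status")]
  structure(
    list(
      transitions = dplyr::mutate(keys, probability = draw$p),
      multipliers = dplyr::mutate(keys, multiplier = draw$m),
      seed = as.integer(seed)
    ),
    class = "gp_parameter_set"
  )
}

#' @export
print.gp_parameter_set <- function(x, ...) {
  cat("<gp_parameter_set> seed", x$seed, "-", nrow(x$transitions),
      "transitions\n")
  if (!is.null(x$deviation)) {
    cat("  convergent:", x$deviation$convergent,
        "| max deviation:", signif(x$deviation$max_pct, 4),
        "| summed |dev|:", signif(x$deviation$total_abs, 5), "\n")
  }
  invisible(x)
}

#' Project the supply model under one sampled parameter set
#'
#' @param set A `gp_parameter_set` from [sample_parameter_set()] or
#'   [calibrate()].
#' @inheritParams project_supply
#' @return A [project_supply()] result.
#' @export
project_parameter_set <- function(set, stock_base, entries = NULL,
                                  aging = NULL, horizon, base_year = NULL) {
  stopifnot(inherits(set, "gp_parameter_set"))
  project_supply(stock_base, set$transitions, entries = entries,
                 aging = aging, multipliers = set$multipliers,
                 horizon = horizon, base_year = base_year)
}

#' Smooth observed calibration targets with per-stratum linear trends
#'
#' Observed stock series suffer definition changes across survey years, so
#' each stratum's series is replaced by its ordinary-least-squares linear
#' trend evaluated at the observed years. A constant or exactly linear
#' series is reproduced unchanged.
#'
#' @param observed Data frame with columns `year`, `headcount` and any
#'   stratum columns among `sex`, `age_band`, `location`, `status`.
#' @return The input tibble with an added `smoothed` column.
#' @export
smooth_targets <- function(observed) {
  obs <- tibble::as_tibble(observed)
  if (!all(c("year", "headcount") %in% names(obs))) {
    abort("Targets need `year` and `headcount` columns.",
          class = "gp_schema_error")
  }
  strata <- intersect(c("sex", "age_band", "location", "status"), names(obs))
  grp <- dplyr::group_by(obs, dplyr::across(dplyr::all_of(strata)))
  dplyr::ungroup(dplyr::mutate(grp, smoothed = {
    if (dplyr::n() < 2L) {
      abort(paste0("At least 2 observations per stratum are needed for ",
                   "smoothing; use the raw value directly for ",
                   "single-observation strata."),
            class = "gp_config_error")
    }
    unname(predict(lm(headcount ~ year,
                      data = data.frame(headcount = .data$headcount,
                                        year = .data$year))))
  }))
}

#' Percent deviations of predictions from smoothed targets
#'
#' Per target (year x stratum), the deviation is
#' `|predicted - smoothed| / smoothed`; a candidate is convergent when every
#' deviation is below the tolerance. Targets whose smoothed value is 0 are
#' excluded with a warning. The summed absolute headcount deviation across
#' all targets is also reported.
#'
#' @param predicted Stock table (e.g. from [project_supply()]) with `year`,
#'   stratum columns and `headcount`.
#' @param smoothed Target table with `year`, stratum columns and a
#'   `smoothed` column (see [smooth_targets()]); a `headcount` column is
#'   used as `smoothed` if no `smoothed` column is present.
#' @param tolerance Convergence tolerance on each deviation (default 0.05).
#' @return A `gp_deviation`: list with `by_target` tibble (`deviation` as a
#'   proportion), `convergent`, `max_pct`, `total_abs`, `n_excluded`.
#' @export
deviation <- function(predicted, smoothed, tolerance = 0.05) {
  pred <- tibble::as_tibble(predicted)
  sm <- tibble::as_tibble(smoothed)
  if (!"smoothed" %in% names(sm)) {
    if (!"headcount" %in% names(sm)) {
      abort("`smoothed` needs a `smoothed` or `headcount` column.",
            class = "gp_schema_error")
    }
    sm$smoothed <- sm$headcount
  }
  strata <- intersect(intersect(c("sex", "age_band", "location", "status"),
                                names(pred)), names(sm))
  by <- c("year", strata)
  joined <- dplyr::inner_join(
    sm[, c(by, "smoothed")],
    dplyr::summarise(dplyr::group_by(pred, dplyr::across(dplyr::all_of(by))),
                     predicted = sum(.data$headcount), .groups = "drop"),
    by = by
  )
  if (!nrow(joined)) {
    abort("Predicted and target series share no (year, stratum) keys.",
          class = "gp_schema_error")
  }
  zero <- joined$smoothed == 0
  if (any(zero)) {
    warn(sprintf("%d target(s) with smoothed value 0 excluded.", sum(zero)))
  }
  keep <- joined[!zero, ]
  keep$deviation <- abs(keep$predicted - keep$smoothed) / keep$smoothed
  structure(
    list(
      by_target = keep,
      convergent = all(keep$deviation < tolerance),
      max_pct = max(keep$deviation),
      total_abs = sum(abs(keep$predicted - keep$smoothed)),
      tolerance = tolerance,
      n_excluded = sum(zero)
    ),
    class = "gp_deviation"
  )
}

#' @export
print.gp_deviation <- function(x, ...) {
  cat("<gp_deviation>", nrow(x$by_target), "targets | convergent:",
      x$convergent, "| max:", signif(x$max_pct, 4),
      "| summed |dev|:", signif(x$total_abs, 5), "\n")
  invisible(x)
}

#' Calibrate the supply sub-model by accept-reject sampling
#'
#' Samples `n_samples` candidate parameter sets from the priors, projects
#' each over the target years, and retains every candidate whose predicted
#' stocks deviate by less than `tolerance` from the smoothed observed
#' targets at every (year, stratum). All convergent sets are kept to support
#' sensitivity analyses. Deterministic given `seed` (candidate `i` uses seed
#' `seed + i`).
#'
#' @param priors A [prior_spec()] table.
#' @param targets Observed stock table (`year`, stratum columns,
#'   `headcount`); smoothed internally via [smooth_targets()].
#' @param stock_base Base-year stock table (its year precedes the first
#'   target year).
#' @inheritParams project_supply
#' @param n_samples Number of candidate draws, `>= 1`.
#' @param seed Base integer seed.
#' @param tolerance Per-target convergence tolerance (default 0.05).
#' @param extra_sets Optional list of `gp_parameter_set`s evaluated in the
#'   candidate pool alongside the sampled ones (e.g. a known truth).
#' @return A `gp_calibration`: list with `accepted` (list of convergent
#'   `gp_parameter_set`s, each with its `deviation` summary), `best`
#'   (minimum-max-deviation candidate, kept even when nothing converges),
#'   `n_samples`, `tolerance`, `seed` and the `smoothed` targets. Use
#'   [tidy()] / [glance()] on it.
#' @export
calibrate <- function(priors, targets, stock_base, entries = NULL,
                      aging = NULL, horizon = NULL, base_year = NULL,
                      n_samples, seed, tolerance = 0.05,
                      extra_sets = list()) {
  if (n_samples < 1) abort("`n_samples` must be >= 1.",
                           class = "gp_config_error")
  pr <- prior_spec(priors)
  stock_base <- tibble::as_tibble(stock_base)
  if (is.null(base_year)) {
    base_year <- if ("year" %in% names(stock_base)) {
      unique(stock_base$year)
    } else 2004L
  }
  sm <- smooth_targets(targets)
  if (is.null(horizon)) horizon <- max(sm$year) - base_year
  if (horizon < 1) abort("Targets must extend beyond the base year.",
                         class = "gp_config_error")

  keys <- pr[, c("sex", "age_band", "from_location", "from_status",
                 "to_location", "to_status")]
  template <- dplyr::mutate(keys, probability = 0)
  eng <- build_engine(stock_base, template, entries, aging, NULL)

  # map each usable target to (state row, year column) of the result matrix
  validate_categories(sm, c("sex", "age_band", "location", "status"),
                      "calibration targets")
  zero <- sm$smoothed == 0
  if (any(zero)) {
    warn(sprintf("%d target(s) with smoothed value 0 excluded.", sum(zero)))
  }
  smk <- sm[!zero, ]
  t_state <- state_match(eng$states, smk$sex, smk$age_band, smk$location,
                         smk$status, "targets")
  t_year <- smk$year - base_year + 1L
  if (any(t_year < 1L | t_year > horizon + 1L)) {
    abort("Target years fall outside the projection horizon.",
          class = "gp_config_error")
  }
  x0 <- stock_to_vector(stock_base, eng$states)

  run_candidate <- function(p, m) {
    x <- x0
    res <- matrix(0, eng$n, horizon + 1L)
    res[, 1L] <- x
    eng$p <- p
    eng$m <- m
    for (j in seq_len(horizon)) {
      x <- engine_step(x, eng, k = j - 1L, year = base_year + j)
      res[, j + 1L] <- x
    }
    predicted <- res[cbind(t_state, t_year)]
    dev <- abs(predicted - smk$smoothed) / smk$smoothed
    list(convergent = all(dev < tolerance), max_pct = max(dev),
         total_abs = sum(abs(predicted - smk$smoothed)))
  }

  evaluate <- function(set, label) {
    d <- run_candidate(
      align_to_priors(set$transitions, pr, "probability"),
      align_to_priors(set$multipliers, pr, "multiplier")
    )
    set$deviation <- d
    set$label <- label
    set
  }

  accepted <- list()
  best <- NULL
  note_best <- function(set) {
    if (is.null(best) || set$deviation$max_pct < best$deviation$max_pct) {
      best <<- set
    }
  }
  for (i in seq_along(extra_sets)) {
    set <- evaluate(extra_sets[[i]], paste0("extra_", i))
    note_best(set)
    if (set$deviation$convergent) accepted[[length(accepted) + 1L]] <- set
  }
  for (i in seq_len(n_samples)) {
    set <- sample_parameter_set(pr, seed + i)
    set <- evaluate(set, paste0("sample_", i))
    note_best(set)
    if (set$deviation$convergent) accepted[[length(accepted) + 1L]] <- set
  }

  structure(
    list(accepted = accepted, best = best, n_samples = n_samples,
         n_extra = length(extra_sets), tolerance = tolerance,
         seed = seed, smoothed = sm, base_year = base_year,
         horizon = horizon),
    class = "gp_calibration"
  )
}

# reorder a keyed parameter table onto the prior row order
align_to_priors <- function(tbl, pr, col) {
  key <- function(d) paste(d$sex, d$age_band, d$from_location,
                           d$from_status, d$to_location, d$to_status)
  i <- match(key(pr), key(tbl))
  if (anyNA(i)) {
    abort("Parameter set does not cover every prior transition.",
          class = "gp_schema_error")
  }
  tbl[[col]][i]
}

#' @export
print.gp_calibration <- function(x, ...) {
  cat("<gp_calibration>", x$n_samples, "samples | accepted:",
      length(x$accepted), "| tolerance:", x$tolerance, "\n")
  if (!length(x$accepted) && !is.null(x$best)) {
    cat("  no convergent set; best candidate max deviation:",
        signif(x$best$deviation$max_pct, 4), "\n")
  }
  invisible(x)
}

#' @rdname calibrate
#' @param x A `gp_calibration` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gp_calibration <- function(x, ...) {
  if (!length(x$accepted)) {
    return(tibble::tibble(label = character(), seed = integer(),
                          max_deviation = double(),
                          total_abs_deviation = double()))
  }
  purrr::map_dfr(x$accepted, function(s) {
    tibble::tibble(label = s$label, seed = s$seed %||% NA_integer_,
                   max_deviation = s$deviation$max_pct,
                   total_abs_deviation = s$deviation$total_abs)
  })
}

#' @rdname calibrate
#' @exportS3Method generics::glance
glance.gp_calibration <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples,
    n_accepted = length(x$accepted),
    acceptance_rate = length(x$accepted) / (x$n_samples + x$n_extra),
    tolerance = x$tolerance,
    best_max_deviation = if (is.null(x$best)) NA_real_ else
      x$best$deviation$max_pct
  )
}
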