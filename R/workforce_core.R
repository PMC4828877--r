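# Shared state vocabulary and headcount <-> FTE conversion.
#
# The workforce state space crosses sex x age band x location x work status.
# Active statuses (full_time, part_time) supply clinical hours; the two exit
# statuses (temporary_exit, permanent_exit) hold zero-FTE headcount so that
# cohort totals are conserved across a projection.

gp_sexes <- c("male", "female")
gp_locations <- c("urban", "rural")
gp_active_statuses <- c("full_time", "part_time")
gp_exit_statuses <- c("temporary_exit", "permanent_exit")
gp_statuses <- c(gp_active_statuses, gp_exit_statuses)

#' Working-age bands used throughout the model
#'
#' Five disjoint, ordered bands covering all working ages: under 35, 35-44,
#' 45-54, 55-64 and 65 plus. All stratified inputs must label age bands with
#' the `label` values returned here.
#'
#' @return A tibble with columns `label`, `lower` and `upper` (years; `upper`
#'   is `NA` for the open-ended terminal band).
#' @examples
#' age_bands()
#' @export
age_bands <- function() {
  tibble::tibble(
    label = c("under_35", "35_44", "45_54", "55_64", "65_plus"),
    lower = c(0, 35, 45, 55, 65),
    upper = c(34, 44, 54, 64, NA_real_)
  )
}

#' Category vocabularies for every stratifier
#'
#' @return Named list of the allowed labels for `sex`, `age_band`, `location`
#'   and `status` columns in all input tables.
#' @export
gp_levels <- function() {
  list(
    sex = gp_sexes,
    age_band = age_bands()$label,
    location = gp_locations,
    status = gp_statuses
  )
}

#' Construct an hours profile
#'
#' An hours profile carries mean weekly clinical hours per workforce stratum
#' together with the full-time standard (40 h/week) and the working year
#' (44 weeks) used to convert headcounts and consultation minutes to
#' full-time-equivalent (FTE) GPs. One FTE supplies
#' `standard_week * working_weeks` clinical hours per year (1760 by default).
#'
#' `hours` may be stratified by `sex`, `age_band` and `status`, or by
#' `status` alone; lookups fall back from the full stratum to the status-level
#' mean, and error when a populated status has no hours at all.
#'
#' @param hours Data frame with a `status` and `weekly_hours` column and
#'   optionally `sex` and `age_band`. Defaults to 40 h full-time, 24 h
#'   part-time.
#' @param standard_week Hours defining one full-time week. Must be positive.
#' @param working_weeks Working weeks per year after leave. Must be positive.
#' @return An object of class `hours_profile`.
#' @examples
#' annual_clinical_hours(hours_profile()) # 1760
#' @export
hours_profile <- function(hours = NULL,
                          standard_week = 40,
                          working_weeks = 44) {
  if (!is.numeric(standard_week) || length(standard_week) != 1L ||
      is.na(standard_week) || standard_week <= 0) {
    abort("`standard_week` must be a single positive number.",
          class = "gp_config_error")
  }
  if (!is.numeric(working_weeks) || length(working_weeks) != 1L ||
      is.na(working_weeks) || working_weeks <= 0) {
    abort("`working_weeks` must be a single positive number.",
          class = "gp_config_error")
  }
  if (is.null(hours)) {
    hours <- tibble::tibble(
      status = gp_active_statuses,
      weekly_hours = c(40, 24)
    )
  }
  hours <- tibble::as_tibble(hours)
  if (!all(c("status", "weekly_hours") %in% names(hours))) {
    abort("`hours` needs columns `status` and `weekly_hours`.",
          class = "gp_schema_error")
  }
  bad <- setdiff(unique(hours$status), gp_active_statuses)
  if (length(bad)) {
    abort(paste0("Unknown status label(s) in hours table: ",
                 paste(bad, collapse = ", ")),
          class = "gp_schema_error")
  }
  if (any(!is.finite(hours$weekly_hours)) || any(hours$weekly_hours < 0)) {
    abort("`weekly_hours` must be finite and non-negative.",
          class = "gp_config_error")
  }
  means <- tapply(hours$weekly_hours, hours$status, mean)
  ft <- if ("full_time" %in% names(means)) means[["full_time"]] else NA_real_
  pt <- if ("part_time" %in% names(means)) means[["part_time"]] else NA_real_
  if (!is.na(pt) && pt >= 35) {
    abort("Mean part-time weekly hours must be below 35.",
          class = "gp_config_error")
  }
  if (!is.na(ft) && ft < 35) {
    abort("Mean full-time weekly hours must be at least 35.",
          class = "gp_config_error")
  }
  structure(
    list(hours = hours, standard_week = standard_week,
         working_weeks = working_weeks),
    class = "hours_profile"
  )
}

#' @export
print.hours_profile <- function(x, ...) {
  cat("<hours_profile> standard week", x$standard_week, "h,",
      x$working_weeks, "working weeks (",
      annual_clinical_hours(x), "clinical h/FTE/year )\n")
  print(x$hours)
  invisible(x)
}

#' Annual clinical hours supplied by one FTE
#'
#' @param profile An [hours_profile()].
#' @return `standard_week * working_weeks`, in hours/year (1760 with the
#'   default 40-hour week and 44-week year).
#' @export
annual_clinical_hours <- function(profile) {
  stopifnot(inherits(profile, "hours_profile"))
  profile$standard_week * profile$working_weeks
}

# Resolve mean weekly hours for each row of `strata` (sex, age_band, status),
# falling back full stratum -> status-only mean. Rows with `need = FALSE`
# (zero headcount) tolerate a missing entry.
lookup_weekly_hours <- function(profile, strata, need = NULL) {
  hrs <- profile$hours
  out <- rep(NA_real_, nrow(strata))
  if (all(c("sex", "age_band") %in% names(hrs))) {
    m <- dplyr::left_join(
      strata, hrs,
      by = c("sex", "age_band", "status")
    )
    out <- m$weekly_hours
  }
  status_mean <- tapply(hrs$weekly_hours, hrs$status, mean)
  miss <- is.na(out)
  out[miss] <- unname(status_mean[strata$status[miss]])
  if (is.null(need)) need <- rep(TRUE, nrow(strata))
  bad <- is.na(out) & need & strata$status %in% gp_active_statuses
  if (any(bad)) {
    abort(paste0(
      "No weekly hours available for populated stratum: ",
      paste(unique(paste(strata$sex[bad], strata$age_band[bad],
                         strata$status[bad], sep = "/")), collapse = "; ")
    ), class = "gp_schema_error")
  }
  out
}

#' Convert a headcount stock to full-time equivalents
#'
#' Each active state's FTE is its headcount times mean weekly clinical hours
#' over the standard full-time week; exit states contribute zero FTE. The
#' conversion is linear, so doubling all headcounts doubles total FTE.
#'
#' @param stock Data frame with columns `sex`, `age_band`, `location`,
#'   `status`, `headcount` (a `year` column is carried through if present).
#' @param profile An [hours_profile()].
#' @return The input as a tibble with an added `fte` column.
#' @seealso [fte_total()] for the scalar sum.
#' @examples
#' stock <- tibble::tibble(
#'   sex = "male", age_band = "45_54", location = "urban",
#'   status = c("full_time", "part_time"), headcount = c(100, 10)
#' )
#' prof <- hours_profile(data.frame(
#'   status = c("full_time", "part_time"), weekly_hours = c(40, 20)
#' ))
#' headcount_to_fte(stock, prof)$fte # 100 and 5
#' @export
headcount_to_fte <- function(stock, profile) {
  stopifnot(inherits(profile, "hours_profile"))
  stock <- tibble::as_tibble(stock)
  validate_categories(stock, c("sex", "age_band", "location", "status"))
  if (!"headcount" %in% names(stock)) {
    abort("`stock` needs a `headcount` column.", class = "gp_schema_error")
  }
  if (any(stock$headcount < 0, na.rm = TRUE)) {
    abort("Headcounts must be non-negative.", class = "gp_schema_error")
  }
  wh <- lookup_weekly_hours(profile, stock, need = stock$headcount > 0)
  active <- stock$status %in% gp_active_statuses
  fte <- numeric(nrow(stock))
  fte[active] <- stock$headcount[active] * wh[active] / profile$standard_week
  dplyr::mutate(stock, fte = fte)
}

#' Total FTE in a stock
#'
#' @inheritParams headcount_to_fte
#' @return Total FTE summed over active states. If `stock` has a `year`
#'   column with several years, a tibble of per-year totals instead.
#' @export
fte_total <- function(stock, profile) {
  ft <- headcount_to_fte(stock, profile)
  if ("year" %in% names(ft) && dplyr::n_distinct(ft$year) > 1L) {
    return(dplyr::summarise(dplyr::group_by(ft, .data$year),
                            headcount = sum(.data$headcount),
                            fte = sum(.data$fte), .groups = "drop"))
  }
  sum(ft$fte)
}

# Validate that the category columns of a table use the fixed vocabulary.
validate_categories <- function(df, cols, where = "table") {
  lv <- gp_levels()
  for (cl in intersect(cols, names(df))) {
    if (!cl %in% names(lv)) next
    bad <- setdiff(unique(df[[cl]]), lv[[cl]])
    if (length(bad)) {
      abort(paste0("Unknown ", cl, " label(s) in ", where, ": ",
                   paste(bad, collapse = ", ")),
            class = "gp_schema_error")
    }
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0("Missing column(s) in ", where, ": ",
                 paste(missing, collapse = ", ")),
          class = "gp_schema_error")
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
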