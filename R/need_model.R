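# Needs-based demand: fit base-year service norms, project burden and
# required consultations, convert to required FTE GPs.
#
# The fit inverts the base-year utilisation data: within each age/sex cell,
# the share of consultations managing each condition chapter times total
# attendances, divided by that chapter's incident plus prevalent cases,
# gives annual consultations per case. Preventive/administrative activity is
# expressed per capita. Shares may sum above 1 because one consultation can
# manage several problems; each chapter is fitted independently and the
# reconstruction identity holds on the share-weighted sum as fitted.

pa_chapter <- "prevent_admin"

#' Fit the base-year service profile
#'
#' Estimates annual consultations per incident/prevalent case for each
#' condition chapter by sex and age band, and per-capita preventive/
#' administrative consultation rates, such that projecting the profile on
#' its own fitting inputs reproduces the base-year attendance totals exactly
#' (reconstruction identity).
#'
#' @param attendances Data frame `sex`, `age_band`, `consultations`
#'   (base-year totals; a single-year `year` column is tolerated).
#' @param mix Data frame `chapter`, `sex`, `age_band`, `proportion`: the
#'   share of consultations in which each chapter is managed. The reserved
#'   chapter `"prevent_admin"` carries the preventive/administrative share.
#' @param burden Data frame `chapter`, `sex`, `age_band`, `incident_cases`,
#'   `prevalent_cases` for the base year.
#' @param population Data frame `sex`, `age_band`, `persons` for the base
#'   year (a single-year `year` column is tolerated).
#' @param lengths Data frame `sex`, `age_band`, `mean_minutes`: mean
#'   consultation length.
#' @return A `service_profile`: list with `per_case`, `prevent_admin`
#'   (per-capita rates), `lengths`, and the fitting inputs' chapter set.
#' @export
fit_service_profile <- function(attendances, mix, burden, population,
                                lengths) {
  att <- one_year(attendances, "consultations")
  pop <- one_year(population, "persons")
  mix <- tibble::as_tibble(mix)
  burden <- tibble::as_tibble(burden)
  lengths <- tibble::as_tibble(lengths)
  validate_categories(att, c("sex", "age_band", "consultations"),
                      "attendances")
  validate_categories(pop, c("sex", "age_band", "persons"), "population")
  validate_categories(mix, c("chapter", "sex", "age_band", "proportion"),
                      "condition mix")
  validate_categories(burden, c("chapter", "sex", "age_band",
                                "incident_cases", "prevalent_cases"),
                      "burden table")
  validate_categories(lengths, c("sex", "age_band", "mean_minutes"),
                      "consultation lengths")
  if (any(lengths$mean_minutes <= 0)) {
    abort("Mean consultation lengths must be positive.",
          class = "gp_config_error")
  }
  if (any(mix$proportion < 0)) {
    abort("Condition-mix proportions must be non-negative.",
          class = "gp_schema_error")
  }
  if (any(burden$incident_cases < 0) || any(burden$prevalent_cases < 0)) {
    abort("Case counts must be non-negative.", class = "gp_schema_error")
  }

  cases <- dplyr::transmute(
    burden, chapter = .data$chapter, sex = .data$sex,
    age_band = .data$age_band,
    cases = .data$incident_cases + .data$prevalent_cases
  )
  cond <- dplyr::filter(mix, .data$chapter != pa_chapter)
  fit <- dplyr::left_join(cond, att, by = c("sex", "age_band"))
  fit <- dplyr::left_join(fit, cases, by = c("chapter", "sex", "age_band"))
  if (anyNA(fit$consultations)) {
    abort("Condition mix covers strata absent from the attendance table.",
          class = "gp_schema_error")
  }
  fit$cases[is.na(fit$cases)] <- 0
  bad <- fit$proportion > 0 & fit$cases == 0
  if (any(bad)) {
    ex <- fit[bad, ][1, ]
    abort(sprintf(
      "Positive consultation share with zero cases for chapter '%s', %s %s.",
      ex$chapter, ex$sex, ex$age_band), class = "gp_fit_error")
  }
  per_case <- dplyr::transmute(
    fit, chapter = .data$chapter, sex = .data$sex, age_band = .data$age_band,
    per_case = ifelse(.data$proportion == 0, 0,
                      .data$consultations * .data$proportion / .data$cases)
  )

  pa <- dplyr::filter(mix, .data$chapter == pa_chapter)
  pa <- dplyr::left_join(pa, att, by = c("sex", "age_band"))
  pa <- dplyr::left_join(pa, pop, by = c("sex", "age_band"))
  if (nrow(pa) && anyNA(pa$persons)) {
    abort("Preventive/administrative shares cover strata missing from the population table.",
          class = "gp_schema_error")
  }
  prevent_admin <- dplyr::transmute(
    pa, sex = .data$sex, age_band = .data$age_band,
    per_capita = ifelse(.data$proportion == 0, 0,
                        .data$consultations * .data$proportion /
                          .data$persons)
  )

  structure(
    list(per_case = per_case, prevent_admin = prevent_admin,
         lengths = lengths,
         chapters = sort(unique(per_case$chapter))),
    class = "service_profile"
  )
}

one_year <- function(df, what) {
  df <- tibble::as_tibble(df)
  if ("year" %in% names(df)) {
    if (dplyr::n_distinct(df$year) > 1L) {
      abort(paste0("The ", what, " table must cover a single (base) year."),
            class = "gp_schema_error")
    }
    df$year <- NULL
  }
  df
}

#' @export
print.service_profile <- function(x, ...) {
  cat("<service_profile>", length(x$chapters), "chapters x",
      nrow(unique(x$per_case[, c("sex", "age_band")])), "strata\n")
  invisible(x)
}

#' @rdname fit_service_profile
#' @param x A `service_profile`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.service_profile <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$per_case, rate = .data$per_case, per_case = NULL,
                  unit = "consultations_per_case"),
    dplyr::mutate(x$prevent_admin, chapter = pa_chapter,
                  rate = .data$per_capita, per_capita = NULL,
                  unit = "consultations_per_person")
  )
}

#' Project burden-of-disease cases to a target year
#'
#' Base-year per-capita case rates (cases divided by persons in each
#' chapter/sex/age cell) are applied to the projected population and
#' compounded by the annual `growth` factor in age- and sex-specific rates:
#' `cases(year) = rate_base * persons(year) * growth^(year - base_year)`.
#' `growth = 1` keeps rates constant (scenarios 1-2); 1.02 raises incidence
#' and prevalence by 2%/year (scenario 3).
#'
#' @param burden Base-year burden table (`chapter`, `sex`, `age_band`,
#'   `incident_cases`, `prevalent_cases`; or a combined `cases` column).
#' @param population Population projection (`year`, `sex`, `age_band`,
#'   `persons`) covering the base year and `year`.
#' @param year Target calendar year.
#' @param base_year Base year of the burden table (default 2003).
#' @param growth Annual growth factor in per-capita case rates.
#' @return Tibble `chapter`, `sex`, `age_band`, `cases` for `year`.
#' @export
project_burden <- function(burden, population, year, base_year = 2003,
                           growth = 1) {
  if (growth <= 0) abort("`growth` must be positive.",
                         class = "gp_config_error")
  burden <- tibble::as_tibble(burden)
  if (!"cases" %in% names(burden)) {
    validate_categories(burden, c("chapter", "sex", "age_band",
                                  "incident_cases", "prevalent_cases"),
                        "burden table")
    burden$cases <- burden$incident_cases + burden$prevalent_cases
  }
  population <- tibble::as_tibble(population)
  validate_categories(population, c("year", "sex", "age_band", "persons"),
                      "population projection")
  pop_b <- dplyr::filter(population, .data$year == base_year)
  pop_t <- dplyr::filter(population, .data$year == .env$year)
  out <- dplyr::left_join(
    burden[, c("chapter", "sex", "age_band", "cases")],
    dplyr::select(pop_b, "sex", "age_band", persons_base = "persons"),
    by = c("sex", "age_band")
  )
  out <- dplyr::left_join(
    out, dplyr::select(pop_t, "sex", "age_band", persons_t = "persons"),
    by = c("sex", "age_band")
  )
  if (anyNA(out$persons_base) || anyNA(out$persons_t)) {
    abort(sprintf(
      "Population projection is missing cells for year %d or %d.",
      base_year, year), class = "gp_schema_error")
  }
  if (any(out$persons_base <= 0 & out$cases > 0)) {
    abort("Positive cases in a cell with zero base-year population.",
          class = "gp_schema_error")
  }
  k <- year - base_year
  dplyr::transmute(
    out, chapter = .data$chapter, sex = .data$sex, age_band = .data$age_band,
    cases = ifelse(.data$cases == 0, 0,
                   .data$cases / .data$persons_base * .data$persons_t *
                     growth^k)
  )
}

#' Required consultations for one year
#'
#' Condition-managing consultations are `per_case * utilisation^k * cases`
#' summed over chapters; preventive/administrative consultations scale with
#' the population at the fitted per-capita rates. At the base year
#' (`k = 0`) on the fitting inputs this reproduces observed attendances
#' exactly.
#'
#' @param profile A [fit_service_profile()] result.
#' @param burden Burden table for the target year (`chapter`, `sex`,
#'   `age_band`, `cases`), e.g. from [project_burden()].
#' @param population Population for the target year (`sex`, `age_band`,
#'   `persons`; a single-year `year` column is tolerated).
#' @param utilisation Annual growth factor in per-case service use
#'   (1.0112 in scenario 2, 1 otherwise).
#' @param k Whole years since the base year.
#' @return Tibble `sex`, `age_band`, `consultations`.
#' @export
project_consultations <- function(profile, burden, population,
                                  utilisation = 1, k = 0) {
  stopifnot(inherits(profile, "service_profile"))
  if (utilisation <= 0) abort("`utilisation` must be positive.",
                              class = "gp_config_error")
  if (k < 0) abort("`k` must be >= 0.", class = "gp_config_error")
  burden <- tibble::as_tibble(burden)
  if (!"cases" %in% names(burden)) {
    burden$cases <- burden$incident_cases + burden$prevalent_cases
  }
  pop <- one_year(population, "persons")
  cond <- dplyr::left_join(
    profile$per_case, burden[, c("chapter", "sex", "age_band", "cases")],
    by = c("chapter", "sex", "age_band")
  )
  cond$cases[is.na(cond$cases)] <- 0
  cond_sum <- dplyr::summarise(
    dplyr::group_by(cond, .data$sex, .data$age_band),
    condition = sum(.data$per_case * utilisation^k * .data$cases),
    .groups = "drop"
  )
  pa <- dplyr::left_join(profile$prevent_admin,
                         pop[, c("sex", "age_band", "persons")],
                         by = c("sex", "age_band"))
  if (nrow(pa) && anyNA(pa$persons)) {
    abort("Population is missing strata needed for preventive/administrative volumes.",
          class = "gp_schema_error")
  }
  pa_sum <- dplyr::transmute(pa, sex = .data$sex, age_band = .data$age_band,
                             pa = .data$per_capita * .data$persons)
  out <- dplyr::full_join(cond_sum, pa_sum, by = c("sex", "age_band"))
  out$condition[is.na(out$condition)] <- 0
  out$pa[is.na(out$pa)] <- 0
  dplyr::transmute(out, sex = .data$sex, age_band = .data$age_band,
                   consultations = .data$condition + .data$pa)
}

#' Convert required consultations to required FTE GPs
#'
#' Total required clinical minutes are consultations times the mean
#' consultation length per age/sex cell; dividing by 60 and by the annual
#' clinical hours of one FTE gives the required FTE GP count.
#'
#' @param consultations Tibble `sex`, `age_band`, `consultations`.
#' @param lengths Tibble `sex`, `age_band`, `mean_minutes`; defaults to the
#'   profile's lengths when `profile` carries them and `lengths` is `NULL`.
#' @param profile An [hours_profile()] (defines annual clinical hours/FTE).
#' @return Required FTE (a single number).
#' @examples
#' prof <- hours_profile()
#' cons <- tibble::tibble(sex = "female", age_band = "35_44",
#'                        consultations = 1760)
#' len <- tibble::tibble(sex = "female", age_band = "35_44",
#'                       mean_minutes = 60)
#' consultations_to_fte(cons, len, prof) # 1
#' @export
consultations_to_fte <- function(consultations, lengths, profile) {
  stopifnot(inherits(profile, "hours_profile"))
  cons <- tibble::as_tibble(consultations)
  validate_categories(cons, c("sex", "age_band", "consultations"),
                      "consultations")
  lengths <- tibble::as_tibble(lengths)
  validate_categories(lengths, c("sex", "age_band", "mean_minutes"),
                      "consultation lengths")
  if (any(lengths$mean_minutes <= 0)) {
    abort("Mean consultation lengths must be positive.",
          class = "gp_config_error")
  }
  j <- dplyr::left_join(cons, lengths, by = c("sex", "age_band"))
  if (anyNA(j$mean_minutes)) {
    abort("Consultation lengths are missing for some strata.",
          class = "gp_schema_error")
  }
  sum(j$consultations * j$mean_minutes) / 60 / annual_clinical_hours(profile)
}

#' Recode burden categories onto condition chapters
#'
#' Burden-of-disease sources group conditions by cause (ICD-10-based
#' categories); the service profile is keyed by primary-care condition
#' chapters (ICPC-2 chapter headings). This applies a user-supplied
#' two-column crosswalk and sums cases within each target chapter.
#'
#' @param burden Data frame with a `chapter` column holding source category
#'   labels plus `sex`, `age_band` and case columns.
#' @param mapping Data frame `source_category`, `icpc2_chapter`.
#' @return The burden table recoded and aggregated by `icpc2_chapter`.
#' @export
map_burden_categories <- function(burden, mapping) {
  burden <- tibble::as_tibble(burden)
  mapping <- tibble::as_tibble(mapping)
  validate_categories(mapping, c("source_category", "icpc2_chapter"),
                      "category mapping")
  i <- match(burden$chapter, mapping$source_category)
  if (anyNA(i)) {
    abort(paste0("Unmapped burden categor(ies): ",
                 paste(unique(burden$chapter[is.na(i)]), collapse = ", ")),
          class = "gp_schema_error")
  }
  burden$chapter <- mapping$icpc2_chapter[i]
  case_cols <- intersect(c("incident_cases", "prevalent_cases", "cases"),
                         names(burden))
  dplyr::summarise(
    dplyr::group_by(burden, .data$chapter, .data$sex, .data$age_band),
    dplyr::across(dplyr::all_of(case_cols), sum),
    .groups = "drop"
  )
}
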