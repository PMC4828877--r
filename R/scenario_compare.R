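# Scenario runner and predicted-vs-observed validation reports.
#
# Three preset scenarios vary what is held constant from the base year:
#   scenario_1: 2003 utilisation optimal, per-capita case rates constant --
#               requirements driven by population demographics alone.
#   scenario_2: utilisation optimal by 2013 -- per-case service use grows
#               1.12%/year (utilisation multiplier 1.0112).
#   scenario_3: need grows -- incidence/prevalence rates rise 2%/year
#               (burden growth 1.02).

#' Specify a need-model scenario
#'
#' @param name Scenario name. `"scenario_1"`, `"scenario_2"` and
#'   `"scenario_3"` are presets fixing the two factors below; `"custom"`
#'   leaves them to the caller.
#' @param utilisation_multiplier Annual growth factor in per-case service
#'   use (preset 1.0112 in scenario 2, else 1).
#' @param burden_growth Annual growth factor in per-capita incidence and
#'   prevalence rates (preset 1.02 in scenario 3, else 1).
#' @param base_year Need-model base year (default 2003).
#' @param horizon Years to project beyond the base year (default 10).
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name = "custom", utilisation_multiplier = 1,
                          burden_growth = 1, base_year = 2003,
                          horizon = 10) {
  presets <- list(
    scenario_1 = c(1, 1),
    scenario_2 = c(1.0112, 1),
    scenario_3 = c(1, 1.02)
  )
  if (name %in% names(presets)) {
    utilisation_multiplier <- presets[[name]][1]
    burden_growth <- presets[[name]][2]
  }
  if (utilisation_multiplier <= 0 || burden_growth <= 0) {
    abort("Scenario growth factors must be positive.",
          class = "gp_config_error")
  }
  if (horizon < 0) abort("`horizon` must be >= 0.", class = "gp_config_error")
  structure(
    list(name = name, utilisation_multiplier = utilisation_multiplier,
         burden_growth = burden_growth, base_year = base_year,
         horizon = horizon),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %s: utilisation x%.4f/yr, burden x%.2f/yr, %d + %d years\n",
    x$name, x$utilisation_multiplier, x$burden_growth, x$base_year,
    x$horizon))
  invisible(x)
}

#' Run a need-model scenario end to end
#'
#' For each year of the horizon, projects burden ([project_burden()]),
#' required consultations ([project_consultations()]) and required FTE GPs
#' ([consultations_to_fte()]).
#'
#' @param spec A [scenario_spec()].
#' @param profile A fitted [fit_service_profile()].
#' @param burden Base-year burden table.
#' @param population Population projection covering all scenario years.
#' @param hours An [hours_profile()].
#' @return A `need_projection` tibble with `year`, `consultations` and
#'   `fte_required`, one row per year from the base year.
#' @export
run_scenario <- function(spec, profile, burden, population, hours) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(profile, "service_profile"),
            inherits(hours, "hours_profile"))
  population <- tibble::as_tibble(population)
  years <- spec$base_year + 0:spec$horizon
  rows <- purrr::map_dfr(years, function(y) {
    k <- y - spec$base_year
    b <- project_burden(burden, population, year = y,
                        base_year = spec$base_year,
                        growth = spec$burden_growth)
    pop_y <- dplyr::filter(population, .data$year == y)
    cons <- project_consultations(profile, b, pop_y,
                                  utilisation = spec$utilisation_multiplier,
                                  k = k)
    tibble::tibble(
      year = y,
      consultations = sum(cons$consultations),
      fte_required = consultations_to_fte(cons, profile$lengths, hours)
    )
  })
  structure(rows, class = c("need_projection", class(rows)),
            scenario = spec)
}

#' Compare a predicted series with an observed series
#'
#' Exact per-year differencing: signed difference (predicted minus
#' observed), absolute difference and percent difference with the observed
#' value as denominator. The report's summary is the summed absolute
#' difference across years.
#'
#' @param predicted,observed Either numeric vectors of equal length or data
#'   frames with a `year` column and one value column (the first non-`year`
#'   column is used); data frames are joined on `year`.
#' @param years Optional years for the vector form.
#' @return A `validation_report` tibble with columns `year`, `predicted`,
#'   `observed`, `diff`, `abs_diff`, `pct_diff` (percent). [glance()] gives
#'   the summary row.
#' @examples
#' glance(compare_series(1140, 1187))$total_abs_diff # 47
#' @export
compare_series <- function(predicted, observed, years = NULL) {
  as_series <- function(x, nm) {
    if (is.data.frame(x)) {
      x <- tibble::as_tibble(x)
      if (!"year" %in% names(x)) {
        abort("Data-frame series need a `year` column.",
              class = "gp_schema_error")
      }
      val <- setdiff(names(x), "year")[1]
      tibble::tibble(year = x$year, value = x[[val]])
    } else {
      tibble::tibble(year = years %||% seq_along(x), value = as.numeric(x))
    }
  }
  p <- as_series(predicted, "predicted")
  o <- as_series(observed, "observed")
  j <- dplyr::inner_join(p, o, by = "year", suffix = c("_p", "_o"))
  if (!nrow(j)) {
    abort("Predicted and observed series share no years.",
          class = "gp_schema_error")
  }
  out <- tibble::tibble(
    year = j$year,
    predicted = j$value_p,
    observed = j$value_o,
    diff = j$value_p - j$value_o,
    abs_diff = abs(j$value_p - j$value_o),
    pct_diff = (j$value_p - j$value_o) / j$value_o * 100
  )
  structure(out, class = c("validation_report", class(out)))
}

#' @rdname compare_series
#' @param x A `validation_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n_years = nrow(x),
    total_abs_diff = sum(x$abs_diff),
    mean_pct_diff = mean(x$pct_diff),
    max_abs_pct_diff = max(abs(x$pct_diff))
  )
}

#' @rdname compare_series
#' @exportS3Method generics::tidy
tidy.validation_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
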