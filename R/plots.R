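# ggplot2 autoplot methods for the main result types.

#' Plot a supply projection
#'
#' Active headcount per year, optionally faceted by a stratifier.
#'
#' @param object A [project_supply()] result.
#' @param by Optional stratifier column to colour by (`"sex"`,
#'   `"age_band"`, `"location"` or `"status"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gp_supply_projection <- function(object, by = NULL, ...) {
  df <- dplyr::filter(tibble::as_tibble(object),
                      .data$status %in% gp_active_statuses)
  grp <- c("year", by)
  df <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(grp))),
    headcount = sum(.data$headcount), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$headcount))
  if (is.null(by)) {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  } else {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data[[by]])) +
      ggplot2::geom_point(ggplot2::aes(colour = .data[[by]]))
  }
  p + ggplot2::labs(y = "Active GP headcount", x = "Year")
}

#' Plot a need projection
#'
#' Required FTE GPs per year under the scenario.
#'
#' @param object A [run_scenario()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.need_projection <- function(object, ...) {
  spec <- attr(object, "scenario")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$year, .data$fte_required)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "Required FTE GPs", x = "Year",
                  title = if (!is.null(spec)) spec$name else NULL)
}

#' Plot a validation report
#'
#' Predicted and observed series as lines over the shared years.
#'
#' @param object A [compare_series()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("year", "predicted", "observed")],
    -"year", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "Value", x = "Year", colour = NULL)
}

#' Plot calibration deviations
#'
#' Maximum per-target deviation of each accepted parameter set against the
#' tolerance.
#'
#' @param object A [calibrate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gp_calibration <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$max_deviation)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$tolerance, linetype = 2) +
    ggplot2::labs(x = "Maximum per-target deviation (accepted sets)",
                  y = "Count")
}
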