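#' Plot the percent changes of a scenario
#'
#' Bar chart of percent change from base case for the primary outcomes
#' (energy, SFA, added sugars, sodium, alcohol) plus food mass.
#'
#' @param object A `scenario_result`.
#' @param nutrients Nutrient columns to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_result <- function(object,
                                     nutrients = c("grams", "energy_kj", "sfa",
                                                   "added_sugars", "sodium", "alcohol"),
                                     ...) {
  df <- object$changes[object$changes$nutrient %in% nutrients, ]
  df$nutrient <- factor(df$nutrient, levels = nutrients)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nutrient, y = .data$pct_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = NULL, y = "% change from base case",
      title = object$label
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity envelope
#'
#' Primary percent changes with error bars spanning the lower/upper
#' sensitivity parameter sets, in the style of scenario-comparison figures.
#'
#' @param suite Result of [run_sensitivity_suite()] containing `primary`,
#'   `lower` and `upper` entries.
#' @param nutrients Nutrient columns to display.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(suite,
                             nutrients = c("grams", "energy_kj", "sfa",
                                           "added_sugars", "sodium", "alcohol")) {
  stopifnot(all(c("primary", "lower", "upper") %in% names(suite)))
  long <- tidy_suite(suite)
  long <- long[long$nutrient %in% nutrients, ]
  wide <- tidyr::pivot_wider(
    long[, c("nutrient", "parameter_set", "pct_change")],
    names_from = "parameter_set", values_from = "pct_change"
  )
  wide$nutrient <- factor(wide$nutrient, levels = nutrients)
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$nutrient, y = .data$primary)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmin(.data$lower, .data$upper),
        ymax = pmax(.data$lower, .data$upper)
      ),
      width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "% change from base case (with sensitivity bounds)") +
    ggplot2::theme_minimal()
}
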