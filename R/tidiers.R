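#' Tidy a scenario result
#'
#' Returns the per-nutrient base/modelled/percent-change table in long
#' form, one row per nutrient of the registry.
#'
#' @param x A `scenario_result` from [run_scenario()].
#' @param ... Unused.
#' @return A tibble with `scenario`, `nutrient`, `unit`, `base_value`,
#'   `modelled_value`, `pct_change`.
#' @export
tidy.scenario_result <- function(x, ...) {
  x$changes
}

#' Glance at a scenario result
#'
#' One-row summary with the model's primary outcomes: percent change in
#' energy, saturated fat, added sugars, sodium and alcohol.
#'
#' @inheritParams tidy.scenario_result
#' @return A one-row tibble.
#' @export
glance.scenario_result <- function(x, ...) {
  grab <- function(nm) x$changes$pct_change[x$changes$nutrient == nm]
  tibble::tibble(
    scenario = x$label,
    family = x$spec$family,
    target = x$spec$target,
    energy_pct = grab("energy_kj"),
    sfa_pct = grab("sfa"),
    added_sugars_pct = grab("added_sugars"),
    sodium_pct = grab("sodium"),
    alcohol_pct = grab("alcohol")
  )
}

#' Tidy a sensitivity suite
#'
#' Binds the tidy tables of a [run_sensitivity_suite()] result, labelling
#' each parameter set.
#'
#' @param suite Named list of `scenario_result`s.
#' @return A long tibble with a `parameter_set` column.
#' @export
tidy_suite <- function(suite) {
  purrr::imap_dfr(suite, function(res, nm) {
    out <- tidy(res)
    out$parameter_set <- nm
    out
  })
}
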