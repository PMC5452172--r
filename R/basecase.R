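#' Aggregate intake profiles
#'
#' An `aggregate_profile` is a tibble of population mean daily intakes with
#' one row per reporting class (`total`, `core`, `discretionary`,
#' `discretionary_food`, `discretionary_beverage`) and one column per
#' nutrient, plus the food mass (`grams`) and tracked energy (`energy_kj`).
#' It is both the output of population-weighted aggregation and, in
#' aggregate mode, a direct input to the scenario transforms, so published
#' class-level mean-intake tables can be run through every scenario without
#' person-level microdata.
#'
#' @param x A data frame with a `class` column and nutrient columns.
#' @param n_effective Sum of population weights behind the means.
#' @return A tibble of class `aggregate_profile`.
#' @export
aggregate_profile <- function(x, n_effective = NA_real_) {
  x <- tibble::as_tibble(x)
  if (!"class" %in% names(x)) abort("An aggregate profile needs a 'class' column")
  unknown <- setdiff(x$class, profile_classes())
  if (length(unknown)) abort(paste0("Unknown profile class(es): ", paste(unknown, collapse = ", ")))
  for (nm in setdiff(nutrient_names(), names(x))) x[[nm]] <- NA_real_
  x <- x[, c("class", nutrient_names())]
  structure(x, class = c("aggregate_profile", class(tibble::tibble()))) |>
    set_n_effective(n_effective)
}

set_n_effective <- function(x, n) {
  attr(x, "n_effective") <- n
  x
}

#' @rdname aggregate_profile
#' @export
n_effective <- function(x) attr(x, "n_effective")

#' @rdname aggregate_profile
#' @export
profile_classes <- function() {
  c("total", "core", "discretionary", "discretionary_food", "discretionary_beverage")
}

# reporting-class membership of food classes; discretionary beverages
# exclude sports products and meal replacements (survey reporting
# convention), which still count toward total discretionary choices.
class_line_filter <- function(lines, which) {
  switch(which,
    total = rep(TRUE, nrow(lines)),
    core = lines$class %in% c("core_food", "core_beverage"),
    discretionary = lines$class %in% c("discretionary_food", "discretionary_beverage"),
    discretionary_food = lines$class == "discretionary_food",
    discretionary_beverage = lines$class == "discretionary_beverage" &
      !lines$is_sports_or_meal_replacement,
    abort(paste0("Unknown profile class: ", which))
  )
}

#' Population-weighted mean daily intake
#'
#' For each nutrient, computes
#' \eqn{\sum_p w_p x_p / \sum_p w_p} where \eqn{x_p} is person \eqn{p}'s
#' daily amount over the selected food classes and \eqn{w_p} the population
#' expansion weight. Persons with no qualifying intake contribute zero to
#' the numerator but remain in the denominator (per-capita means).
#'
#' @param data A [diet_data()] object.
#' @param classes Food classes to include (see [food_classes()]); default all.
#' @param lines Optionally, a pre-expanded line table from [expand_intake()]
#'   (possibly transformed by a scenario) to aggregate instead of
#'   `data$intakes`.
#' @return A one-row tibble of mean daily amounts with attribute
#'   `n_effective`.
#' @export
population_mean_intake <- function(data, classes = food_classes(), lines = NULL) {
  stopifnot(inherits(data, "diet_data"))
  if (is.null(lines)) lines <- expand_intake(data)
  total_w <- sum(data$persons$weight)
  if (total_w <= 0) abort("Total population weight must be positive")
  keep <- lines[lines$class %in% classes, ]
  weighted_line_means(keep, data$persons, total_w)
}

weighted_line_means <- function(lines, persons, total_w = sum(persons$weight)) {
  if (total_w <= 0) abort("Total population weight must be positive")
  w <- persons$weight[match(lines$person_id, persons$person_id)]
  cols <- c("grams", intersect(profile_columns(), names(lines)))
  out <- tibble::as_tibble(lapply(
    setNames(cols, cols),
    function(col) sum(w * lines[[col]]) / total_w
  ))
  set_n_effective(out, total_w)
}

#' Aggregate a dataset into the standard class-level profile table
#'
#' Builds the five-row [aggregate_profile()] (total, core, discretionary,
#' discretionary foods, discretionary beverages) from person-level data —
#' the base-case table of a simulation run.
#'
#' @inheritParams population_mean_intake
#' @return An [aggregate_profile()].
#' @export
aggregate_classes <- function(data, lines = NULL) {
  stopifnot(inherits(data, "diet_data"))
  if (is.null(lines)) lines <- expand_intake(data)
  total_w <- sum(data$persons$weight)
  rows <- purrr::map(profile_classes(), function(cl) {
    keep <- lines[class_line_filter(lines, cl), ]
    m <- weighted_line_means(keep, data$persons, total_w)
    tibble::tibble(class = cl, !!!m)
  })
  aggregate_profile(dplyr::bind_rows(rows), n_effective = total_w)
}

#' Published Australian adult base-case intake profile
#'
#' Population-weighted mean daily intake of Australian adults (19 years and
#' over) from the 2011--12 National Nutrition and Physical Activity Survey
#' (single 24-h recall, n = 9341), as published at the class level: total
#' intake, core choices, all discretionary choices, discretionary foods and
#' discretionary beverages (the last excluding meal replacements and sports
#' products). This is the reference input for aggregate-mode scenario runs.
#' MUFA/PUFA splits are not published at this level and are `NA`.
#'
#' Note the published class columns are independently rounded, so they do
#' not always sum exactly to the published totals (e.g. sodium).
#'
#' @return An [aggregate_profile()] with `n_effective = 9341`.
#' @export
#' @examples
#' aus_basecase()
aus_basecase <- function() {
  vals <- tibble::tribble(
    ~nutrient,      ~total, ~core, ~discretionary, ~discretionary_food, ~discretionary_beverage,
    "grams",        3337.7, 2652.2, 685.5, 178.8, 513.6,
    "energy_kj",    8697.8, 5654.0, 3043.8, 2173.5, 841.9,
    "protein",      91.0,   75.6,  15.4,  13.5,  0.9,
    "total_fat",    73.8,   47.4,  26.4,  26.1,  0.3,
    "sfa",          27.7,   16.1,  11.6,  11.4,  0.2,
    "carbohydrate", 225.9,  145.6, 80.4,  56.3,  23.6,
    "total_sugars", 102.9,  51.3,  51.5,  30.7,  20.6,
    "added_sugars", 50.6,   6.7,   43.9,  25.2,  18.6,
    "free_sugars",  57.8,   10.8,  47.1,  26.8,  20.2,
    "sodium",       2430.5, 1567.1, 863.5, 796.8, 61.6,
    "alcohol",      14.4,   0.0,   14.4,  0.0,   14.4,
    "fiber",        22.9,   19.9,  3.0,   2.9,   0.1,
    "vit_a_re",     851.8,  732.2, 119.6, 107.3, 7.9,
    "thiamin",      1.5,    1.2,   0.3,   0.3,   0.0,
    "riboflavin",   1.9,    1.5,   0.4,   0.3,   0.1,
    "niacin_eq",    41.4,   33.5,  7.9,   6.2,   1.4,
    "folate_dfe",   609.9,  529.0, 80.9,  74.1,  4.8,
    "vit_b6",       1.5,    1.1,   0.4,   0.2,   0.2,
    "vit_b12",      4.5,    3.8,   0.7,   0.6,   0.1,
    "vit_c",        102.3,  86.1,  16.2,  3.9,   12.1,
    "vit_e",        10.5,   7.8,   2.7,   2.6,   0.1,
    "calcium",      804.6,  677.6, 127.0, 93.4,  25.1,
    "iodine",       172.3,  146.5, 25.8,  17.9,  6.5,
    "iron",         11.1,   9.0,   2.2,   1.7,   0.4,
    "magnesium",    338.7,  274.2, 64.5,  40.6,  21.4,
    "phosphorus",   1466.9, 1137.3, 329.6, 259.8, 58.6,
    "potassium",    2912.5, 2345.5, 567.0, 413.2, 141.4,
    "selenium",     91.0,   75.4,  15.6,  12.9,  2.5,
    "zinc",         11.0,   9.3,   1.7,   1.5,   0.1
  )
  wide <- tidyr::pivot_longer(vals, -"nutrient", names_to = "class") |>
    tidyr::pivot_wider(names_from = "nutrient", values_from = "value")
  aggregate_profile(wide, n_effective = 9341)
}

profile_row <- function(profile, which) {
  row <- profile[profile$class == which, ]
  if (nrow(row) != 1) abort(paste0("Profile has no '", which, "' row"))
  row
}
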