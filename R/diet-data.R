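#' Assemble a validated survey dataset
#'
#' Bundles a food composition table, a person table with population
#' expansion weights, and single-day intake records into one validated
#' container, the unit every pipeline stage operates on.
#'
#' @param foods Tibble of foods: `food_code` (8-digit identifier), `name`,
#'   `subgroup_code` (3-digit food subgroup), logical flags
#'   `is_discretionary`, `is_beverage`, `is_water_based`, `is_alcoholic`,
#'   `is_milk`, `is_sports_or_meal_replacement`, and per-100 g nutrient
#'   columns named as in [nutrient_registry()] (except `grams`/`energy_kj`,
#'   which are derived).
#' @param persons Tibble with `person_id`, `weight` (> 0 expansion weight),
#'   optional `age`, `sex`.
#' @param intakes Tibble with `person_id`, `food_code`, `grams` consumed
#'   (>= 0; zero-gram trace records are legal and inert).
#' @param fat_tolerance Allowed excess of `sfa + mufa + pufa` over
#'   `total_fat` as a fraction (default 0.02, covering trans fats and
#'   rounding in source tables).
#' @return An object of class `diet_data`: a named list of the three
#'   validated tibbles, with the foods table augmented by a `class` column
#'   from [classify_foods()].
#' @export
diet_data <- function(foods, persons, intakes, fat_tolerance = 0.02) {
  foods <- validate_foods(foods, fat_tolerance = fat_tolerance)
  persons <- validate_persons(persons)
  intakes <- validate_intakes(intakes, foods, persons)
  structure(
    list(foods = classify_foods(foods), persons = persons, intakes = intakes),
    class = "diet_data"
  )
}

#' @export
print.diet_data <- function(x, ...) {
  cat(
    "<diet_data> ", nrow(x$persons), " persons, ", nrow(x$foods), " foods, ",
    nrow(x$intakes), " intake lines\n",
    sep = ""
  )
  cat("  classes:", paste(sort(unique(x$foods$class)), collapse = ", "), "\n")
  invisible(x)
}

food_flag_columns <- function() {
  c(
    "is_discretionary", "is_beverage", "is_water_based", "is_alcoholic",
    "is_milk", "is_sports_or_meal_replacement"
  )
}

validate_foods <- function(foods, fat_tolerance = 0.02) {
  foods <- tibble::as_tibble(foods)
  required <- c("food_code", "name", "subgroup_code", food_flag_columns())
  missing <- setdiff(required, names(foods))
  if (length(missing)) {
    abort(paste0("Composition table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  nut_required <- setdiff(profile_columns(), c("energy_kj", "mufa", "pufa"))
  missing_nut <- setdiff(nut_required, names(foods))
  if (length(missing_nut)) {
    abort(paste0("Composition table is missing nutrient column(s): ", paste(missing_nut, collapse = ", ")))
  }
  foods$food_code <- as.character(foods$food_code)
  foods$subgroup_code <- as.character(foods$subgroup_code)
  dup <- foods$food_code[duplicated(foods$food_code)]
  if (length(dup)) abort(paste0("Duplicate food_code(s): ", paste(unique(dup), collapse = ", ")))
  for (fl in food_flag_columns()) foods[[fl]] <- as.logical(foods[[fl]])
  bad_flag <- foods$food_code[foods$is_water_based & !foods$is_beverage]
  if (length(bad_flag)) abort(paste0("is_water_based implies is_beverage; violated by: ", paste(bad_flag, collapse = ", ")))
  bad_flag <- foods$food_code[foods$is_alcoholic & !foods$is_beverage]
  if (length(bad_flag)) abort(paste0("is_alcoholic implies is_beverage; violated by: ", paste(bad_flag, collapse = ", ")))
  msgs <- check_profile_invariants(foods, tolerance = fat_tolerance)
  if (length(msgs)) abort(paste0("Invalid composition values:\n  ", paste(msgs, collapse = "\n  ")))
  if (!"energy_kj" %in% names(foods)) foods$energy_kj <- compute_energy(foods)
  foods
}

validate_persons <- function(persons) {
  persons <- tibble::as_tibble(persons)
  missing <- setdiff(c("person_id", "weight"), names(persons))
  if (length(missing)) abort(paste0("Person table is missing column(s): ", paste(missing, collapse = ", ")))
  persons$person_id <- as.character(persons$person_id)
  persons$weight <- as.numeric(persons$weight)
  dup <- persons$person_id[duplicated(persons$person_id)]
  if (length(dup)) abort(paste0("Duplicate person_id(s): ", paste(unique(dup), collapse = ", ")))
  bad <- persons$person_id[is.na(persons$weight) | persons$weight <= 0]
  if (length(bad)) abort(paste0("Non-positive population weight for person(s): ", paste(bad, collapse = ", ")))
  if (!"age" %in% names(persons)) persons$age <- NA_real_
  if (!"sex" %in% names(persons)) persons$sex <- NA_character_
  persons
}

validate_intakes <- function(intakes, foods, persons) {
  intakes <- tibble::as_tibble(intakes)
  missing <- setdiff(c("person_id", "food_code", "grams"), names(intakes))
  if (length(missing)) abort(paste0("Intake table is missing column(s): ", paste(missing, collapse = ", ")))
  intakes$person_id <- as.character(intakes$person_id)
  intakes$food_code <- as.character(intakes$food_code)
  intakes$grams <- as.numeric(intakes$grams)
  if (any(is.na(intakes$grams) | intakes$grams < 0)) {
    bad <- which(is.na(intakes$grams) | intakes$grams < 0)
    abort(paste0("Negative or missing grams on intake line(s): ", paste(utils::head(bad, 10), collapse = ", ")))
  }
  unknown_food <- setdiff(unique(intakes$food_code), foods$food_code)
  if (length(unknown_food)) {
    abort(paste0("Intake lines reference unknown food_code(s): ", paste(unknown_food, collapse = ", ")))
  }
  unknown_person <- setdiff(unique(intakes$person_id), persons$person_id)
  if (length(unknown_person)) {
    abort(paste0("Intake lines reference unknown person_id(s): ", paste(unknown_person, collapse = ", ")))
  }
  intakes
}

#' Classify foods into core/discretionary food/beverage classes
#'
#' Every food maps to exactly one of `core_food`, `core_beverage`,
#' `discretionary_food`, `discretionary_beverage` from its survey flags.
#' Milk (plain or flavoured), although consumed as a liquid, is treated as
#' a food on nutritional grounds (protein, calcium, satiety) and because it
#' is typically consumed with meals, so milk-flagged beverages classify as
#' `core_food` and participate in food-side substitution.
#'
#' @param foods Foods tibble with the classification flag columns.
#' @param milk_as_food Treat `is_milk` beverages as foods (default `TRUE`).
#' @return The tibble with a `class` factor column appended.
#' @export
classify_foods <- function(foods, milk_as_food = TRUE) {
  beverage <- foods$is_beverage & !(milk_as_food & foods$is_milk)
  cls <- dplyr::case_when(
    !foods$is_discretionary & !beverage ~ "core_food",
    !foods$is_discretionary & beverage ~ "core_beverage",
    foods$is_discretionary & !beverage ~ "discretionary_food",
    TRUE ~ "discretionary_beverage"
  )
  foods$class <- factor(cls, levels = food_classes())
  foods
}

#' @rdname classify_foods
#' @export
food_classes <- function() {
  c("core_food", "core_beverage", "discretionary_food", "discretionary_beverage")
}

#' Expand intake lines into per-line consumed nutrient amounts
#'
#' Joins each intake record to its food's per-100 g composition and scales
#' linearly to the consumed grams, yielding the line-level nutrient table
#' that all person-mode scenario transforms operate on. Line energy is
#' recomputed from the macronutrients so it stays consistent after
#' composition-altering transforms.
#'
#' @param data A [diet_data()] object.
#' @return A tibble with `person_id`, `food_code`, `subgroup_code`, `class`,
#'   the food flags, `grams`, and absolute nutrient amount columns.
#' @export
expand_intake <- function(data) {
  stopifnot(inherits(data, "diet_data"))
  nut <- intersect(profile_columns(), names(data$foods))
  nut <- setdiff(nut, "energy_kj")
  comp <- data$foods[, c("food_code", "subgroup_code", "class", food_flag_columns(), nut)]
  out <- dplyr::inner_join(data$intakes, comp, by = "food_code")
  for (col in nut) out[[col]] <- out[[col]] * out$grams / 100
  out$energy_kj <- compute_energy(out)
  out
}
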