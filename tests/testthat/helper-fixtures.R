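# Small deterministic fixtures built in code.

zero_nutrients <- function() {
  nms <- setdiff(dietscen::nutrient_names(), c("grams", "energy_kj"))
  setNames(as.list(rep(0, length(nms))), nms)
}

# a minimal composition row; nutrient values per 100 g
toy_food <- function(food_code, name, subgroup_code,
                     discretionary = FALSE, beverage = FALSE,
                     water_based = FALSE, alcoholic = FALSE, milk = FALSE,
                     sports = FALSE, ...) {
  vals <- utils::modifyList(zero_nutrients(), list(...))
  tibble::tibble(
    food_code = food_code, name = name, subgroup_code = subgroup_code,
    is_discretionary = discretionary, is_beverage = beverage,
    is_water_based = water_based, is_alcoholic = alcoholic,
    is_milk = milk, is_sports_or_meal_replacement = sports,
    !!!vals
  )
}

toy_foods <- function() {
  dplyr::bind_rows(
    toy_food("10000001", "bread", "101",
             protein = 9, total_fat = 2.5, sfa = 0.5, mufa = 1, pufa = 0.9,
             carbohydrate = 45, total_sugars = 3, sodium = 450, fiber = 5,
             calcium = 30, iron = 1.1),
    toy_food("10000002", "milk", "102", beverage = TRUE, milk = TRUE,
             protein = 3.4, total_fat = 3.5, sfa = 2.3, mufa = 0.9, pufa = 0.2,
             carbohydrate = 5, total_sugars = 5, sodium = 44, calcium = 120),
    toy_food("10000003", "water", "103", beverage = TRUE, water_based = TRUE),
    toy_food("20000001", "cake", "201", discretionary = TRUE,
             protein = 5, total_fat = 15, sfa = 6, mufa = 6, pufa = 2.5,
             carbohydrate = 55, total_sugars = 30, added_sugars = 28,
             free_sugars = 28, sodium = 330, fiber = 1.5, calcium = 20),
    toy_food("20000002", "beer", "202", discretionary = TRUE, beverage = TRUE,
             water_based = TRUE, alcoholic = TRUE,
             protein = 0.3, carbohydrate = 1.5, total_sugars = 0.2, sodium = 5,
             alcohol = 3.9),
    toy_food("20000003", "soft drink", "203", discretionary = TRUE,
             beverage = TRUE, water_based = TRUE,
             carbohydrate = 11, total_sugars = 10.6, added_sugars = 10.6,
             free_sugars = 10.6, sodium = 12),
    toy_food("20000004", "protein shake", "204", discretionary = TRUE,
             beverage = TRUE, sports = TRUE,
             protein = 15, total_fat = 1.5, sfa = 0.5, mufa = 0.5, pufa = 0.3,
             carbohydrate = 5, total_sugars = 3, added_sugars = 2,
             free_sugars = 2, sodium = 90)
  )
}

toy_persons <- function(weights = c(1, 3)) {
  tibble::tibble(
    person_id = paste0("p", seq_along(weights)),
    weight = weights
  )
}

toy_intakes <- function() {
  tibble::tribble(
    ~person_id, ~food_code, ~grams,
    "p1", "10000001", 150,
    "p1", "20000001", 100,
    "p1", "20000003", 250,
    "p2", "10000001", 200,
    "p2", "10000002", 300,
    "p2", "10000003", 500,
    "p2", "20000002", 400,
    "p2", "20000004", 50
  )
}

toy_data <- function() {
  dietscen::diet_data(toy_foods(), toy_persons(), toy_intakes())
}

# small generated populations for property tests (cached per session)
gen_cached <- local({
  cache <- list()
  function(n = 200, seed = 42) {
    key <- paste(n, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- dietscen::generate_population(
        dietscen::generator_config(n_persons = n, seed = seed)
      )
    }
    cache[[key]]
  }
})

total_row <- function(profile) profile[profile$class == "total", ]
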