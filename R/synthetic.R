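#' Food archetypes for the synthetic population generator
#'
#' A compact food-composition table of archetypal Australian foods and
#' beverages spanning all four intake classes, with per-100 g compositions
#' loosely modelled on typical products: discretionary beverages are
#' sugar- and alcohol-dense, discretionary foods saturated-fat- and
#' sodium-dense, and core choices carry most of the micronutrient density.
#' Each archetype also carries its sampling parameters: the probability a
#' person consumes it on the recall day (`consumer_fraction`), the expected
#' per-capita daily grams it contributes (`grams_per_capita`), and the
#' log-normal shape of consumer portions (`sdlog`).
#'
#' Micronutrients are filled from a reference per-100 g micronutrient
#' vector scaled by each archetype's `micro_density` (water zero, core
#' choices densest), with a few food-specific overrides (dairy calcium,
#' meat iron/B12, fruit and vegetable vitamin C).
#'
#' @return A tibble, one row per archetype.
#' @export
default_archetypes <- function() {
  a <- tibble::tribble(
    ~food_code, ~name, ~subgroup_code, ~is_discretionary, ~is_beverage, ~is_water_based, ~is_alcoholic, ~is_milk, ~is_sports_or_meal_replacement,
    ~consumer_fraction, ~grams_per_capita, ~sdlog, ~micro_density,
    ~protein, ~total_fat, ~sfa, ~mufa, ~pufa, ~carbohydrate, ~total_sugars, ~added_sugars, ~free_sugars, ~sodium, ~alcohol, ~fiber,
    # core foods
    "12101001", "wholemeal bread",     "121", FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, 0.95, 172, 0.5, 1.3,  9.0, 2.5, 0.5, 1.0, 0.9, 45.0, 3.0, 0.0, 0.0, 520, 0.0, 5.0,
    "12301001", "breakfast cereal",    "123", FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, 0.50,  55, 0.5, 2.0,  8.0, 2.0, 0.4, 0.7, 0.8, 70.0, 13.0, 10.0, 10.0, 350, 0.0, 8.0,
    "19101001", "milk, plain",         "191", FALSE, TRUE,  FALSE, FALSE, TRUE,  FALSE, 0.80, 160, 0.6, 1.0,  3.4, 3.5, 2.3, 0.9, 0.2,  5.0, 5.0, 0.0, 0.0,  44, 0.0, 0.0,
    "19201001", "cheddar cheese",      "192", FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, 0.60,  25, 0.6, 1.2, 25.0, 33.0, 21.0, 9.0, 1.5, 1.0, 0.5, 0.0, 0.0, 650, 0.0, 0.0,
    "16101001", "apple, raw",          "161", FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, 0.60, 120, 0.6, 0.9,  0.3, 0.2, 0.05, 0.01, 0.05, 14.0, 12.0, 0.0, 0.0,   2, 0.0, 2.4,
    "13101001", "mixed vegetables",    "131", FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, 0.95, 280, 0.5, 2.2,  2.0, 0.3, 0.06, 0.02, 0.1,  6.0, 3.0, 0.0, 0.0,  20, 0.0, 3.0,
    "15101001", "beef, lean cooked",   "151", FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, 0.75, 125, 0.5, 1.5, 26.0, 10.0, 4.0, 4.5, 0.5,  0.0, 0.0, 0.0, 0.0,  60, 0.0, 0.0,
    "19301001", "yoghurt, natural",    "193", FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, 0.40,  60, 0.6, 1.1,  5.0, 4.0, 2.6, 1.0, 0.2,  7.0, 7.0, 2.0, 2.0,  60, 0.0, 0.0,
    # core beverages
    "11101001", "water, tap",          "111", FALSE, TRUE,  TRUE,  FALSE, FALSE, FALSE, 0.95, 900, 0.5, 0.0,  0.0, 0.0, 0.0, 0.0, 0.0,  0.0, 0.0, 0.0, 0.0,   1, 0.0, 0.0,
    "11401001", "orange juice",        "114", FALSE, TRUE,  FALSE, FALSE, FALSE, FALSE, 0.35,  90, 0.6, 0.6,  0.6, 0.1, 0.02, 0.02, 0.02, 9.0, 8.5, 0.0, 8.5,   3, 0.0, 0.3,
    "11201001", "coffee and tea",      "112", FALSE, TRUE,  TRUE,  FALSE, FALSE, FALSE, 0.80, 560, 0.5, 0.1,  0.2, 0.1, 0.05, 0.03, 0.02, 0.4, 0.3, 0.0, 0.0,   3, 0.0, 0.0,
    # discretionary foods
    "21101001", "cake and muffins",    "211", TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, 0.15,  18, 0.6, 0.5,  5.5, 15.0, 5.0, 6.5, 2.5, 55.0, 32.0, 30.0, 30.0, 330, 0.0, 1.5,
    "21201001", "chocolate",           "212", TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, 0.12,  10, 0.6, 0.4,  7.0, 30.0, 16.0, 11.0, 1.5, 57.0, 54.0, 50.0, 50.0,  80, 0.0, 2.0,
    "21301001", "potato crisps",       "213", TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, 0.13,  12, 0.6, 0.5,  6.5, 32.0, 10.0, 14.0, 7.0, 50.0, 0.5, 0.0, 0.0, 1000, 0.0, 4.0,
    "21401001", "meat pie, takeaway",  "214", TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, 0.26,  45, 0.5, 0.6,  9.0, 12.0, 5.0, 5.5, 1.0, 24.0, 2.0, 1.0, 1.0, 750, 0.0, 1.5,
    "21501001", "ice cream",           "215", TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, 0.35,  50, 0.6, 0.5,  3.5, 10.0, 6.0, 3.2, 0.4, 22.0, 20.0, 18.0, 18.0,  60, 0.0, 0.0,
    "21601001", "sweet biscuits",      "216", TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, 0.14,  14, 0.6, 0.4,  6.0, 22.0, 10.0, 9.0, 2.5, 65.0, 29.0, 28.0, 28.0, 400, 0.0, 2.0,
    "21701001", "hot chips, takeaway", "217", TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, 0.26,  30, 0.6, 0.6,  3.5, 13.0, 4.0, 6.5, 2.0, 33.0, 0.6, 0.0, 0.0, 600, 0.0, 3.3,
    # discretionary beverages
    "22101001", "cola soft drink",     "221", TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE, 0.37, 120, 0.6, 0.05, 0.0, 0.0, 0.0, 0.0, 0.0, 11.0, 10.6, 10.6, 10.6,  12, 0.0, 0.0,
    "22201001", "cordial",             "222", TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE, 0.15,  30, 0.6, 0.05, 0.0, 0.0, 0.0, 0.0, 0.0,  9.0, 8.8, 8.8, 8.8,  10, 0.0, 0.0,
    "22301001", "beer, full strength", "223", TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE, 0.33, 195, 0.7, 0.1,  0.3, 0.0, 0.0, 0.0, 0.0,  1.5, 0.2, 0.0, 0.0,   5, 3.9, 0.0,
    "22401001", "wine",                "224", TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE, 0.23,  52, 0.7, 0.1,  0.1, 0.0, 0.0, 0.0, 0.0,  2.0, 0.8, 0.0, 0.8,   6, 10.5, 0.0,
    "22501001", "spirits",             "225", TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE, 0.07,   3, 0.7, 0.0,  0.0, 0.0, 0.0, 0.0, 0.0,  0.1, 0.1, 0.1, 0.1,   2, 33.0, 0.0,
    "22601001", "iced chocolate drink","226", TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE, 0.19,  40, 0.6, 0.3,  3.0, 0.8, 0.5, 0.2, 0.05,  9.5, 9.3, 8.0, 8.0,  45, 0.0, 0.2,
    "22701001", "diet cola",           "227", TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE, 0.23,  85, 0.6, 0.02, 0.0, 0.0, 0.0, 0.0, 0.0,  0.1, 0.05, 0.05, 0.05, 12, 0.0, 0.0,
    # sports products / meal replacements (discretionary, but excluded
    # from the discretionary-beverage reporting class)
    "23101001", "protein shake",       "231", TRUE,  TRUE,  FALSE, FALSE, FALSE, TRUE,  0.05,   8, 0.6, 0.8, 15.0, 1.5, 0.5, 0.5, 0.3,  5.0, 3.0, 2.0, 2.0,  90, 0.0, 0.5
  )
  micro_ref <- c(
    vit_a_re = 25.5, thiamin = 0.045, riboflavin = 0.057, niacin_eq = 1.24,
    folate_dfe = 18.3, vit_b6 = 0.045, vit_b12 = 0.135, vit_c = 3.1,
    vit_e = 0.31, calcium = 24.1, iodine = 5.2, iron = 0.33,
    magnesium = 10.1, phosphorus = 43.9, potassium = 87.3,
    selenium = 2.7, zinc = 0.33
  )
  for (nm in names(micro_ref)) a[[nm]] <- micro_ref[[nm]] * a$micro_density
  # food-specific touches so the synthetic table looks like food
  bump <- function(a, code, col, value) { a[[col]][a$food_code == code] <- value; a }
  a <- bump(a, "19101001", "calcium", 120)
  a <- bump(a, "19201001", "calcium", 720)
  a <- bump(a, "19301001", "calcium", 150)
  a <- bump(a, "15101001", "iron", 2.5)
  a <- bump(a, "15101001", "zinc", 4.5)
  a <- bump(a, "15101001", "vit_b12", 2.0)
  a <- bump(a, "13101001", "vit_c", 25)
  a <- bump(a, "16101001", "vit_c", 5)
  a <- bump(a, "11401001", "vit_c", 35)
  a
}

key_calibration_nutrients <- function() {
  c("grams", "energy_kj", "sfa", "added_sugars", "sodium", "alcohol")
}

#' @rdname generate_population
#' @export
default_generator_targets <- function() {
  base <- aus_basecase()
  key <- key_calibration_nutrients()
  purrr::map(
    setNames(
      c("core", "discretionary_food", "discretionary_beverage"),
      c("core", "discretionary_food", "discretionary_beverage")
    ),
    function(cl) unlist(profile_row(base, cl)[, key])
  )
}

#' Configure the synthetic population generator
#'
#' @param n_persons Number of simulated respondents (default 500).
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   the seed and configuration.
#' @param archetypes Archetype/composition table, see [default_archetypes()].
#' @param targets Per-class calibration targets for the key nutrients
#'   (grams, energy, SFA, added sugars, sodium, alcohol); defaults to the
#'   published national base-case class means.
#' @param weight_shape Shape of the gamma-distributed population weights
#'   (normalised to mean 1).
#' @param calibrate If `TRUE` (default), [calibrate_population()] is applied
#'   so the weighted class means hit the targets exactly.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_persons = 500, seed = 1,
                             archetypes = default_archetypes(),
                             targets = default_generator_targets(),
                             weight_shape = 4, calibrate = TRUE) {
  if (n_persons < 1) abort("n_persons must be at least 1")
  if (any(archetypes$consumer_fraction < 0 | archetypes$consumer_fraction > 1)) {
    abort("consumer_fraction must lie in [0, 1]")
  }
  if (any(archetypes$sdlog <= 0) || any(archetypes$grams_per_capita < 0)) {
    abort("Invalid portion distribution parameters")
  }
  check_generator_targets(targets)
  msgs <- check_profile_invariants(archetypes)
  if (length(msgs)) abort(paste0("Invalid archetype composition:\n  ", paste(msgs, collapse = "\n  ")))
  structure(
    list(
      n_persons = n_persons, seed = seed, archetypes = archetypes,
      targets = targets, weight_shape = weight_shape, calibrate = calibrate
    ),
    class = "generator_config"
  )
}

check_generator_targets <- function(targets) {
  if (is.null(targets)) return(invisible(targets))
  key <- key_calibration_nutrients()
  for (cl in names(targets)) {
    tv <- targets[[cl]]
    if (!all(key %in% names(tv))) {
      abort(paste0("Calibration targets for '", cl, "' must name: ", paste(key, collapse = ", ")))
    }
    if (any(tv < 0)) abort(paste0("Negative calibration target for '", cl, "'"))
    if (tv[["energy_kj"]] > 0 && tv[["grams"]] == 0) {
      abort(paste0("Infeasible targets for '", cl, "': energy without mass"))
    }
  }
  disc <- intersect(c("discretionary_food", "discretionary_beverage"), names(targets))
  if ("core" %in% names(targets) && length(disc)) {
    disc_e <- sum(purrr::map_dbl(targets[disc], "energy_kj"))
    # discretionary share of energy cannot plausibly exceed the core share
    # by an order of magnitude in a national diet; guard the obvious error
    if (disc_e > 10 * targets[["core"]][["energy_kj"]] && targets[["core"]][["energy_kj"]] > 0) {
      abort("Infeasible targets: discretionary energy vastly exceeds core energy")
    }
  }
  invisible(targets)
}

#' Generate a synthetic 24-h recall population
#'
#' Simulates a single-day dietary recall survey: `n_persons` respondents
#' with gamma-distributed population weights; each person consumes each
#' food archetype with its `consumer_fraction` probability, in a log-normal
#' portion whose scale is set so the expected per-capita contribution
#' equals the archetype's `grams_per_capita`. The dataset is then
#' calibrated (see [calibrate_population()]) so the population-weighted
#' class means of grams, energy, SFA, added sugars, sodium and alcohol hit
#' the configured targets exactly. Output is deterministic for a fixed
#' seed and configuration.
#'
#' @param config A [generator_config()].
#' @return A [diet_data()] object with attributes `calibration` (per-food
#'   scale factors) and `manifest` (seed, sizes, achieved-vs-target table).
#' @export
generate_population <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_persons
  persons <- tibble::tibble(
    person_id = sprintf("P%05d", seq_len(n)),
    weight = rgamma(n, shape = config$weight_shape, rate = config$weight_shape),
    age = round(runif(n, 19, 90)),
    sex = sample(c("female", "male"), n, replace = TRUE)
  )
  persons$weight <- persons$weight / mean(persons$weight)

  arch <- config$archetypes
  intakes <- purrr::map_dfr(seq_len(nrow(arch)), function(i) {
    cf <- arch$consumer_fraction[i]
    eats <- rbinom(n, 1, cf) == 1
    if (!any(eats)) return(NULL)
    sdl <- arch$sdlog[i]
    meanlog <- log(arch$grams_per_capita[i] / max(cf, 1e-9)) - sdl^2 / 2
    tibble::tibble(
      person_id = persons$person_id[eats],
      food_code = arch$food_code[i],
      grams = rlnorm(sum(eats), meanlog = meanlog, sdlog = sdl)
    )
  })
  intakes <- dplyr::arrange(intakes, .data$person_id, .data$food_code)

  foods <- arch[, c(
    "food_code", "name", "subgroup_code", food_flag_columns(),
    intersect(profile_columns(), names(arch))
  )]
  data <- diet_data(foods, persons, intakes)
  if (isTRUE(config$calibrate) && !is.null(config$targets)) {
    data <- calibrate_population(data, config$targets)
  }
  attr(data, "manifest") <- generator_manifest(data, config)
  data
}

#' Calibrate a synthetic dataset to class-level targets
#'
#' Rescales intake grams with one multiplicative factor per food so that
#' the population-weighted class means of the key nutrients (grams, energy,
#' SFA, added sugars, sodium, alcohol) equal the targets exactly. Within
#' each class the factors are the minimum-norm deviation from 1 satisfying
#' the linear constraint system; nutrient means outside the key set then
#' follow the realised composition mix. Errors if a class has no intake
#' against a non-zero target, or if no positive scaling solves the system.
#'
#' @param data A [diet_data()] object.
#' @param targets Named list class -> named key-nutrient target vector, as
#'   [default_generator_targets()].
#' @return The calibrated [diet_data()], with attribute `calibration`
#'   holding the per-food scale factors and residual report.
#' @export
calibrate_population <- function(data, targets = default_generator_targets()) {
  stopifnot(inherits(data, "diet_data"))
  check_generator_targets(targets)
  lines <- expand_intake(data)
  total_w <- sum(data$persons$weight)
  w <- data$persons$weight[match(lines$person_id, data$persons$person_id)]
  key <- key_calibration_nutrients()
  scales <- tibble::tibble(food_code = character(), class = character(), scale = numeric())

  for (cl in names(targets)) {
    sel <- class_line_filter(lines, cl)
    b <- as.numeric(targets[[cl]][key])
    if (!any(sel)) {
      if (any(b > 0)) abort(paste0("No intake in class '", cl, "' but non-zero target"))
      next
    }
    sub <- lines[sel, ]
    codes <- sort(unique(sub$food_code))
    # per-food weighted per-capita contribution to each key nutrient
    M <- sapply(codes, function(fc) {
      r <- sub$food_code == fc
      sapply(key, function(nu) sum(w[sel][r] * sub[[nu]][r]) / total_w)
    })
    M <- matrix(M, nrow = length(key), dimnames = list(key, codes))
    raw <- rowSums(M)
    keep <- !(b == 0 & raw < 1e-12)
    if (any(b[!keep] == 0 & raw[!keep] > 1e-12)) keep[b == 0 & raw > 1e-12] <- TRUE
    A <- M[keep, , drop = FALSE]
    resid <- b[keep] - raw[keep]
    # weighted minimum-norm solution: spread relative adjustments in
    # proportion to each food's gram contribution so large items absorb
    # proportionally more of the correction; foods whose factor would go
    # below a small positive floor are pinned there (active set) and the
    # remaining foods re-solved
    wgt <- pmax(M["grams", ], 1e-9)
    floor_scale <- 0.02
    free <- rep(TRUE, ncol(A))
    x <- rep(NA_real_, ncol(A))
    solve_free <- function(free, x) {
      target <- resid - if (any(!free)) {
        drop(A[, !free, drop = FALSE] %*% (x[!free] - 1))
      } else 0
      Af <- A[, free, drop = FALSE]
      AW <- sweep(Af, 2, wgt[free], "*")
      1 + wgt[free] * drop(t(Af) %*% solve(AW %*% t(Af), target))
    }
    for (pass in seq_len(ncol(A))) {
      xf <- tryCatch(
        solve_free(free, x),
        error = function(e) abort(paste0("Calibration system for class '", cl, "' is singular: ", conditionMessage(e)))
      )
      x[free] <- xf
      low <- free & x < floor_scale
      if (!any(low)) break
      x[low] <- floor_scale
      free <- free & !low
      if (!any(free)) break
    }
    if (any(x < floor_scale - 1e-9) || !any(free)) {
      abort(paste0(
        "Calibration for class '", cl, "' needs non-positive scale factors; ",
        "targets infeasible for the generated mix"
      ))
    }
    fit <- drop(A %*% (x - 1))
    if (max(abs(fit - resid) / pmax(abs(b[keep]), 1)) > 1e-6) {
      abort(paste0("Calibration for class '", cl, "' could not reach its targets within tolerance"))
    }
    scales <- dplyr::bind_rows(scales, tibble::tibble(food_code = codes, class = cl, scale = x))
  }

  fac <- setNames(scales$scale, scales$food_code)
  hit <- data$intakes$food_code %in% names(fac)
  data$intakes$grams[hit] <- data$intakes$grams[hit] * fac[data$intakes$food_code[hit]]

  achieved <- aggregate_classes(data)
  report <- purrr::map_dfr(names(targets), function(cl) {
    tv <- targets[[cl]][key]
    av <- unlist(profile_row(achieved, cl)[, key])
    tibble::tibble(class = cl, nutrient = key, target = as.numeric(tv),
                   achieved = as.numeric(av),
                   residual = as.numeric(av) - as.numeric(tv))
  })
  attr(data, "calibration") <- list(scales = scales, report = report)
  data
}

generator_manifest <- function(data, config) {
  cal <- attr(data, "calibration")
  list(
    seed = config$seed,
    n_persons = config$n_persons,
    n_foods = nrow(data$foods),
    n_intake_lines = nrow(data$intakes),
    config_hash = config_digest(config),
    achieved_vs_target = if (!is.null(cal)) cal$report else NULL
  )
}

# small stable digest without external dependencies: hash the serialized
# object bytes with a polynomial rolling hash
config_digest <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @rdname generate_population
#' @param data A generated [diet_data()].
#' @param dir Output directory.
#' @export
write_population <- function(data, dir) {
  write_diet_data(data, dir)
  manifest <- attr(data, "manifest")
  if (!is.null(manifest)) {
    manifest$achieved_vs_target <- NULL
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    cal <- attr(data, "calibration")
    if (!is.null(cal)) readr::write_tsv(cal$report, file.path(dir, "calibration_report.tsv"), progress = FALSE)
  }
  invisible(dir)
}
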