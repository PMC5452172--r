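#' Nutrient registry
#'
#' The canonical set of nutrient columns handled by the package, with the
#' reporting unit for each and, for the energy-yielding components, the
#' gross energy conversion factor used throughout (protein and carbohydrate
#' 16.736 kJ/g, fat 37.656 kJ/g, dietary fibre 8.368 kJ/g, alcohol
#' 29.288 kJ/g). Sugars inherit the carbohydrate factor and the fatty-acid
#' classes inherit the fat factor, so that percent-of-energy figures can be
#' derived for them; only the five base components (`protein`,
#' `carbohydrate`, `total_fat`, `fiber`, `alcohol`) enter the energy sum
#' itself.
#'
#' All composition tables store these quantities per 100 g of food;
#' profile tables store absolute daily amounts. Sodium and most minerals
#' are carried in mg, trace nutrients in µg, as flagged by `unit`.
#'
#' @return A tibble with columns `nutrient`, `unit`, `kj_per_g`
#'   (NA for non-energy-yielding nutrients) and `in_energy_sum`.
#' @export
#' @examples
#' nutrient_registry()
nutrient_registry <- function() {
  tibble::tribble(
    ~nutrient,        ~unit, ~kj_per_g, ~in_energy_sum,
    "grams",          "g",   NA,        FALSE,
    "energy_kj",      "kJ",  NA,        FALSE,
    "protein",        "g",   16.736,    TRUE,
    "total_fat",      "g",   37.656,    TRUE,
    "sfa",            "g",   37.656,    FALSE,
    "mufa",           "g",   37.656,    FALSE,
    "pufa",           "g",   37.656,    FALSE,
    "carbohydrate",   "g",   16.736,    TRUE,
    "total_sugars",   "g",   16.736,    FALSE,
    "added_sugars",   "g",   16.736,    FALSE,
    "free_sugars",    "g",   16.736,    FALSE,
    "sodium",         "mg",  NA,        FALSE,
    "alcohol",        "g",   29.288,    TRUE,
    "fiber",          "g",   8.368,     TRUE,
    "vit_a_re",       "ug",  NA,        FALSE,
    "thiamin",        "mg",  NA,        FALSE,
    "riboflavin",     "mg",  NA,        FALSE,
    "niacin_eq",      "mg",  NA,        FALSE,
    "folate_dfe",     "ug",  NA,        FALSE,
    "vit_b6",         "mg",  NA,        FALSE,
    "vit_b12",        "ug",  NA,        FALSE,
    "vit_c",          "mg",  NA,        FALSE,
    "vit_e",          "mg",  NA,        FALSE,
    "calcium",        "mg",  NA,        FALSE,
    "iodine",         "ug",  NA,        FALSE,
    "iron",           "mg",  NA,        FALSE,
    "magnesium",      "mg",  NA,        FALSE,
    "phosphorus",     "mg",  NA,        FALSE,
    "potassium",      "mg",  NA,        FALSE,
    "selenium",       "ug",  NA,        FALSE,
    "zinc",           "mg",  NA,        FALSE
  )
}

#' @rdname nutrient_registry
#' @export
nutrient_names <- function() nutrient_registry()$nutrient

# nutrient columns other than the food mass itself
profile_columns <- function() setdiff(nutrient_names(), "grams")

micronutrient_names <- function() {
  reg <- nutrient_registry()
  setdiff(reg$nutrient[is.na(reg$kj_per_g)], c("grams", "energy_kj", "sodium"))
}

energy_factors <- function() {
  reg <- nutrient_registry()
  reg <- reg[reg$in_energy_sum, ]
  setNames(reg$kj_per_g, reg$nutrient)
}

#' Compute dietary energy from macronutrient amounts
#'
#' Gross (metabolisable, fibre-inclusive) energy in kJ from the five
#' energy-yielding components:
#' \deqn{E = 16.736(P + C) + 37.656 F + 8.368 \mathrm{Fib} + 29.288 A}
#' with all amounts in grams. Works row-wise on any data frame that carries
#' `protein`, `carbohydrate`, `total_fat`, `fiber` and `alcohol` columns
#' (absent columns are treated as zero).
#'
#' @param profile A data frame (or named list/vector coercible to one) of
#'   nutrient amounts in grams.
#' @return A numeric vector of energy in kJ, one value per row.
#' @export
#' @examples
#' compute_energy(tibble::tibble(protein = 10))  # 167.36 kJ
compute_energy <- function(profile) {
  if (!is.data.frame(profile)) profile <- tibble::as_tibble(as.list(profile))
  fac <- energy_factors()
  e <- rep(0, nrow(profile))
  for (nm in names(fac)) {
    if (nm %in% names(profile)) {
      x <- profile[[nm]]
      x[is.na(x)] <- 0
      e <- e + fac[[nm]] * x
    }
  }
  e
}

#' Percent of total energy contributed by a nutrient
#'
#' The share of dietary energy contributed by an energy-yielding nutrient,
#' using the fixed kJ/g conversion factors of [nutrient_registry()].
#' Saturated/unsaturated fatty acids use the fat factor and the sugar
#' fractions use the carbohydrate factor, the standard convention for
#' energy-share reporting.
#'
#' @param profile A one-row data frame (or named vector) of daily amounts.
#' @param nutrient Name of an energy-yielding nutrient column.
#' @param energy_kj Total daily energy to use as denominator. Defaults to the
#'   profile's tracked `energy_kj` if present, else [compute_energy()].
#' @return Percent of total energy (numeric scalar, full precision).
#' @export
percent_energy <- function(profile, nutrient, energy_kj = NULL) {
  if (!is.data.frame(profile)) profile <- tibble::as_tibble(as.list(profile))
  reg <- nutrient_registry()
  kj <- reg$kj_per_g[match(nutrient, reg$nutrient)]
  if (length(kj) != 1 || is.na(kj)) {
    abort(paste0("No energy conversion factor for nutrient '", nutrient, "'"))
  }
  if (is.null(energy_kj)) {
    energy_kj <- if ("energy_kj" %in% names(profile)) profile$energy_kj else compute_energy(profile)
  }
  if (any(energy_kj <= 0)) abort("Total energy must be positive to compute %E")
  profile[[nutrient]] * kj / energy_kj * 100
}

#' Nutrient density per 1000 kJ
#'
#' Nutrient amount per standardised unit of energy (1000 kJ), computed as a
#' ratio of population means (mean amount over mean energy) when applied to
#' an aggregate profile row.
#'
#' @param profile A one-row data frame (or named vector) of amounts, with an
#'   `energy_kj` column (or computable energy).
#' @param nutrient Column to standardise; `"grams"` gives food mass density.
#' @return Amount per 1000 kJ in the nutrient's own unit.
#' @export
nutrient_density <- function(profile, nutrient) {
  if (!is.data.frame(profile)) profile <- tibble::as_tibble(as.list(profile))
  energy_kj <- if ("energy_kj" %in% names(profile)) profile$energy_kj else compute_energy(profile)
  if (any(energy_kj <= 0)) abort("Total energy must be positive to compute nutrient density")
  profile[[nutrient]] / energy_kj * 1000
}

#' Percent change from a base to a modelled amount
#'
#' `(modelled - base) / base * 100`; `NA` where the base amount is zero
#' (undefined relative change).
#'
#' @param base,modelled Numeric vectors of base-case and modelled amounts.
#' @return Percent change, full precision.
#' @export
percent_change <- function(base, modelled) {
  out <- (modelled - base) / base * 100
  out[!is.na(base) & base == 0] <- NA_real_
  out
}

# Validate per-100 g composition rows (or absolute profile rows).
# Returns a character vector of violation messages, empty when clean.
check_profile_invariants <- function(df, tolerance = 0.02, label = df$food_code) {
  msgs <- character()
  if (is.null(label)) label <- seq_len(nrow(df))
  num_cols <- intersect(nutrient_names(), names(df))
  for (col in num_cols) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) {
      msgs <- c(msgs, paste0("negative ", col, " for: ", paste(label[bad], collapse = ", ")))
    }
  }
  has <- function(...) all(c(...) %in% names(df))
  zna <- function(x) ifelse(is.na(x), 0, x)
  if (has("sfa", "total_fat")) {
    bad <- which(zna(df$sfa) > df$total_fat + 1e-9)
    if (length(bad)) msgs <- c(msgs, paste0("sfa exceeds total_fat for: ", paste(label[bad], collapse = ", ")))
  }
  if (has("sfa", "mufa", "pufa", "total_fat")) {
    fat_sum <- zna(df$sfa) + zna(df$mufa) + zna(df$pufa)
    bad <- which(fat_sum > df$total_fat * (1 + tolerance) + 1e-9)
    if (length(bad)) {
      msgs <- c(msgs, paste0(
        "sfa+mufa+pufa exceeds total_fat beyond ", tolerance * 100,
        "% tolerance for: ", paste(label[bad], collapse = ", ")
      ))
    }
  }
  if (has("added_sugars", "free_sugars")) {
    bad <- which(zna(df$added_sugars) > zna(df$free_sugars) + 1e-9)
    if (length(bad)) msgs <- c(msgs, paste0("added_sugars exceeds free_sugars for: ", paste(label[bad], collapse = ", ")))
  }
  if (has("free_sugars", "total_sugars")) {
    bad <- which(zna(df$free_sugars) > zna(df$total_sugars) + 1e-9)
    if (length(bad)) msgs <- c(msgs, paste0("free_sugars exceeds total_sugars for: ", paste(label[bad], collapse = ", ")))
  }
  if (has("total_sugars", "carbohydrate")) {
    bad <- which(zna(df$total_sugars) > df$carbohydrate + 1e-9)
    if (length(bad)) msgs <- c(msgs, paste0("total_sugars exceeds carbohydrate for: ", paste(label[bad], collapse = ", ")))
  }
  msgs
}
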