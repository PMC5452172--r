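#' Specify a dietary scenario
#'
#' A `scenario_spec` captures the full parameter block for one scenario
#' family:
#' \describe{
#' \item{moderation}{reduce discretionary intake by `reduction_fraction`
#'   with no replacement; a `compensation_fraction` of the *food*-derived
#'   energy deficit may be eaten back across the compensation pool
#'   (beverage energy deficits are never compensated, as compensation after
#'   reduced liquid intake is unlikely).}
#' \item{substitution}{replace `reduction_fraction` of discretionary grams
#'   with replacement-pool grams scaled by a replacement ratio; removed
#'   discretionary foods draw from core foods (or only fresh/frozen/canned
#'   fruit and vegetables), removed discretionary beverages from water and
#'   fruit/vegetable juices. No further energy compensation.}
#' \item{reformulation}{alter discretionary product composition in place:
#'   swap `sfa_replace_fraction` of saturated fat into unsaturated fats at
#'   the item's current MUFA:PUFA ratio (foods only; total fat unchanged),
#'   cut added sugars by `added_sugar_reduction`, sodium by
#'   `sodium_reduction`, and alcohol content by `alcohol_reduction` in
#'   alcoholic beverages. Consumption quantities stay constant apart from
#'   the removed ingredient mass.}
#' }
#'
#' @param family `"moderation"`, `"substitution"` or `"reformulation"`.
#' @param target Which discretionary items the scenario manipulates:
#'   `"all"`, `"foods"` or `"beverages"`.
#' @param reduction_fraction Fraction of targeted intake removed
#'   (moderation/substitution; default 0.5).
#' @param compensation_fraction Fraction of the food-derived energy deficit
#'   eaten back (moderation; default 0, sensitivity bounds 0.25 and 0.75).
#' @param compensation_pool Food classes over which compensation is spread,
#'   pro rata to base-case energy share (default core foods plus
#'   post-moderation discretionary foods; never beverages).
#' @param substitution_pool `"all_core"` or `"fruit_veg_only"` for the
#'   food-side replacement pool.
#' @param replacement_ratios Named numeric vector, 3-digit subgroup code ->
#'   grams of replacement added per gram removed; falls back to
#'   `default_ratio` for subgroups not listed.
#' @param default_ratio Overall replacement ratio (default 1.29, the
#'   population median-intake ratio of core to discretionary choices, i.e.
#'   100 g removed -> 129 g added).
#' @param beverage_ratio Replacement ratio for discretionary beverages
#'   (default 1: volume-for-volume with water/juice).
#' @param fruit_veg_subgroups,juice_water_subgroups Optional 3-digit
#'   subgroup code sets delimiting the restricted replacement pools in
#'   person mode.
#' @param sfa_replace_fraction,added_sugar_reduction,sodium_reduction,alcohol_reduction
#'   Reformulation fractions in `[0, 1]` (defaults 0.50 / 0.25 / 0.20 / 0.25).
#' @param sweetener_replacement If `TRUE`, removed added sugars are assumed
#'   replaced by an energy- and mass-equivalent bulk sweetener, so sugar
#'   removal changes neither item mass nor energy (default `FALSE`:
#'   non-nutritive sweeteners or no replacement).
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(family = c("moderation", "substitution", "reformulation"),
                          target = c("all", "foods", "beverages"),
                          reduction_fraction = 0.5,
                          compensation_fraction = 0,
                          compensation_pool = c("core_food", "discretionary_food"),
                          substitution_pool = c("all_core", "fruit_veg_only"),
                          replacement_ratios = NULL,
                          default_ratio = 1.29,
                          beverage_ratio = 1,
                          fruit_veg_subgroups = NULL,
                          juice_water_subgroups = NULL,
                          sfa_replace_fraction = 0.5,
                          added_sugar_reduction = 0.25,
                          sodium_reduction = 0.20,
                          alcohol_reduction = 0.25,
                          sweetener_replacement = FALSE) {
  family <- match.arg(family)
  target <- match.arg(target)
  substitution_pool <- match.arg(substitution_pool)
  fracs <- c(
    reduction_fraction = reduction_fraction,
    compensation_fraction = compensation_fraction,
    sfa_replace_fraction = sfa_replace_fraction,
    added_sugar_reduction = added_sugar_reduction,
    sodium_reduction = sodium_reduction,
    alcohol_reduction = alcohol_reduction
  )
  bad <- names(fracs)[is.na(fracs) | fracs < 0 | fracs > 1]
  if (length(bad)) abort(paste0("Scenario fractions must lie in [0, 1]: ", paste(bad, collapse = ", ")))
  if (!is.null(replacement_ratios)) {
    if (is.null(names(replacement_ratios)) || any(replacement_ratios <= 0)) {
      abort("replacement_ratios must be a named vector of positive ratios (subgroup_code -> ratio)")
    }
  }
  if (default_ratio <= 0 || beverage_ratio <= 0) abort("Replacement ratios must be positive")
  bad_pool <- setdiff(compensation_pool, food_classes())
  if (length(bad_pool)) abort(paste0("Unknown compensation pool class(es): ", paste(bad_pool, collapse = ", ")))
  if (any(grepl("beverage", compensation_pool))) {
    abort("Energy compensation is restricted to food classes; beverages cannot compensate")
  }
  structure(
    list(
      family = family, target = target,
      reduction_fraction = reduction_fraction,
      compensation_fraction = compensation_fraction,
      compensation_pool = compensation_pool,
      substitution_pool = substitution_pool,
      replacement_ratios = replacement_ratios,
      default_ratio = default_ratio,
      beverage_ratio = beverage_ratio,
      fruit_veg_subgroups = fruit_veg_subgroups,
      juice_water_subgroups = juice_water_subgroups,
      sfa_replace_fraction = sfa_replace_fraction,
      added_sugar_reduction = added_sugar_reduction,
      sodium_reduction = sodium_reduction,
      alcohol_reduction = alcohol_reduction,
      sweetener_replacement = sweetener_replacement
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$family, " of discretionary ", x$target, "\n", sep = "")
  if (x$family %in% c("moderation", "substitution")) {
    cat("  reduction:", x$reduction_fraction, "\n")
  }
  if (x$family == "moderation") cat("  energy compensation:", x$compensation_fraction, "\n")
  if (x$family == "reformulation") {
    cat(
      "  SFA swap:", x$sfa_replace_fraction,
      " added sugars:", x$added_sugar_reduction,
      " sodium:", x$sodium_reduction,
      " alcohol:", x$alcohol_reduction, "\n"
    )
  }
  invisible(x)
}

target_profile_class <- function(target) {
  switch(target,
    foods = "discretionary_food",
    beverages = "discretionary_beverage",
    all = "discretionary"
  )
}

# line-level membership of a scenario target; "beverages" follows the
# reporting convention and excludes sports products / meal replacements,
# while "all" covers every discretionary choice including them
target_line_filter <- function(lines, target) {
  switch(target,
    foods = lines$class == "discretionary_food",
    beverages = class_line_filter(lines, "discretionary_beverage"),
    all = lines$class %in% c("discretionary_food", "discretionary_beverage")
  )
}

profile_ancestors <- function(class) {
  switch(class,
    discretionary_food = c("discretionary", "total"),
    discretionary_beverage = c("discretionary", "total"),
    discretionary = "total",
    core = "total",
    total = character()
  )
}

profile_descendants <- function(class) {
  if (class == "discretionary") c("discretionary_food", "discretionary_beverage") else character()
}

# numeric nutrient vector of one profile row
row_values <- function(profile, class) {
  unlist(profile_row(profile, class)[, nutrient_names()])
}

# add a delta vector to a set of profile rows (NA cells stay NA)
add_to_rows <- function(profile, classes, delta) {
  for (cl in classes) {
    i <- which(profile$class == cl)
    for (nm in names(delta)) {
      if (!is.na(delta[[nm]])) profile[[nm]][i] <- profile[[nm]][i] + delta[[nm]]
    }
  }
  profile
}

scale_rows <- function(profile, classes, factor) {
  i <- which(profile$class %in% classes)
  for (nm in nutrient_names()) profile[[nm]][i] <- profile[[nm]][i] * factor
  profile
}

#' Moderation: proportional reduction of discretionary intake
#'
#' Scales every targeted discretionary item by `1 - reduction_fraction`, so
#' all its nutrients (and energy) fall by the same fraction, then applies
#' [compensate_energy()] to the food-derived energy deficit when
#' `compensation_fraction > 0`. Beverage-derived deficits are never
#' compensated.
#'
#' @param x An [aggregate_profile()] (aggregate mode) or [diet_data()]
#'   (person mode).
#' @param spec A `scenario_spec(family = "moderation")`.
#' @param lines Person mode only: pre-expanded line table to transform.
#' @return Aggregate mode: the modelled [aggregate_profile()]. Person mode:
#'   the modelled line-level table (aggregate with [aggregate_classes()]).
#' @export
moderate_intake <- function(x, spec, ...) UseMethod("moderate_intake")

#' @rdname moderate_intake
#' @param ... Unused.
#' @export
moderate_intake.aggregate_profile <- function(x, spec, ...) {
  stopifnot(spec$family == "moderation")
  f <- spec$reduction_fraction
  tclass <- target_profile_class(spec$target)
  base <- x
  delta <- -f * row_values(x, tclass)
  out <- scale_rows(x, c(tclass, profile_descendants(tclass)), 1 - f)
  out <- add_to_rows(out, profile_ancestors(tclass), delta)
  if (spec$compensation_fraction > 0) {
    food_deficit <- if (spec$target == "beverages") 0 else {
      f * profile_row(base, "discretionary_food")$energy_kj
    }
    out <- compensate_energy(out, food_deficit, base = base,
                             fraction = spec$compensation_fraction)
  }
  out
}

#' @rdname moderate_intake
#' @export
moderate_intake.diet_data <- function(x, spec, lines = NULL, ...) {
  stopifnot(spec$family == "moderation")
  if (is.null(lines)) lines <- expand_intake(x)
  f <- spec$reduction_fraction
  base <- lines
  hit <- target_line_filter(lines, spec$target)
  cols <- c("grams", intersect(profile_columns(), names(lines)))
  lines[hit, cols] <- lines[hit, cols] * (1 - f)
  if (spec$compensation_fraction > 0) {
    w <- x$persons$weight[match(base$person_id, x$persons$person_id)]
    food_deficit <- sum((w * base$energy_kj)[hit & base$class == "discretionary_food"]) * f
    lines <- compensate_energy(lines, food_deficit, base = base,
                               pool = spec$compensation_pool,
                               fraction = spec$compensation_fraction,
                               persons = x$persons)
  }
  lines
}

#' Energy compensation over a food pool
#'
#' Adds back `fraction * deficit_kj` of energy by scaling up pool items in
#' their base-case proportions: every pool member gains
#' \eqn{\lambda \times} its base-case amount, with
#' \eqn{\lambda = \mathrm{fraction} \cdot \mathrm{deficit} / E_{pool}} and
#' \eqn{E_{pool}} the base-case pool energy. All nutrients of pool items
#' rise proportionally, so compensation adds nutrients only in base-case
#' pool proportions. The pool contains foods only (core plus, after
#' moderation, discretionary foods).
#'
#' @param x Modelled [aggregate_profile()] or line-level table.
#' @param deficit_kj Food-derived energy deficit being compensated (>= 0).
#' @param base Base-case counterpart of `x` (pre-moderation).
#' @param pool Food classes forming the pool (person mode).
#' @param fraction Compensation fraction in `[0, 1]`.
#' @param persons Person mode: person table supplying population weights,
#'   so that the deficit and the pool energy are measured on the same
#'   population-weighted scale. Omit for unweighted line tables.
#' @return Same shape as `x`.
#' @export
compensate_energy <- function(x, deficit_kj, base, fraction,
                              pool = c("core_food", "discretionary_food"),
                              persons = NULL) {
  if (deficit_kj < 0) abort("Energy deficit must be non-negative")
  if (fraction == 0 || deficit_kj == 0) return(x)
  e_add <- fraction * deficit_kj
  if (inherits(x, "aggregate_profile")) {
    core_base <- row_values(base, "core")
    food_base <- row_values(base, "discretionary_food")
    pool_energy <- core_base[["energy_kj"]] + food_base[["energy_kj"]]
    if (pool_energy <= 0) abort("Compensation pool has no energy")
    lambda <- e_add / pool_energy
    x <- add_to_rows(x, "core", lambda * core_base)
    x <- add_to_rows(x, "total", lambda * core_base)
    x <- add_to_rows(x, c("discretionary_food", "discretionary", "total"), lambda * food_base)
    return(x)
  }
  in_pool <- base$class %in% pool
  w <- if (is.null(persons)) rep(1, nrow(base)) else persons$weight[match(base$person_id, persons$person_id)]
  pool_energy <- sum((w * base$energy_kj)[in_pool])
  if (pool_energy <= 0) abort("Compensation pool has no energy")
  lambda <- e_add / pool_energy
  cols <- c("grams", intersect(profile_columns(), names(x)))
  x[in_pool, cols] <- x[in_pool, cols] + lambda * base[in_pool, cols]
  x
}

#' Substitution: replace discretionary intake with core choices
#'
#' Removes `reduction_fraction` of targeted discretionary grams and adds
#' `grams removed x replacement ratio` of replacement items, distributed
#' across the replacement pool pro rata to base-case gram share (so the
#' replacement mirrors observed eating patterns). Discretionary foods draw
#' from core foods (milk included) or, in the restricted variant, from
#' fresh/frozen/canned fruit and vegetables; discretionary beverages
#' (including alcoholic drinks) draw only from water and fruit/vegetable
#' juices. No further energy compensation is applied.
#'
#' In aggregate mode, subgroup-level ratios are unavailable, so the overall
#' `default_ratio` applies to the food side and `beverage_ratio` to the
#' beverage side, with beverage replacement modelled as water (mass without
#' nutrients).
#'
#' @inheritParams moderate_intake
#' @param spec A `scenario_spec(family = "substitution")`.
#' @return As [moderate_intake()].
#' @export
substitute_intake <- function(x, spec, ...) UseMethod("substitute_intake")

#' @rdname substitute_intake
#' @param ... Unused.
#' @export
substitute_intake.aggregate_profile <- function(x, spec, ...) {
  stopifnot(spec$family == "substitution")
  f <- spec$reduction_fraction
  out <- x
  if (spec$target %in% c("all", "foods")) {
    removed <- f * row_values(x, "discretionary_food")
    out <- scale_rows(out, "discretionary_food", 1 - f)
    out <- add_to_rows(out, c("discretionary", "total"), -removed)
    add_g <- spec$default_ratio * removed[["grams"]]
    core <- row_values(x, "core")
    if (core[["grams"]] <= 0) abort("Empty replacement pool: core intake has no mass")
    gain <- core * (add_g / core[["grams"]])
    out <- add_to_rows(out, c("core", "total"), gain)
  }
  if (spec$target %in% c("all", "beverages")) {
    removed <- f * row_values(x, "discretionary_beverage")
    out <- scale_rows(out, "discretionary_beverage", 1 - f)
    out <- add_to_rows(out, c("discretionary", "total"), -removed)
    water_g <- spec$beverage_ratio * removed[["grams"]]
    gain <- setNames(rep(0, length(nutrient_names())), nutrient_names())
    gain[["grams"]] <- water_g
    out <- add_to_rows(out, c("core", "total"), gain)
  }
  out
}

subgroup_ratio <- function(spec, subgroups) {
  ratios <- rep(NA_real_, length(subgroups))
  if (!is.null(spec$replacement_ratios)) {
    ratios <- as.numeric(spec$replacement_ratios[subgroups])
  }
  if (any(is.na(ratios))) {
    if (is.null(spec$default_ratio)) {
      abort(paste0(
        "No replacement ratio for subgroup(s): ",
        paste(subgroups[is.na(ratios)], collapse = ", ")
      ))
    }
    ratios[is.na(ratios)] <- spec$default_ratio
  }
  setNames(ratios, subgroups)
}

#' @rdname substitute_intake
#' @export
substitute_intake.diet_data <- function(x, spec, lines = NULL, ...) {
  stopifnot(spec$family == "substitution")
  if (is.null(lines)) lines <- expand_intake(x)
  f <- spec$reduction_fraction
  base <- lines
  cols <- c("grams", intersect(profile_columns(), names(lines)))

  pour_into_pool <- function(lines, in_pool, add_g, side) {
    if (add_g <= 0) return(lines)
    pool_g <- sum(base$grams[in_pool])
    if (!any(in_pool) || pool_g <= 0) {
      abort(paste0("Empty ", side, " replacement pool"))
    }
    lambda <- add_g / pool_g
    lines[in_pool, cols] <- lines[in_pool, cols] + lambda * base[in_pool, cols]
    lines
  }

  if (spec$target %in% c("all", "foods")) {
    hit <- lines$class == "discretionary_food"
    if (any(hit)) {
      ratios <- subgroup_ratio(spec, sort(unique(lines$subgroup_code[hit])))
      removed_by_sub <- tapply(f * base$grams[hit], lines$subgroup_code[hit], sum)
      add_g <- sum(ratios[names(removed_by_sub)] * as.numeric(removed_by_sub))
      lines[hit, cols] <- lines[hit, cols] * (1 - f)
      in_pool <- base$class == "core_food"
      if (spec$substitution_pool == "fruit_veg_only") {
        if (is.null(spec$fruit_veg_subgroups)) {
          abort("fruit_veg_only substitution needs spec$fruit_veg_subgroups")
        }
        in_pool <- in_pool & base$subgroup_code %in% spec$fruit_veg_subgroups
      }
      lines <- pour_into_pool(lines, in_pool, add_g, "food")
    }
  }
  if (spec$target %in% c("all", "beverages")) {
    hit <- class_line_filter(lines, "discretionary_beverage")
    if (any(hit)) {
      subs <- sort(unique(lines$subgroup_code[hit]))
      ratios <- setNames(rep(NA_real_, length(subs)), subs)
      if (!is.null(spec$replacement_ratios)) {
        ratios[] <- as.numeric(spec$replacement_ratios[subs])
      }
      ratios[is.na(ratios)] <- spec$beverage_ratio
      removed_by_sub <- tapply(f * base$grams[hit], lines$subgroup_code[hit], sum)
      add_g <- sum(ratios[names(removed_by_sub)] * as.numeric(removed_by_sub))
      lines[hit, cols] <- lines[hit, cols] * (1 - f)
      in_pool <- base$class == "core_beverage" & !base$is_alcoholic
      if (!is.null(spec$juice_water_subgroups)) {
        in_pool <- in_pool & base$subgroup_code %in% spec$juice_water_subgroups
      }
      lines <- pour_into_pool(lines, in_pool, add_g, "beverage")
    }
  }
  lines
}

#' Replacement ratio from population median intakes
#'
#' Grams of replacement per gram removed, computed as the ratio of median
#' per-consumer daily subgroup intakes: for every person x 3-digit subgroup
#' combination with positive intake in a group, take the daily grams; the
#' ratio is the target-group median divided by the source-group median.
#' With the national survey data this yields 1.29 for core relative to
#' overall discretionary choices (100 g removed -> 129 g added).
#'
#' @param data A [diet_data()] object.
#' @param source_classes Food classes being removed (default all
#'   discretionary).
#' @param target_classes Replacement food classes (default all core).
#' @return A single positive ratio.
#' @export
compute_replacement_ratio <- function(data,
                                      source_classes = c("discretionary_food", "discretionary_beverage"),
                                      target_classes = c("core_food", "core_beverage")) {
  lines <- expand_intake(data)
  med <- function(classes) {
    keep <- lines[lines$class %in% classes & lines$grams > 0, ]
    if (nrow(keep) == 0) abort("No consumption in group; cannot form a replacement ratio")
    per <- dplyr::summarise(
      dplyr::group_by(keep, .data$person_id, .data$subgroup_code),
      grams = sum(.data$grams), .groups = "drop"
    )
    median(per$grams)
  }
  med(target_classes) / med(source_classes)
}

# deltas from reformulating one profile vector; sfa_base supplies the
# food-level SFA pool when operating on the combined discretionary row
reform_delta <- function(vals, spec, apply_sfa, sfa_pool = NULL) {
  delta <- setNames(rep(0, length(nutrient_names())), nutrient_names())
  sug_rm <- spec$added_sugar_reduction * vals[["added_sugars"]]
  # clip so sugar hierarchies stay non-negative
  sug_rm <- min(sug_rm, vals[["free_sugars"]], vals[["total_sugars"]], vals[["carbohydrate"]], na.rm = TRUE)
  na_rm <- spec$sodium_reduction * vals[["sodium"]]
  alc_rm <- spec$alcohol_reduction * vals[["alcohol"]]
  delta[["added_sugars"]] <- -sug_rm
  delta[["free_sugars"]] <- -sug_rm
  delta[["total_sugars"]] <- -sug_rm
  delta[["sodium"]] <- -na_rm
  delta[["alcohol"]] <- -alc_rm
  energy <- -29.288 * alc_rm
  mass <- -(alc_rm + na_rm / 1000)
  if (!spec$sweetener_replacement) {
    delta[["carbohydrate"]] <- -sug_rm
    energy <- energy - 16.736 * sug_rm
    mass <- mass - sug_rm
  }
  if (apply_sfa) {
    sfa_rm <- spec$sfa_replace_fraction * (if (is.null(sfa_pool)) vals[["sfa"]] else sfa_pool)
    delta[["sfa"]] <- -sfa_rm
    mufa <- vals[["mufa"]]
    pufa <- vals[["pufa"]]
    if (!is.na(mufa) && !is.na(pufa)) {
      share <- if (mufa + pufa > 0) mufa / (mufa + pufa) else 0.5
      delta[["mufa"]] <- sfa_rm * share
      delta[["pufa"]] <- sfa_rm * (1 - share)
    }
    # total fat unchanged: removed SFA becomes unsaturated fat, so no
    # energy or mass effect from the swap
  }
  delta[["energy_kj"]] <- energy
  delta[["grams"]] <- mass
  delta
}

#' Reformulation: alter discretionary product composition
#'
#' Applies the multi-nutrient reformulation of [scenario_spec()] to the
#' targeted discretionary items: the saturated-fat swap (foods only, total
#' fat conserved), added-sugar, sodium and alcohol reductions. Item mass
#' falls by the removed ingredient mass (sugar grams + alcohol grams +
#' sodium converted mg to g) and energy falls by the energy of the removed
#' carbohydrate and alcohol; protein, fibre and all micronutrients are
#' untouched.
#'
#' @inheritParams moderate_intake
#' @param spec A `scenario_spec(family = "reformulation")`.
#' @return As [moderate_intake()].
#' @export
reformulate_intake <- function(x, spec, ...) UseMethod("reformulate_intake")

#' @rdname reformulate_intake
#' @param ... Unused.
#' @export
reformulate_intake.aggregate_profile <- function(x, spec, ...) {
  stopifnot(spec$family == "reformulation")
  tclass <- target_profile_class(spec$target)
  sfa_pool <- if (tclass == "discretionary") row_values(x, "discretionary_food")[["sfa"]] else NULL
  delta <- reform_delta(
    row_values(x, tclass), spec,
    apply_sfa = tclass != "discretionary_beverage",
    sfa_pool = sfa_pool
  )
  out <- add_to_rows(x, tclass, delta)
  # children transform from their own values; ancestors get the target delta
  for (child in profile_descendants(tclass)) {
    child_delta <- reform_delta(row_values(x, child), spec,
                                apply_sfa = child == "discretionary_food")
    out <- add_to_rows(out, child, child_delta)
  }
  add_to_rows(out, profile_ancestors(tclass), delta)
}

#' @rdname reformulate_intake
#' @export
reformulate_intake.diet_data <- function(x, spec, lines = NULL, ...) {
  stopifnot(spec$family == "reformulation")
  if (is.null(lines)) lines <- expand_intake(x)
  hit <- which(target_line_filter(lines, spec$target))
  for (i in hit) {
    vals <- unlist(lines[i, intersect(nutrient_names(), names(lines))])
    beverage <- lines$class[i] == "discretionary_beverage"
    alc_spec <- spec
    if (!lines$is_alcoholic[i]) alc_spec$alcohol_reduction <- 0
    delta <- reform_delta(vals, alc_spec, apply_sfa = !beverage)
    for (nm in names(delta)) {
      if (!is.na(delta[[nm]]) && nm %in% names(lines)) {
        lines[[nm]][i] <- lines[[nm]][i] + delta[[nm]]
      }
    }
  }
  lines
}

#' Run one scenario end to end
#'
#' Dispatches to the family transform, aggregates base and modelled
#' profiles, and computes percent changes for the full nutrient panel. The
#' primary outcomes of the model are the percent changes in energy,
#' saturated fat, added sugars, sodium and alcohol.
#'
#' @param x An [aggregate_profile()] or [diet_data()].
#' @param spec A [scenario_spec()].
#' @param label Optional scenario label carried into tidy output.
#' @return A `scenario_result`: list with `spec`, `base` and `modelled`
#'   aggregate profiles and a tidy `changes` table.
#' @export
run_scenario <- function(x, spec, label = spec$family) {
  transform <- switch(spec$family,
    moderation = moderate_intake,
    substitution = substitute_intake,
    reformulation = reformulate_intake
  )
  if (inherits(x, "aggregate_profile")) {
    base <- x
    modelled <- transform(x, spec)
  } else if (inherits(x, "diet_data")) {
    lines <- expand_intake(x)
    base <- aggregate_classes(x, lines = lines)
    modelled <- aggregate_classes(x, lines = transform(x, spec, lines = lines))
  } else {
    abort("run_scenario() needs an aggregate_profile or diet_data input")
  }
  base_tot <- profile_row(base, "total")
  mod_tot <- profile_row(modelled, "total")
  reg <- nutrient_registry()
  changes <- tibble::tibble(
    scenario = label,
    nutrient = reg$nutrient,
    unit = reg$unit,
    base_value = unname(unlist(base_tot[, reg$nutrient])),
    modelled_value = unname(unlist(mod_tot[, reg$nutrient]))
  )
  changes$pct_change <- percent_change(changes$base_value, changes$modelled_value)
  structure(
    list(spec = spec, label = label, base = base, modelled = modelled, changes = changes),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$label, " (", x$spec$family, ", target ", x$spec$target, ")\n", sep = "")
  key <- c("energy_kj", "sfa", "added_sugars", "sodium", "alcohol")
  tab <- x$changes[x$changes$nutrient %in% key, c("nutrient", "base_value", "modelled_value", "pct_change")]
  tab$pct_change <- sprintf("%+.1f%%", tab$pct_change)
  print(as.data.frame(tab), row.names = FALSE, digits = 6)
  invisible(x)
}

#' Primary and sensitivity-bound parameter sets for a scenario family
#'
#' Runs the family's primary parameterisation together with its lower and
#' upper sensitivity bounds: moderation at 0%/25%/75% energy compensation;
#' reformulation with (SFA swap, added-sugar, sodium, alcohol) fractions of
#' (25, 10, 10, 25)% / (50, 25, 20, 25)% / (75, 40, 40, 50)%. Substitution
#' carries no sensitivity bounds and returns its two replacement-pool
#' variants instead.
#'
#' @param x An [aggregate_profile()] or [diet_data()].
#' @param family Scenario family.
#' @param target Discretionary target set.
#' @param ... Further arguments passed to [scenario_spec()].
#' @return Named list of `scenario_result` (`lower`, `primary`, `upper`; or
#'   `all_core`, `fruit_veg_only` for substitution).
#' @export
run_sensitivity_suite <- function(x, family = c("moderation", "reformulation", "substitution"),
                                  target = "all", ...) {
  family <- match.arg(family)
  presets <- switch(family,
    moderation = list(
      primary = list(compensation_fraction = 0),
      lower = list(compensation_fraction = 0.25),
      upper = list(compensation_fraction = 0.75)
    ),
    reformulation = list(
      primary = list(sfa_replace_fraction = 0.50, added_sugar_reduction = 0.25,
                     sodium_reduction = 0.20, alcohol_reduction = 0.25),
      lower = list(sfa_replace_fraction = 0.25, added_sugar_reduction = 0.10,
                   sodium_reduction = 0.10, alcohol_reduction = 0.25),
      upper = list(sfa_replace_fraction = 0.75, added_sugar_reduction = 0.40,
                   sodium_reduction = 0.40, alcohol_reduction = 0.50)
    ),
    substitution = list(
      all_core = list(substitution_pool = "all_core"),
      fruit_veg_only = list(substitution_pool = "fruit_veg_only")
    )
  )
  purrr::imap(presets, function(args, nm) {
    spec <- do.call(scenario_spec, c(list(family = family, target = target), args, list(...)))
    run_scenario(x, spec, label = paste(family, nm, sep = "_"))
  })
}
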