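test_that("moderation is linear: modelled = base - fraction x class contribution", {
  # brute-force oracle on generated person-level data
  d <- gen_cached(n = 200, seed = 42)
  lines <- expand_intake(d)
  base <- aggregate_classes(d, lines = lines)
  nut <- setdiff(nutrient_names(), c("mufa", "pufa"))
  for (target in c("foods", "beverages", "all")) {
    for (f in c(0, 0.3, 1)) {
      spec <- scenario_spec("moderation", target, reduction_fraction = f)
      mod <- aggregate_classes(d, lines = moderate_intake(d, spec, lines = lines))
      # independent oracle: weighted means of the targeted lines only
      w <- d$persons$weight[match(lines$person_id, d$persons$person_id)]
      hit <- dietscen:::target_line_filter(lines, target)
      expected <- sapply(nut, function(nm) {
        total_row(base)[[nm]] - f * sum(w[hit] * lines[[nm]][hit]) / sum(d$persons$weight)
      })
      expect_equal(unlist(total_row(mod)[, nut]), expected, tolerance = 1e-10)
    }
  }
})

test_that("zero-fraction transforms are identities", {
  b <- aus_basecase()
  m0 <- moderate_intake(b, scenario_spec("moderation", "all", reduction_fraction = 0))
  expect_equal(as.data.frame(m0), as.data.frame(b))
  r0 <- reformulate_intake(b, scenario_spec(
    "reformulation", "all",
    sfa_replace_fraction = 0, added_sugar_reduction = 0,
    sodium_reduction = 0, alcohol_reduction = 0
  ))
  expect_equal(as.data.frame(r0), as.data.frame(b))
  s0 <- substitute_intake(b, scenario_spec("substitution", "all", reduction_fraction = 0))
  expect_equal(as.data.frame(s0), as.data.frame(b))
})

test_that("moderation obeys the composition law f1 then f2 = 1-(1-f1)(1-f2)", {
  b <- aus_basecase()
  f <- 0.4
  once <- moderate_intake(b, scenario_spec("moderation", "all", reduction_fraction = 1 - (1 - f)^2))
  twice <- moderate_intake(
    moderate_intake(b, scenario_spec("moderation", "all", reduction_fraction = f)),
    scenario_spec("moderation", "all", reduction_fraction = f)
  )
  expect_equal(as.data.frame(twice), as.data.frame(once), tolerance = 1e-12)
})

test_that("energy compensation distributes pro rata over base-case pool energy", {
  # two-food synthetic pool: base energies 600 and 400 kJ; deficit 100 kJ,
  # full compensation -> gains of exactly 60 and 40 kJ
  foods <- dplyr::bind_rows(
    toy_food("30000001", "rice", "301", carbohydrate = 600 / 16.736),
    toy_food("30000002", "oats", "302", carbohydrate = 400 / 16.736)
  )
  d <- diet_data(
    foods, toy_persons(weights = 1),
    tibble::tibble(person_id = "p1", food_code = c("30000001", "30000002"), grams = 100)
  )
  lines <- expand_intake(d)
  comp <- compensate_energy(lines, deficit_kj = 100, base = lines, fraction = 1)
  expect_equal(comp$energy_kj - lines$energy_kj, c(60, 40), tolerance = 1e-9)

  # conservation on generated data: energy added equals fraction x deficit
  d <- gen_cached(n = 200, seed = 42)
  lines <- expand_intake(d)
  base <- aggregate_classes(d, lines = lines)
  for (cf in c(0.25, 0.75)) {
    spec <- scenario_spec("moderation", "all", compensation_fraction = cf)
    mod <- aggregate_classes(d, lines = moderate_intake(d, spec, lines = lines))
    deficit_food <- 0.5 * profile_row(base, "discretionary_food")$energy_kj
    no_comp <- aggregate_classes(d, lines = moderate_intake(
      d, scenario_spec("moderation", "all", compensation_fraction = 0), lines = lines
    ))
    added <- total_row(mod)$energy_kj - total_row(no_comp)$energy_kj
    expect_equal(added, cf * deficit_food, tolerance = 1e-6)
    # compensation must not touch beverages
    expect_equal(
      profile_row(mod, "discretionary_beverage")$energy_kj,
      profile_row(no_comp, "discretionary_beverage")$energy_kj,
      tolerance = 1e-9
    )
  }
})

test_that("substitution keeps the mass ledger: added = ratio x removed", {
  # one discretionary + one core food, ratio 1, fraction 0.5: mass conserved
  foods <- dplyr::bind_rows(
    toy_food("40000001", "porridge", "401", carbohydrate = 20),
    toy_food("40000002", "doughnut", "402", discretionary = TRUE,
             carbohydrate = 40, total_sugars = 20, added_sugars = 15, free_sugars = 15)
  )
  d <- diet_data(
    foods, toy_persons(weights = 1),
    tibble::tibble(person_id = "p1", food_code = c("40000001", "40000002"), grams = c(100, 80))
  )
  spec1 <- scenario_spec("substitution", "foods", reduction_fraction = 0.5, default_ratio = 1)
  mod <- aggregate_classes(d, lines = substitute_intake(d, spec1))
  expect_equal(total_row(mod)$grams, 180, tolerance = 1e-10)

  # published worked example: removing 100 g at ratio 1.29 adds 129 g
  spec129 <- scenario_spec("substitution", "foods", reduction_fraction = 1, default_ratio = 1.29)
  mod129 <- aggregate_classes(d, lines = substitute_intake(d, spec129))
  expect_equal(total_row(mod129)$grams, 100 + 1.29 * 80, tolerance = 1e-10)

  # generated data: gram ledger holds per subgroup and nothing goes negative
  d <- gen_cached(n = 200, seed = 42)
  lines <- expand_intake(d)
  ratios <- setNames(c(1.1, 0.8, 1.3, 1.29, 1.0, 1.2, 0.9),
                     c("211", "212", "213", "214", "215", "216", "217"))
  spec <- scenario_spec("substitution", "all", replacement_ratios = ratios, beverage_ratio = 1)
  out <- substitute_intake(d, spec, lines = lines)
  expect_true(all(out$grams >= 0))
  hit_f <- lines$class == "discretionary_food"
  removed <- tapply(0.5 * lines$grams[hit_f], lines$subgroup_code[hit_f], sum)
  expected_add <- sum(ratios[names(removed)] * as.numeric(removed))
  pool <- lines$class == "core_food"
  expect_equal(sum(out$grams[pool]) - sum(lines$grams[pool]), expected_add, tolerance = 1e-8)
  # beverage side: water/juice pool grows by exactly the removed beverage grams
  hit_b <- dietscen:::class_line_filter(lines, "discretionary_beverage")
  bev_pool <- lines$class == "core_beverage" & !lines$is_alcoholic
  expect_equal(
    sum(out$grams[bev_pool]) - sum(lines$grams[bev_pool]),
    0.5 * sum(lines$grams[hit_b]),
    tolerance = 1e-8
  )
})

test_that("substitution errors on empty pools and missing ratios", {
  foods <- dplyr::bind_rows(
    toy_food("40000002", "doughnut", "402", discretionary = TRUE, carbohydrate = 40)
  )
  d <- diet_data(
    foods, toy_persons(weights = 1),
    tibble::tibble(person_id = "p1", food_code = "40000002", grams = 80)
  )
  spec <- scenario_spec("substitution", "foods")
  expect_error(substitute_intake(d, spec), "Empty food replacement pool")
  spec_nodefault <- scenario_spec("substitution", "foods")
  spec_nodefault$default_ratio <- NULL
  expect_error(substitute_intake(d, spec_nodefault), "402")
})

test_that("replacement ratios derive from median per-consumer subgroup intakes", {
  # identical intake distributions give ratio 1
  foods <- dplyr::bind_rows(
    toy_food("50000001", "core item", "501", carbohydrate = 10),
    toy_food("50000002", "treat", "502", discretionary = TRUE, carbohydrate = 10)
  )
  persons <- toy_persons(weights = c(1, 1, 1))
  same <- tidyr::expand_grid(person_id = persons$person_id,
                             food_code = c("50000001", "50000002"))
  same$grams <- 150
  d_same <- diet_data(foods, persons, same)
  expect_equal(compute_replacement_ratio(d_same), 1)

  # medians 258 g (core) vs 200 g (discretionary) give 1.29
  shifted <- same
  shifted$grams <- ifelse(shifted$food_code == "50000001", 258, 200)
  d_shift <- diet_data(foods, persons, shifted)
  expect_equal(compute_replacement_ratio(d_shift), 1.29)
})

test_that("reformulation conserves fat mass, protein, fibre and micronutrients", {
  d <- gen_cached(n = 200, seed = 42)
  lines <- expand_intake(d)
  base <- aggregate_classes(d, lines = lines)
  spec <- scenario_spec("reformulation", "all")
  out_lines <- reformulate_intake(d, spec, lines = lines)
  mod <- aggregate_classes(d, lines = out_lines)
  bt <- total_row(base)
  mt <- total_row(mod)
  # invariants: total fat, protein, fibre, all micronutrients
  for (nm in c("total_fat", "protein", "fiber", dietscen:::micronutrient_names())) {
    expect_equal(mt[[nm]], bt[[nm]], tolerance = 1e-10)
  }
  # SFA moves into MUFA + PUFA one for one
  expect_equal(
    (bt$sfa - mt$sfa), (mt$mufa - bt$mufa) + (mt$pufa - bt$pufa),
    tolerance = 1e-10
  )
  # energy falls by exactly the removed sugar and alcohol energy
  sugar_rm <- bt$added_sugars - mt$added_sugars
  alc_rm <- bt$alcohol - mt$alcohol
  expect_equal(bt$energy_kj - mt$energy_kj, 16.736 * sugar_rm + 29.288 * alc_rm,
               tolerance = 1e-8)
  # mass falls by removed sugar + alcohol + sodium (mg -> g)
  na_rm <- bt$sodium - mt$sodium
  expect_equal(bt$grams - mt$grams, sugar_rm + alc_rm + na_rm / 1000, tolerance = 1e-8)
  # tracked energy still equals recomputed energy after the transform
  expect_equal(compute_energy(mt), mt$energy_kj, tolerance = 1e-8)

  # with bulk-sweetener replacement, sugar removal leaves mass and energy
  spec_sw <- scenario_spec("reformulation", "all", sweetener_replacement = TRUE)
  mod_sw <- aggregate_classes(d, lines = reformulate_intake(d, spec_sw, lines = lines))
  mst <- total_row(mod_sw)
  expect_equal(bt$energy_kj - mst$energy_kj, 29.288 * alc_rm, tolerance = 1e-8)
  expect_equal(mst$added_sugars, mt$added_sugars, tolerance = 1e-10)
})

test_that("alcohol reformulation only touches alcoholic beverages", {
  d <- gen_cached(n = 200, seed = 42)
  lines <- expand_intake(d)
  out <- reformulate_intake(d, scenario_spec("reformulation", "beverages"), lines = lines)
  non_alc <- !lines$is_alcoholic
  expect_equal(out$alcohol[non_alc], lines$alcohol[non_alc])
  alc <- lines$is_alcoholic
  expect_equal(out$alcohol[alc], 0.75 * lines$alcohol[alc], tolerance = 1e-12)
  # SFA untouched on the beverage side
  expect_equal(out$sfa, lines$sfa)
})

test_that("aggregate mode equals person mode for the linear transforms", {
  d <- gen_cached(n = 120, seed = 11)
  agg <- aggregate_classes(d)
  nut <- setdiff(nutrient_names(), c("mufa", "pufa"))
  cases <- list(
    scenario_spec("moderation", "all", reduction_fraction = 0.5),
    scenario_spec("moderation", "foods", reduction_fraction = 0.3),
    scenario_spec("moderation", "beverages", reduction_fraction = 0.8),
    scenario_spec("reformulation", "all"),
    scenario_spec("reformulation", "foods"),
    scenario_spec("reformulation", "beverages",
                  added_sugar_reduction = 0.4, sodium_reduction = 0.4, alcohol_reduction = 0.5)
  )
  for (spec in cases) {
    person <- run_scenario(d, spec)
    aggregate <- run_scenario(agg, spec)
    expect_equal(
      unlist(total_row(person$modelled)[, nut]),
      unlist(total_row(aggregate$modelled)[, nut]),
      tolerance = 1e-8
    )
  }
})

test_that("sensitivity suites span the documented parameter sets", {
  b <- aus_basecase()
  suite <- run_sensitivity_suite(b, "moderation", target = "all")
  expect_named(suite, c("primary", "lower", "upper"))
  # alcohol falls by exactly the reduction fraction at every compensation
  # level: the compensation pool holds no alcohol
  for (res in suite) {
    expect_equal(res$changes$pct_change[res$changes$nutrient == "alcohol"], -50)
  }
  # compensation monotonically recovers energy
  e <- sapply(suite, function(r) r$changes$pct_change[r$changes$nutrient == "energy_kj"])
  expect_true(e[["primary"]] < e[["lower"]])
  expect_true(e[["lower"]] < e[["upper"]])

  ref <- run_sensitivity_suite(b, "reformulation", target = "all")
  sfa <- sapply(ref, function(r) r$changes$pct_change[r$changes$nutrient == "sfa"])
  # oracle: the swap removes srf x discretionary-food SFA from the total
  base_sfa <- 27.7
  oracle <- function(srf) -srf * 11.4 / base_sfa * 100
  expect_equal(sfa[["primary"]], oracle(0.50), tolerance = 1e-10)
  expect_equal(sfa[["lower"]], oracle(0.25), tolerance = 1e-10)
  expect_equal(sfa[["upper"]], oracle(0.75), tolerance = 1e-10)

  # suite on a dataset without discretionary intake is a no-op
  foods <- toy_foods()
  core_only <- toy_intakes()[toy_intakes()$food_code %in% c("10000001", "10000002", "10000003"), ]
  d0 <- diet_data(foods, toy_persons(), core_only)
  s0 <- run_sensitivity_suite(d0, "moderation", target = "all")
  for (res in s0) {
    pc <- res$changes$pct_change
    expect_true(all(is.na(pc) | abs(pc) < 1e-10))
  }
})

test_that("scenario results stay internally consistent and tidy", {
  d <- gen_cached(n = 120, seed = 11)
  res <- run_scenario(d, scenario_spec("moderation", "all"))
  td <- tidy(res)
  expect_equal(
    td$pct_change,
    percent_change(td$base_value, td$modelled_value)
  )
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$alcohol_pct, td$pct_change[td$nutrient == "alcohol"])
  expect_s3_class(autoplot(res), "ggplot")
  suite <- run_sensitivity_suite(aus_basecase(), "reformulation", target = "all")
  expect_s3_class(plot_sensitivity(suite), "ggplot")
})

test_that("scenario specs validate their fractions and pools", {
  expect_error(scenario_spec("moderation", reduction_fraction = 1.2), "\\[0, 1\\]")
  expect_error(scenario_spec("reformulation", sodium_reduction = -0.1), "\\[0, 1\\]")
  expect_error(scenario_spec("moderation", compensation_pool = c("core_beverage")), "beverage")
  expect_error(scenario_spec("substitution", replacement_ratios = c(2)), "named")
})
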