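test_that("generation is deterministic for a fixed seed", {
  a <- generate_population(generator_config(n_persons = 80, seed = 3))
  b <- generate_population(generator_config(n_persons = 80, seed = 3))
  expect_identical(a$intakes, b$intakes)
  expect_identical(a$persons, b$persons)
  expect_identical(a$foods, b$foods)
  c <- generate_population(generator_config(n_persons = 80, seed = 4))
  expect_false(identical(a$intakes, c$intakes))
})

test_that("generated datasets cover all classes and special flags", {
  d <- gen_cached(n = 200, seed = 42)
  expect_setequal(as.character(unique(d$foods$class)), food_classes())
  expect_true(any(d$foods$is_alcoholic))
  expect_true(any(d$foods$is_water_based))
  expect_true(any(d$foods$is_sports_or_meal_replacement))
  # milk override: a milk-flagged beverage classifies as core food
  milk <- d$foods[d$foods$is_milk, ]
  expect_true(nrow(milk) > 0 && all(milk$class == "core_food"))
  # every class is actually consumed
  lines <- expand_intake(d)
  expect_setequal(as.character(unique(lines$class)), food_classes())
})

test_that("calibration hits the key class targets exactly", {
  d <- gen_cached(n = 200, seed = 42)
  agg <- aggregate_classes(d)
  targets <- default_generator_targets()
  key <- dietscen:::key_calibration_nutrients()
  for (cl in names(targets)) {
    achieved <- unlist(agg[agg$class == cl, key])
    expect_equal(achieved, targets[[cl]][key], tolerance = 1e-8)
  }
  # calibration report agrees
  rep <- attr(d, "calibration")$report
  expect_true(all(abs(rep$residual) < 1e-6))
  # energy closure survives calibration
  tot <- total_row(agg)
  expect_equal(compute_energy(tot), tot$energy_kj, tolerance = 5e-3)
})

test_that("calibration is an identity when targets equal current means", {
  d <- generate_population(generator_config(n_persons = 80, seed = 5, calibrate = FALSE))
  agg <- aggregate_classes(d)
  key <- dietscen:::key_calibration_nutrients()
  self_targets <- purrr::map(
    setNames(names(default_generator_targets()), names(default_generator_targets())),
    function(cl) unlist(agg[agg$class == cl, key])
  )
  d2 <- calibrate_population(d, self_targets)
  expect_equal(attr(d2, "calibration")$scales$scale,
               rep(1, nrow(attr(d2, "calibration")$scales)), tolerance = 1e-8)
  # doubling a class target doubles that class's mean grams
  doubled <- self_targets
  doubled$discretionary_food <- 2 * doubled$discretionary_food
  d3 <- calibrate_population(d, doubled)
  agg3 <- aggregate_classes(d3)
  expect_equal(
    agg3$grams[agg3$class == "discretionary_food"],
    2 * agg$grams[agg$class == "discretionary_food"],
    tolerance = 1e-8
  )
})

test_that("infeasible or inconsistent targets error before or during calibration", {
  expect_error(
    generator_config(targets = list(core = c(
      grams = 0, energy_kj = 5000, sfa = 0, added_sugars = 0, sodium = 0, alcohol = 0
    ))),
    "energy without mass"
  )
  bad <- default_generator_targets()
  bad$discretionary_food["energy_kj"] <- bad$core[["energy_kj"]] * 20
  expect_error(check_feasible <- generator_config(targets = bad), "vastly exceeds")
  # a class target with no intake in that class
  d <- generate_population(generator_config(n_persons = 30, seed = 6, calibrate = FALSE))
  d$intakes <- d$intakes[!d$intakes$food_code %in%
                           d$foods$food_code[d$foods$class == "discretionary_food"], ]
  d <- diet_data(d$foods, d$persons, d$intakes)
  expect_error(calibrate_population(d, default_generator_targets()), "No intake in class")
})

test_that("without discretionary consumption every scenario is a no-op", {
  cfg <- generator_config(n_persons = 60, seed = 9, calibrate = FALSE)
  cfg$archetypes$consumer_fraction[cfg$archetypes$is_discretionary] <- 0
  d <- generate_population(cfg)
  for (fam in c("moderation", "substitution", "reformulation")) {
    res <- run_scenario(d, scenario_spec(fam, "all"))
    pc <- res$changes$pct_change
    expect_true(all(is.na(pc) | abs(pc) < 1e-10), info = fam)
  }
})

test_that("the discretionary:core median-intake ratio brackets 1.29 across seeds", {
  ratios <- sapply(1:20, function(s) {
    d <- generate_population(generator_config(n_persons = 150, seed = 100 + s))
    compute_replacement_ratio(d)
  })
  expect_lt(min(ratios), 1.29)
  expect_gt(max(ratios), 1.29)
  expect_equal(median(ratios), 1.29, tolerance = 0.08)
})

test_that("written populations reproduce byte-identically from the same seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_population(generate_population(generator_config(n_persons = 40, seed = 12)), dir1)
  write_population(generate_population(generator_config(n_persons = 40, seed = 12)), dir2)
  for (f in c("composition.tsv", "persons.tsv", "intakes.tsv")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_true(file.exists(file.path(dir1, "calibration_report.tsv")))
})
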