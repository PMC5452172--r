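#' Format a class-level profile as a survey-style report table
#'
#' One row per nutrient, one column per reporting class, values rounded to
#' one decimal place with percent-of-energy in parentheses for the
#' energy-yielding nutrients (against the total-intake energy of the same
#' profile), mirroring how national survey base-case tables are presented.
#'
#' @param profile An [aggregate_profile()].
#' @return A tibble of formatted character cells.
#' @export
format_profile_table <- function(profile) {
  reg <- nutrient_registry()
  total_e <- profile_row(profile, "total")$energy_kj
  rows <- purrr::map_dfr(seq_len(nrow(reg)), function(i) {
    nm <- reg$nutrient[i]
    cells <- purrr::map_chr(profile_classes(), function(cl) {
      v <- profile_row(profile, cl)[[nm]]
      if (is.na(v)) return("-")
      cell <- sprintf("%.1f", v)
      if (!is.na(reg$kj_per_g[i]) && nm != "energy_kj" && total_e > 0) {
        cell <- sprintf("%s (%.1f)", cell, v * reg$kj_per_g[i] / total_e * 100)
      }
      cell
    })
    tibble::tibble(
      nutrient = nm, unit = reg$unit[i],
      !!!setNames(as.list(cells), profile_classes())
    )
  })
  rows
}

#' Command-style pipeline entry points
#'
#' Thin wrappers that read the survey input files, run the requested
#' computation and write tidy TSV outputs plus a run manifest, used by the
#' bundled command-line script but equally callable from R.
#'
#' `cmd_basecase()` writes the class-level base-case profile table;
#' `cmd_run()` runs one scenario (or its sensitivity suite) and writes the
#' per-nutrient base/modelled/percent-change table per parameter set;
#' `cmd_generate()` writes a synthetic population.
#'
#' @param input_dir Directory with `composition.tsv`, `persons.tsv`,
#'   `intakes.tsv`; or `NULL` with `aggregate_csv` for aggregate mode.
#' @param out_dir Output directory (created if needed).
#' @param aggregate_csv Optional path to a class-level profile table
#'   (columns `class` + nutrient names) to run scenarios in aggregate mode.
#' @return Invisibly, the paths written.
#' @name pipeline_commands
NULL

load_pipeline_input <- function(input_dir, aggregate_csv) {
  if (!is.null(aggregate_csv)) {
    raw <- read_delim_auto(aggregate_csv)
    aggregate_profile(raw)
  } else if (!is.null(input_dir)) {
    read_diet_data(input_dir)
  } else {
    abort("Provide input_dir (person mode) or aggregate_csv (aggregate mode)")
  }
}

write_run_manifest <- function(out_dir, command, extra = list()) {
  manifest <- c(
    list(
      command = command,
      package_version = as.character(packageVersion("dietscen")),
      r_version = as.character(getRversion()),
      timestamp = format(Sys.time(), tz = "UTC", "%Y-%m-%dT%H:%M:%SZ")
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

file_digest <- function(path) {
  config_digest(readBin(path, "raw", n = file.size(path)))
}

#' @rdname pipeline_commands
#' @export
cmd_basecase <- function(input_dir = NULL, out_dir = ".", aggregate_csv = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  x <- load_pipeline_input(input_dir, aggregate_csv)
  profile <- if (inherits(x, "diet_data")) aggregate_classes(x) else x
  if (profile_row(profile, "total")$grams == 0) {
    warn("Base case has zero recorded intake; report is all zero")
  }
  path <- file.path(out_dir, "basecase_profile.tsv")
  readr::write_tsv(format_profile_table(profile), path, progress = FALSE)
  raw_path <- file.path(out_dir, "basecase_profile_raw.tsv")
  readr::write_tsv(tibble::as_tibble(profile), raw_path, progress = FALSE)
  write_run_manifest(out_dir, "basecase",
                     list(inputs = input_hashes(input_dir, aggregate_csv)))
  invisible(c(path, raw_path))
}

input_hashes <- function(input_dir, aggregate_csv) {
  files <- if (!is.null(aggregate_csv)) {
    aggregate_csv
  } else {
    file.path(input_dir, c("composition.tsv", "persons.tsv", "intakes.tsv"))
  }
  setNames(as.list(purrr::map_chr(files, file_digest)), basename(files))
}

#' Read a scenario configuration file
#'
#' YAML (or JSON) with fields matching the [scenario_spec()] arguments; a
#' `suite: true` flag requests the sensitivity suite. The bundled default
#' at `system.file("extdata", "default_scenarios.yaml", package =
#' "dietscen")` encodes the primary and sensitivity-bound parameter sets of
#' the three families.
#'
#' @param path Configuration file path.
#' @return A list of [scenario_spec()]s (and suite flags).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Scenario config not found: ", path))
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(cfg$scenarios)) abort("Scenario config needs a top-level 'scenarios' list")
  purrr::map(cfg$scenarios, function(sc) {
    suite <- isTRUE(sc$suite)
    sc$suite <- NULL
    label <- sc$label %||% NULL
    sc$label <- NULL
    if (!is.null(sc$replacement_ratios)) sc$replacement_ratios <- unlist(sc$replacement_ratios)
    spec <- do.call(scenario_spec, sc)
    list(spec = spec, suite = suite, label = label %||% paste(spec$family, spec$target, sep = "_"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname pipeline_commands
#' @param scenario_config Path to a scenario configuration file; defaults
#'   to the bundled parameter sets.
#' @export
cmd_run <- function(input_dir = NULL, out_dir = ".", scenario_config = NULL,
                    aggregate_csv = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(scenario_config)) {
    scenario_config <- system.file("extdata", "default_scenarios.yaml", package = "dietscen")
  }
  x <- load_pipeline_input(input_dir, aggregate_csv)
  entries <- read_scenario_config(scenario_config)
  paths <- character()
  for (entry in entries) {
    if (entry$suite) {
      suite <- run_sensitivity_suite(x, entry$spec$family, target = entry$spec$target)
      out <- tidy_suite(suite)
      path <- file.path(out_dir, paste0(entry$label, ".tsv"))
    } else {
      res <- run_scenario(x, entry$spec, label = entry$label)
      out <- tidy(res)
      path <- file.path(out_dir, paste0(entry$label, ".tsv"))
    }
    readr::write_tsv(out, path, progress = FALSE)
    paths <- c(paths, path)
  }
  write_run_manifest(out_dir, "run", list(
    scenario_config = basename(scenario_config),
    config_hash = file_digest(scenario_config),
    inputs = input_hashes(input_dir, aggregate_csv)
  ))
  invisible(paths)
}

#' @rdname pipeline_commands
#' @param n_persons,seed Generator size and seed.
#' @export
cmd_generate <- function(out_dir = ".", n_persons = 500, seed = 1) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  data <- generate_population(generator_config(n_persons = n_persons, seed = seed))
  write_population(data, out_dir)
  write_run_manifest(out_dir, "generate", list(n_persons = n_persons, seed = seed))
  invisible(out_dir)
}
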