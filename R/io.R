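#' Read and write survey input files
#'
#' Plain-text I/O for the three survey inputs. Files are UTF-8, either
#' tab- or comma-delimited (auto-detected from the header line), with "."
#' as the decimal separator. Composition nutrient columns carry an explicit
#' unit suffix (e.g. `sodium_mg_per100g`, `sfa_g_per100g`); units are
#' checked against the registry on read and converted to the canonical
#' internal units. `write_composition()` emits the canonical tab-delimited
#' dialect, so a write/read cycle is lossless.
#'
#' @param path File path.
#' @param foods,persons Reference tables used to validate intake lines.
#' @return `read_composition()`: validated foods tibble;
#'   `read_intakes()`: validated intake tibble; `read_persons()`: person
#'   tibble.
#' @name survey_io
NULL

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) return("\t")
  if (grepl("\t", header)) "\t" else ","
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_delim(
    path,
    delim = sniff_delim(path), col_types = readr::cols(.default = readr::col_guess()),
    progress = FALSE, show_col_types = FALSE
  )
}

composition_column_map <- function() {
  reg <- nutrient_registry()
  reg <- reg[!reg$nutrient %in% c("grams", "energy_kj"), ]
  setNames(paste0(reg$nutrient, "_", reg$unit, "_per100g"), reg$nutrient)
}

#' @rdname survey_io
#' @param fat_tolerance Passed through to composition validation.
#' @export
read_composition <- function(path, fat_tolerance = 0.02) {
  raw <- read_delim_auto(path)
  cmap <- composition_column_map()
  optional <- c("mufa", "pufa")
  missing <- setdiff(cmap[!names(cmap) %in% optional], names(raw))
  # energy is derivable from the macronutrients
  missing <- setdiff(missing, "energy_kj_per100g")
  if (length(missing)) {
    abort(paste0("Composition file is missing column(s): ", paste(missing, collapse = ", ")))
  }
  for (nm in names(cmap)) {
    if (cmap[[nm]] %in% names(raw)) names(raw)[names(raw) == cmap[[nm]]] <- nm
  }
  validate_foods(raw, fat_tolerance = fat_tolerance)
}

#' @rdname survey_io
#' @export
read_intakes <- function(path, foods, persons) {
  raw <- read_delim_auto(path)
  validate_intakes(raw, foods, validate_persons(persons))
}

#' @rdname survey_io
#' @export
read_persons <- function(path) {
  validate_persons(read_delim_auto(path))
}

# canonical numeric formatting (10 significant digits) so that a
# write -> read -> write cycle is byte-stable
format_numeric_cols <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.10g", df[[nm]])
  }
  df
}

#' @rdname survey_io
#' @param x Table to write.
#' @export
write_composition <- function(x, path) {
  cmap <- composition_column_map()
  out <- x[, c("food_code", "name", "subgroup_code", food_flag_columns(),
               intersect(names(cmap), names(x)))]
  for (nm in names(cmap)) {
    if (nm %in% names(out)) names(out)[names(out) == nm] <- cmap[[nm]]
  }
  readr::write_tsv(format_numeric_cols(out), path, progress = FALSE)
  invisible(path)
}

#' @rdname survey_io
#' @export
write_intakes <- function(x, path) {
  readr::write_tsv(format_numeric_cols(x[, c("person_id", "food_code", "grams")]),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname survey_io
#' @export
write_persons <- function(x, path) {
  out <- x[, intersect(c("person_id", "weight", "age", "sex"), names(x))]
  readr::write_tsv(format_numeric_cols(out), path, progress = FALSE)
  invisible(path)
}

#' @rdname survey_io
#' @param dir Directory holding `composition.tsv`, `persons.tsv`,
#'   `intakes.tsv` (as written by [write_diet_data()]).
#' @export
read_diet_data <- function(dir) {
  foods <- read_composition(file.path(dir, "composition.tsv"))
  persons <- read_persons(file.path(dir, "persons.tsv"))
  intakes <- read_intakes(file.path(dir, "intakes.tsv"), foods, persons)
  diet_data(foods, persons, intakes)
}

#' @rdname survey_io
#' @param data A [diet_data()] object.
#' @export
write_diet_data <- function(data, dir) {
  stopifnot(inherits(data, "diet_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_composition(data$foods, file.path(dir, "composition.tsv"))
  write_persons(data$persons, file.path(dir, "persons.tsv"))
  write_intakes(data$intakes, file.path(dir, "intakes.tsv"))
  invisible(dir)
}
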