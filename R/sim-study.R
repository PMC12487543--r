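#' Generate a complete synthetic study
#'
#' Convenience wrapper tying together [sim_exposures()] and [sim_deaths()]:
#' returns every input table the analysis pipeline consumes plus the ground
#' truth used by validation studies.
#'
#' @param config A [sim_config()].
#' @return An object of class `motomort_study`: a list with `config`,
#'   `exposures`, `deaths`, `population`, `correction_factors`,
#'   `ground_truth`.
#' @export
#' @examples
#' study <- sim_study(sim_config(cities_per_country = 3, seed = 7))
#' names(study)
sim_study <- function(config) {
  exposures <- sim_exposures(config)
  d <- sim_deaths(config, exposures)
  structure(
    c(list(config = config, exposures = exposures), d),
    class = "motomort_study"
  )
}

#' @export
print.motomort_study <- function(x, ...) {
  cat("<motomort_study>\n")
  cat("  cities:", nrow(x$exposures),
      " deaths rows:", nrow(x$deaths),
      " total deaths:", sum(x$deaths$n_deaths), "\n")
  invisible(x)
}

# check that all tables refer to the same city/stratum keys; error listing
# orphan keys otherwise
validate_study_keys <- function(study) {
  cities_exp <- sort(unique(study$exposures$city_id))
  cities_pop <- sort(unique(study$population$city_id))
  cities_cf <- sort(unique(study$correction_factors$city_id))
  orphans <- list(
    deaths_without_population = setdiff(unique(study$deaths$city_id), cities_pop),
    population_without_exposures = setdiff(cities_pop, cities_exp),
    exposures_without_population = setdiff(cities_exp, cities_pop),
    population_without_factor = setdiff(cities_pop, cities_cf)
  )
  bad <- orphans[vapply(orphans, length, 1L) > 0]
  if (length(bad)) {
    msg <- paste(vapply(names(bad), function(nm) {
      paste0(nm, ": ", paste(head(bad[[nm]], 10), collapse = ", "))
    }, ""), collapse = "; ")
    stop("study tables have mismatched keys - ", msg)
  }
  invisible(TRUE)
}

#' Write a study to a directory of plain-text files
#'
#' Emits `deaths.csv`, `population.csv`, `correction_factors.csv`,
#' `exposures.csv` and `ground_truth.json`. The CSV files round-trip
#' losslessly through [read_study()].
#'
#' @param study A `motomort_study` (or a list with the same tables).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  validate_study_keys(study)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(study$deaths, file.path(dir, "deaths.csv"))
  readr::write_csv(study$population, file.path(dir, "population.csv"))
  readr::write_csv(study$correction_factors,
                   file.path(dir, "correction_factors.csv"))
  exp_out <- study$exposures
  attr(exp_out, "realized_corr") <- NULL
  attr(exp_out, "moto_full") <- NULL
  readr::write_csv(exp_out, file.path(dir, "exposures.csv"))
  gt <- study$ground_truth
  if (!is.null(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Read a study back from a directory
#'
#' @param dir Directory written by [write_study()].
#' @return A list with `deaths`, `population`, `correction_factors`,
#'   `exposures` tibbles (and `ground_truth` if present).
#' @export
read_study <- function(dir) {
  ct <- readr::cols(
    city_id = readr::col_character(),
    year = readr::col_integer(),
    .default = readr::col_double()
  )
  deaths <- readr::read_csv(
    file.path(dir, "deaths.csv"), show_col_types = FALSE,
    col_types = readr::cols(
      city_id = readr::col_character(), country_id = readr::col_character(),
      year = readr::col_integer(), sex = readr::col_character(),
      age_group = readr::col_character(), icd10_code = readr::col_character(),
      n_deaths = readr::col_integer()
    )
  )
  population <- readr::read_csv(
    file.path(dir, "population.csv"), show_col_types = FALSE,
    col_types = readr::cols(
      city_id = readr::col_character(), year = readr::col_integer(),
      sex = readr::col_character(), age_group = readr::col_character(),
      population = readr::col_integer()
    )
  )
  cf <- readr::read_csv(file.path(dir, "correction_factors.csv"),
                        show_col_types = FALSE, col_types = ct)
  exposures <- readr::read_csv(
    file.path(dir, "exposures.csv"), show_col_types = FALSE,
    col_types = readr::cols(
      city_id = readr::col_character(),
      country_id = readr::col_character(),
      .default = readr::col_double()
    )
  )
  class(exposures) <- c("motomort_exposures", class(exposures))
  out <- list(deaths = deaths, population = population,
              correction_factors = cf, exposures = exposures)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    out$ground_truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  out
}
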