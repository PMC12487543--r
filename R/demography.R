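#' Completeness-corrected person-years
#'
#' Person-years per (city, sex, age group): the sum over calendar years of
#' the population count multiplied by that city-year's registration
#' correction factor.
#'
#' @param population Tibble with `city_id`, `year`, `sex`, `age_group`,
#'   `population`.
#' @param correction_factors Tibble with `city_id`, `year`, `factor`
#'   (strictly positive). City-years without a factor use 1.0 with a
#'   warning.
#' @return A tibble with `city_id`, `sex`, `age_group`, `person_years`.
#' @export
#' @examples
#' pop <- tidyr::expand_grid(city_id = "A", year = 2010:2019,
#'                           sex = "M", age_group = "20-24")
#' pop$population <- 100000
#' cf <- tibble::tibble(city_id = "A", year = 2010:2019, factor = 1)
#' build_person_years(pop, cf)
build_person_years <- function(population, correction_factors) {
  if (any(population$population < 0)) {
    stop("negative population counts")
  }
  if (any(correction_factors$factor <= 0)) {
    stop("correction factors must be strictly positive")
  }
  x <- dplyr::left_join(population, correction_factors,
                        by = c("city_id", "year"))
  if (anyNA(x$factor)) {
    warning(sum(is.na(x$factor)), " city-years without a correction factor; ",
            "using 1.0")
    x$factor[is.na(x$factor)] <- 1
  }
  dplyr::summarise(
    dplyr::group_by(x, .data$city_id, .data$sex, .data$age_group),
    person_years = sum(.data$population * .data$factor),
    .groups = "drop"
  )
}

#' Crude mortality rate per 100,000
#'
#' @param deaths Total death count.
#' @param py Total person-years (> 0 when `deaths` > 0).
#' @return Rate per 100,000 person-years.
#' @export
#' @examples
#' crude_rate(109052, 2.62e9) # 4.16
crude_rate <- function(deaths, py) {
  stopifnot(deaths >= 0)
  if (any(py <= 0 & deaths > 0)) {
    stop("undefined rate: zero person-years with positive deaths")
  }
  ifelse(deaths == 0, 0, 1e5 * deaths / py)
}

#' Directly age-standardized rate
#'
#' Weighted mean of age-specific rates with external standard weights
#' normalized to sum to 1. Age groups with positive standard weight must
#' have defined rates (zero person-years there is an error, not a zero
#' rate).
#'
#' @param age_rates Tibble with `age_group` and `rate` (per 100,000), one
#'   row per age group.
#' @param std Standard population tibble (`age_group`, `weight`), default
#'   [who_standard()].
#' @return Standardized rate per 100,000 (scalar).
#' @export
#' @examples
#' r <- tibble::tibble(age_group = age_group_labels(), rate = 10)
#' age_standardize(r) # 10
age_standardize <- function(age_rates, std = who_standard()) {
  m <- dplyr::left_join(std, age_rates, by = "age_group")
  bad <- m$weight > 0 & (is.na(m$rate) | !is.finite(m$rate))
  if (any(bad)) {
    stop("rate undefined for age group(s) with positive standard weight: ",
         paste(m$age_group[bad], collapse = ", "))
  }
  w <- m$weight / sum(m$weight)
  sum(w * m$rate)
}

#' City-level age-standardized rates from stratum counts
#'
#' Computes, for each city and sex category (`F`, `M`, `both`), the
#' age-specific rates and their directly standardized summary.
#'
#' @param counts Tibble with `city_id`, `sex`, `age_group`, `n_deaths`
#'   (e.g., one draw of redistributed motorcyclist deaths, or draw-averaged
#'   counts).
#' @param py Person-years from [build_person_years()].
#' @param std Standard population.
#' @return Tibble with `city_id`, `sex` (F/M/both), `rate_std` per 100,000,
#'   `deaths`, `person_years`.
#' @export
city_standardized_rates <- function(counts, py, std = who_standard()) {
  x <- dplyr::left_join(
    py, counts[, c("city_id", "sex", "age_group", "n_deaths")],
    by = c("city_id", "sex", "age_group")
  )
  x$n_deaths[is.na(x$n_deaths)] <- 0
  both <- dplyr::summarise(
    dplyr::group_by(x, .data$city_id, .data$age_group),
    n_deaths = sum(.data$n_deaths),
    person_years = sum(.data$person_years), .groups = "drop"
  )
  both$sex <- "both"
  x <- dplyr::bind_rows(x, both)
  bad_py <- x$person_years <= 0
  if (any(bad_py)) {
    stop("zero person-years in age group(s) with positive standard weight: ",
         paste(unique(paste(x$city_id, x$sex, x$age_group)[bad_py])[1:5],
               collapse = "; "))
  }
  x$rate <- crude_rate(x$n_deaths, x$person_years)
  x$w <- std$weight[match(x$age_group, std$age_group)] / sum(std$weight)
  if (anyNA(x$w)) {
    stop("age group(s) missing from the standard population: ",
         paste(unique(x$age_group[is.na(x$w)]), collapse = ", "))
  }
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$city_id, .data$sex),
    rate_std = sum(.data$w * .data$rate),
    deaths = sum(.data$n_deaths),
    person_years = sum(.data$person_years),
    n_groups = dplyr::n(),
    .groups = "drop"
  )
  if (any(out$n_groups != nrow(std))) {
    stop("cities with incomplete age-group coverage: ",
         paste(unique(out$city_id[out$n_groups != nrow(std)])[1:5],
               collapse = ", "))
  }
  out$n_groups <- NULL
  out
}

#' Mortality rate per 100,000 motorcycle registrations
#'
#' Both-sex, all-age city rates using registration-years as the
#' denominator; cities without registration data are excluded with a
#' message.
#'
#' @param deaths Tibble with `city_id` and `n_deaths` (already averaged
#'   over draws), any further columns ignored.
#' @param registrations Tibble with `city_id` and `registrations`
#'   (registration-years over the study period; `NA` = no data).
#' @return Tibble `city_id`, `rate_per_100k_reg`, `deaths`,
#'   `registrations`.
#' @export
registration_rate <- function(deaths, registrations) {
  d <- dplyr::summarise(dplyr::group_by(deaths, .data$city_id),
                        n_deaths = sum(.data$n_deaths), .groups = "drop")
  x <- dplyr::left_join(registrations, d, by = "city_id")
  x$n_deaths[is.na(x$n_deaths)] <- 0
  drop <- is.na(x$registrations) | x$registrations <= 0
  if (any(drop)) {
    message(sum(drop), " of ", nrow(x),
            " cities excluded from the registration-denominator analysis ",
            "(no registration data)")
  }
  x <- x[!drop, , drop = FALSE]
  tibble::tibble(
    city_id = x$city_id,
    rate_per_100k_reg = crude_rate(x$n_deaths, x$registrations),
    deaths = x$n_deaths,
    registrations = x$registrations
  )
}

#' Median (IQR) of city standardized rates by country and sex
#'
#' Per-draw city rates are averaged across draws first, then summarized
#' over cities within country (and overall) by sex, using type-7
#' (linear-interpolation) quantiles.
#'
#' @param rates Tibble with `draw` (optional), `city_id`, `country_id`,
#'   `sex`, `rate_std`.
#' @return Tibble `country_id` (including "all"), `sex`, `n_cities`,
#'   `median`, `q25`, `q75`.
#' @export
summarize_rates <- function(rates) {
  if ("draw" %in% names(rates)) {
    rates <- dplyr::summarise(
      dplyr::group_by(rates, .data$city_id, .data$country_id, .data$sex),
      rate_std = mean(.data$rate_std), .groups = "drop"
    )
  }
  all_r <- rates
  all_r$country_id <- "all"
  rates <- dplyr::bind_rows(rates, all_r)
  dplyr::summarise(
    dplyr::group_by(rates, .data$country_id, .data$sex),
    n_cities = dplyr::n(),
    median = median(.data$rate_std),
    q25 = quantile(.data$rate_std, 0.25, type = 7, names = FALSE),
    q75 = quantile(.data$rate_std, 0.75, type = 7, names = FALSE),
    .groups = "drop"
  )
}

#' Read or write standard-population weights as YAML
#'
#' The standard population is an editable YAML mapping of age-group label
#' to weight, so alternative standards (e.g., finer top age groups) can be
#' dropped in without code changes.
#'
#' @param path YAML file path.
#' @return `read_standard_population()` returns a tibble with `age_group`
#'   and `weight`; `write_standard_population()` returns `path`, invisibly.
#' @export
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_standard_population(who_standard(), p)
#' read_standard_population(p)
read_standard_population <- function(path) {
  x <- yaml::read_yaml(path)
  std <- tibble::tibble(age_group = names(x$weights),
                        weight = as.numeric(unlist(x$weights)))
  if (any(std$weight <= 0)) stop("standard weights must be positive")
  std
}

#' @rdname read_standard_population
#' @param std Standard population tibble (`age_group`, `weight`).
#' @param source_label Free-text provenance label stored in the file.
#' @export
write_standard_population <- function(std, path,
                                      source_label = "WHO world standard 2000-2025, 80+ collapsed") {
  yaml::write_yaml(
    list(source = source_label,
         weights = as.list(setNames(std$weight, std$age_group))),
    path, precision = 12
  )
  invisible(path)
}
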