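#' Simulation configuration for the synthetic multi-city study
#'
#' Bundles every tunable of the synthetic data generator: study layout
#' (countries, cities, years), the true exposure effects on the log-rate
#' scale, between-city heterogeneity, negative binomial overdispersion,
#' garbage-coding intensity, registration completeness, and the target
#' correlation structure of the city-level exposures.
#'
#' Defaults emulate a 337-city, 7-country Latin-American study over
#' 2010-2019: male baseline motorcyclist mortality peaking in the 20-24 age
#' group at roughly eight times the female rate, country log-offsets spanning
#' low- to high-mortality countries, ~11% of external-cause deaths garbage
#' coded, and one strong exposure correlation (patch density with
#' intersection density, target 0.7).
#'
#' @param n_countries Number of countries.
#' @param cities_per_country Integer vector (recycled to `n_countries`) of
#'   cities per country. The default mirrors a 337-city layout:
#'   33/152/21/35/1/92/3.
#' @param years Inclusive study years.
#' @param age_groups The 17 five-year age-group labels.
#' @param beta Named numeric: true log rate ratio per 1 SD of each exposure
#'   (per unit for `transit`). Unnamed exposures have effect 0.
#' @param sigma_city SD of the city random intercept (log scale).
#' @param alpha_nb NB2 dispersion alpha (variance = mu + alpha * mu^2);
#'   `0` means Poisson counts.
#' @param p_illdefined Fraction of external-cause deaths whose cause is
#'   overwritten with a garbage code (split between partially defined
#'   road-traffic and ill-defined external according to
#'   `garbage_split_partial`).
#' @param garbage_split_partial For road-traffic deaths, the share of
#'   garbage coding that uses a partially defined road-traffic code rather
#'   than a fully ill-defined external code (default 0.5). Non-road-traffic
#'   external deaths can only receive ill-defined codes, and do so with the
#'   same ill-defined propensity as road-traffic deaths, so the ill-defined
#'   pool's cause composition matches the observed external-cause
#'   composition (the assumption under which composition-based
#'   redistribution is unbiased).
#' @param garbage_social_gradient Log-odds change in the garbage-coding
#'   propensity per SD decrease of the social environment index (default 0:
#'   a single uniform probability). Positive values emulate worse coding
#'   quality in cities with worse social environment.
#' @param completeness Either a single number in (0, 1], a numeric vector of
#'   length 2 giving a uniform range from which per-city death-registration
#'   completeness is drawn, or a function(n_cities) returning completeness
#'   per city.
#' @param exposure_corr Data frame with columns `var1`, `var2`, `rho` giving
#'   target pairwise Pearson correlations between exposures; unlisted pairs
#'   are independent. `NULL` means all independent.
#' @param male_female_ratio Ratio of male to female baseline rates.
#' @param country_effects Numeric vector of fixed country log-offsets
#'   (recycled to `n_countries`).
#' @param baseline_male Numeric length-17 male baseline motorcyclist
#'   mortality rates per 100,000 person-years by age group (piecewise
#'   constant, peak at 20-24 by default).
#' @param registration_countries Indices of countries for which motorcycle
#'   registration data exist (others get `NA` in `moto_per_1000`).
#' @param seed Master RNG seed (integer).
#' @return An object of class `motomort_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(cities_per_country = 5, seed = 1)
#' cfg$n_cities
sim_config <- function(n_countries = 7,
                       cities_per_country = c(33, 152, 21, 35, 1, 92, 3),
                       years = 2010:2019,
                       age_groups = age_group_labels(),
                       beta = c(
                         mean_nn_distance = log(1.07),
                         circuity = log(0.97),
                         intersection_density = log(0.91),
                         population_density = log(0.92),
                         transit = log(0.94),
                         social_index = log(0.88),
                         moto_per_1000 = log(1.20)
                       ),
                       sigma_city = 0.3,
                       alpha_nb = 0.5,
                       p_illdefined = 0.11,
                       garbage_split_partial = 0.5,
                       garbage_social_gradient = 0,
                       completeness = c(0.8, 1),
                       exposure_corr = default_exposure_corr(),
                       male_female_ratio = 8,
                       country_effects = c(0.17, 0.48, -1.48, 0.77,
                                           0.01, -0.57, -1.88),
                       baseline_male = c(0.3, 0.3, 1.5, 12, 17, 15, 12, 10,
                                         8, 6, 5, 4, 3, 2.5, 2, 1.5, 1.2),
                       registration_countries = c(2, 3, 4, 6),
                       seed = 1L) {
  stopifnot(
    n_countries >= 1, length(years) >= 1,
    sigma_city >= 0, alpha_nb >= 0,
    p_illdefined >= 0, p_illdefined < 1,
    garbage_split_partial >= 0, garbage_split_partial <= 1,
    male_female_ratio > 0,
    length(baseline_male) == length(age_groups),
    all(baseline_male >= 0)
  )
  if (length(age_groups) != 17L) {
    stop("`age_groups` must have exactly 17 entries (five-year groups 0-4 ... 80+)")
  }
  cities_per_country <- rep_len(as.integer(cities_per_country), n_countries)
  stopifnot(all(cities_per_country >= 1))
  country_effects <- rep_len(country_effects, n_countries)
  registration_countries <- intersect(registration_countries, seq_len(n_countries))

  if (is.numeric(completeness) && length(completeness) <= 2) {
    rng <- range(completeness)
    if (rng[1] <= 0 || rng[2] > 1) {
      stop("completeness values must lie in (0, 1]")
    }
  }
  exposures <- exposure_names(include_moto = TRUE)
  if (length(beta)) {
    stopifnot(!is.null(names(beta)))
    bad <- setdiff(names(beta), exposures)
    if (length(bad)) stop("unknown exposure in `beta`: ", paste(bad, collapse = ", "))
  }
  beta_full <- setNames(numeric(length(exposures)), exposures)
  beta_full[names(beta)] <- beta

  structure(list(
    n_countries = n_countries,
    cities_per_country = cities_per_country,
    n_cities = sum(cities_per_country),
    years = years,
    age_groups = age_groups,
    beta = beta_full,
    sigma_city = sigma_city,
    alpha_nb = alpha_nb,
    p_illdefined = p_illdefined,
    garbage_split_partial = garbage_split_partial,
    garbage_social_gradient = garbage_social_gradient,
    completeness = completeness,
    exposure_corr = exposure_corr,
    male_female_ratio = male_female_ratio,
    country_effects = country_effects,
    baseline_male = baseline_male,
    registration_countries = registration_countries,
    seed = as.integer(seed)
  ), class = "motomort_config")
}

#' Default target exposure correlations
#'
#' One strong pair (patch density with intersection density, 0.7) plus two
#' moderate pairs, so that the realized correlation surface is "mostly weak
#' or moderate" with a single strong entry.
#'
#' @return A tibble with columns `var1`, `var2`, `rho`.
#' @export
default_exposure_corr <- function() {
  tibble::tibble(
    var1 = c("patch_density", "gdp_pc", "street_length_avg"),
    var2 = c("intersection_density", "social_index", "street_node_avg"),
    rho = c(0.7, 0.45, 0.3)
  )
}

#' @export
print.motomort_config <- function(x, ...) {
  cat("<motomort_config>\n")
  cat("  countries:", x$n_countries, " cities:", x$n_cities,
      " years:", min(x$years), "-", max(x$years), "\n")
  cat("  sigma_city:", x$sigma_city, " alpha_nb:", x$alpha_nb,
      " p_illdefined:", x$p_illdefined, "\n")
  nz <- x$beta[x$beta != 0]
  if (length(nz)) {
    cat("  nonzero true RRs per SD:\n")
    for (nm in names(nz)) cat(sprintf("    %-22s %.3f\n", nm, exp(nz[[nm]])))
  }
  invisible(x)
}

# per-city completeness vector, drawn deterministically from the config seed
resolve_completeness <- function(config, n_cities) {
  cc <- config$completeness
  if (is.function(cc)) {
    out <- cc(n_cities)
  } else if (length(cc) == 1) {
    out <- rep(cc, n_cities)
  } else {
    out <- runif(n_cities, min(cc), max(cc))
  }
  stopifnot(length(out) == n_cities, all(out > 0), all(out <= 1))
  out
}
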