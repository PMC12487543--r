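# population age shares for the 17 groups (younger pyramid typical of the
# region; normalized internally)
.age_shares <- c(8.5, 8.5, 8.5, 8.5, 8.5, 8.0, 7.5, 7.0, 6.5, 6.0,
                 5.5, 4.5, 3.5, 3.0, 2.5, 2.0, 1.5)

# expected deaths in the non-motorcyclist external-cause classes, as
# multipliers of the (exposure-free) motorcyclist baseline
.other_class_mult <- c(
  pedestrian = 1.0, bicyclist = 0.15, car_occupant = 0.8,
  other_rt = 0.4, non_rt_external = 3.0
)

# representative ICD-10 codes per cause class, with assignment weights
.class_codes <- list(
  specific_motorcyclist = c(V23 = 0.3, V27 = 0.3, V28 = 0.2, V29 = 0.2),
  pedestrian            = c(V03 = 0.6, V09 = 0.4),
  bicyclist             = c(V13 = 1.0),
  car_occupant          = c(V43 = 0.4, V47 = 0.3, V49 = 0.3),
  other_rt              = c(V69 = 0.5, V78 = 0.5),
  partially_defined_rt  = c(V87 = 0.3, V89 = 0.6, V99 = 0.1),
  ill_defined_external  = c(X59 = 0.6, Y34 = 0.4),
  non_rt_external       = c(W10 = 0.25, W74 = 0.15, X70 = 0.30, X95 = 0.30)
)

# vectorized multinomial via sequential binomials: one draw per row of
# `counts`, probabilities `p` shared across rows. Returns matrix n x length(p).
rmultinom_rows <- function(counts, p) {
  k <- length(p)
  n <- length(counts)
  out <- matrix(0L, n, k)
  rem <- as.integer(counts)
  prem <- 1
  for (j in seq_len(k - 1L)) {
    pj <- if (prem > 0) min(1, p[j] / prem) else 0
    out[, j] <- rbinom(n, rem, pj)
    rem <- rem - out[, j]
    prem <- prem - p[j]
  }
  out[, k] <- rem
  out
}

#' Generate synthetic death records, population and correction factors
#'
#' Simulates, for every city x year x sex x age stratum, motorcyclist deaths
#' from a negative binomial log-linear model with person-years offset, true
#' exposure effects, country fixed log-offsets and a city random intercept;
#' adds deaths in the other external-cause classes; garbage-codes a fraction
#' of all external-cause deaths (overwriting their cause with a partially
#' defined road-traffic or ill-defined external code); and finally thins
#' both deaths and emitted population by per-city registration completeness,
#' storing the matching correction factor `1/completeness`.
#'
#' @param config A [sim_config()].
#' @param exposures Output of [sim_exposures()] for the same config.
#' @return A list with elements `deaths` (tibble: city_id, country_id, year,
#'   sex, age_group, icd10_code, n_deaths), `population` (tibble, thinned
#'   registration-consistent counts), `correction_factors` (tibble: city_id,
#'   year, factor), and `ground_truth` (list; pre-corruption quantities and
#'   all true parameters - consumed only by validation code, never by the
#'   analysis pipeline).
#' @export
sim_deaths <- function(config, exposures) {
  stopifnot(inherits(config, "motomort_config"),
            inherits(exposures, "motomort_exposures"))
  if (!setequal(exposures$city_id, city_frame(config)$city_id)) {
    stop("exposures do not cover the cities in `config`")
  }
  set.seed(hash_seed(config$seed, 202L))

  cities <- dplyr::arrange(
    tibble::tibble(
      city_id = exposures$city_id,
      country_id = exposures$country_id
    ),
    .data$city_id
  )
  n_city <- nrow(cities)
  cities$completeness <- resolve_completeness(config, n_city)
  cities$b_city <- rnorm(n_city, 0, config$sigma_city)
  cities$base_pop <- rlnorm(n_city, meanlog = log(450000), sdlog = 1.05)

  # standardized exposure scores used by the true log-linear model
  z <- standardize_exposures(exposures)
  zm <- as.matrix(z[, exposure_names()])
  moto_full <- attr(exposures, "moto_full")
  zm <- cbind(zm, moto_per_1000 = as.numeric(scale(moto_full)))
  rownames(zm) <- exposures$city_id
  zm <- zm[cities$city_id, , drop = FALSE]
  beta <- config$beta[colnames(zm)]
  cities$xb <- drop(zm %*% beta)
  cities$country_effect <-
    config$country_effects[match(cities$country_id,
                                 country_labels(config$n_countries))]

  shares <- .age_shares / sum(.age_shares)
  grid <- tidyr::expand_grid(
    city_id = cities$city_id,
    year = config$years,
    sex = .sexes,
    age_group = config$age_groups
  )
  grid <- dplyr::left_join(grid, cities, by = "city_id")
  grid$age_idx <- match(grid$age_group, config$age_groups)
  grid$pop_true <- round(
    grid$base_pop * 1.01^(grid$year - min(config$years)) *
      0.5 * shares[grid$age_idx]
  )
  r0 <- config$baseline_male[grid$age_idx] / 1e5
  r0 <- r0 * ifelse(grid$sex == "F", 1 / config$male_female_ratio, 1)
  if (any(grid$pop_true == 0 & r0 > 0)) {
    stop("stratum with zero person-years but nonzero baseline rate; ",
         "increase city population sizes")
  }

  # motorcyclist deaths: NB2 with true exposure effects and random intercept
  mu_moto <- grid$pop_true * r0 *
    exp(grid$country_effect + grid$xb + grid$b_city)
  n <- nrow(grid)
  counts <- matrix(0L, n, 6,
                   dimnames = list(NULL, c("specific_motorcyclist",
                                           names(.other_class_mult))))
  counts[, 1] <- if (config$alpha_nb > 0) {
    rnbinom(n, mu = mu_moto, size = 1 / config$alpha_nb)
  } else {
    rpois(n, mu_moto)
  }
  # other external classes: class multipliers on the same city-level
  # log-linear surface (Poisson). The exposure effects and the city
  # intercept are shared across cause classes: they are city-level
  # contextual effects, and a composition that is homogeneous within
  # country-sex-age strata makes the planted coefficients an exactly
  # recoverable target for the redistribution + regression machinery.
  mu_base <- mu_moto
  for (k in names(.other_class_mult)) {
    counts[, k] <- rpois(n, mu_base * .other_class_mult[[k]])
  }

  truth_classes <- colSums(counts)
  truth_moto <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(city_id = grid$city_id, sex = grid$sex,
                     age_group = grid$age_group, n = counts[, 1]),
      .data$city_id, .data$sex, .data$age_group
    ),
    n_deaths = sum(.data$n), .groups = "drop"
  )

  # garbage coding. Ill-defined coding (mechanism lost entirely) hits every
  # external-cause class with the same propensity u, so the ill-defined
  # pool's cause mix matches the external-cause mix; partially defined
  # road-traffic coding (road-user group lost, V87-V89/V99) can only arise
  # from road-traffic deaths and has propensity v there. With the default
  # 50/50 split a road-traffic death is garbage coded with probability
  # p_illdefined overall. Coding quality may optionally worsen with the
  # city's social environment (garbage_social_gradient).
  s <- config$garbage_split_partial
  p_city <- stats::plogis(
    stats::qlogis(min(max(config$p_illdefined, 1e-12), 1 - 1e-12)) -
      config$garbage_social_gradient * zm[cities$city_id, "social_index"]
  )
  p_row <- if (config$p_illdefined > 0) {
    p_city[match(grid$city_id, cities$city_id)]
  } else {
    rep(0, n)
  }
  u <- p_row * (1 - s)          # ill-defined propensity, all classes
  v <- p_row * s                # partial-RT propensity, RT classes only
  rt_classes <- c("specific_motorcyclist", names(.other_class_mult))
  rt_classes <- setdiff(rt_classes, "non_rt_external")
  ill_add <- integer(n)
  part_add <- integer(n)
  obs_counts <- counts
  for (j in seq_len(ncol(counts))) {
    cl <- colnames(counts)[j]
    ill_j <- rbinom(n, counts[, j], u)
    left <- counts[, j] - ill_j
    part_j <- if (cl %in% rt_classes) {
      rbinom(n, left, ifelse(u < 1, pmin(1, v / (1 - u)), 0))
    } else {
      integer(n)
    }
    obs_counts[, j] <- left - part_j
    ill_add <- ill_add + ill_j
    part_add <- part_add + part_j
  }
  garbage_share <- if (sum(counts) > 0) {
    (sum(ill_add) + sum(part_add)) / sum(counts)
  } else {
    0
  }
  obs <- cbind(obs_counts,
               partially_defined_rt = part_add,
               ill_defined_external = ill_add)

  # registration thinning of deaths
  for (j in seq_len(ncol(obs))) {
    obs[, j] <- rbinom(n, obs[, j], grid$completeness)
  }

  deaths <- expand_icd_codes(grid, obs)

  population <- tibble::tibble(
    city_id = grid$city_id,
    year = grid$year,
    sex = grid$sex,
    age_group = grid$age_group,
    population = as.integer(round(grid$pop_true * grid$completeness))
  )
  correction_factors <- tidyr::expand_grid(
    city_id = cities$city_id, year = config$years
  )
  correction_factors$factor <-
    1 / cities$completeness[match(correction_factors$city_id, cities$city_id)]

  py_true <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(city_id = grid$city_id, sex = grid$sex,
                     age_group = grid$age_group, py = grid$pop_true),
      .data$city_id, .data$sex, .data$age_group
    ),
    person_years = sum(.data$py), .groups = "drop"
  )

  ground_truth <- list(
    beta = as.list(beta),
    sigma_city = config$sigma_city,
    alpha_nb = config$alpha_nb,
    p_illdefined = config$p_illdefined,
    realized_garbage_share = garbage_share,
    male_female_ratio = config$male_female_ratio,
    country_effects = as.list(setNames(config$country_effects,
                                       country_labels(config$n_countries))),
    city_intercepts = as.list(setNames(cities$b_city, cities$city_id)),
    completeness = as.list(setNames(cities$completeness, cities$city_id)),
    baseline_male_per_100k = config$baseline_male,
    total_deaths_by_class = as.list(truth_classes),
    true_moto_deaths = truth_moto,
    true_person_years = py_true
  )

  list(deaths = deaths, population = population,
       correction_factors = correction_factors, ground_truth = ground_truth)
}

# city_id/country_id frame implied by a config (canonical order)
city_frame <- function(config) {
  country_id <- rep(country_labels(config$n_countries),
                    config$cities_per_country)
  tibble::tibble(
    city_id = sprintf("%s-%03d", country_id,
                      unlist(lapply(config$cities_per_country, seq_len))),
    country_id = country_id
  )
}

# spread per-stratum class counts over representative ICD-10 codes and
# return the long death table (zero rows dropped)
expand_icd_codes <- function(grid, obs) {
  pieces <- vector("list", ncol(obs))
  for (j in seq_len(ncol(obs))) {
    cls <- colnames(obs)[j]
    codes <- .class_codes[[cls]]
    nz <- which(obs[, j] > 0L)
    if (!length(nz)) next
    alloc <- rmultinom_rows(obs[nz, j], codes / sum(codes))
    colnames(alloc) <- names(codes)
    piece <- tibble::tibble(
      city_id = rep(grid$city_id[nz], ncol(alloc)),
      country_id = rep(grid$country_id[nz], ncol(alloc)),
      year = rep(grid$year[nz], ncol(alloc)),
      sex = rep(grid$sex[nz], ncol(alloc)),
      age_group = rep(grid$age_group[nz], ncol(alloc)),
      icd10_code = rep(colnames(alloc), each = length(nz)),
      n_deaths = as.integer(alloc)
    )
    pieces[[j]] <- piece[piece$n_deaths > 0L, ]
  }
  out <- dplyr::bind_rows(pieces)
  dplyr::arrange(out, .data$city_id, .data$year, .data$sex,
                 .data$age_group, .data$icd10_code)
}
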