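# shared fixtures and independent oracles, built in code at test time

# small multi-country study (28 cities) for structural tests
fx_small_config <- function(seed = 21, ...) {
  sim_config(cities_per_country = 4, seed = seed, ...)
}

# cache expensive fixtures across test files within one run
.fx_cache <- new.env()
fx_cached <- function(name, expr) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- force(expr)
  .fx_cache[[name]]
}

# medium clean study (no garbage, full registration) with one active
# exposure; used by several model tests
fx_model_base <- function() {
  fx_cached("model_base", {
    cfg <- sim_config(cities_per_country = 8,
                      beta = c(social_index = log(0.85)),
                      sigma_city = 0.25, alpha_nb = 0.4,
                      p_illdefined = 0, completeness = 1, seed = 21)
    st <- sim_study(cfg)
    cl <- classify_deaths(st$deaths)
    dr <- redistribute_deaths(cl, redistribution_probs(cl), M = 1, seed = 1)
    py <- build_person_years(st$population, st$correction_factors)
    z <- standardize_exposures(st$exposures)
    base <- dplyr::left_join(py, z, by = "city_id")
    d1 <- dr[dr$draw == 1, ]
    key <- paste(base$city_id, base$sex, base$age_group)
    kd <- paste(d1$city_id, d1$sex, d1$age_group)
    base$n_deaths <- d1$n_deaths[match(key, kd)]
    base$n_deaths[is.na(base$n_deaths)] <- 0
    base
  })
}

# hand-built classified death table: one stratum with specific counts
# (moto 30, pedestrian 10, other 10) plus garbage
fx_one_stratum_deaths <- function(partial = 20L, ill = 0L, non_rt = 0L) {
  rows <- tibble::tibble(
    city_id = "A-001", country_id = "A", year = 2010L, sex = "M",
    age_group = "20-24",
    cause_class = c("specific_motorcyclist", "pedestrian", "other_rt",
                    "partially_defined_rt", "ill_defined_external",
                    "non_rt_external"),
    n_deaths = c(30L, 10L, 10L, partial, ill, non_rt)
  )
  rows[rows$n_deaths > 0, ]
}

# independent oracle: marginal log-likelihood by trapezoid integration on a
# fixed grid over b in [-span*sigma, span*sigma]
oracle_loglik <- function(frame, beta, alpha, sigma, npts = 2001, span = 8) {
  eta <- drop(frame$X %*% beta) + frame$offset
  tot <- 0
  for (c in seq_along(frame$city_len)) {
    idx <- frame$city_start[c] + seq_len(frame$city_len[c])
    b <- seq(-span * sigma, span * sigma, length.out = npts)
    h <- vapply(b, function(bb) {
      mu <- exp(eta[idx] + bb)
      ll <- if (alpha > 0) {
        sum(dnbinom(frame$y[idx], mu = mu, size = 1 / alpha, log = TRUE))
      } else {
        sum(dpois(frame$y[idx], mu, log = TRUE))
      }
      ll + dnorm(bb, 0, sigma, log = TRUE)
    }, 0)
    m <- max(h)
    tot <- tot + m + log(sum(exp(h - m)) * (b[2] - b[1]))
  }
  tot
}

# tiny 3-city x 4-strata model frame with fixed counts
fx_tiny_frame <- function(seed = 5) {
  set.seed(seed)
  d <- tibble::tibble(
    city_id = rep(c("X-1", "X-2", "X-3"), each = 4),
    country_id = "X",
    sex = rep(c("F", "M"), 6),
    age_group = rep(c("20-24", "25-29"), each = 2, times = 3),
    person_years = exp(runif(12, 9, 11.5)),
    z = rep(c(-1, 0.2, 0.9), each = 4)
  )
  d$n_deaths <- rpois(12, d$person_years * 8e-5 *
                        exp(0.3 * d$z + (d$sex == "M")))
  nb_model_frame(d, "z")
}

# one replicate of the synthetic recovery pipeline; returns pooled fit for
# the named exposure
fx_recovery_rep <- function(r, beta, M = 20, n_cities = 300, start = NULL,
                            exposure = "social_index", seed_base = 1000L) {
  cpc <- rep(n_cities %/% 7, 7)
  cpc[7] <- cpc[7] + n_cities %% 7
  cfg <- sim_config(cities_per_country = cpc, beta = beta,
                    sigma_city = 0.3, alpha_nb = 0.5, p_illdefined = 0.11,
                    seed = seed_base + r)
  st <- sim_study(cfg)
  cl <- classify_deaths(st$deaths)
  dr <- redistribute_deaths(cl, redistribution_probs(cl), M = M,
                            seed = seed_base + 5000L + r)
  py <- build_person_years(st$population, st$correction_factors)
  z <- standardize_exposures(st$exposures)
  base <- dplyr::left_join(py, z, by = "city_id")
  base$n_deaths <- 0
  fit_pooled(base, dr, exposure, model = "M1", start = start)
}
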