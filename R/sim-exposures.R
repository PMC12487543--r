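# Marginal distributions of the synthetic exposures. Medians and spreads are
# chosen to resemble published city-level descriptive tables for Latin
# American cities; they are design constants of the generator, not estimates.
exposure_marginals <- function() {
  tibble::tribble(
    ~var,                   ~dist,        ~par1,   ~par2,
    "mean_nn_distance",     "lognormal",  84,      0.25,
    "patch_density",        "lognormal",  0.30,    0.55,
    "circuity",             "normal",     1.065,   0.02,
    "street_length_avg",    "lognormal",  137,     0.15,
    "intersection_density", "lognormal",  4.7,     0.60,
    "street_node_avg",      "normal",     3.0,     0.15,
    "population_density",   "lognormal",  6400,    0.35,
    "transit",              "bernoulli",  0.16,    NA,
    "travel_delay_index",   "lognormal",  0.12,    0.50,
    "gdp_pc",               "lognormal",  15000,   0.45,
    "social_index",         "normal",     0.20,    0.45,
    "moto_per_1000",        "lognormal",  80,      0.90
  )
}

# Map a target Pearson correlation on the observed scale to the latent
# Gaussian correlation. Exact (Gaussian copula) for lognormal-lognormal
# pairs; other pairs use the target directly, which is accurate to within
# a few hundredths for the mild transforms used here.
latent_rho <- function(rho, dist1, s1, dist2, s2) {
  if (dist1 == "lognormal" && dist2 == "lognormal") {
    arg <- 1 + rho * sqrt(expm1(s1^2) * expm1(s2^2))
    if (arg <= 0) stop("target correlation ", rho, " infeasible for lognormal pair")
    out <- log(arg) / (s1 * s2)
    if (abs(out) > 1) stop("target correlation ", rho, " infeasible for lognormal pair")
    out
  } else {
    rho
  }
}

#' Generate city-level exposures
#'
#' Draws one row per city of the 11 built/social-environment variables plus
#' the motorization rate, with a Gaussian-copula dependence structure
#' matched to the configured target Pearson correlations. `transit` is
#' Bernoulli (0/1); `moto_per_1000` is `NA` for countries without
#' registration data.
#'
#' @param config A [sim_config()].
#' @return A tibble (class `motomort_exposures`) with columns `city_id`,
#'   `country_id` and one column per exposure. The realized pairwise
#'   correlation matrix of the continuous exposures is attached as attribute
#'   `realized_corr` when there are at least 2 cities (`NULL` otherwise).
#' @export
#' @examples
#' ex <- sim_exposures(sim_config(cities_per_country = 4, seed = 1))
#' ex
sim_exposures <- function(config) {
  stopifnot(inherits(config, "motomort_config"))
  marg <- exposure_marginals()
  p <- nrow(marg)
  R <- diag(p)
  dimnames(R) <- list(marg$var, marg$var)
  ec <- config$exposure_corr
  if (!is.null(ec) && nrow(ec)) {
    for (i in seq_len(nrow(ec))) {
      v1 <- ec$var1[i]; v2 <- ec$var2[i]
      if (!v1 %in% marg$var || !v2 %in% marg$var) {
        stop("exposure_corr names unknown variable: ", v1, " / ", v2)
      }
      m1 <- marg[marg$var == v1, ]; m2 <- marg[marg$var == v2, ]
      r <- latent_rho(ec$rho[i], m1$dist, m1$par2, m2$dist, m2$par2)
      R[v1, v2] <- R[v2, v1] <- r
    }
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    load <- abs(ev$vectors[, which.min(ev$values)])
    bad <- marg$var[order(load, decreasing = TRUE)][1:min(3, p)]
    stop("exposure correlation matrix is not positive semi-definite; ",
         "offending submatrix involves: ", paste(bad, collapse = ", "))
  }

  n <- config$n_cities
  country_id <- rep(country_labels(config$n_countries), config$cities_per_country)
  city_id <- sprintf("%s-%03d", country_id, unlist(lapply(config$cities_per_country, seq_len)))

  set.seed(hash_seed(config$seed, 101L))
  # PSD-safe square root (eigen) so exactly singular targets are accepted
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)
  Z <- matrix(rnorm(n * p), n, p) %*% rt
  colnames(Z) <- marg$var

  X <- matrix(NA_real_, n, p, dimnames = list(NULL, marg$var))
  for (j in seq_len(p)) {
    z <- Z[, j]
    X[, j] <- switch(marg$dist[j],
      lognormal = exp(log(marg$par1[j]) + marg$par2[j] * z),
      normal    = marg$par1[j] + marg$par2[j] * z,
      bernoulli = as.numeric(z < qnorm(marg$par1[j]))
    )
  }

  out <- tibble::as_tibble(X)
  out <- dplyr::bind_cols(
    tibble::tibble(city_id = city_id, country_id = country_id), out
  )
  no_reg <- !(match(country_id, country_labels(config$n_countries)) %in%
                config$registration_countries)
  # full motorization vector (pre-masking) retained for the generator's own
  # use: the true effect acts in every city even where registrations are
  # unobserved
  attr(out, "moto_full") <- out$moto_per_1000
  out$moto_per_1000[no_reg] <- NA_real_

  rc <- NULL
  if (n >= 2) {
    cont <- setdiff(marg$var, "transit")
    rc <- suppressWarnings(stats::cor(X[, cont], use = "pairwise.complete.obs"))
  }
  attr(out, "realized_corr") <- rc
  class(out) <- c("motomort_exposures", class(out))
  out
}
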