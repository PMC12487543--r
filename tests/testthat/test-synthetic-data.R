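test_that("exposure generator hits target correlations and marginal forms", {
  cfg <- sim_config(cities_per_country = 43, seed = 1)
  ex <- sim_exposures(cfg)
  expect_equal(nrow(ex), 301)
  expect_true(all(ex$transit %in% c(0, 1)))
  rc <- attr(ex, "realized_corr")
  expect_gte(rc["patch_density", "intersection_density"], 0.55)
  expect_lte(rc["patch_density", "intersection_density"], 0.85)
  # all configured targets realized within +-0.15
  ec <- default_exposure_corr()
  for (i in seq_len(nrow(ec))) {
    expect_lt(abs(rc[ec$var1[i], ec$var2[i]] - ec$rho[i]), 0.15)
  }
  expect_true(all(ex$circuity > 0.9), info = "circuity near 1")
  expect_true(all(ex$gdp_pc > 0))
})

test_that("identity correlation config yields near-independent exposures", {
  cfg <- sim_config(cities_per_country = 43, exposure_corr = NULL, seed = 2)
  ex <- sim_exposures(cfg)
  rc <- attr(ex, "realized_corr")
  off <- rc[upper.tri(rc)]
  expect_true(all(abs(off) < 0.15))
})

test_that("single-city request is valid with correlations reported absent", {
  cfg <- sim_config(n_countries = 1, cities_per_country = 1, seed = 3,
                    country_effects = 0)
  ex <- sim_exposures(cfg)
  expect_equal(nrow(ex), 1)
  expect_null(attr(ex, "realized_corr"))
})

test_that("non-PSD correlation target errors naming the offending variables", {
  bad <- tibble::tibble(
    var1 = c("circuity", "circuity", "street_node_avg"),
    var2 = c("street_node_avg", "social_index", "social_index"),
    rho = c(0.9, 0.9, -0.9)
  )
  cfg <- sim_config(cities_per_country = 4, exposure_corr = bad, seed = 4)
  expect_error(sim_exposures(cfg), "positive semi-definite")
  expect_error(sim_exposures(cfg), "circuity|street_node_avg|social_index")
})

test_that("uncorrupted generator conserves class totals against ground truth", {
  cfg <- fx_small_config(p_illdefined = 0, completeness = 1)
  st <- sim_study(cfg)
  cl <- classify_deaths(st$deaths)
  expect_false(any(cl$cause_class %in%
                     c("partially_defined_rt", "ill_defined_external")))
  gt <- st$ground_truth$total_deaths_by_class
  obs <- tapply(cl$n_deaths, cl$cause_class, sum)
  for (k in names(gt)) {
    expect_identical(unname(obs[[k]]), as.integer(gt[[k]]))
  }
  # pre-thinning motorcyclist truth matches observed stratum by stratum
  moto <- cl[cl$cause_class == "specific_motorcyclist", ]
  moto_tot <- tapply(moto$n_deaths, paste(moto$city_id, moto$sex), sum)
  tm <- st$ground_truth$true_moto_deaths
  tm_tot <- tapply(tm$n_deaths, paste(tm$city_id, tm$sex), sum)
  common <- intersect(names(moto_tot), names(tm_tot))
  expect_identical(as.integer(moto_tot[common]), as.integer(tm_tot[common]))
})

test_that("garbage coding corrupts roughly the configured fraction", {
  cfg <- fx_small_config(p_illdefined = 0.11, completeness = 1, seed = 8)
  st <- sim_study(cfg)
  share <- st$ground_truth$realized_garbage_share
  # road-traffic deaths are garbage coded at p_illdefined, non-RT external
  # at half that (ill-defined only), so the overall share is between
  expect_gt(share, 0.055)
  expect_lt(share, 0.11)
  cl <- classify_deaths(st$deaths)
  g <- sum(cl$n_deaths[cl$cause_class %in%
                         c("partially_defined_rt", "ill_defined_external")])
  expect_equal(g / sum(cl$n_deaths), share, tolerance = 0.01)
})

test_that("Poisson limit: variance/mean ratio of stratum counts is ~1", {
  cfg <- sim_config(cities_per_country = 5, beta = c(), sigma_city = 0,
                    alpha_nb = 0, p_illdefined = 0, completeness = 1,
                    seed = 31)
  st <- sim_study(cfg)
  cl <- classify_deaths(st$deaths)
  moto <- cl[cl$cause_class == "specific_motorcyclist", ]
  # within (city, sex, age), yearly counts share one Poisson mean
  key <- paste(moto$city_id, moto$sex, moto$age_group)
  full <- tidyr::expand_grid(key = unique(key), year = 2010:2019)
  obs <- tibble::tibble(key = key, year = moto$year, n = moto$n_deaths)
  full <- dplyr::left_join(full, obs, by = c("key", "year"))
  full$n[is.na(full$n)] <- 0
  disp <- dplyr::summarise(dplyr::group_by(full, key),
                           m = mean(n), v = var(n), .groups = "drop")
  disp <- disp[disp$m >= 2, ]
  expect_gt(nrow(disp), 100)
  ratio <- mean(disp$v / disp$m)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("dispersion of stratum counts is non-decreasing in alpha", {
  ratio_at <- function(alpha, seed) {
    cfg <- sim_config(cities_per_country = 5, beta = c(), sigma_city = 0,
                      alpha_nb = alpha, p_illdefined = 0, completeness = 1,
                      seed = seed)
    st <- sim_study(cfg)
    cl <- classify_deaths(st$deaths)
    moto <- cl[cl$cause_class == "specific_motorcyclist", ]
    key <- paste(moto$city_id, moto$sex, moto$age_group)
    full <- tidyr::expand_grid(key = unique(key), year = 2010:2019)
    obs <- tibble::tibble(key = key, year = moto$year, n = moto$n_deaths)
    full <- dplyr::left_join(full, obs, by = c("key", "year"))
    full$n[is.na(full$n)] <- 0
    disp <- dplyr::summarise(dplyr::group_by(full, key),
                             m = mean(n), v = var(n), .groups = "drop")
    disp <- disp[disp$m >= 2, ]
    mean(disp$v / disp$m)
  }
  r <- vapply(c(0, 0.5, 2), ratio_at, 0, seed = 77)
  expect_true(all(diff(r) > 0))
})

test_that("registration thinning removes the configured fraction of deaths", {
  cfg <- fx_small_config(p_illdefined = 0, completeness = 0.8, seed = 13)
  st <- sim_study(cfg)
  cl <- classify_deaths(st$deaths)
  moto_obs <- tapply(
    cl$n_deaths[cl$cause_class == "specific_motorcyclist"],
    cl$city_id[cl$cause_class == "specific_motorcyclist"], sum
  )
  tm <- st$ground_truth$true_moto_deaths
  moto_true <- tapply(tm$n_deaths, tm$city_id, sum)
  big <- names(moto_true)[moto_true >= 1000]
  expect_gt(length(big), 0)
  for (ct in big) {
    expect_gt(moto_obs[[ct]] / moto_true[[ct]], 0.75)
    expect_lt(moto_obs[[ct]] / moto_true[[ct]], 0.85)
  }
  # corrected person-years recover the true person-years within rounding
  py <- build_person_years(st$population, st$correction_factors)
  tp <- st$ground_truth$true_person_years
  m <- dplyr::inner_join(py, tp, by = c("city_id", "sex", "age_group"))
  expect_lt(max(abs(m$person_years.x - m$person_years.y) /
                  m$person_years.y), 2e-3)
  expect_lt(abs(sum(m$person_years.x) / sum(m$person_years.y) - 1), 1e-5)
})

test_that("identical config and seed reproduce the study exactly", {
  a <- sim_study(fx_small_config(seed = 99))
  b <- sim_study(fx_small_config(seed = 99))
  expect_identical(a$deaths, b$deaths)
  expect_identical(a$population, b$population)
  expect_identical(dplyr::select(tibble::as_tibble(a$exposures),
                                 dplyr::everything()),
                   dplyr::select(tibble::as_tibble(b$exposures),
                                 dplyr::everything()))
})

test_that("study files round-trip losslessly and have the expected shape", {
  st <- sim_study(fx_small_config(seed = 5))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_setequal(
    list.files(dir),
    c("deaths.csv", "population.csv", "correction_factors.csv",
      "exposures.csv", "ground_truth.json")
  )
  rt <- read_study(dir)
  expect_equal(as.data.frame(rt$deaths), as.data.frame(st$deaths))
  expect_equal(as.data.frame(rt$population), as.data.frame(st$population))
  expect_equal(as.data.frame(rt$correction_factors),
               as.data.frame(st$correction_factors))
  expect_equal(as.data.frame(rt$exposures)[, names(st$exposures)],
               as.data.frame(st$exposures), tolerance = 1e-12,
               ignore_attr = TRUE)
  # population has one row per city x year x sex x age group
  expect_equal(nrow(st$population), 28 * 10 * 2 * 17)
  # all age labels are the 17 fixed strings
  expect_setequal(unique(st$population$age_group), age_group_labels())
})

test_that("an empty death table writes a valid header-only file", {
  st <- sim_study(fx_small_config(seed = 5))
  st$deaths <- st$deaths[0, ]
  dir <- withr::local_tempdir()
  write_study(st, dir)
  rt <- read_study(dir)
  expect_equal(nrow(rt$deaths), 0)
  expect_named(rt$deaths, names(st$deaths))
})

test_that("mismatched city keys across tables error with the orphan keys", {
  st <- sim_study(fx_small_config(seed = 5))
  st$population <- st$population[st$population$city_id != "C01-001", ]
  expect_error(write_study(st, withr::local_tempdir()),
               "mismatched keys.*C01-001")
})
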