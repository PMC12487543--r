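test_that("person-years sum population times correction factors", {
  pop <- tidyr::expand_grid(city_id = "A", year = 2010:2019, sex = "M",
                            age_group = "20-24")
  pop$population <- 100000L
  cf <- tibble::tibble(city_id = "A", year = 2010:2019, factor = 1)
  expect_equal(build_person_years(pop, cf)$person_years, 1e6)
  cf2 <- cf
  cf2$factor[cf2$year == 2014] <- 1.05
  expect_equal(build_person_years(pop, cf2)$person_years, 1005000)
  expect_error(build_person_years(pop, dplyr::mutate(cf, factor = 0)),
               "strictly positive")
  pop$population[1] <- -1L
  expect_error(build_person_years(pop, cf), "negative population")
})

test_that("city-years without a factor default to 1 with a warning", {
  pop <- tidyr::expand_grid(city_id = "A", year = 2010:2011, sex = "M",
                            age_group = "20-24")
  pop$population <- 1000L
  cf <- tibble::tibble(city_id = "A", year = 2010L, factor = 2)
  expect_warning(py <- build_person_years(pop, cf), "without a correction")
  expect_equal(py$person_years, 3000)
})

test_that("crude rate matches direct arithmetic", {
  expect_equal(round(crude_rate(109052, 2.62e9), 2), 4.16)
  expect_equal(crude_rate(0, 1e6), 0)
  expect_equal(crude_rate(1, 1e5), 1)
  expect_equal(crude_rate(100, 63551), 157.35, tolerance = 1e-4)
  expect_error(crude_rate(5, 0), "undefined rate")
})

test_that("direct standardization is a normalized weighted mean", {
  std <- who_standard()
  flat <- tibble::tibble(age_group = age_group_labels(), rate = 7.3)
  expect_equal(age_standardize(flat, std), 7.3)
  # packaged WHO weight for 0-4 is 0.0886 after normalization
  one <- tibble::tibble(age_group = age_group_labels(),
                        rate = c(10, rep(0, 16)))
  expect_equal(age_standardize(one, std), 0.886, tolerance = 2e-3)
  r <- tibble::tibble(age_group = age_group_labels(), rate = runif(17, 0, 20))
  expect_equal(age_standardize(dplyr::mutate(r, rate = 2 * rate), std),
               2 * age_standardize(r, std))
})

test_that("standardized rate is bounded by the age-specific extremes", {
  std <- who_standard()
  set.seed(99)
  for (i in 1:1000) {
    r <- tibble::tibble(age_group = age_group_labels(),
                        rate = rexp(17, 1 / 5))
    s <- age_standardize(r, std)
    expect_gte(s, min(r$rate))
    expect_lte(s, max(r$rate))
  }
})

test_that("missing age groups with positive weight are an error, not zero", {
  r <- tibble::tibble(age_group = age_group_labels()[-1],
                      rate = rep(1, 16))
  expect_error(age_standardize(r), "0-4")
})

test_that("WHO standard covers all 17 groups with positive weights", {
  std <- who_standard()
  expect_equal(std$age_group, age_group_labels())
  expect_true(all(std$weight > 0))
  expect_equal(sum(std$weight), 1)
  raw <- who_standard(normalize = FALSE)
  expect_equal(sum(raw$weight), 100, tolerance = 1e-3)
})

test_that("crude rate equals the person-years-weighted mean of age rates", {
  st <- sim_study(fx_small_config(seed = 61))
  py <- build_person_years(st$population, st$correction_factors)
  cl <- classify_deaths(st$deaths)
  moto <- cl[cl$cause_class == "specific_motorcyclist", ]
  counts <- dplyr::summarise(
    dplyr::group_by(moto, city_id, sex, age_group),
    n_deaths = sum(n_deaths), .groups = "drop"
  )
  x <- dplyr::left_join(py, counts, by = c("city_id", "sex", "age_group"))
  x$n_deaths[is.na(x$n_deaths)] <- 0
  age_rates <- dplyr::summarise(
    dplyr::group_by(x, age_group),
    rate = 1e5 * sum(n_deaths) / sum(person_years),
    py = sum(person_years), .groups = "drop"
  )
  crude_direct <- crude_rate(sum(x$n_deaths), sum(x$person_years))
  crude_weighted <- sum(age_rates$rate * age_rates$py) / sum(age_rates$py)
  expect_lt(abs(crude_direct - crude_weighted), 1e-10)
})

test_that("registration rates are per 100,000 registration-years", {
  deaths <- tibble::tibble(city_id = c("A", "A", "B", "C"),
                           n_deaths = c(60, 40, 10, 0))
  regs <- tibble::tibble(city_id = c("A", "B", "C", "D"),
                         registrations = c(63551, 20000, 5000, NA))
  expect_message(rr <- registration_rate(deaths, regs), "1 of 4")
  expect_equal(rr$rate_per_100k_reg[rr$city_id == "A"], 1e5 * 100 / 63551)
  expect_equal(rr$rate_per_100k_reg[rr$city_id == "C"], 0)
  expect_false("D" %in% rr$city_id)
})

test_that("registration and population denominators can reverse rankings", {
  # city A: fewer deaths, far fewer motorcycles; city B: more deaths,
  # many motorcycles
  deaths <- tibble::tibble(city_id = c("A", "B"), n_deaths = c(50, 100))
  regs <- tibble::tibble(city_id = c("A", "B"),
                         registrations = c(10000, 100000))
  py <- c(A = 1e6, B = 1e6)
  pop_rate <- 1e5 * deaths$n_deaths / py[deaths$city_id]
  reg_rate <- registration_rate(deaths, regs)$rate_per_100k_reg
  expect_lt(pop_rate[1], pop_rate[2])
  expect_gt(reg_rate[1], reg_rate[2])
})

test_that("rate summaries use draw-averaged rates and type-7 quantiles", {
  rates <- tibble::tibble(
    city_id = paste0("c", 1:5), country_id = "X", sex = "both",
    rate_std = 1:5
  )
  s <- summarize_rates(rates)
  row <- s[s$country_id == "X", ]
  expect_equal(row$median, 3)
  expect_equal(row$q25, 2)
  expect_equal(row$q75, 4)
  # one-city country: median and IQR bounds coincide
  one <- summarize_rates(tibble::tibble(city_id = "z", country_id = "Z",
                                        sex = "both", rate_std = 4.05))
  expect_equal(one$median[1], 4.05)
  expect_equal(one$q25[1], 4.05)
  expect_equal(one$q75[1], 4.05)
  # identical draws: averaging is a no-op
  two <- dplyr::bind_rows(dplyr::mutate(rates, draw = 1),
                          dplyr::mutate(rates, draw = 2))
  expect_equal(summarize_rates(two), s)
})

test_that("per-draw averaged rates equal rates of averaged counts", {
  st <- sim_study(fx_small_config(seed = 62))
  cl <- classify_deaths(st$deaths)
  dr <- redistribute_deaths(cl, redistribution_probs(cl), M = 4, seed = 3)
  py <- build_person_years(st$population, st$correction_factors)
  per_draw <- lapply(1:4, function(d) {
    city_standardized_rates(dr[dr$draw == d, ], py)$rate_std
  })
  avg_of_rates <- Reduce(`+`, per_draw) / 4
  counts_avg <- dplyr::summarise(
    dplyr::group_by(dr, city_id, sex, age_group),
    n_deaths = sum(n_deaths) / 4, .groups = "drop"
  )
  rates_of_avg <- city_standardized_rates(counts_avg, py)$rate_std
  expect_equal(avg_of_rates, rates_of_avg, tolerance = 1e-12)
})

test_that("standard-population weights round-trip through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  write_standard_population(who_standard(), p)
  std <- read_standard_population(p)
  expect_equal(std$age_group, age_group_labels())
  expect_equal(std$weight, who_standard()$weight, tolerance = 1e-9)
  # packaged copy matches the built-in weights
  pkg_yaml <- system.file("extdata", "who_standard_2000_2025.yaml",
                          package = "motomort")
  expect_equal(read_standard_population(pkg_yaml)$weight,
               who_standard()$weight, tolerance = 1e-9)
})
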