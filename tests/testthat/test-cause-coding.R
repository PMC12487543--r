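test_that("ICD-10 codes classify into the documented cause classes", {
  m <- cause_map()
  expect_equal(classify_icd10("V23.4", m), "specific_motorcyclist")
  expect_equal(classify_icd10("V20", m), "specific_motorcyclist")
  expect_equal(classify_icd10("V39", m), "specific_motorcyclist")
  expect_equal(classify_icd10("V894", m), "partially_defined_rt")
  expect_equal(classify_icd10("V89", m), "partially_defined_rt")
  expect_equal(classify_icd10("V99", m), "partially_defined_rt")
  expect_equal(classify_icd10("W10", m), "non_rt_external")
  expect_equal(classify_icd10("X59", m), "ill_defined_external")
  expect_equal(classify_icd10("Y21", m), "ill_defined_external")
  expect_equal(classify_icd10("V03", m), "pedestrian")
  expect_equal(classify_icd10("V13", m), "bicyclist")
  expect_equal(classify_icd10("V47", m), "car_occupant")
  expect_equal(classify_icd10("V78", m), "other_rt")
  expect_equal(classify_icd10("V92", m), "non_rt_external") # water transport
  expect_equal(classify_icd10("A09", m), "not_external")
  # every V-code maps to exactly one class
  v <- sprintf("V%02d", 1:99)
  cls <- classify_icd10(v, m)
  expect_false(anyNA(cls))
  expect_true(all(table(substr(v, 1, 3)) == 1))
})

test_that("malformed codes raise a classification error naming the code", {
  expect_error(classify_icd10("banana"), "malformed.*banana")
  expect_error(classify_icd10(c("V23", "9X9")), "9X9")
})

test_that("cause map rejects overlapping prefix sets", {
  expect_error(cause_map(partially_defined = c("V25", "V87")), "disjoint")
})

test_that("redistribution probabilities are proportional to specific counts", {
  d <- fx_one_stratum_deaths(partial = 20L)
  pr <- redistribution_probs(d)
  expect_equal(pr$p_specific_motorcyclist, 0.6)
  expect_equal(pr$p_pedestrian, 0.2)
  expect_equal(pr$p_other_rt, 0.2)
  expect_equal(pr$p_bicyclist, 0)
  pcols <- paste0("p_", road_user_groups())
  expect_lt(abs(sum(pr[1, pcols]) - 1), 1e-12)
})

test_that("probability vectors normalize across every stratum of a study", {
  st <- sim_study(fx_small_config(seed = 41))
  pr <- redistribution_probs(classify_deaths(st$deaths))
  pcols <- paste0("p_", road_user_groups())
  sums <- rowSums(as.matrix(pr[, pcols]))
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(pr$p_rt >= 0 & pr$p_rt <= 1))
})

test_that("zero-cell strata back off along the documented ladder", {
  d <- fx_one_stratum_deaths(partial = 5L)
  # a second stratum (same country/sex, different age) with garbage only
  extra <- tibble::tibble(
    city_id = "A-001", country_id = "A", year = 2011L, sex = "M",
    age_group = "55-59", cause_class = "partially_defined_rt", n_deaths = 4L
  )
  pr <- redistribution_probs(dplyr::bind_rows(d, extra))
  row <- pr[pr$age_group == "55-59", ]
  expect_equal(row$level, "country-sex")
  # backoff uses the country-sex margin: same probabilities as the only
  # populated stratum
  expect_equal(row$p_specific_motorcyclist, 0.6)
  # and the populated stratum used its own rung
  expect_equal(pr$level[pr$age_group == "20-24"], "country-sex-age-period")
})

test_that("degenerate probabilities allocate everything to one group", {
  d <- tibble::tibble(
    city_id = "A-001", country_id = "A", year = 2010L, sex = "M",
    age_group = "20-24",
    cause_class = c("specific_motorcyclist", "partially_defined_rt"),
    n_deaths = c(7L, 10L)
  )
  pr <- redistribution_probs(d)
  dr <- redistribute_deaths(d, pr, M = 100, seed = 3)
  expect_true(all(dr$n_deaths == 17L))
  expect_equal(nrow(dr), 100)
})

test_that("mean allocation converges to garbage x probability", {
  d <- fx_one_stratum_deaths(partial = 20L)
  pr <- redistribution_probs(d)
  dr <- redistribute_deaths(d, pr, M = 2000, seed = 11)
  added <- dr$n_deaths - 30L
  # E = 20 * 0.6 = 12; tolerance = spec's binomial band
  expect_gte(mean(added), 11.4)
  expect_lte(mean(added), 12.6)
})

test_that("with no garbage deaths all draws equal the observed counts", {
  st <- sim_study(fx_small_config(p_illdefined = 0, seed = 17))
  cl <- classify_deaths(st$deaths)
  dr <- redistribute_deaths(cl, redistribution_probs(cl), M = 5, seed = 2)
  obs <- cl[cl$cause_class == "specific_motorcyclist", ]
  obs_tot <- sum(obs$n_deaths)
  for (d in 1:5) {
    expect_identical(sum(dr$n_deaths[dr$draw == d]), obs_tot)
  }
  expect_true(all(attr(dr, "draw_summary")$garbage_in == 0))
})

test_that("every draw conserves the garbage pool exactly", {
  st <- sim_study(fx_small_config(seed = 43))
  cl <- classify_deaths(st$deaths)
  dr <- redistribute_deaths(cl, redistribution_probs(cl), M = 25, seed = 7)
  s <- attr(dr, "draw_summary")
  expect_identical(s$allocated_rt + s$allocated_non_rt, s$garbage_in)
  expect_true(all(s$conservation_residual == 0))
  # global external-cause total is invariant across draws
  expect_equal(length(unique(s$allocated_rt + s$allocated_non_rt)), 1L)
})

test_that("draw d is reproducible in isolation and depends on the seed", {
  st <- sim_study(fx_small_config(seed = 43))
  cl <- classify_deaths(st$deaths)
  pr <- redistribution_probs(cl)
  d5 <- redistribute_deaths(cl, pr, M = 5, seed = 7)
  d3 <- redistribute_deaths(cl, pr, M = 3, seed = 7)
  expect_equal(d5[d5$draw == 3, ], d3[d3$draw == 3, ], ignore_attr = TRUE)
  other <- redistribute_deaths(cl, pr, M = 3, seed = 8)
  expect_false(identical(d3$n_deaths, other$n_deaths))
})

test_that("raising the observed motorcyclist share raises expected allocation", {
  make <- function(moto) {
    tibble::tibble(
      city_id = "A-001", country_id = "A", year = 2010L, sex = "M",
      age_group = "20-24",
      cause_class = c("specific_motorcyclist", "pedestrian",
                      "partially_defined_rt"),
      n_deaths = c(moto, 50L - moto, 30L)
    )
  }
  mean_added <- vapply(c(10L, 25L, 40L), function(m) {
    d <- make(m)
    dr <- redistribute_deaths(d, redistribution_probs(d), M = 400, seed = 5)
    mean(dr$n_deaths - m)
  }, 0)
  expect_true(all(diff(mean_added) > 0))
})

test_that("missing probabilities for a garbage stratum are a hard error", {
  d <- fx_one_stratum_deaths(partial = 5L)
  pr <- redistribution_probs(d)
  pr2 <- pr[0, ]
  class(pr2) <- class(pr)
  attr(pr2, "years_all") <- attr(pr, "years_all")
  attr(pr2, "pooling_years") <- attr(pr, "pooling_years")
  expect_error(redistribute_deaths(d, pr2, M = 2, seed = 1),
               "missing redistribution probabilities")
})

test_that("single-stage mode keeps all ill-defined deaths in road traffic", {
  d <- fx_one_stratum_deaths(partial = 0L, ill = 10L, non_rt = 30L)
  pr <- redistribution_probs(d)
  dr2 <- redistribute_deaths(d, pr, M = 200, seed = 9, two_stage = FALSE)
  s2 <- attr(dr2, "draw_summary")
  expect_true(all(s2$allocated_non_rt == 0))
  dr1 <- redistribute_deaths(d, pr, M = 200, seed = 9, two_stage = TRUE)
  s1 <- attr(dr1, "draw_summary")
  expect_gt(sum(s1$allocated_non_rt), 0)
})

test_that("pooling periods use 3-year blocks with a short tail merged", {
  y <- 2010:2019
  p <- motomort:::pooling_period(y, y)
  expect_equal(p, c(0, 0, 0, 1, 1, 1, 2, 2, 2, 2))
})
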