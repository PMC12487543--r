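#' Run the full analysis pipeline on a study
#'
#' End to end: classify causes, build redistribution probabilities,
#' draw `M` multinomial redistributions, build corrected person-years,
#' compute draw-averaged crude and age-standardized rates, fit and pool the
#' regression models, and compute the descriptive surfaces.
#'
#' @param study A `motomort_study` (from [sim_study()]) or a list with
#'   `deaths`, `population`, `correction_factors`, `exposures`.
#' @param M Number of redistribution draws.
#' @param seed Seed for the redistribution substreams.
#' @param models Character subset of `c("model1", "model2", "sub",
#'   "sensitivity")`.
#' @param street_subsets Subsets for the sensitivity analysis (default:
#'   each street-layout variable alone).
#' @param nodes Quadrature nodes for the mixed-model fits.
#' @param variance Variance mode passed to the fits.
#' @param quorum Minimum converged fraction of draws.
#' @return A list of class `motomort_results`: `crude_rate`, `city_rates`,
#'   `rate_summary`, `pooled` (all models bound together), `quartiles`,
#'   `correlations`, `icc`, `profiles`, `draws_summary`, `M`.
#' @export
run_pipeline <- function(study, M = 100L, seed = 1L,
                         models = c("model1", "model2"),
                         street_subsets = NULL,
                         nodes = 15L, variance = "cluster-robust",
                         quorum = 0.9) {
  classified <- classify_deaths(study$deaths)
  probs <- redistribution_probs(classified)
  draws <- redistribute_deaths(classified, probs, M = M, seed = seed)
  py <- build_person_years(study$population, study$correction_factors)

  counts_avg <- dplyr::summarise(
    dplyr::group_by(draws, .data$city_id, .data$sex, .data$age_group),
    n_deaths = sum(.data$n_deaths) / M, .groups = "drop"
  )
  total_deaths <- sum(counts_avg$n_deaths)
  total_py <- sum(py$person_years)
  crude <- crude_rate(total_deaths, total_py)

  city_rates <- city_standardized_rates(counts_avg, py)
  cc <- dplyr::distinct(study$exposures, .data$city_id, .data$country_id)
  city_rates <- dplyr::left_join(city_rates, cc, by = "city_id")
  rate_summary <- summarize_rates(city_rates)

  exposures_z <- standardize_exposures(study$exposures)
  pooled <- list()
  if ("model1" %in% models) {
    pooled$m1 <- run_model1(py, exposures_z, draws, nodes = nodes,
                            variance = variance, quorum = quorum)
  }
  if ("model2" %in% models) {
    pooled$m2 <- run_model2(py, exposures_z, draws, nodes = nodes,
                            variance = variance, quorum = quorum)
  }
  if ("sub" %in% models) {
    pooled$sub <- run_subanalysis(py, study$exposures, draws, nodes = nodes,
                                  variance = variance, quorum = quorum)
  }
  if ("sensitivity" %in% models) {
    if (is.null(street_subsets)) {
      street_subsets <- list("street_length_avg", "intersection_density",
                             "street_node_avg", "circuity")
    }
    pooled$sens <- run_sensitivity(py, exposures_z, draws,
                                   street_subsets = street_subsets,
                                   nodes = nodes, variance = variance,
                                   quorum = quorum)
  }
  pooled_all <- dplyr::bind_rows(pooled)
  class(pooled_all) <- c("motomort_pooled", class(pooled_all))

  both <- city_rates[city_rates$sex == "both", ]
  quart <- tryCatch(quartile_table(both, study$exposures),
                    error = function(e) NULL)
  corr <- exposure_correlations(study$exposures)
  icc <- tryCatch(within_country_icc(both), error = function(e) NULL)
  profiles <- rate_profiles(counts_avg, py, city_rates)

  structure(list(
    crude_rate = crude, total_deaths = total_deaths, total_py = total_py,
    city_rates = city_rates, rate_summary = rate_summary,
    pooled = pooled_all, quartiles = quart, correlations = corr,
    icc = icc, profiles = profiles,
    draws_summary = attr(draws, "draw_summary"), M = M
  ), class = "motomort_results")
}

#' @export
print.motomort_results <- function(x, ...) {
  cat("<motomort_results>\n")
  cat(sprintf("  crude rate: %.2f per 100,000 (%d deaths / %.3g PY)\n",
              x$crude_rate, round(x$total_deaths), x$total_py))
  if (!is.null(x$icc)) {
    cat(sprintf("  within-country ICC of log standardized rates: %.2f\n",
                x$icc$icc))
  }
  if (nrow(x$pooled)) print(x$pooled)
  invisible(x)
}

#' Write all pipeline result files
#'
#' Emits `rates.csv`, `results_model1.csv`, `results_model2.csv`,
#' `results_sub.csv`, `results_sensitivity.csv` (as applicable),
#' `descriptives.csv`, `correlations.csv` and `icc.json`. Identical
#' pipelines produce byte-identical files.
#'
#' @param results A `motomort_results`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(results$city_rates, file.path(dir, "rates.csv"))
  readr::write_csv(results$rate_summary, file.path(dir, "rate_summary.csv"))
  p <- results$pooled
  tags <- list(
    results_model1.csv = grepl("^M1:", p$model),
    results_model2.csv = p$model == "M2",
    results_sub.csv = grepl("-sub", p$model),
    results_sensitivity.csv = grepl("^sensitivity:", p$model)
  )
  for (f in names(tags)) {
    if (any(tags[[f]])) {
      readr::write_csv(p[tags[[f]], , drop = FALSE], file.path(dir, f))
    }
  }
  if (!is.null(results$quartiles)) {
    readr::write_csv(results$quartiles, file.path(dir, "descriptives.csv"))
  }
  readr::write_csv(results$correlations$bands,
                   file.path(dir, "correlations.csv"))
  if (!is.null(results$icc)) {
    jsonlite::write_json(results$icc, file.path(dir, "icc.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
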