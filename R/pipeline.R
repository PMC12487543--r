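#' Standardize city-level exposures
#'
#' Z-scores each exposure over the analysis city set (sample SD, n-1
#' denominator); binary indicators (`transit`) are left as 0/1. Means and
#' SDs are attached so per-SD rate ratios can be mapped back to natural
#' units.
#'
#' @param raw Exposure tibble (one row per city).
#' @param vars Columns to standardize (default the 11 exposures).
#' @param binary Columns left untouched.
#' @return Tibble with the same columns, standardized; attributes `center`
#'   and `scale`.
#' @export
standardize_exposures <- function(raw, vars = exposure_names(),
                                  binary = "transit") {
  stopifnot(nrow(raw) >= 2)
  out <- raw
  center <- scale_ <- setNames(numeric(0), character(0))
  for (v in setdiff(vars, binary)) {
    x <- raw[[v]]
    m <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero-variance exposure: ", v)
    out[[v]] <- (x - m) / s
    center[v] <- m
    scale_[v] <- s
  }
  attr(out, "center") <- center
  attr(out, "scale") <- scale_
  out
}

#' Rubin's rule for pooling across redistribution draws
#'
#' Pooled estimate `Qbar` is the mean of the per-draw estimates; total
#' variance `T = W + (1 + 1/M) B` combines the mean within-draw variance
#' `W` and the between-draw variance `B` (sample variance of estimates);
#' degrees of freedom `(M-1) (1 + W / ((1+1/M) B))^2`, infinite when
#' `B = 0`.
#'
#' @param estimates Numeric vector of per-draw estimates.
#' @param variances Numeric vector of per-draw variances (same length).
#' @return List with `qbar`, `W`, `B`, `T`, `df`, `M`.
#' @export
#' @examples
#' rubins_rule(c(0.4, 0.6), c(0.04, 0.04)) # T = 0.07
rubins_rule <- function(estimates, variances) {
  if (length(estimates) != length(variances)) {
    stop("estimates and variances must have equal length")
  }
  bad <- which(!is.finite(estimates) | !is.finite(variances))
  if (length(bad)) {
    stop("non-finite inputs at draw(s): ", paste(bad, collapse = ", "))
  }
  if (any(variances < 0)) stop("negative variances")
  M <- length(estimates)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- if (M > 1) var(estimates) else 0
  Tt <- W + (1 + 1 / M) * B
  df <- if (B > 0 && M > 1) {
    (M - 1) * (1 + W / ((1 + 1 / M) * B))^2
  } else {
    Inf
  }
  list(qbar = qbar, W = W, B = B, T = Tt, df = df, M = M)
}

# pooled row for one term
pool_term <- function(term, estimates, variances, model, n_used, M,
                      conf.level = 0.95) {
  r <- rubins_rule(estimates, variances)
  tq <- if (is.finite(r$df)) qt(1 - (1 - conf.level) / 2, r$df) else {
    qnorm(1 - (1 - conf.level) / 2)
  }
  half <- tq * sqrt(r$T)
  tibble::tibble(
    model = model, term = term,
    rr = exp(r$qbar),
    ci_low = exp(r$qbar - half), ci_high = exp(r$qbar + half),
    qbar = r$qbar, W = r$W, B = r$B, T = r$T, df = r$df,
    n_draws_used = n_used, M = M
  )
}

# model data: person-years grid joined with country and standardized
# exposures; counts filled per draw
model_base_data <- function(py, exposures_z) {
  base <- dplyr::left_join(
    py, exposures_z,
    by = "city_id"
  )
  if (anyNA(base$country_id)) {
    stop("exposures missing for cities: ",
         paste(unique(base$city_id[is.na(base$country_id)]), collapse = ", "))
  }
  base$n_deaths <- 0
  base
}

#' Fit the NB mixed model on every redistribution draw and pool
#'
#' Shares one design matrix across draws (denominators and covariates are
#' draw-invariant), warm-starts each fit at the previous draw's optimum,
#' and pools each requested term's log-RR and robust variance by Rubin's
#' rule. Fails if fewer than `quorum` of the draws converge; otherwise
#' pools over converged draws and records the count.
#'
#' @param base Stratum data from `model_base_data()` (or any tibble
#'   accepted by [nb_model_frame()]).
#' @param draws A [redistribute_deaths()] result.
#' @param exposure_terms Exposure columns entering the fixed effects.
#' @param report_terms Terms to pool and report (default `exposure_terms`).
#' @param model Model tag stored in the output.
#' @param nodes,variance,quorum,conf.level Tuning: quadrature nodes,
#'   variance mode, minimum converged fraction, CI level.
#' @param start Optional warm-start list (`beta`, `alpha`, `sigma`) for the
#'   first draw's fit; subsequent draws warm-start at the previous draw's
#'   optimum. The last converged optimum is attached as attribute
#'   `last_start`.
#' @return A `motomort_pooled` tibble, one row per reported term.
#' @export
fit_pooled <- function(base, draws, exposure_terms,
                       report_terms = exposure_terms,
                       model = "M", nodes = 15L,
                       variance = "cluster-robust",
                       quorum = 0.9, conf.level = 0.95,
                       start = NULL) {
  M <- attr(draws, "M")
  frame <- nb_model_frame(base, exposure_terms)
  draw_split <- split(
    draws[, c("city_id", "sex", "age_group", "n_deaths")], draws$draw
  )
  est <- matrix(NA_real_, M, length(report_terms),
                dimnames = list(NULL, report_terms))
  vva <- est
  conv <- logical(M)
  for (d in seq_len(M)) {
    dd <- draw_split[[as.character(d)]]
    key_d <- paste(dd$city_id, dd$sex, dd$age_group, sep = "\r")
    y <- dd$n_deaths[match(frame$key, key_d)]
    y[is.na(y)] <- 0
    frame$y <- as.numeric(y)
    fit <- nb_fit_frame(frame, nodes = nodes, variance = variance,
                        start = start)
    conv[d] <- fit$convergence$converged
    if (conv[d]) {
      start <- list(beta = unname(fit$beta), alpha = fit$alpha,
                    sigma = max(fit$sigma, 1e-3))
    }
    v <- if (variance == "cluster-robust") fit$vcov_robust else fit$vcov_model
    est[d, ] <- fit$beta[report_terms]
    vva[d, ] <- diag(v)[report_terms]
  }
  n_conv <- sum(conv)
  if (n_conv < ceiling(quorum * M)) {
    stop("only ", n_conv, " of ", M, " draws converged (quorum ",
         quorum * 100, "%)")
  }
  use <- conv
  out <- dplyr::bind_rows(lapply(report_terms, function(tm) {
    pool_term(tm, est[use, tm], vva[use, tm], model, n_conv, M, conf.level)
  }))
  class(out) <- c("motomort_pooled", class(out))
  attr(out, "last_start") <- start
  out
}

#' Model 1: one exposure at a time
#'
#' For each exposure, fits the NB city random-intercept model adjusted for
#' country, sex and age group on every draw, and pools by Rubin's rule.
#'
#' @param py Person-years from [build_person_years()].
#' @param exposures_z Standardized exposures ([standardize_exposures()]).
#' @param draws Redistribution draws.
#' @param exposures Exposure names to evaluate (default all 11).
#' @param ... Passed to [fit_pooled()].
#' @return `motomort_pooled` tibble with tags `M1:<exposure>`.
#' @export
run_model1 <- function(py, exposures_z, draws,
                       exposures = exposure_names(), ...) {
  base <- model_base_data(py, exposures_z)
  out <- dplyr::bind_rows(lapply(exposures, function(v) {
    fit_pooled(base, draws, exposure_terms = v,
               model = paste0("M1:", v), ...)
  }))
  class(out) <- c("motomort_pooled", class(out))
  out
}

#' Model 2: all exposures simultaneously
#'
#' Multivariable version of Model 1; collinearity diagnostics (condition
#' number of the standardized exposure block and variance inflation
#' factors) are attached as attribute `collinearity`.
#'
#' @inheritParams run_model1
#' @return `motomort_pooled` tibble with tag `M2`.
#' @export
run_model2 <- function(py, exposures_z, draws,
                       exposures = exposure_names(), ...) {
  base <- model_base_data(py, exposures_z)
  Z <- as.matrix(exposures_z[, exposures])
  R <- stats::cor(Z)
  diag_inv <- tryCatch(diag(solve(R)), error = function(e) rep(NA_real_,
                                                               ncol(R)))
  coll <- list(
    condition_number = kappa(R, exact = TRUE),
    vif = setNames(diag_inv, exposures)
  )
  out <- fit_pooled(base, draws, exposure_terms = exposures,
                    model = "M2", ...)
  attr(out, "collinearity") <- coll
  out
}

#' Registration subanalysis
#'
#' Restricts the analysis to cities with motorcycle registration data,
#' restandardizes all exposures (including the motorization rate) on that
#' subset, and reruns Model 1 (motorization rate only, plus optionally each
#' exposure) and Model 2 with the motorization rate added.
#'
#' @param py Person-years.
#' @param exposures Raw (unstandardized) exposure tibble with
#'   `moto_per_1000`.
#' @param draws Redistribution draws.
#' @param min_cities Refuse below this many cities with registrations.
#' @param ... Passed to [fit_pooled()].
#' @return `motomort_pooled` tibble with tags `M1-sub:moto_per_1000` and
#'   `M2-sub`.
#' @export
run_subanalysis <- function(py, exposures, draws, min_cities = 10, ...) {
  if (!"moto_per_1000" %in% names(exposures) ||
      all(is.na(exposures$moto_per_1000))) {
    stop("no motorcycle registration data available for any city")
  }
  sub <- exposures[!is.na(exposures$moto_per_1000), , drop = FALSE]
  if (nrow(sub) < min_cities) {
    stop("registration subanalysis refused: only ", nrow(sub),
         " cities with registration data (need >= ", min_cities, ")")
  }
  sub_z <- standardize_exposures(
    sub, vars = exposure_names(include_moto = TRUE)
  )
  keep <- py$city_id %in% sub$city_id
  py_sub <- py[keep, , drop = FALSE]
  draws_sub <- draws[draws$city_id %in% sub$city_id, , drop = FALSE]
  attr(draws_sub, "M") <- attr(draws, "M")
  base <- model_base_data(py_sub, sub_z)
  m1 <- fit_pooled(base, draws_sub, exposure_terms = "moto_per_1000",
                   model = "M1-sub:moto_per_1000", ...)
  m2 <- fit_pooled(base, draws_sub,
                   exposure_terms = exposure_names(include_moto = TRUE),
                   model = "M2-sub", ...)
  out <- dplyr::bind_rows(m1, m2)
  class(out) <- c("motomort_pooled", class(out))
  out
}

#' Street-layout sensitivity analysis
#'
#' Reruns Model 2 with only a subset of the four street-layout variables
#' (street length average, intersection density, street node average,
#' circuity), keeping all non-street exposures.
#'
#' @param py,exposures_z,draws As in [run_model2()].
#' @param street_subsets List of character vectors, each a subset of the
#'   street-layout variables.
#' @param ... Passed to [fit_pooled()].
#' @return `motomort_pooled` tibble, tags `sensitivity:<vars>`.
#' @export
run_sensitivity <- function(py, exposures_z, draws,
                            street_subsets = list(), ...) {
  street <- c("street_length_avg", "intersection_density",
              "street_node_avg", "circuity")
  if (!length(street_subsets)) {
    message("empty street subset list; nothing to do")
    return(invisible(tibble::tibble()))
  }
  base <- model_base_data(py, exposures_z)
  other <- setdiff(exposure_names(), street)
  out <- dplyr::bind_rows(lapply(street_subsets, function(ss) {
    bad <- setdiff(ss, street)
    if (length(bad)) {
      stop("not street-layout variables: ", paste(bad, collapse = ", "))
    }
    fit_pooled(base, draws, exposure_terms = c(other, ss),
               model = paste0("sensitivity:", paste(sort(ss),
                                                    collapse = "+")), ...)
  }))
  class(out) <- c("motomort_pooled", class(out))
  out
}

#' @export
print.motomort_pooled <- function(x, ...) {
  cat("<motomort_pooled> rate ratios per 1 SD (Rubin-pooled over",
      max(x$M), "draws)\n")
  df <- as.data.frame(x[, c("model", "term", "rr", "ci_low", "ci_high")])
  df$rr <- sprintf("%.3f", df$rr)
  df$ci <- sprintf("(%.3f, %.3f)", x$ci_low, x$ci_high)
  print(df[, c("model", "term", "rr", "ci")], row.names = FALSE)
  invisible(x)
}

#' Forest plot of pooled rate ratios
#'
#' @param object A `motomort_pooled` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.motomort_pooled <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$rr, y = .data$term, color = .data$model)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Rate ratio per 1 SD (95% CI, log scale)", y = NULL,
      title = "Motorcyclist mortality rate ratios"
    ) +
    ggplot2::theme_minimal()
}

#' Write pooled results to CSV
#'
#' @param pooled A `motomort_pooled` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pooled <- function(pooled, path) {
  readr::write_csv(pooled, path)
  invisible(path)
}
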