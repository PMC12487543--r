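# quartile membership by rank: sizes differ by at most 1, with any
# remainder going to the upper quartiles (337 -> 84/84/84/85); ties broken
# by order of appearance so membership is invariant under strictly
# monotone transforms of the ranking variable
quartile_assign <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  base <- n %/% 4L
  rem <- n %% 4L
  sizes <- base + as.integer(seq_len(4L) > 4L - rem)
  cut_points <- cumsum(sizes)
  findInterval(r, c(0, cut_points), left.open = TRUE, rightmost.closed = TRUE)
}

# rank-based inverse normal transform (Blom offsets)
inverse_normal <- function(x) {
  qnorm((rank(x, ties.method = "average") - 0.375) / (length(x) + 0.25))
}

# heteroskedasticity-robust joint Wald test that the quartile-indicator
# coefficients are zero in a regression of (transformed) exposure on
# quartile
wald_quartile_p <- function(x, quartile) {
  if (length(unique(x[!is.na(x)])) <= 1) {
    return(list(stat = 0, p = 1))
  }
  keep <- !is.na(x)
  xx <- x[keep]
  qq <- factor(quartile[keep])
  fit <- lm(xx ~ qq)
  V <- sandwich::vcovHC(fit, type = "HC1")
  idx <- grep("^qq", names(coef(fit)))
  b <- coef(fit)[idx]
  Vb <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(b) %*% solve(Vb, b)), error = function(e) NA_real_)
  if (!is.finite(stat)) return(list(stat = NA_real_, p = NA_real_))
  list(stat = stat, p = pchisq(stat, df = length(b), lower.tail = FALSE))
}

#' City characteristics by quartiles of standardized mortality
#'
#' Splits cities into quartiles of the age-standardized motorcyclist
#' mortality rate (sizes differing by at most 1, remainder to the top
#' quartile), reports each exposure's median (IQR) within quartile, and a
#' heteroskedasticity-robust Wald P value for differences across quartiles:
#' the exposure is rank-inverse-normal transformed (binary indicators are
#' left 0/1) and regressed on quartile indicators; the joint test that the
#' three quartile coefficients vanish gives the P value.
#'
#' @param city_rates Tibble with `city_id` and `rate_std` (both sexes,
#'   draw-averaged).
#' @param exposures Tibble with `city_id` and exposure columns.
#' @param vars Exposure columns to tabulate (default: the 11 exposures plus
#'   `moto_per_1000` when present).
#' @return A `motomort_quartiles` tibble: one row per exposure with
#'   per-quartile `median (IQR)` strings, plus `wald_p`. Attributes:
#'   `quartile_sizes`, `boundaries`.
#' @export
quartile_table <- function(city_rates, exposures, vars = NULL) {
  x <- dplyr::inner_join(city_rates, exposures, by = "city_id")
  n <- nrow(x)
  if (n < 8) stop("need at least 8 cities for quartiles (got ", n, ")")
  if (is.null(vars)) {
    vars <- intersect(exposure_names(include_moto = TRUE), names(exposures))
  }
  q <- quartile_assign(x$rate_std)
  sizes <- tabulate(q, 4L)
  bounds <- vapply(1:4, function(k) range(x$rate_std[q == k]),
                   numeric(2))
  binary <- vapply(vars, function(v) {
    all(x[[v]] %in% c(0, 1, NA))
  }, TRUE)

  rows <- lapply(vars, function(v) {
    cells <- vapply(1:4, function(k) {
      xi <- x[[v]][q == k]
      xi <- xi[!is.na(xi)]
      if (!length(xi)) return(NA_character_)
      if (binary[[v]]) {
        sprintf("%d (%.1f%%)", sum(xi), 100 * mean(xi))
      } else {
        qs <- quantile(xi, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
        sprintf("%.2f (%.2f to %.2f)", qs[1], qs[2], qs[3])
      }
    }, "")
    xv <- if (binary[[v]]) x[[v]] else inverse_normal(x[[v]])
    w <- wald_quartile_p(xv, q)
    tibble::tibble(
      exposure = v, q1 = cells[1], q2 = cells[2], q3 = cells[3],
      q4 = cells[4], wald_stat = w$stat, wald_p = w$p
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "quartile_sizes") <- sizes
  attr(out, "boundaries") <- bounds
  class(out) <- c("motomort_quartiles", class(out))
  out
}

#' Pairwise Pearson correlations of the exposures
#'
#' Pairwise-complete Pearson correlations with a banded summary at the
#' 0.3 / 0.6 cutpoints (weak / moderate / strong). Zero-variance columns
#' are reported as absent (`NA`), not zero.
#'
#' @param exposures Exposure tibble.
#' @param vars Columns to correlate (default: continuous exposures present).
#' @return List with `r` (matrix), `bands` (long tibble: var1, var2, r,
#'   band).
#' @export
exposure_correlations <- function(exposures,
                                  vars = NULL) {
  if (is.null(vars)) {
    vars <- intersect(setdiff(exposure_names(include_moto = TRUE), "transit"),
                      names(exposures))
  }
  X <- as.matrix(exposures[, vars])
  if (nrow(X) < 3) stop("need at least 3 cities for correlations")
  sds <- apply(X, 2, sd, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[idx]
  band <- ifelse(abs(rv) > 0.6, "strong",
                 ifelse(abs(rv) >= 0.3, "moderate", "weak"))
  bands <- tibble::tibble(
    var1 = vars[idx[, 1]], var2 = vars[idx[, 2]], r = rv, band = band
  )
  list(r = r, bands = bands)
}

#' Within-country intraclass correlation of city rates
#'
#' One-way random-effects ANOVA ICC of (by default log) city
#' age-standardized rates: the share of total variance attributable to
#' between-country differences, with variance components from the ANOVA
#' mean squares (unbalanced-design n0) and a negative between-component
#' truncated at zero.
#'
#' @param city_rates Tibble with `city_id`, `country_id`, `rate_std`.
#' @param log_scale Compute on log rates (default `TRUE`).
#' @return List with `icc`, `sigma2_between`, `sigma2_within`,
#'   `n_countries`, `n_cities`.
#' @export
within_country_icc <- function(city_rates, log_scale = TRUE) {
  x <- city_rates
  k <- length(unique(x$country_id))
  if (k < 2) stop("all cities in one country; ICC undefined")
  y <- if (log_scale) log(x$rate_std) else x$rate_std
  if (any(!is.finite(y))) {
    stop("non-finite (log) rates; cities with zero rates cannot enter the ",
         "log-scale ICC")
  }
  g <- factor(x$country_id)
  fit <- aov(y ~ g)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  ni <- tabulate(g)
  N <- sum(ni)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b <- max((msb - msw) / n0, 0)
  icc <- s2b / (s2b + msw)
  list(icc = icc, sigma2_between = s2b, sigma2_within = msw,
       n_countries = k, n_cities = N)
}

#' Rate profiles by sex and age
#'
#' City-level rate summaries by sex and age group (draw-averaged), pooled
#' and by country, with identification of the peak age group per sex (ties
#' reported as a set) and the male/female ratio of median standardized
#' rates.
#'
#' @param counts Draw-averaged motorcyclist death counts per
#'   (city_id, sex, age_group).
#' @param py Person-years.
#' @param city_rates City standardized rates by sex
#'   ([city_standardized_rates()]) including `country_id`.
#' @return List: `by_age` (pooled city-level quartiles of age-specific
#'   rates per sex/age), `peak` (per sex: age group(s) with highest median
#'   rate), `mf_ratio` (ratio of median male to median female standardized
#'   rate).
#' @export
rate_profiles <- function(counts, py, city_rates) {
  x <- dplyr::left_join(
    py, counts[, c("city_id", "sex", "age_group", "n_deaths")],
    by = c("city_id", "sex", "age_group")
  )
  x$n_deaths[is.na(x$n_deaths)] <- 0
  x$rate <- crude_rate(x$n_deaths, x$person_years)
  by_age <- dplyr::summarise(
    dplyr::group_by(x, .data$sex, .data$age_group),
    n_cities = dplyr::n(),
    median = median(.data$rate),
    q25 = quantile(.data$rate, 0.25, names = FALSE),
    q75 = quantile(.data$rate, 0.75, names = FALSE),
    .groups = "drop"
  )
  by_age$age_group <- factor(by_age$age_group, levels = age_group_labels())
  by_age <- dplyr::arrange(by_age, .data$sex, .data$age_group)
  peak <- lapply(split(by_age, by_age$sex), function(d) {
    mx <- max(d$median)
    if (mx == 0) return(as.character(d$age_group))
    as.character(d$age_group[d$median == mx])
  })
  med <- dplyr::summarise(
    dplyr::group_by(city_rates[city_rates$sex %in% c("M", "F"), ],
                    .data$sex),
    med = median(.data$rate_std), .groups = "drop"
  )
  mf <- med$med[med$sex == "M"] / med$med[med$sex == "F"]
  list(by_age = by_age, peak = peak, mf_ratio = mf)
}
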