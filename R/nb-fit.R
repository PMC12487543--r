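#' Build the model frame for the NB mixed model
#'
#' Assembles outcome, design matrix, log person-years offset and the city
#' cluster index from a stratum-level tibble. Fixed effects are country,
#' sex and age-group indicators plus any exposure columns given in
#' `exposure_terms`. Reference levels: first country alphabetically,
#' female, youngest age group. Strata with zero person-years are dropped
#' with a message (listed in the `dropped` element).
#'
#' @param data Tibble with `city_id`, `country_id`, `sex`, `age_group`,
#'   `n_deaths`, `person_years`, and any exposure columns.
#' @param exposure_terms Character vector of exposure column names to
#'   include (already standardized where applicable).
#' @return List with `y`, `X`, `offset`, `city` (factor), `city_start`,
#'   `city_len` (0-based contiguous blocks), `dropped`.
#' @export
nb_model_frame <- function(data, exposure_terms = character()) {
  need <- c("city_id", "country_id", "sex", "age_group", "n_deaths",
            "person_years", exposure_terms)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  drop <- data$person_years <= 0 | !is.finite(data$person_years)
  dropped <- data[drop, c("city_id", "sex", "age_group"), drop = FALSE]
  if (nrow(dropped)) {
    message("dropping ", nrow(dropped), " strata with zero person-years")
    data <- data[!drop, , drop = FALSE]
  }
  data <- dplyr::arrange(data, .data$city_id, .data$sex, .data$age_group)
  data$country_id <- factor(data$country_id)
  data$sex <- factor(data$sex, levels = .sexes[.sexes %in% data$sex])
  ages <- age_group_labels()
  data$age_group <- factor(data$age_group,
                           levels = ages[ages %in% data$age_group])
  terms <- c(
    if (nlevels(data$country_id) > 1) "country_id",
    if (nlevels(data$sex) > 1) "sex",
    if (nlevels(data$age_group) > 1) "age_group",
    sprintf("`%s`", exposure_terms)
  )
  fml <- stats::reformulate(if (length(terms)) terms else "1")
  X <- model.matrix(fml, data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  city <- factor(data$city_id)
  rle_c <- rle(as.integer(city))
  city_len <- rle_c$lengths
  city_start <- cumsum(c(0L, city_len[-length(city_len)]))
  list(
    y = as.numeric(data$n_deaths),
    X = X,
    offset = log(data$person_years),
    key = paste(data$city_id, data$sex, data$age_group, sep = "\r"),
    city = city,
    city_ids = levels(city),
    city_start = as.integer(city_start),
    city_len = as.integer(city_len),
    dropped = dropped
  )
}

#' Marginal log-likelihood of the NB2 random-intercept model
#'
#' For each city, the NB2 likelihood of its strata is integrated over the
#' Gaussian city intercept by adaptive Gauss-Hermite quadrature centered
#' and scaled at the empirical-Bayes mode (default 15 nodes). With
#' `sigma = 0` the integral collapses and the function returns the sum of
#' NB2 log-pmfs exactly.
#'
#' @param frame A [nb_model_frame()].
#' @param beta Coefficient vector (length `ncol(frame$X)`).
#' @param alpha NB2 dispersion (>= 0; variance = mu + alpha mu^2).
#' @param sigma SD of the city random intercept (>= 0).
#' @param nodes Number of quadrature nodes.
#' @return Scalar log-likelihood.
#' @export
nb_marginal_loglik <- function(frame, beta, alpha, sigma, nodes = 15L) {
  stopifnot(length(beta) == ncol(frame$X), alpha >= 0, sigma >= 0)
  gh <- statmod::gauss.quad(nodes, kind = "hermite")
  res <- nbagq_core(
    frame$y, frame$X, frame$offset, frame$city_start, frame$city_len,
    as.numeric(beta), log(max(alpha, 1e-300)),
    if (sigma > 0) log(sigma) else 0,
    gh$nodes, gh$weights, numeric(0),
    FALSE, FALSE, FALSE, sigma == 0
  )
  if (!is.finite(res$loglik)) {
    bad <- which(!is.finite(res$b_hat))
    stop("non-finite marginal likelihood",
         if (length(bad)) paste0(" (city ", frame$city_ids[bad[1]], ")"))
  }
  res$loglik
}

# starting values from a fixed-effects NB fit (MASS::glm.nb), with a
# Poisson + moment-dispersion fallback
nb_start_values <- function(frame) {
  start <- tryCatch({
    fit0 <- suppressWarnings(MASS::glm.nb(
      frame$y ~ frame$X - 1 + offset(frame$offset),
      control = stats::glm.control(maxit = 50)
    ))
    list(beta = unname(coef(fit0)), alpha = 1 / fit0$theta)
  }, error = function(e) NULL)
  if (is.null(start)) {
    fit0 <- suppressWarnings(stats::glm.fit(
      frame$X, frame$y, offset = frame$offset,
      family = stats::poisson()
    ))
    mu <- pmax(fit0$fitted.values, 1e-10)
    alpha0 <- max((sum((frame$y - mu)^2 / mu) - length(frame$y)) / sum(mu),
                  1e-3)
    start <- list(beta = unname(fit0$coefficients), alpha = alpha0)
  }
  start$alpha <- min(max(start$alpha, 1e-3), 50)
  start
}

#' Fit the negative binomial city random-intercept model
#'
#' Maximizes the adaptive Gauss-Hermite marginal likelihood over
#' (beta, log alpha, log sigma) with L-BFGS-B, starting from a
#' fixed-effects NB fit. The fit is deterministic given the data. Both the
#' model-based variance (inverse observed information) and the city-level
#' cluster-robust sandwich variance (with finite-cluster correction
#' g/(g-1)) are computed; `variance` selects which one `vcov()` and
#' `tidy()` report.
#'
#' @param data Stratum-level tibble (see [nb_model_frame()]).
#' @param exposure_terms Exposure columns to include as fixed effects.
#' @param nodes Quadrature nodes (default 15).
#' @param variance `"cluster-robust"` (default) or `"model-based"`.
#' @param sigma_fixed If `0`, the random intercept is removed and a plain
#'   fixed-effects NB2 model is fitted by the same code path.
#' @param start Optional list with `beta`, `alpha`, `sigma` starting
#'   values (used for warm starts across redistribution draws).
#' @param control List: `maxit` (default 500), `factr`, `grad_tol`
#'   (declared-convergence threshold on the max absolute scaled gradient).
#' @return Object of class `nb_mixed_fit`.
#' @export
nb_mixed_fit <- function(data, exposure_terms = character(), nodes = 15L,
                         variance = c("cluster-robust", "model-based"),
                         sigma_fixed = NULL, start = NULL,
                         control = list()) {
  variance <- match.arg(variance)
  frame <- nb_model_frame(data, exposure_terms)
  fit <- nb_fit_frame(frame, nodes = nodes, variance = variance,
                      sigma_fixed = sigma_fixed, start = start,
                      control = control)
  fit$exposure_terms <- exposure_terms
  fit
}

# core fitter on a prepared frame (reused by the pipeline for warm starts).
# Strategy: quasi-Newton (L-BFGS-B) from the fixed-effects NB start, then
# Newton refinement using the analytic observed information; warm starts
# (redistribution draws 2..M) go straight to Newton with an L-BFGS-B
# fallback.
nb_fit_frame <- function(frame, nodes = 15L,
                         variance = "cluster-robust",
                         sigma_fixed = NULL, start = NULL,
                         control = list()) {
  g <- length(frame$city_len)
  if (is.null(sigma_fixed) && g < 2) {
    stop("need at least 2 cities to fit a city random intercept")
  }
  if (var(frame$y) == 0) stop("outcome is degenerate (constant)")
  ctrl <- utils::modifyList(
    list(maxit = 500L, factr = 1e8, grad_tol = 1e-3, newton_tol = 1e-7),
    control
  )
  sigma_zero <- !is.null(sigma_fixed) && sigma_fixed == 0
  p <- ncol(frame$X)
  gh <- statmod::gauss.quad(nodes, kind = "hermite")

  warm <- !is.null(start)
  if (is.null(start)) start <- nb_start_values(frame)
  theta0 <- c(start$beta, log(start$alpha),
              if (!sigma_zero) log(if (is.null(start$sigma)) 0.2
                                   else max(start$sigma, 1e-4)))

  nq <- p + 1 + !sigma_zero
  lower <- c(rep(-Inf, p), log(1e-8), if (!sigma_zero) log(1e-6))
  upper <- c(rep(Inf, p), log(100), if (!sigma_zero) log(5))

  env <- new.env()
  env$b <- numeric(0)
  env$last_theta <- NULL
  env$neval <- 0L
  evaluate <- function(theta, hess = FALSE) {
    if (!hess && identical(theta, env$last_theta)) return(env$last)
    if (hess && identical(theta, env$last_theta) &&
        !is.null(env$last$hessian)) return(env$last)
    lt <- if (sigma_zero) 0 else theta[p + 2]
    res <- nbagq_core(
      frame$y, frame$X, frame$offset, frame$city_start, frame$city_len,
      theta[1:p], theta[p + 1], lt,
      gh$nodes, gh$weights, env$b,
      TRUE, hess, hess, sigma_zero
    )
    env$b <- res$b_hat
    env$last_theta <- theta
    env$last <- res
    env$neval <- env$neval + 1L
    res
  }
  fn <- function(theta) {
    ll <- evaluate(theta)$loglik
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  gr <- function(theta) {
    gg <- -evaluate(theta)$grad
    if (sigma_zero) gg <- gg[1:(p + 1)]
    gg[!is.finite(gg)] <- 0
    gg
  }
  scaled_grad <- function(theta) {
    max(abs(gr(theta))) / max(1, abs(fn(theta)))
  }
  clip <- function(theta) pmin(pmax(theta, lower), upper)

  # damped Newton on the analytic observed information; returns NULL if it
  # cannot make progress (caller falls back to L-BFGS-B)
  newton <- function(theta, maxit = 40L) {
    for (it in seq_len(maxit)) {
      res <- evaluate(theta, hess = TRUE)
      if (!is.finite(res$loglik)) return(NULL)
      gg <- res$grad[1:nq]
      gg[!is.finite(gg)] <- 0
      tol <- ctrl$newton_tol * max(1, abs(res$loglik))
      if (max(abs(gg)) < tol) {
        return(list(par = theta, value = -res$loglik, iters = it))
      }
      A <- -res$hessian[1:nq, 1:nq, drop = FALSE]
      step <- NULL
      ridge <- 0
      for (try in 1:4) {
        ch <- tryCatch(chol(A + diag(ridge, nq)), error = function(e) NULL)
        if (!is.null(ch)) {
          step <- backsolve(ch, forwardsolve(t(ch), gg))
          break
        }
        ridge <- if (ridge == 0) 1e-6 * max(diag(A), 1) else ridge * 100
      }
      if (is.null(step) || !all(is.finite(step))) return(NULL)
      ll0 <- res$loglik
      t_ <- 1
      ok <- FALSE
      for (h in 1:15) {
        cand <- clip(theta + t_ * step)
        llc <- evaluate(cand)$loglik
        if (is.finite(llc) && llc >= ll0 - 1e-12 * max(1, abs(ll0))) {
          # accept non-decreasing step (equality allowed: we may be at
          # machine precision of the optimum)
          theta <- cand
          ok <- llc > ll0 || max(abs(step)) < 1e-8
          break
        }
        t_ <- t_ / 2
      }
      if (!ok && h == 15) return(NULL)
      if (ok && max(abs(t_ * step)) < 1e-10) {
        res <- evaluate(theta)
        return(list(par = theta, value = -res$loglik, iters = it))
      }
    }
    res <- evaluate(theta)
    gg <- gr(theta)
    if (max(abs(gg)) < 1e-4 * max(1, abs(res$loglik))) {
      return(list(par = theta, value = -res$loglik, iters = maxit))
    }
    NULL
  }

  run_lbfgs <- function(th0, maxit = ctrl$maxit) {
    optim(th0, fn, gr, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = maxit, factr = ctrl$factr))
  }

  restarted <- FALSE
  opt <- NULL
  if (warm) {
    nt <- newton(clip(theta0))
    if (!is.null(nt)) opt <- list(par = nt$par, value = nt$value,
                                  convergence = 0, counts = c(nt$iters, NA),
                                  message = "newton")
  }
  if (is.null(opt)) {
    o <- run_lbfgs(clip(theta0))
    nt <- newton(o$par, maxit = 20L)
    if (!is.null(nt) && nt$value <= o$value + 1e-10) {
      opt <- list(par = nt$par, value = nt$value, convergence = 0,
                  counts = c(unname(o$counts[1]) + nt$iters, NA),
                  message = "lbfgs+newton")
    } else {
      opt <- o
    }
  }
  gnorm <- scaled_grad(opt$par)
  if (opt$convergence != 0 || gnorm > ctrl$grad_tol) {
    # deterministic perturbed restart
    restarted <- TRUE
    o2 <- run_lbfgs(clip(opt$par + 0.01 * rep_len(c(1, -1),
                                                  length(opt$par))))
    nt <- newton(o2$par, maxit = 20L)
    if (!is.null(nt) && nt$value <= o2$value) {
      o2 <- list(par = nt$par, value = nt$value, convergence = 0,
                 counts = o2$counts, message = "restart+newton")
    }
    if (o2$value <= opt$value) opt <- o2
    gnorm <- scaled_grad(opt$par)
  }
  converged <- opt$convergence == 0 && gnorm <= ctrl$grad_tol

  theta <- opt$par
  beta <- theta[1:p]
  alpha <- exp(theta[p + 1])
  sigma <- if (sigma_zero) 0 else exp(theta[p + 2])

  final <- evaluate(theta, hess = TRUE)
  H <- final$hessian
  keep <- seq_len(nq)
  A <- -H[keep, keep, drop = FALSE]
  Ainv <- tryCatch(solve(A), error = function(e) {
    MASS::ginv(A)
  })
  Ainv <- (Ainv + t(Ainv)) / 2
  S <- final$scores[, keep, drop = FALSE]
  B <- crossprod(S) * g / max(g - 1, 1)
  V_rob <- Ainv %*% B %*% Ainv
  V_rob <- (V_rob + t(V_rob)) / 2

  nm <- c(colnames(frame$X), "log_alpha", if (!sigma_zero) "log_sigma")
  dimnames(Ainv) <- dimnames(V_rob) <- list(nm, nm)
  names(beta) <- colnames(frame$X)

  structure(list(
    beta = beta, alpha = alpha, sigma = sigma,
    loglik = -opt$value,
    vcov_model = Ainv, vcov_robust = V_rob,
    variance = variance,
    n_cities = g, n_strata = length(frame$y),
    nodes = nodes,
    convergence = list(converged = converged, code = opt$convergence,
                       iterations = unname(opt$counts[1]),
                       grad_norm = gnorm, restarted = restarted,
                       message = opt$message),
    b_hat = setNames(final$b_hat, frame$city_ids),
    dropped = frame$dropped,
    sigma_zero = sigma_zero
  ), class = "nb_mixed_fit")
}

#' Cluster-robust variance of a fitted NB mixed model
#'
#' City-level sandwich estimator on the marginal likelihood:
#' `A^{-1} B A^{-1}` with `A` the observed information and `B` the
#' finite-cluster-corrected (g/(g-1)) sum of per-city score outer
#' products. Stored on the fit at fit time; this accessor returns it.
#'
#' @param fit An `nb_mixed_fit`.
#' @return Symmetric PSD variance matrix for (beta, log alpha[, log sigma]).
#' @export
robust_vcov <- function(fit) {
  stopifnot(inherits(fit, "nb_mixed_fit"))
  if (fit$n_cities < 2) stop("cluster-robust variance needs >= 2 cities")
  fit$vcov_robust
}

#' @export
vcov.nb_mixed_fit <- function(object, ...) {
  if (object$variance == "cluster-robust") object$vcov_robust
  else object$vcov_model
}

#' @export
print.nb_mixed_fit <- function(x, ...) {
  cat("<nb_mixed_fit> NB2 city random-intercept model (AGQ", x$nodes,
      "nodes)\n")
  cat(sprintf("  strata: %d  cities: %d  logLik: %.2f\n",
              x$n_strata, x$n_cities, x$loglik))
  cat(sprintf("  alpha: %.4f  sigma_city: %.4f  converged: %s\n",
              x$alpha, x$sigma, x$convergence$converged))
  if (length(x$exposure_terms)) {
    v <- vcov(x)
    for (tm in x$exposure_terms) {
      nm <- if (tm %in% names(x$beta)) tm else sprintf("`%s`", tm)
      cat(sprintf("  %-22s RR/SD %.3f (robust SE of log RR %.3f)\n",
                  tm, exp(x$beta[[nm]]), sqrt(v[nm, nm])))
    }
  }
  invisible(x)
}

#' @export
tidy.nb_mixed_fit <- function(x, exponentiate = FALSE, conf.level = 0.95,
                              ...) {
  v <- vcov(x)
  terms <- names(x$beta)
  se <- sqrt(diag(v)[terms])
  est <- x$beta
  zq <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = terms, estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    conf.low = unname(est - zq * se), conf.high = unname(est + zq * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @export
glance.nb_mixed_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, alpha = x$alpha, sigma_city = x$sigma,
    nobs = x$n_strata, n_cities = x$n_cities,
    converged = x$convergence$converged,
    iterations = x$convergence$iterations
  )
}

#' Serialize a fitted model to JSON
#'
#' Writes coefficients, both variance matrices, dispersion and
#' random-intercept estimates, and convergence diagnostics.
#'
#' @param fit An `nb_mixed_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "nb_mixed_fit"))
  out <- list(
    coefficients = as.list(fit$beta),
    alpha = fit$alpha,
    sigma_city = fit$sigma,
    loglik = fit$loglik,
    vcov_model = fit$vcov_model,
    vcov_robust = fit$vcov_robust,
    n_strata = fit$n_strata,
    n_cities = fit$n_cities,
    nodes = fit$nodes,
    convergence = fit$convergence
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
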