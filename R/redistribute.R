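# calendar-year -> 3-year pooling period; a short trailing block is merged
# into the previous full block (e.g., 2010-12, 2013-15, 2016-18, 2019->2016-18)
pooling_period <- function(year, years_all, pooling_years = 3L) {
  y0 <- min(years_all)
  idx <- (year - y0) %/% pooling_years
  n_full <- length(unique(years_all)) %/% pooling_years
  if (n_full >= 1) idx <- pmin(idx, n_full - 1L)
  idx
}

# row-specific multinomial via sequential binomials; P is n x k matrix of
# probabilities (rows sum to 1)
rmultinom_vec <- function(counts, P) {
  n <- length(counts)
  k <- ncol(P)
  out <- matrix(0L, n, k, dimnames = list(NULL, colnames(P)))
  rem <- as.integer(counts)
  prem <- rep(1, n)
  for (j in seq_len(k - 1L)) {
    pj <- ifelse(prem > 0, pmin(1, pmax(0, P[, j] / prem)), 0)
    out[, j] <- rbinom(n, rem, pj)
    rem <- rem - out[, j]
    prem <- prem - P[, j]
  }
  out[, k] <- rem
  out
}

#' Redistribution probabilities with zero-cell backoff
#'
#' For every (country, sex, age group, 3-year period) stratum observed in
#' the classified death table, computes (a) the probability vector over the
#' five specific road-user groups, proportional to observed specific
#' road-traffic deaths, used to allocate partially defined road-traffic
#' deaths; and (b) the road-traffic share of non-garbage external deaths,
#' used to allocate ill-defined external deaths between road traffic and
#' other external causes.
#'
#' Strata with zero specific road-traffic deaths fall back along the ladder
#' (country, sex, age, period) -> (country, sex, age) -> (country, sex) ->
#' (country) -> all data; the rung used is recorded in `level`.
#'
#' @param deaths Classified death table from [classify_deaths()].
#' @param pooling_years Length of the pooling period in calendar years
#'   (default 3).
#' @return A tibble (class `redistribution_probs`) keyed by (country_id,
#'   sex, age_group, period) with columns `p_rt`, one `p_<group>` column per
#'   road-user group (summing to 1 within 1e-12), and `level`.
#' @export
redistribution_probs <- function(deaths, pooling_years = 3L) {
  stopifnot(pooling_years >= 1)
  groups <- road_user_groups()
  years_all <- sort(unique(deaths$year))
  deaths$period <- pooling_period(deaths$year, years_all, pooling_years)

  # collapse once to (country, sex, age, period, class); ladder margins are
  # built from this small table
  ckey <- paste(deaths$country_id, deaths$sex, deaths$age_group,
                deaths$period, deaths$cause_class, sep = "\r")
  cfirst <- !duplicated(ckey)
  cagg <- rowsum(as.numeric(deaths$n_deaths), ckey)
  deaths <- deaths[cfirst, c("country_id", "sex", "age_group", "period",
                             "cause_class")]
  deaths$n_deaths <- cagg[match(ckey[cfirst], rownames(cagg)), 1]

  is_spec <- deaths$cause_class %in% groups
  is_nonrt <- deaths$cause_class == "non_rt_external"
  is_partial <- deaths$cause_class == "partially_defined_rt"

  count_at <- function(keys, rows) {
    dplyr::summarise(
      dplyr::group_by(deaths[rows, , drop = FALSE],
                      dplyr::across(dplyr::all_of(keys)),
                      .data$cause_class),
      n = sum(.data$n_deaths), .groups = "drop"
    )
  }
  key_sets <- list(
    c("country_id", "sex", "age_group", "period"),
    c("country_id", "sex", "age_group"),
    c("country_id", "sex"),
    "country_id",
    character(0)
  )
  # specific road-user counts and external composition at each ladder rung
  spec_tabs <- lapply(key_sets, function(k) {
    tab <- count_at(k, is_spec)
    tidyr::pivot_wider(tab, names_from = "cause_class", values_from = "n",
                       values_fill = 0L)
  })
  ext_tabs <- lapply(key_sets, function(k) {
    dplyr::summarise(
      dplyr::group_by(deaths[is_spec | is_nonrt | is_partial, , drop = FALSE],
                      dplyr::across(dplyr::all_of(k))),
      n_rt = sum(.data$n_deaths[.data$cause_class != "non_rt_external"]),
      n_ext = sum(.data$n_deaths), .groups = "drop"
    )
  })

  strata <- dplyr::distinct(
    deaths, .data$country_id, .data$sex, .data$age_group, .data$period
  )
  out <- strata
  for (g in groups) out[[paste0("p_", g)]] <- NA_real_
  out$p_rt <- NA_real_
  out$level <- NA_character_
  level_names <- c("country-sex-age-period", "country-sex-age",
                   "country-sex", "country", "all")

  for (r in seq_along(key_sets)) {
    todo <- is.na(out$level)
    if (!any(todo)) break
    keys <- key_sets[[r]]
    st <- spec_tabs[[r]]
    for (g in groups) if (!g %in% names(st)) st[[g]] <- 0L
    if (length(keys)) {
      m <- dplyr::left_join(out[todo, keys, drop = FALSE], st, by = keys)
    } else {
      m <- st[rep(1, sum(todo)), , drop = FALSE]
    }
    tot <- rowSums(as.matrix(m[, groups]), na.rm = TRUE)
    ok <- !is.na(tot) & tot > 0
    if (any(ok)) {
      idx <- which(todo)[ok]
      for (g in groups) {
        out[[paste0("p_", g)]][idx] <- m[[g]][ok] / tot[ok]
      }
      out$level[idx] <- level_names[r]
    }
  }
  if (anyNA(out$level)) {
    stop("no specific road-traffic deaths anywhere; cannot build ",
         "redistribution probabilities")
  }

  # stage-1 road-traffic share of non-garbage external deaths, same ladder
  out$rt_level <- NA_character_
  for (r in seq_along(key_sets)) {
    todo <- is.na(out$rt_level)
    if (!any(todo)) break
    keys <- key_sets[[r]]
    et <- ext_tabs[[r]]
    if (length(keys)) {
      m <- dplyr::left_join(out[todo, keys, drop = FALSE], et, by = keys)
    } else {
      m <- et[rep(1, sum(todo)), , drop = FALSE]
    }
    ok <- !is.na(m$n_ext) & m$n_ext > 0
    if (any(ok)) {
      idx <- which(todo)[ok]
      out$p_rt[idx] <- m$n_rt[ok] / m$n_ext[ok]
      out$rt_level[idx] <- level_names[r]
    }
  }

  pcols <- paste0("p_", groups)
  stopifnot(all(abs(rowSums(as.matrix(out[, pcols])) - 1) < 1e-12))
  attr(out, "pooling_years") <- pooling_years
  attr(out, "years_all") <- years_all
  class(out) <- c("redistribution_probs", class(out))
  out
}

#' Multinomial redistribution of garbage-coded deaths
#'
#' Performs, for each of `M` draws, the two-stage stochastic reallocation:
#' (1) each stratum's ill-defined external deaths are split binomially
#' between road traffic and other external causes using the stratum's
#' observed external-cause composition (`p_rt`); (2) the partially defined
#' road-traffic pool (original plus stage-1 arrivals) is allocated
#' multinomially across the five specific road-user groups. Motorcyclist
#' counts are extracted per draw and pooled over the study period.
#'
#' Every draw conserves the garbage total exactly. Draw `d` is reproducible
#' in isolation: its RNG substream is derived from (`seed`, `d`) by a
#' counter hash, with strata processed in a fixed canonical order.
#'
#' @param deaths Classified death table from [classify_deaths()].
#' @param probs A [redistribution_probs()] table covering every stratum
#'   that contains garbage deaths.
#' @param M Number of redistribution draws (default 100).
#' @param seed Master seed for the redistribution substreams.
#' @param two_stage If `FALSE`, stage 1 is skipped and all ill-defined
#'   external deaths are assumed to be road traffic (`p_rt = 1`).
#' @return A tibble (class `motomort_draws`) with columns `draw`, `city_id`,
#'   `country_id`, `sex`, `age_group`, `n_deaths`: motorcyclist deaths per
#'   stratum pooled over all years, per draw. Attribute `draw_summary` holds
#'   per-draw totals (observed specific, allocated by group, garbage input,
#'   conservation checksum).
#' @export
redistribute_deaths <- function(deaths, probs, M = 100L, seed = 1L,
                                two_stage = TRUE) {
  stopifnot(M >= 1, inherits(probs, "redistribution_probs"))
  groups <- road_user_groups()
  pcols <- paste0("p_", groups)
  years_all <- attr(probs, "years_all")
  deaths$period <- pooling_period(deaths$year, years_all,
                                  attr(probs, "pooling_years"))

  # observed specific motorcyclist deaths pooled over the period
  obs_moto <- dplyr::summarise(
    dplyr::group_by(
      deaths[deaths$cause_class == "specific_motorcyclist", , drop = FALSE],
      .data$city_id, .data$country_id, .data$sex, .data$age_group
    ),
    n_obs = sum(.data$n_deaths), .groups = "drop"
  )

  # garbage pool per stratum-year
  g <- deaths[deaths$cause_class %in%
                c("partially_defined_rt", "ill_defined_external"), , drop = FALSE]
  g <- tidyr::pivot_wider(g, names_from = "cause_class",
                          values_from = "n_deaths", values_fill = 0L)
  for (cl in c("partially_defined_rt", "ill_defined_external")) {
    if (!cl %in% names(g)) g[[cl]] <- 0L
  }
  g <- dplyr::arrange(g, .data$city_id, .data$year, .data$sex, .data$age_group)
  g <- dplyr::left_join(
    g, probs[, c("country_id", "sex", "age_group", "period", "p_rt", pcols)],
    by = c("country_id", "sex", "age_group", "period")
  )
  if (nrow(g) && anyNA(g$p_specific_motorcyclist)) {
    miss <- g[is.na(g$p_specific_motorcyclist), ]
    stop("missing redistribution probabilities for ", nrow(miss),
         " strata with garbage deaths (first: ",
         paste(miss$country_id[1], miss$sex[1], miss$age_group[1],
               miss$period[1]), ")")
  }

  strat_key <- NULL
  if (nrow(g)) {
    strat_key <- factor(paste(g$city_id, g$sex, g$age_group, sep = "\r"))
  }
  Pm <- as.matrix(g[, pcols])
  n <- nrow(g)

  draws <- vector("list", M)
  summ <- vector("list", M)
  for (d in seq_len(M)) {
    if (n) {
      set.seed(hash_seed(seed, 303L, d))
      ill_rt <- if (two_stage) {
        rbinom(n, g$ill_defined_external, pmin(1, pmax(0, g$p_rt)))
      } else {
        g$ill_defined_external
      }
      pool <- g$partially_defined_rt + ill_rt
      alloc <- rmultinom_vec(pool, Pm)
      moto_add <- rowsum(alloc[, 1], strat_key)
      add_tab <- tibble::tibble(key = rownames(moto_add),
                                n_add = as.integer(moto_add))
      checksum <- sum(alloc) + sum(g$ill_defined_external) - sum(ill_rt) -
        sum(g$partially_defined_rt) - sum(g$ill_defined_external)
      summ[[d]] <- tibble::tibble(
        draw = d,
        garbage_in = sum(g$partially_defined_rt) + sum(g$ill_defined_external),
        allocated_rt = sum(alloc),
        allocated_non_rt = sum(g$ill_defined_external) - sum(ill_rt),
        allocated_moto = sum(alloc[, 1]),
        conservation_residual = checksum
      )
    } else {
      add_tab <- tibble::tibble(key = character(0), n_add = integer(0))
      summ[[d]] <- tibble::tibble(draw = d, garbage_in = 0L,
                                  allocated_rt = 0L, allocated_non_rt = 0L,
                                  allocated_moto = 0L,
                                  conservation_residual = 0)
    }
    dd <- obs_moto
    key <- paste(dd$city_id, dd$sex, dd$age_group, sep = "\r")
    dd$n_add <- add_tab$n_add[match(key, add_tab$key)]
    dd$n_add[is.na(dd$n_add)] <- 0L
    extra <- add_tab[!add_tab$key %in% key, , drop = FALSE]
    if (nrow(extra)) {
      parts <- strsplit(extra$key, "\r", fixed = TRUE)
      cc <- vapply(parts, `[`, "", 1)
      extra_tab <- tibble::tibble(
        city_id = cc,
        country_id = g$country_id[match(cc, g$city_id)],
        sex = vapply(parts, `[`, "", 2),
        age_group = vapply(parts, `[`, "", 3),
        n_obs = 0L, n_add = extra$n_add
      )
      dd <- dplyr::bind_rows(dd, extra_tab)
    }
    dd$draw <- d
    dd$n_deaths <- dd$n_obs + dd$n_add
    draws[[d]] <- dd[, c("draw", "city_id", "country_id", "sex",
                         "age_group", "n_deaths")]
  }
  out <- dplyr::bind_rows(draws)
  attr(out, "draw_summary") <- dplyr::bind_rows(summ)
  attr(out, "M") <- M
  class(out) <- c("motomort_draws", class(out))
  out
}

#' Write redistributed counts and the per-draw summary
#'
#' @param draws A [redistribute_deaths()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_draws <- function(draws, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(draws, file.path(dir, "redistributed_counts.csv"))
  jsonlite::write_json(
    attr(draws, "draw_summary"),
    file.path(dir, "draw_summary.json"),
    dataframe = "rows", digits = NA
  )
  invisible(dir)
}
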