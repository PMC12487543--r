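#' Five-year age group labels
#'
#' The 17 five-year age groups used throughout the package, from 0-4 up to
#' the open-ended 80+ group.
#'
#' @return Character vector of length 17, ordered youngest to oldest.
#' @export
#' @examples
#' age_group_labels()
age_group_labels <- function() {
  c(paste(seq(0, 75, by = 5), seq(4, 79, by = 5), sep = "-"), "80+")
}

# WHO world standard population 2000-2025 (percent weights per 5-year group,
# 0-4 ... 95-99, 100+). Top groups are collapsed into 80+ to match the
# 17-group scheme used here.
.who_std_full <- c(
  8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
  5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.44, 0.15, 0.04, 0.005
)

#' WHO world standard population weights
#'
#' The WHO 2000-2025 world standard population, collapsed to the package's
#' 17 age groups (weights for 80-84 and above are summed into 80+). Weights
#' are normalized to sum to 1 before use in direct standardization.
#'
#' @param normalize Logical; if `TRUE` (default) weights are rescaled to sum
#'   to exactly 1.
#' @return A tibble with columns `age_group` and `weight`.
#' @export
#' @examples
#' who_standard()
who_standard <- function(normalize = TRUE) {
  w <- c(.who_std_full[1:16], sum(.who_std_full[17:21]))
  if (normalize) w <- w / sum(w)
  tibble::tibble(age_group = age_group_labels(), weight = w)
}

#' Default country labels
#'
#' Seven synthetic country labels mirroring a Latin-American multi-country
#' study layout. Purely synthetic identifiers.
#'
#' @return Character vector of length 7.
#' @keywords internal
country_labels <- function(n = 7) {
  stopifnot(n >= 1)
  paste0("C", sprintf("%02d", seq_len(n)))
}

#' Names of the city-level exposure variables
#'
#' The 11 built/social-environment exposures consumed by the models, plus
#' (optionally) the motorization rate used in the registration subanalysis.
#'
#' @param include_moto Logical; append `moto_per_1000`.
#' @return Character vector.
#' @export
exposure_names <- function(include_moto = FALSE) {
  nm <- c(
    "mean_nn_distance",      # area-weighted mean nearest neighbor distance (m)
    "patch_density",         # built-up patches per km^2 (fragmentation)
    "circuity",              # average street circuity (>= 1)
    "street_length_avg",     # mean street segment length (m)
    "intersection_density",  # intersections per km^2 of built-up area
    "street_node_avg",       # mean streets radiating per node
    "population_density",    # inhabitants per km^2 (built-up)
    "transit",               # presence of BRT/rail mass transit (0/1)
    "travel_delay_index",    # urban congestion delay index
    "gdp_pc",                # GDP per capita (constant intl USD)
    "social_index"           # composite social environment index
  )
  if (include_moto) nm <- c(nm, "moto_per_1000")
  nm
}

# sex labels used everywhere
.sexes <- c("F", "M")

# deterministic 31-bit hash for deriving substream seeds from a master seed
# and one or more counters; keeps results < 2^31 so set.seed() accepts them.
hash_seed <- function(master, ...) {
  x <- as.double(master) %% 2147483647
  for (k in c(...)) {
    x <- (x * 2654435761 + as.double(k) * 40503 + 1013904223) %% 2147483647
  }
  as.integer(x)
}
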