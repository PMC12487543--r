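# expand "V20-V39" style ranges into 3-character prefixes
icd_range <- function(letter, from, to) {
  sprintf("%s%02d", letter, from:to)
}

#' Cause-class map for external-cause ICD-10 codes
#'
#' Defines the disjoint sets of 3-character ICD-10 prefixes used to classify
#' external-cause deaths into road-user groups, partially defined
#' road-traffic causes, ill-defined external causes and the remaining
#' non-road-traffic external causes. Motorcyclists are V20-V39 (two- and
#' three-wheeled motor vehicle occupants). The garbage-code sets default to
#' V87-V89 and V99 (partially defined road traffic) and X59, Y10-Y34
#' (ill-defined external) and are configurable.
#'
#' @param partially_defined Character vector of prefixes treated as
#'   partially defined road-traffic causes.
#' @param ill_defined Character vector of prefixes treated as ill-defined
#'   external causes.
#' @return An object of class `cause_map`: a named list of prefix sets.
#' @export
#' @examples
#' m <- cause_map()
#' classify_icd10(c("V23.4", "V89", "W10"), m)
cause_map <- function(partially_defined = c(icd_range("V", 87, 89), "V99"),
                      ill_defined = c("X59", icd_range("Y", 10, 34))) {
  m <- list(
    specific_motorcyclist = icd_range("V", 20, 39),
    pedestrian = icd_range("V", 1, 9),
    bicyclist = icd_range("V", 10, 19),
    car_occupant = icd_range("V", 40, 49),
    other_rt = setdiff(icd_range("V", 50, 86), partially_defined),
    partially_defined_rt = partially_defined,
    ill_defined_external = ill_defined
  )
  all_pref <- unlist(m, use.names = FALSE)
  if (anyDuplicated(all_pref)) {
    stop("cause_map prefix sets must be pairwise disjoint; duplicated: ",
         paste(unique(all_pref[duplicated(all_pref)]), collapse = ", "))
  }
  structure(m, class = "cause_map")
}

#' Specific road-user groups
#'
#' The five specifically defined road-user groups that partially defined
#' road-traffic deaths are redistributed across.
#'
#' @return Character vector.
#' @export
road_user_groups <- function() {
  c("specific_motorcyclist", "pedestrian", "bicyclist", "car_occupant",
    "other_rt")
}

#' Classify ICD-10 codes into cause classes
#'
#' Codes are matched on their 3-character prefix (a letter plus two digits);
#' 4-character codes such as "V23.4" or "V234" classify by prefix. Any
#' external-cause code (V01-Y98) not in a road-traffic or garbage set is
#' `non_rt_external`; codes outside the external-cause chapter return
#' `not_external`.
#'
#' @param code Character vector of ICD-10 codes.
#' @param map A [cause_map()].
#' @return Character vector of cause classes, same length as `code`.
#' @export
classify_icd10 <- function(code, map = cause_map()) {
  stopifnot(inherits(map, "cause_map"))
  orig <- code
  code <- toupper(trimws(code))
  ok <- grepl("^[A-Z][0-9]{2}(\\.?[0-9X]{0,2})?$", code)
  if (any(!ok)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(orig[!ok]), collapse = ", "))
  }
  prefix <- substr(code, 1, 3)
  out <- rep(NA_character_, length(code))
  for (cls in names(map)) {
    out[prefix %in% map[[cls]]] <- cls
  }
  letter <- substr(prefix, 1, 1)
  external <- letter %in% c("V", "W", "X", "Y")
  out[is.na(out) & external] <- "non_rt_external"
  out[is.na(out)] <- "not_external"
  out
}

#' Aggregate a long death table into cause-class counts
#'
#' @param deaths Tibble with columns `city_id`, `country_id`, `year`, `sex`,
#'   `age_group`, `icd10_code`, `n_deaths`.
#' @param map A [cause_map()].
#' @return Tibble keyed by (city_id, country_id, year, sex, age_group,
#'   cause_class) with integer `n_deaths`.
#' @export
classify_deaths <- function(deaths, map = cause_map()) {
  deaths$cause_class <- classify_icd10(deaths$icd10_code, map)
  key <- paste(deaths$city_id, deaths$country_id, deaths$year, deaths$sex,
               deaths$age_group, deaths$cause_class, sep = "\r")
  first <- !duplicated(key)
  agg <- rowsum(as.numeric(deaths$n_deaths), key)
  out <- deaths[first, c("city_id", "country_id", "year", "sex",
                         "age_group", "cause_class")]
  out$n_deaths <- as.integer(agg[match(key[first], rownames(agg)), 1])
  dplyr::arrange(tibble::as_tibble(out), .data$city_id, .data$year,
                 .data$sex, .data$age_group, .data$cause_class)
}
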