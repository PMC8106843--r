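#' Aggregate small-area counts to regions
#'
#' Sums Asian/Pacific Islander (API), White, and total population counts from
#' area units (e.g. ZIP code tabulation areas) up to regions (e.g. hospital
#' referral regions) through a unit-to-region crosswalk. This is the first
#' step in building region-level segregation profiles.
#'
#' @param units Data frame of area-unit counts with columns `unit_id`,
#'   `api_count`, `white_count`, `total_pop`, and optionally `period` (a
#'   census-period label such as `"census2000"`). Counts must be nonnegative
#'   and group counts may not exceed `total_pop`.
#' @param crosswalk Data frame with columns `unit_id`, `region_id` mapping
#'   every unit to exactly one region.
#' @return A tibble with one row per region (and per `period` when present):
#'   `region_id`, `n_units`, `api_total`, `white_total`, `pop_total`.
#' @examples
#' units <- tibble::tibble(
#'   unit_id = c("z1", "z2", "z3"),
#'   api_count = c(10, 40, 5), white_count = c(80, 50, 90),
#'   total_pop = c(100, 100, 100)
#' )
#' xw <- tibble::tibble(unit_id = c("z1", "z2", "z3"), region_id = c("A", "A", "B"))
#' aggregate_to_region(units, xw)
#' @export
aggregate_to_region <- function(units, crosswalk) {
  check_columns(units, c("unit_id", "api_count", "white_count", "total_pop"), "`units`")
  check_columns(crosswalk, c("unit_id", "region_id"), "`crosswalk`")
  if (nrow(units) == 0) {
    return(tibble::tibble(
      region_id = character(), n_units = integer(),
      api_total = numeric(), white_total = numeric(), pop_total = numeric()
    ))
  }
  validate_unit_counts(units)
  has_period <- "period" %in% names(units)
  key_cols <- if (has_period) c("period", "unit_id") else "unit_id"
  dup <- units |>
    dplyr::count(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate unit_id in `units`: ", paste(dup$unit_id, collapse = ", ")))
  }
  if (anyDuplicated(crosswalk$unit_id)) {
    abort("duplicate unit_id in `crosswalk`")
  }
  unmapped <- setdiff(unique(units$unit_id), crosswalk$unit_id)
  if (length(unmapped) > 0) {
    abort(paste0("unit_id missing from crosswalk: ", paste(unmapped, collapse = ", ")))
  }
  units |>
    dplyr::inner_join(crosswalk[c("unit_id", "region_id")], by = "unit_id") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(
      if (has_period) "period", "region_id"
    )))) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      api_total = sum(.data$api_count),
      white_total = sum(.data$white_count),
      pop_total = sum(.data$total_pop),
      .groups = "drop"
    )
}

validate_unit_counts <- function(units) {
  bad <- which(units$api_count < 0 | units$white_count < 0 | units$total_pop < 0)
  if (length(bad) > 0) {
    abort(paste0("negative counts in `units` at row(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  over <- which(units$api_count > units$total_pop | units$white_count > units$total_pop)
  if (length(over) > 0) {
    abort(paste0(
      "group count exceeds total_pop in `units` at row(s): ",
      paste(head(over, 5), collapse = ", ")
    ))
  }
  invisible(units)
}

#' API population density of a region
#'
#' Percentage of a region's residents who are API: `100 * A_T / P_T` where
#' `A_T` is the region API count and `P_T` the region population. Ranges 0-100;
#' 100 means the region consists only of API residents.
#'
#' @param api_total Region API count(s).
#' @param pop_total Region total population(s); must be positive.
#' @return Numeric vector of percentages in \[0, 100\].
#' @examples
#' api_density(25, 100)
#' @export
api_density <- function(api_total, pop_total) {
  if (any(pop_total <= 0)) abort("empty region: pop_total must be positive")
  100 * api_total / pop_total
}

#' API-White dissimilarity index
#'
#' Evenness measure `0.5 * sum_i |w_i/W_T - a_i/A_T|` over a region's area
#' units: the share of either group that would have to relocate for the two
#' groups to be identically distributed. 0 means identical distributions,
#' 1 absolute geographic separation.
#'
#' @param api_count Vector of per-unit API counts (`a_i`).
#' @param white_count Vector of per-unit White counts (`w_i`).
#' @return Dissimilarity index in \[0, 1\].
#' @examples
#' dissimilarity_index(api_count = c(20, 80), white_count = c(80, 20))
#' @export
dissimilarity_index <- function(api_count, white_count) {
  stopifnot(length(api_count) == length(white_count))
  a_t <- sum(api_count)
  w_t <- sum(white_count)
  if (a_t <= 0 || w_t <= 0) abort("index undefined for empty group")
  0.5 * sum(abs(white_count / w_t - api_count / a_t))
}

#' API isolation index
#'
#' Exposure measure `sum_i (a_i/A_T) * (a_i/P_i)`: the probability that a
#' randomly chosen API resident's random within-unit contact is also API.
#' Ranges 0-1; 1 means API residents only share units with other API
#' residents.
#'
#' The standard index uses the unit population `P_i` in the second factor.
#' `strict_printed_form = TRUE` substitutes the region population `P_T`, a
#' variant that appears in some published formula tables; note that variant
#' cannot reach 1 for multi-unit regions, so the default is the standard form.
#'
#' @param api_count Vector of per-unit API counts (`a_i`).
#' @param total_pop Vector of per-unit total populations (`P_i`).
#' @param strict_printed_form Use region total `P_T` instead of `P_i`.
#' @return Isolation index in \[0, 1\].
#' @examples
#' isolation_index(api_count = c(20, 80), total_pop = c(100, 100))
#' @export
isolation_index <- function(api_count, total_pop, strict_printed_form = FALSE) {
  stopifnot(length(api_count) == length(total_pop))
  a_t <- sum(api_count)
  if (a_t <= 0) abort("index undefined for empty group")
  if (any(api_count > 0 & total_pop <= 0)) {
    abort("unit with api_count > 0 has total_pop = 0")
  }
  if (strict_printed_form) {
    p_t <- sum(total_pop)
    return(sum((api_count / a_t) * (api_count / p_t)))
  }
  keep <- api_count > 0
  sum((api_count[keep] / a_t) * (api_count[keep] / total_pop[keep]))
}

#' Region segregation profiles
#'
#' Computes the three enclave-defining measures -- API population density,
#' API-White dissimilarity, and API isolation -- for every region (and census
#' period) from area-unit counts, optionally attaching a region poverty rate.
#'
#' @inheritParams aggregate_to_region
#' @param poverty Optional data frame `region_id`, `poverty_rate` (fraction
#'   of residents below the poverty threshold), recycled across periods.
#' @param strict_printed_form Passed to [isolation_index()].
#' @return A tibble with columns `region_id`, `period` (if supplied),
#'   `api_density` (percent), `dissimilarity`, `isolation`, `n_units`,
#'   `api_total`, `white_total`, `pop_total`, and `poverty_rate` if given.
#' @examples
#' units <- tibble::tibble(
#'   unit_id = c("z1", "z2"), api_count = c(20, 80),
#'   white_count = c(80, 20), total_pop = c(100, 100)
#' )
#' xw <- tibble::tibble(unit_id = c("z1", "z2"), region_id = "A")
#' region_profiles(units, xw)
#' @export
region_profiles <- function(units, crosswalk, poverty = NULL,
                            strict_printed_form = FALSE) {
  check_columns(units, c("unit_id", "api_count", "white_count", "total_pop"), "`units`")
  check_columns(crosswalk, c("unit_id", "region_id"), "`crosswalk`")
  validate_unit_counts(units)
  has_period <- "period" %in% names(units)
  joined <- units |>
    dplyr::inner_join(crosswalk[c("unit_id", "region_id")], by = "unit_id")
  if (nrow(joined) < nrow(units)) {
    abort(paste0(
      "unit_id missing from crosswalk: ",
      paste(setdiff(units$unit_id, crosswalk$unit_id), collapse = ", ")
    ))
  }
  prof <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(
      if (has_period) "period", "region_id"
    )))) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      api_total = sum(.data$api_count),
      white_total = sum(.data$white_count),
      pop_total = sum(.data$total_pop),
      api_density = api_density(sum(.data$api_count), sum(.data$total_pop)),
      dissimilarity = dissimilarity_index(.data$api_count, .data$white_count),
      isolation = isolation_index(.data$api_count, .data$total_pop,
        strict_printed_form = strict_printed_form
      ),
      .groups = "drop"
    ) |>
    dplyr::relocate(
      dplyr::all_of(c(if (has_period) "period", "region_id")),
      "api_density", "dissimilarity", "isolation"
    )
  if (!is.null(poverty)) {
    check_columns(poverty, c("region_id", "poverty_rate"), "`poverty`")
    prof <- dplyr::left_join(prof, poverty[c("region_id", "poverty_rate")],
      by = "region_id"
    )
  }
  prof
}
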