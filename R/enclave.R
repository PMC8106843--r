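#' Tertile cutpoints of a distribution
#'
#' Lower and upper tertile cutpoints (33.333rd and 66.667th percentiles) by
#' the linear-interpolation sample quantile, optionally weighted (e.g. by
#' region population for person-weighted "population-based" percentiles).
#'
#' @param values Numeric vector, at least 3 finite values.
#' @param weights Optional nonnegative weights, same length as `values`.
#' @return Named numeric vector `c(lower = ..., upper = ...)`.
#' @examples
#' tertile_cutpoints(1:9)
#' @export
tertile_cutpoints <- function(values, weights = NULL) {
  if (any(!is.finite(values))) abort("`values` contains non-finite entries")
  if (length(values) < 3) abort("need at least 3 values to form tertiles")
  cuts <- weighted_quantile(values, c(1, 2) / 3, weights)
  c(lower = cuts[1], upper = cuts[2])
}

# low/medium/high assignment with the ">= cutpoint => upper tertile" rule;
# degenerate distributions (lower == upper) therefore classify everything high
tertile_of <- function(values, cuts) {
  factor(
    ifelse(values >= cuts["upper"], "high",
      ifelse(values >= cuts["lower"], "medium", "low")
    ),
    levels = c("low", "medium", "high")
  )
}

#' Classify regions as ethnic enclaves
#'
#' Labels each region low/medium/high on API density, dissimilarity, and
#' isolation using within-period tertile cutpoints, and flags a region as an
#' ethnic enclave when it sits at or above the upper (66.667th percentile)
#' cutpoint on all three measures simultaneously.
#'
#' Cutpoints are computed over the distribution of regions present in
#' `profiles`, each region one observation, unless `weighting = "population"`
#' in which case regions are weighted by `pop_total`. All profiles must come
#' from a single census period; classify periods separately so tertiles are
#' period-specific.
#'
#' @param profiles Tibble from [region_profiles()] with columns `region_id`,
#'   `api_density`, `dissimilarity`, `isolation` (and `period`, `pop_total`).
#' @param weighting `"none"` (default; each region one observation) or
#'   `"population"` (regions weighted by `pop_total`).
#' @return `profiles` plus `density_tertile`, `dissimilarity_tertile`,
#'   `isolation_tertile` (factors low/medium/high) and logical `is_enclave`.
#' @export
classify_enclaves <- function(profiles, weighting = c("none", "population")) {
  weighting <- match.arg(weighting)
  check_columns(
    profiles, c("region_id", "api_density", "dissimilarity", "isolation"),
    "`profiles`"
  )
  if ("period" %in% names(profiles) &&
    dplyr::n_distinct(profiles$period) > 1) {
    abort("`profiles` mixes census periods; classify each period separately")
  }
  w <- if (weighting == "population") {
    check_columns(profiles, "pop_total", "`profiles`")
    profiles$pop_total
  }
  out <- profiles
  measures <- c(
    density_tertile = "api_density",
    dissimilarity_tertile = "dissimilarity",
    isolation_tertile = "isolation"
  )
  for (tert in names(measures)) {
    cuts <- tertile_cutpoints(profiles[[measures[[tert]]]], w)
    out[[tert]] <- tertile_of(profiles[[measures[[tert]]]], cuts)
  }
  out$is_enclave <- out$density_tertile == "high" &
    out$dissimilarity_tertile == "high" &
    out$isolation_tertile == "high"
  out
}
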