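joint_category_levels <- function() {
  c("LowVOC_Enclave", "LowVOC_NoEnclave", "HighVOC_Enclave", "HighVOC_NoEnclave")
}

#' Joint VOC-by-enclave exposure category
#'
#' Crosses a dichotomized VOC level with enclave residence into the four
#' joint categories. `LowVOC_Enclave` is the reference (anticipated lowest
#' risk) category.
#'
#' @param level `"low"`/`"high"` vector (character or factor).
#' @param is_enclave Logical vector.
#' @return Factor with levels `LowVOC_Enclave`, `LowVOC_NoEnclave`,
#'   `HighVOC_Enclave`, `HighVOC_NoEnclave`.
#' @examples
#' assign_joint_category(c("low", "high"), c(TRUE, FALSE))
#' @export
assign_joint_category <- function(level, is_enclave) {
  level <- as.character(level)
  if (!all(level %in% c("low", "high"))) abort("`level` must be 'low' or 'high'")
  if (anyNA(is_enclave)) abort("`is_enclave` must be TRUE/FALSE with no missing")
  factor(
    paste0(
      ifelse(level == "high", "HighVOC", "LowVOC"), "_",
      ifelse(is_enclave, "Enclave", "NoEnclave")
    ),
    levels = joint_category_levels()
  )
}

#' Attach joint exposure categories to a cohort
#'
#' Combines per-pregnancy dichotomized VOC levels with each pregnancy's
#' period-specific region enclave label to produce one joint category per
#' pregnancy x VOC x window.
#'
#' @param cohort Data frame with `pregnancy_id`, `region_id`, and `period`
#'   (the census-period label the pregnancy links to).
#' @param levels Tibble from [dichotomize_high()].
#' @param labels Enclave labels from [classify_enclaves()] (rows for every
#'   period present in `cohort`), columns `region_id`, `period`, `is_enclave`.
#' @return Tibble `pregnancy_id`, `voc`, `window`, `level`, `is_enclave`,
#'   `category`.
#' @export
joint_exposures <- function(cohort, levels, labels) {
  check_columns(cohort, c("pregnancy_id", "region_id", "period"), "`cohort`")
  check_columns(levels, c("pregnancy_id", "voc", "window", "level"), "`levels`")
  check_columns(labels, c("region_id", "period", "is_enclave"), "`labels`")
  enclave <- cohort |>
    dplyr::select("pregnancy_id", "region_id", "period") |>
    dplyr::left_join(labels[c("region_id", "period", "is_enclave")],
      by = c("region_id", "period")
    )
  if (anyNA(enclave$is_enclave)) {
    abort(paste0(
      "no enclave label for region/period of pregnancy: ",
      paste(head(enclave$pregnancy_id[is.na(enclave$is_enclave)], 5), collapse = ", ")
    ))
  }
  levels |>
    dplyr::inner_join(enclave[c("pregnancy_id", "is_enclave")], by = "pregnancy_id") |>
    dplyr::mutate(category = assign_joint_category(.data$level, .data$is_enclave)) |>
    dplyr::select("pregnancy_id", "voc", "window", "level", "is_enclave", "category")
}

#' Stratified outcome tabulation
#'
#' Frequency-and-percent table of a binary outcome by one or more grouping
#' variables, in the layout of published cohort characteristic tables:
#' per-stratum size, outcome count, and percent with the outcome to one
#' decimal (half-up rounding). Empty factor strata are reported with `n = 0`
#' and no percent.
#'
#' @param data Data frame.
#' @param outcome Unquoted binary (logical or 0/1) outcome column.
#' @param ... Unquoted grouping columns.
#' @return Tibble with the grouping columns, `n`, `n_outcome`,
#'   `percent_outcome`.
#' @examples
#' d <- tibble::tibble(g = c("a", "a", "b"), y = c(TRUE, FALSE, TRUE))
#' tabulate_outcome(d, y, g)
#' @export
tabulate_outcome <- function(data, outcome, ...) {
  out <- dplyr::pull(dplyr::mutate(data, .out = as.logical({{ outcome }})), ".out")
  if (anyNA(out)) abort("outcome must be binary with no missing values")
  data |>
    dplyr::mutate(.out = out) |>
    dplyr::group_by(..., .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_outcome = sum(.data$.out),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      percent_outcome = ifelse(.data$n > 0,
        round_half_up(100 * .data$n_outcome / .data$n, 1), NA_real_
      )
    )
}

#' Crude odds ratio from a 2x2 table
#'
#' Unadjusted odds ratio `(a*d)/(b*c)` with the 95% Wald confidence interval
#' `exp(log OR +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. All four cells must
#' be positive; no continuity correction is applied silently.
#'
#' @param a,b Exposed cases and exposed non-cases.
#' @param c,d Unexposed cases and unexposed non-cases.
#' @return Tibble `or`, `conf_low`, `conf_high`.
#' @examples
#' crude_or(142, 1749, 757, 6421)
#' @export
crude_or <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells <= 0)) {
    abort(paste0(
      "zero or negative cell(s): ",
      paste(names(cells)[cells <= 0], collapse = ", "),
      " (no continuity correction is applied)"
    ))
  }
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble::tibble(
    or = exp(log_or),
    conf_low = exp(log_or - 1.96 * se),
    conf_high = exp(log_or + 1.96 * se)
  )
}
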