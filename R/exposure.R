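#' The fourteen modelled VOC species
#'
#' Canonical tokens for the 14 ambient volatile organic compounds carried
#' through the analysis, in display order. `voc_labels()` gives matching
#' display names.
#'
#' @return Character vector of length 14.
#' @examples
#' voc_names()
#' @export
voc_names <- function() {
  c(
    "benzene", "butadiene_13", "ethylbenzene", "cyclohexane", "mtbe",
    "n_hexane", "emk", "m_xylene", "o_xylene", "p_xylene", "propene",
    "sesquiterpene", "styrene", "toluene"
  )
}

#' @rdname voc_names
#' @export
voc_labels <- function() {
  setNames(
    c(
      "Benzene", "1,3-Butadiene", "Ethylbenzene", "Cyclohexane",
      "Methyl tertiary-butyl ether", "n-Hexane", "Ethyl methyl ketone",
      "m-Xylene", "o-Xylene", "p-Xylene", "Propene", "Sesquiterpene",
      "Styrene", "Toluene"
    ),
    voc_names()
  )
}

# the 7 VOCs that travel together in ambient mixtures (traffic-related block)
#' @rdname voc_names
#' @export
voc_block7 <- function() {
  c("benzene", "ethylbenzene", "toluene", "m_xylene", "o_xylene", "p_xylene", "n_hexane")
}

#' Exposure-window bounds around a conception date
#'
#' The preconception window covers the 91 days (3 months) ending the day
#' before conception; the first-trimester window covers conception through 13
#' gestational weeks, a 91-day span starting at conception. The two windows
#' are adjacent and disjoint.
#'
#' @param conception_date `Date` vector.
#' @param window `"preconception"` or `"first_trimester"` (recycled).
#' @param preconception_days,trimester_days Window lengths in days.
#' @return Tibble `window`, `start`, `end` (closed interval, both `Date`).
#' @examples
#' window_bounds(as.Date("2005-07-01"), "preconception")
#' @export
window_bounds <- function(conception_date,
                          window = c("preconception", "first_trimester"),
                          preconception_days = 91, trimester_days = 91) {
  if (!inherits(conception_date, "Date")) abort("`conception_date` must be a Date")
  bad <- setdiff(window, c("preconception", "first_trimester"))
  if (length(bad) > 0) {
    abort(paste0("unknown window label: ", paste(bad, collapse = ", ")))
  }
  tibble::tibble(window = window, conception_date = conception_date) |>
    dplyr::mutate(
      start = dplyr::if_else(.data$window == "preconception",
        .data$conception_date - preconception_days, .data$conception_date
      ),
      end = dplyr::if_else(.data$window == "preconception",
        .data$conception_date - 1, .data$conception_date + trimester_days - 1
      )
    ) |>
    dplyr::select("window", "start", "end")
}

#' Mean concentration over a closed time window
#'
#' Arithmetic mean of the concentrations whose timestamps fall in
#' `[start, end]`, equally weighted. Works for daily or hourly series.
#'
#' @param timestamps Sorted `Date` or `POSIXct` vector.
#' @param concentrations Nonnegative ppb values, same length.
#' @param start,end Closed window bounds (same class as `timestamps`).
#' @return List with `mean_ppb` and `n_points`.
#' @export
window_average <- function(timestamps, concentrations, start, end) {
  stopifnot(length(timestamps) == length(concentrations))
  inside <- timestamps >= start & timestamps <= end
  n <- sum(inside)
  if (n == 0) abort("no exposure coverage in window")
  list(mean_ppb = mean(concentrations[inside]), n_points = n)
}

#' Per-pregnancy exposure-window averages
#'
#' For every pregnancy, VOC, and exposure window, averages the pregnancy's
#' region concentration series over the window. Series are matched to
#' pregnancies by `region_id`; each series must cover every requested window.
#'
#' @param cohort Data frame with `pregnancy_id`, `region_id`,
#'   `conception_date`.
#' @param exposure Long data frame `region_id`, `voc`, `date`, `ppb` (daily)
#'   or with a `POSIXct` `date` column for hourly series.
#' @param windows Which windows to compute.
#' @inheritParams window_bounds
#' @return Tibble `pregnancy_id`, `voc`, `window`, `mean_ppb`, `n_points`.
#' @export
window_averages <- function(cohort, exposure,
                            windows = c("preconception", "first_trimester"),
                            preconception_days = 91, trimester_days = 91) {
  check_columns(cohort, c("pregnancy_id", "region_id", "conception_date"), "`cohort`")
  check_columns(exposure, c("region_id", "voc", "date", "ppb"), "`exposure`")
  if (any(exposure$ppb < 0) || any(!is.finite(exposure$ppb))) {
    abort("`exposure` concentrations must be nonnegative and finite")
  }
  missing_regions <- setdiff(unique(cohort$region_id), unique(exposure$region_id))
  if (length(missing_regions) > 0) {
    abort(paste0(
      "no exposure series for region(s): ",
      paste(head(missing_regions, 5), collapse = ", ")
    ))
  }

  wins <- cohort |>
    dplyr::select("pregnancy_id", "region_id", "conception_date") |>
    tidyr::crossing(window = windows) |>
    dplyr::mutate(window_bounds(.data$conception_date, .data$window,
      preconception_days = preconception_days,
      trimester_days = trimester_days
    )[c("start", "end")])

  # cumulative sums per (region, voc) series give O(1) window means
  series <- exposure |>
    dplyr::arrange(.data$region_id, .data$voc, .data$date) |>
    dplyr::group_by(.data$region_id, .data$voc)
  keys <- dplyr::group_keys(series)
  chunks <- dplyr::group_split(series)

  out <- purrr::map2(chunks, seq_len(nrow(keys)), function(ser, k) {
    w <- wins[wins$region_id == keys$region_id[k], ]
    if (nrow(w) == 0) return(NULL)
    ts <- as.numeric(ser$date)
    if (is.unsorted(ts, strictly = TRUE)) {
      abort(paste0(
        "timestamps not strictly increasing for region ", keys$region_id[k],
        ", voc ", keys$voc[k]
      ))
    }
    cs <- c(0, cumsum(ser$ppb))
    # closed [start-of-day, end-of-day] window in the series' own time unit
    if (inherits(ser$date, "POSIXct")) {
      tz <- attr(ser$date, "tzone") %||% "UTC"
      s_num <- as.numeric(as.POSIXct(as.character(w$start), tz = tz))
      e_num <- as.numeric(as.POSIXct(as.character(w$end + 1), tz = tz))
    } else {
      s_num <- as.numeric(w$start)
      e_num <- as.numeric(w$end) + 1
    }
    i0 <- findInterval(s_num - 1e-6, ts)
    i1 <- findInterval(e_num - 1e-6, ts)
    n <- i1 - i0
    if (any(n == 0)) {
      abort(paste0(
        "no exposure coverage for pregnancy ",
        paste(head(w$pregnancy_id[n == 0], 5), collapse = ", "),
        " (voc ", keys$voc[k], ")"
      ))
    }
    tibble::tibble(
      pregnancy_id = w$pregnancy_id, voc = keys$voc[k], window = w$window,
      mean_ppb = (cs[i1 + 1] - cs[i0 + 1]) / n, n_points = n
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$pregnancy_id, .data$voc, .data$window)
}

#' Dichotomize window averages at the 75th percentile
#'
#' Within each (VOC, window) stratum, computes the 75th percentile
#' (linear-interpolation quantile) of the per-pregnancy window averages over
#' the analytic sample; averages at or above the cutoff are "high", the rest
#' "low". Roughly a quarter of the sample is high for continuous data; with a
#' degenerate (all-equal) stratum everyone is high by the `>=` rule.
#'
#' @param averages Tibble from [window_averages()].
#' @param prob Percentile for the cutoff (default 0.75).
#' @return `averages` plus a `level` factor (`low`/`high`) and the stratum
#'   `cutoff_ppb`.
#' @export
dichotomize_high <- function(averages, prob = 0.75) {
  check_columns(averages, c("pregnancy_id", "voc", "window", "mean_ppb"), "`averages`")
  if (nrow(averages) == 0) abort("empty exposure stratum")
  small <- averages |>
    dplyr::count(.data$voc, .data$window) |>
    dplyr::filter(.data$n < 4)
  if (nrow(small) > 0) {
    abort(paste0(
      "need at least 4 averages per (voc, window) stratum; too few for ",
      paste(small$voc, small$window, sep = "/", collapse = ", ")
    ))
  }
  averages |>
    dplyr::group_by(.data$voc, .data$window) |>
    dplyr::mutate(
      cutoff_ppb = quantile(.data$mean_ppb, prob, type = 7, names = FALSE),
      level = factor(ifelse(.data$mean_ppb >= .data$cutoff_ppb, "high", "low"),
        levels = c("low", "high")
      )
    ) |>
    dplyr::ungroup()
}

#' Spearman rank-correlation matrix of VOC window averages
#'
#' Pairwise Spearman correlations between the per-pregnancy window averages
#' of each VOC, within one exposure window. Constant VOC vectors make the
#' correlation undefined; those entries are returned as `NA` with a warning
#' rather than silently zeroed.
#'
#' @param averages Tibble from [window_averages()].
#' @param window Which exposure window to correlate.
#' @return Symmetric correlation matrix with unit diagonal, one row/column
#'   per VOC present.
#' @export
spearman_voc_matrix <- function(averages, window = "preconception") {
  check_columns(averages, c("pregnancy_id", "voc", "window", "mean_ppb"), "`averages`")
  wide <- averages |>
    dplyr::filter(.data$window == !!window) |>
    dplyr::select("pregnancy_id", "voc", "mean_ppb") |>
    tidyr::pivot_wider(names_from = "voc", values_from = "mean_ppb")
  if (anyNA(wide)) abort("pregnancy set differs across VOCs")
  m <- as.matrix(wide[-1])
  constant <- apply(m, 2, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  if (any(constant)) {
    rho[constant, ] <- NA_real_
    rho[, constant] <- NA_real_
    warn(paste0(
      "constant VOC vector(s), correlations undefined: ",
      paste(colnames(m)[constant], collapse = ", ")
    ))
  }
  diag(rho) <- 1
  rho
}
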