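#' Parameter-recovery simulation study
#'
#' Repeatedly simulates a study with known joint-category effects, runs the
#' full analysis pipeline on each replicate (segregation profiles, enclave
#' classification, driver-VOC window averaging and dichotomization, joint
#' categories, BMI multiple imputation, pooled random-intercept logistic
#' fit), and scores the pooled estimates against the generating log odds
#' ratios: per-replicate estimates, confidence-interval coverage, and
#' whether the High VOC/No Enclave odds ratio exceeds High VOC/Enclave.
#'
#' @param n_rep Number of replicates.
#' @param config Generator configuration; the default scales the study
#'   conditions to 5000 mothers in 40 regions with only the driver VOC
#'   simulated (the estimates for other VOCs are not scored).
#' @param m Imputations per replicate.
#' @param method Fitting method; `"pirls"` (default) is the fast
#'   approximation appropriate for thousands of fits, see
#'   [fit_hier_logit()].
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return List with `estimates` (tibble: replicate, term, true, estimate,
#'   conf_low, conf_high, covered), `summary` (per-term mean estimate, bias,
#'   relative bias, coverage), and `ordering` (share of replicates with
#'   OR(HighVOC_NoEnclave) > OR(HighVOC_Enclave)).
#' @export
recovery_study <- function(n_rep = 200,
                           config = study_config(
                             n_mothers = 5000,
                             vocs = "benzene",
                             voc_block = character(0)
                           ),
                           m = 10, method = "pirls", seed = 1) {
  truth <- config$true_log_ors
  rows <- vector("list", n_rep)
  ordering <- logical(n_rep)
  failed <- 0L
  for (r in seq_len(n_rep)) {
    est <- tryCatch(
      recovery_replicate(config, m, method, seed + r),
      error = function(e) NULL
    )
    if (is.null(est)) {
      # zero-event categories at small stratum sizes abort the fit; such
      # replicates are recorded as failures, not silently redrawn
      failed <- failed + 1L
      next
    }
    est$replicate <- r
    rows[[r]] <- est
    o <- est$estimate[match(
      c("HighVOC_NoEnclave", "HighVOC_Enclave"), est$term
    )]
    ordering[r] <- o[1] > o[2]
  }
  estimates <- dplyr::bind_rows(rows)
  summary <- estimates |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      true = .data$true[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate) - .data$true[1],
      rel_bias = (mean(.data$estimate) - .data$true[1]) / .data$true[1],
      coverage = mean(.data$covered),
      .groups = "drop"
    )
  list(
    estimates = estimates, summary = summary,
    ordering = mean(ordering[estimates$replicate[!duplicated(estimates$replicate)]]),
    n_failed = failed
  )
}

recovery_replicate <- function(config, m, method, seed) {
  sim <- simulate_study(config, seed = seed)
  prof <- region_profiles(sim$units, sim$crosswalk, sim$poverty)
  lab <- prof |>
    dplyr::group_split(.data$period) |>
    purrr::map(classify_enclaves) |>
    dplyr::bind_rows()
  avg <- window_averages(
    sim$cohort, sim$exposure[sim$exposure$voc == config$driver_voc, ],
    windows = config$driver_window
  )
  lv <- dichotomize_high(avg)
  jc <- joint_exposures(sim$cohort, lv, lab)
  imps <- impute_bmi(sim$cohort, m = m)
  pooled <- fit_pooled(
    lapply(imps, function(d) {
      dplyr::inner_join(d,
        jc[jc$voc == config$driver_voc & jc$window == config$driver_window,
          c("pregnancy_id", "category")],
        by = "pregnancy_id"
      )
    }),
    joint_model_formula(), "region_id", "mother_id", method
  )
  truth <- config$true_log_ors
  idx <- match(paste0("category", names(truth)), names(pooled$coefficients))
  tibble::tibble(
    term = names(truth),
    true = unname(truth),
    estimate = unname(pooled$coefficients[idx]),
    conf_low = unname(pooled$conf_low[idx]),
    conf_high = unname(pooled$conf_high[idx]),
    covered = .data$conf_low <= .data$true & .data$true <= .data$conf_high
  )
}
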