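#' Configuration for the synthetic nested-cohort generator
#'
#' Defaults emulate the study conditions of the motivating cohort: 8350
#' mothers with 7.9% of births being repeat births (about 9070 pregnancies),
#' ~9.9% GDM prevalence, 20.8% of births in enclave regions, 42% missing
#' BMI, 14 correlated VOC fields with a 7-VOC high-correlation block, a
#' region random-intercept sd of 0.3, and true joint-category odds ratios
#' {Low VOC/No Enclave 1.5, High VOC/Enclave 1.2, High VOC/No Enclave 2.0}
#' against the Low VOC/Enclave reference. Covariate category frequencies
#' follow the published cohort characteristic table.
#'
#' @param ... Named overrides of any default listed in the function body
#'   (e.g. `n_regions`, `n_mothers`, `true_log_ors`, `random_intercept_sd`).
#' @return A validated `evoc_config` list.
#' @examples
#' cfg <- study_config(n_regions = 12, n_mothers = 500)
#' @export
study_config <- function(...) {
  cfg <- list(
    # regions and small-area composition
    n_regions = 40,
    units_per_region = 25,
    enclave_birth_share = 0.208, # share of births in enclave regions
    api_share_enclave = c(0.15, 0.35),
    api_share_other = c(0.01, 0.08),
    segregation_strength = 0.5, # Dirichlet concentration; low = clustered
    mixing_factor = 40, # extra concentration for non-enclave regions
    unit_pop_log_mean = log(15000),
    unit_pop_log_sd = 0.6,
    white_share = 0.6,
    periods = c("census2000", "acs2007_2011"),
    period_growth_sd = 0.05,
    poverty_beta = c(2.6, 12),
    # cohort
    n_mothers = 8350,
    repeat_birth_fraction = 0.079,
    conception_range = as.Date(c("2002-01-01", "2008-03-01")),
    gestation_mean = 270, gestation_sd = 13, gestation_min = 150,
    age_band_probs = c(
      `15-19` = 168, `20-24` = 1289, `25-29` = 2797,
      `30-34` = 2958, `35-43` = 1851
    ) / 9063,
    marital_probs = c(married = 7642, single = 1241, other = 186) / 9069,
    insurance_probs = c(private = 6374, public = 1280, self_pay = 193, other = 1222) / 9069,
    parity_probs = c(nulliparous = 4433, multiparous = 4636) / 9069,
    hospital_probs = c(
      university = 0.41, community_teaching = 0.546,
      community_nonteaching = 0.044
    ),
    bmi_cat_probs = c(underweight = 621, normal = 3466, overweight = 744, obese = 425) / 5256,
    bmi_ranges = list(
      underweight = c(16, 18.4), normal = c(18.5, 24.9),
      overweight = c(25, 29.9), obese = c(30, 45)
    ),
    bmi_missing_fraction = 0.42,
    # outcome model (log-odds scale)
    # reference-category log odds, calibrated once so that the marginal GDM
    # prevalence under the default effects is ~9.9%
    baseline_gdm_logit = -3.15,
    true_log_ors = c(
      LowVOC_NoEnclave = log(1.5),
      HighVOC_Enclave = log(1.2),
      HighVOC_NoEnclave = log(2.0)
    ),
    random_intercept_sd = 0.3,
    driver_voc = "benzene",
    driver_window = "preconception",
    covariate_effects = list(
      age_years = log(1.07), # per year, centered at 28
      marital_status = c(single = -0.45, other = 0.05),
      insurance = c(public = -0.08, self_pay = -0.12, other = -0.5),
      bmi_cat = c(underweight = -0.55, overweight = 0.75, obese = 1.0),
      parity = c(multiparous = 0.22),
      season = c(summer = -0.10, fall = 0.10, winter = 0.20),
      hospital_type = c(community_teaching = 0.20, community_nonteaching = -0.20),
      poverty_rate = 0.30
    ),
    # exposure fields
    vocs = voc_names(),
    voc_block = voc_block7(),
    block_correlation = 0.9,
    background_correlation = 0.1,
    voc_log_means = setNames(
      c(-0.7, -2.3, -1.6, -1.9, -0.9, -1.2, -0.5, -1.4, -1.8, -1.7,
        -0.8, -2.8, -2.1, 0.2),
      voc_names()
    ),
    sd_region = 0.30, # between-region log sd
    sd_month = 0.35, # within-region monthly anomaly log sd
    sd_day = 0.15, # day-to-day log sd (independent across VOCs)
    seasonal_amplitude = 0.12,
    preconception_days = 91,
    trimester_days = 91
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  if (!"voc_block" %in% names(overrides)) {
    cfg$voc_block <- intersect(cfg$voc_block, cfg$vocs)
  }
  if (!"voc_log_means" %in% names(overrides)) {
    cfg$voc_log_means <- cfg$voc_log_means[cfg$vocs]
  }
  validate_config(cfg)
  structure(cfg, class = "evoc_config")
}

validate_config <- function(cfg) {
  probs <- c(
    cfg$enclave_birth_share, cfg$repeat_birth_fraction,
    cfg$bmi_missing_fraction, cfg$age_band_probs, cfg$marital_probs,
    cfg$insurance_probs, cfg$parity_probs, cfg$hospital_probs, cfg$bmi_cat_probs
  )
  if (any(probs < 0 | probs > 1)) abort("config probabilities must lie in [0, 1]")
  if (any(c(cfg$sd_region, cfg$sd_month, cfg$sd_day, cfg$random_intercept_sd) < 0)) {
    abort("config standard deviations must be nonnegative")
  }
  if (cfg$n_regions < 3 || cfg$units_per_region < 2) {
    abort("need at least 3 regions and 2 units per region")
  }
  if (!all(cfg$voc_block %in% cfg$vocs)) abort("voc_block must be a subset of vocs")
  if (cfg$block_correlation < 0 || cfg$block_correlation > 1 ||
    cfg$background_correlation < 0 || cfg$background_correlation >= 1) {
    abort("correlations must lie in [0, 1)")
  }
  invisible(cfg)
}

#' Generate synthetic regions and small-area composition
#'
#' Draws area units nested in regions for both census periods. A designated
#' top-tertile-sized subset of regions is made enclave-like:
#' high API share drawn from `api_share_enclave` and strongly clustered API
#' allocation across units (low Dirichlet concentration
#' `segregation_strength`); remaining regions get low shares and nearly even
#' mixing (concentration multiplied by `mixing_factor`), so very large
#' `segregation_strength` drives dissimilarity toward 0 everywhere.
#'
#' @param config An `evoc_config` from [study_config()].
#' @param seed Optional integer seed; omit to use the current RNG stream.
#' @return List: `units` (per period), `crosswalk`, `poverty`, and `regions`
#'   (with `designated_enclave`, `hospital_type`, `poverty_rate`,
#'   `birth_weight`).
#' @export
gen_regions <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_r <- config$n_regions
  n_u <- config$units_per_region
  region_id <- sprintf("R%02d", seq_len(n_r))
  # designate exactly the number of regions the >=-cutpoint tertile rule
  # labels "high" (ranks ceil(h)..n at h = (n-1)*2/3 + 1), so the designated
  # set and the classifier's enclave set coincide when designated regions
  # dominate all three measures; round(n/3) is off by one for e.g. n = 40,
  # which silently contaminates the reference category
  n_encl <- max(1, n_r - ceiling((n_r - 1) * 2 / 3))
  designated <- region_id %in% sample(region_id, n_encl)

  base <- purrr::map(seq_len(n_r), function(r) {
    pop <- pmax(200, round(rlnorm(n_u, config$unit_pop_log_mean, config$unit_pop_log_sd)))
    share_rng <- if (designated[r]) config$api_share_enclave else config$api_share_other
    share <- runif(1, share_rng[1], share_rng[2])
    conc <- config$segregation_strength *
      (if (designated[r]) 1 else config$mixing_factor)
    alpha <- conc * n_u * pop / sum(pop)
    p <- as.numeric(rdirichlet(1, alpha))
    api <- pmin(round(p * share * sum(pop)), floor(0.95 * pop))
    white <- pmin(
      round(runif(n_u, 0.85, 1.15) * config$white_share * (pop - api)),
      pop - api
    )
    tibble::tibble(
      unit_id = sprintf("Z%02d%02d", r, seq_len(n_u)),
      region_id = region_id[r],
      api_count = api, white_count = white, total_pop = pop
    )
  }) |> dplyr::bind_rows()

  # second period: same structure with small demographic drift
  units <- dplyr::bind_rows(lapply(
    setNames(config$periods, config$periods),
    function(p) {
      u <- base
      if (p != config$periods[1]) {
        grow <- function(x) pmax(0, round(x * rlnorm(length(x), 0, config$period_growth_sd)))
        u$api_count <- grow(u$api_count)
        u$white_count <- grow(u$white_count)
        u$total_pop <- pmax(u$total_pop, u$api_count + u$white_count)
      }
      u
    }
  ), .id = "period")

  crosswalk <- base[c("unit_id", "region_id")]
  pops <- base |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(pop_total = sum(.data$total_pop), .groups = "drop")
  regions <- tibble::tibble(
    region_id = region_id,
    designated_enclave = designated,
    hospital_type = factor(
      sample(names(config$hospital_probs), n_r, TRUE, config$hospital_probs),
      levels = names(config$hospital_probs)
    ),
    poverty_rate = rbeta(n_r, config$poverty_beta[1], config$poverty_beta[2])
  ) |>
    dplyr::left_join(pops, by = "region_id")
  # births split enclave_birth_share / rest, proportional to population within
  w <- regions$pop_total * ifelse(
    regions$designated_enclave,
    config$enclave_birth_share / sum(regions$pop_total[regions$designated_enclave]),
    (1 - config$enclave_birth_share) / sum(regions$pop_total[!regions$designated_enclave])
  )
  regions$birth_weight <- w / sum(w)

  list(
    units = units[c("period", "unit_id", "api_count", "white_count", "total_pop")],
    crosswalk = crosswalk,
    poverty = regions[c("region_id", "poverty_rate")],
    regions = regions
  )
}

season_of <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  factor(
    c(
      "winter", "winter", "spring", "spring", "spring", "summer",
      "summer", "summer", "fall", "fall", "fall", "winter"
    )[m],
    levels = c("spring", "summer", "fall", "winter")
  )
}

period_of <- function(delivery_date, periods = c("census2000", "acs2007_2011")) {
  yr <- as.integer(format(delivery_date, "%Y"))
  factor(ifelse(yr <= 2004, periods[1], periods[2]), levels = periods)
}

#' Generate a synthetic pregnancy cohort
#'
#' Assigns mothers to regions (designated enclave regions receive
#' `enclave_birth_share` of births), draws repeat births, covariates, and --
#' unless `outcome = FALSE` -- the GDM outcome from a logistic model with a
#' region random intercept, the configured covariate effects, and the true
#' joint-category log odds ratios applied to the designated enclave status
#' crossed with a per-pregnancy latent high-exposure flag.
#'
#' @inheritParams gen_regions
#' @param regions Output of [gen_regions()].
#' @param latent_high Optional logical vector (one per pregnancy, in output
#'   row order) of true high-VOC flags; when `NULL` an independent
#'   Bernoulli(0.25) flag is drawn. [simulate_study()] passes the
#'   dichotomized driver-VOC window average here so generated effects match
#'   what the pipeline estimates.
#' @param outcome Draw the GDM outcome (set `FALSE` to build the frame first
#'   and add the outcome later via the returned structure).
#' @return List with `cohort` (tibble) and `truth` (region intercepts, true
#'   categories, parameters) when `outcome = TRUE`.
#' @export
gen_cohort <- function(config, regions, seed = NULL, latent_high = NULL,
                       outcome = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  reg <- regions$regions
  n_m <- config$n_mothers
  f <- config$repeat_birth_fraction
  n_rep <- round(n_m * f / (1 - f))

  mother_id <- sprintf("M%05d", seq_len(n_m))
  m_region <- sample(reg$region_id, n_m, TRUE, reg$birth_weight)
  band <- sample(names(config$age_band_probs), n_m, TRUE, config$age_band_probs)
  bounds <- do.call(rbind, strsplit(band, "-"))
  m_age <- runif(n_m, as.numeric(bounds[, 1]), as.numeric(bounds[, 2]))
  m_marital <- sample(names(config$marital_probs), n_m, TRUE, config$marital_probs)
  m_insur <- sample(names(config$insurance_probs), n_m, TRUE, config$insurance_probs)
  m_parity <- sample(names(config$parity_probs), n_m, TRUE, config$parity_probs)

  rng <- as.numeric(diff(config$conception_range))
  conc1 <- config$conception_range[1] + round(runif(n_m) * rng)
  rep_idx <- if (n_rep > 0) sample.int(n_m, n_rep) else integer(0)
  gap <- round(runif(n_rep, 400, 1100))
  conc2 <- pmin(conc1[rep_idx] + gap, config$conception_range[2])

  cohort <- tibble::tibble(
    mother_id = c(mother_id, mother_id[rep_idx]),
    region_id = c(m_region, m_region[rep_idx]),
    conception_date = c(conc1, conc2),
    age_years = c(m_age, m_age[rep_idx] + gap / 365.25),
    marital_status = factor(c(m_marital, m_marital[rep_idx]),
      levels = names(config$marital_probs)
    ),
    insurance = factor(c(m_insur, m_insur[rep_idx]),
      levels = names(config$insurance_probs)
    ),
    parity = factor(c(m_parity, rep("multiparous", n_rep)),
      levels = names(config$parity_probs)
    )
  ) |>
    dplyr::arrange(.data$mother_id, .data$conception_date) |>
    dplyr::mutate(pregnancy_id = sprintf("P%05d", dplyr::row_number()), .before = 1)

  n <- nrow(cohort)
  gest <- pmax(config$gestation_min, round(rnorm(n, config$gestation_mean, config$gestation_sd)))
  cohort$delivery_date <- cohort$conception_date + gest
  cohort$season <- season_of(cohort$conception_date)
  cohort$period <- period_of(cohort$delivery_date, config$periods)

  bcat <- sample(names(config$bmi_cat_probs), n, TRUE, config$bmi_cat_probs)
  lo <- vapply(config$bmi_ranges[bcat], `[`, numeric(1), 1)
  hi <- vapply(config$bmi_ranges[bcat], `[`, numeric(1), 2)
  cohort$bmi <- round(runif(n, lo, hi), 1)
  cohort$bmi[runif(n) < config$bmi_missing_fraction] <- NA_real_
  cohort$bmi_cat <- bmi_category(cohort$bmi)

  cohort <- cohort |>
    dplyr::left_join(
      reg[c("region_id", "hospital_type", "poverty_rate", "designated_enclave")],
      by = "region_id"
    )

  if (!outcome) {
    return(list(cohort = cohort, truth = NULL))
  }
  if (is.null(latent_high)) latent_high <- runif(n) < 0.25
  draw_outcome(config, cohort, latent_high)
}

# GDM draw given the cohort frame and the true latent high-exposure flag
draw_outcome <- function(config, cohort, latent_high, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(latent_high) == nrow(cohort))
  reg_ids <- sort(unique(cohort$region_id))
  u <- setNames(rnorm(length(reg_ids), 0, config$random_intercept_sd), reg_ids)
  true_cat <- assign_joint_category(
    ifelse(latent_high, "high", "low"), cohort$designated_enclave
  )
  eta <- config$baseline_gdm_logit +
    c(0, config$true_log_ors)[as.integer(true_cat)] +
    covariate_linpred(config, cohort) +
    u[cohort$region_id]
  out <- cohort
  out$gdm <- unname(runif(nrow(cohort)) < plogis(eta))
  list(
    cohort = out,
    truth = list(
      region_intercepts = u,
      true_category = true_cat,
      latent_high = latent_high,
      true_log_ors = config$true_log_ors,
      baseline_gdm_logit = config$baseline_gdm_logit,
      random_intercept_sd = config$random_intercept_sd
    )
  )
}

covariate_linpred <- function(config, cohort) {
  ce <- config$covariate_effects
  pick <- function(effects, values) {
    out <- effects[as.character(values)]
    out[is.na(out)] <- 0 # reference levels
    unname(out)
  }
  # BMI effect: missing BMI contributes through its (unknown) true category;
  # use the drawn category before masking when available, else 0 at reference
  bmi_term <- pick(ce$bmi_cat, as.character(cohort$bmi_cat))
  bmi_term[is.na(cohort$bmi_cat)] <- 0
  ce$age_years * (cohort$age_years - 28) +
    pick(ce$marital_status, cohort$marital_status) +
    pick(ce$insurance, cohort$insurance) +
    bmi_term +
    pick(ce$parity, cohort$parity) +
    pick(ce$season, cohort$season) +
    pick(ce$hospital_type, cohort$hospital_type) +
    ce$poverty_rate * cohort$poverty_rate
}

#' Generate per-region daily VOC concentration series
#'
#' Log-normal daily fields: region-level mean offsets and monthly regional
#' anomalies are drawn jointly across VOCs with a correlation matrix holding
#' `block_correlation` inside the 7-VOC traffic block and
#' `background_correlation` elsewhere, plus an annual sinusoid (independent
#' phase per VOC) and independent day-to-day noise. Window averages of these
#' series therefore reproduce the configured between-VOC correlation
#' structure.
#'
#' @inheritParams gen_cohort
#' @param cohort Optional cohort list (from [gen_cohort()]) used to size the
#'   date range so every pregnancy's windows are covered.
#' @return Long tibble `region_id`, `voc`, `date`, `ppb`.
#' @export
gen_exposure <- function(config, regions, cohort = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conc <- if (!is.null(cohort)) range(cohort$cohort$conception_date) else config$conception_range
  dates <- seq(conc[1] - config$preconception_days - 3,
    conc[2] + config$trimester_days + 3,
    by = "day"
  )
  vocs <- config$vocs
  v <- length(vocs)
  corr <- matrix(config$background_correlation, v, v, dimnames = list(vocs, vocs))
  blk <- intersect(config$voc_block, vocs)
  corr[blk, blk] <- config$block_correlation
  diag(corr) <- 1
  cl <- corr_sqrt(corr) # eigen square root; tolerates singular (rho = 1) blocks
  mu0 <- config$voc_log_means[vocs]
  phase <- runif(v, 0, 2 * pi)
  doy <- as.integer(format(dates, "%j"))
  seas <- config$seasonal_amplitude *
    sin(outer(2 * pi * doy / 365.25, phase, `+`)) # days x vocs
  months <- unique(format(dates, "%Y-%m"))
  month_idx <- match(format(dates, "%Y-%m"), months)
  n_d <- length(dates)

  reg_ids <- regions$regions$region_id
  out <- lapply(reg_ids, function(r) {
    rmean <- mu0 + config$sd_region * drop(rnorm(v) %*% cl)
    manom <- matrix(rnorm(length(months) * v), ncol = v) %*% cl * config$sd_month
    lg <- matrix(rmean, n_d, v, byrow = TRUE) + manom[month_idx, , drop = FALSE] +
      seas + matrix(rnorm(n_d * v, 0, config$sd_day), n_d, v)
    tibble::tibble(
      region_id = r,
      voc = rep(vocs, each = n_d),
      date = rep(dates, v),
      ppb = exp(as.numeric(lg))
    )
  })
  dplyr::bind_rows(out)
}

#' Simulate a complete study with known ground truth
#'
#' End-to-end generator: regions and small-area composition, cohort frame,
#' exposure series, then the GDM outcome drawn with the true joint-category
#' effects applied to the *actual* dichotomized driver-VOC window average
#' (so the estimand targeted by the analysis pipeline matches the generating
#' model) and the designated enclave status.
#'
#' @inheritParams gen_regions
#' @param seed Integer seed fixing every draw.
#' @return List: `config`, `units`, `crosswalk`, `poverty`, `regions`,
#'   `cohort`, `exposure`, `truth`.
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  set.seed(seed)
  regions <- gen_regions(config)
  base <- gen_cohort(config, regions, outcome = FALSE)
  exposure <- gen_exposure(config, regions, cohort = base)
  driver <- exposure[exposure$voc == config$driver_voc, ]
  avg <- window_averages(base$cohort, driver,
    windows = config$driver_window,
    preconception_days = config$preconception_days,
    trimester_days = config$trimester_days
  )
  lv <- dichotomize_high(avg)
  latent <- lv$level[match(base$cohort$pregnancy_id, lv$pregnancy_id)] == "high"
  drawn <- draw_outcome(config, base$cohort, latent)
  list(
    config = config,
    units = regions$units,
    crosswalk = regions$crosswalk,
    poverty = regions$poverty,
    regions = regions$regions,
    cohort = drawn$cohort,
    exposure = exposure,
    truth = drawn$truth
  )
}
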