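test_that("generation is deterministic under a seed", {
  cfg <- tiny_config()
  r1 <- gen_regions(cfg, seed = 3)
  r2 <- gen_regions(cfg, seed = 3)
  expect_identical(r1, r2)

  s1 <- simulate_study(cfg, seed = 4)
  s2 <- simulate_study(cfg, seed = 4)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$truth, s2$truth)
})

test_that("very large mixing concentration drives dissimilarity to zero", {
  cfg <- tiny_config(segregation_strength = 1e6)
  reg <- gen_regions(cfg, seed = 6)
  prof <- region_profiles(
    dplyr::filter(reg$units, period == "census2000"), reg$crosswalk
  )
  expect_lt(max(prof$dissimilarity), 0.05)
})

test_that("designated enclave-like regions land in the top tertile of all measures", {
  hits <- vapply(1:10, function(s) {
    cfg <- tiny_config()
    reg <- gen_regions(cfg, seed = 100 + s)
    prof <- region_profiles(
      dplyr::filter(reg$units, period == "census2000"), reg$crosswalk
    )
    lab <- classify_enclaves(dplyr::mutate(prof, period = "census2000"))
    designated <- reg$regions$region_id[reg$regions$designated_enclave]
    mean(designated %in% lab$region_id[lab$is_enclave])
  }, numeric(1))
  expect_gt(mean(hits), 0.9)
})

test_that("null generator hits the configured marginal prevalence", {
  zero_effects <- list(
    age_years = 0,
    marital_status = c(single = 0, other = 0),
    insurance = c(public = 0, self_pay = 0, other = 0),
    bmi_cat = c(underweight = 0, overweight = 0, obese = 0),
    parity = c(multiparous = 0),
    season = c(summer = 0, fall = 0, winter = 0),
    hospital_type = c(community_teaching = 0, community_nonteaching = 0),
    poverty_rate = 0
  )
  cfg <- study_config(
    vocs = "benzene", voc_block = character(0),
    covariate_effects = zero_effects,
    true_log_ors = c(
      LowVOC_NoEnclave = 0, HighVOC_Enclave = 0, HighVOC_NoEnclave = 0
    ),
    random_intercept_sd = 0,
    baseline_gdm_logit = qlogis(0.099)
  )
  sim <- simulate_study(cfg, seed = 8)
  n <- nrow(sim$cohort)
  expect_gt(n, 9000) # ~9069 births from 8350 mothers at 7.9% repeats
  se <- sqrt(0.099 * 0.901 / n)
  expect_lt(abs(mean(sim$cohort$gdm) - 0.099), 4 * se)

  # zero random-intercept variance: between-region variation is binomial
  by_region <- sim$cohort |>
    dplyr::group_by(region_id) |>
    dplyr::summarise(n = dplyr::n(), p = mean(gdm), .groups = "drop")
  p0 <- mean(sim$cohort$gdm)
  dispersion <- sum((by_region$p - p0)^2 * by_region$n) / (p0 * (1 - p0)) /
    (nrow(by_region) - 1)
  expect_lt(dispersion, 2)
})

test_that("repeat fraction zero gives one pregnancy per mother", {
  cfg <- tiny_config(repeat_birth_fraction = 0, n_mothers = 300)
  sim <- gen_cohort(cfg, gen_regions(cfg, seed = 2), seed = 3)
  expect_equal(nrow(sim$cohort), 300)
  expect_equal(dplyr::n_distinct(sim$cohort$mother_id), 300)
})

test_that("covariate marginals track the configured distributions", {
  cohort <- tiny_sim$cohort
  cfg <- tiny_config()
  n <- nrow(cohort)
  for (var in c("marital_status", "insurance", "parity")) {
    probs <- cfg[[paste0(
      c(marital_status = "marital", insurance = "insurance", parity = "parity")[var],
      "_probs"
    )]]
    got <- prop.table(table(cohort[[var]]))
    expect_lt(max(abs(got[names(probs)] - probs)), 4 * sqrt(0.25 / n) + 0.02)
  }
  expect_equal(mean(is.na(cohort$bmi)), 0.42, tolerance = 0.05)
  expect_equal(
    mean(cohort$designated_enclave), 0.208,
    tolerance = 0.06
  )
  frac_repeat <- 1 - dplyr::n_distinct(cohort$mother_id) / n
  expect_equal(frac_repeat, 0.079, tolerance = 0.02)
})

test_that("exposure generator respects degenerate noise settings", {
  cfg <- tiny_config(
    sd_region = 0, sd_month = 0, sd_day = 0, seasonal_amplitude = 0,
    n_mothers = 50, n_regions = 3
  )
  reg <- gen_regions(cfg, seed = 1)
  base <- gen_cohort(cfg, reg, seed = 2, outcome = FALSE)
  expo <- gen_exposure(cfg, reg, base, seed = 3)
  spread <- expo |>
    dplyr::group_by(region_id, voc) |>
    dplyr::summarise(s = sd(ppb), m = mean(ppb), .groups = "drop")
  expect_true(all(spread$s == 0)) # constant series
  expect_equal(
    unique(round(log(spread$m[spread$voc == "benzene"]), 10)),
    unname(round(cfg$voc_log_means["benzene"], 10))
  )
})

test_that("perfect block correlation yields identical high/low labels", {
  cfg <- tiny_config(block_correlation = 1, sd_day = 0, seasonal_amplitude = 0)
  sim <- simulate_study(cfg, seed = 9)
  lv <- dichotomize_high(window_averages(sim$cohort, sim$exposure))
  wide <- lv |>
    dplyr::filter(window == "preconception") |>
    dplyr::select(pregnancy_id, voc, level) |>
    tidyr::pivot_wider(names_from = voc, values_from = level)
  expect_identical(wide$benzene, wide$toluene)
})

test_that("window-average spearman reproduces the configured block structure", {
  # full 14-VOC panel: 21 within-block and 49 cross pairs, so the block
  # means average over enough entries to beat region-level sampling noise
  cfg <- study_config(n_mothers = 2000)
  sim <- simulate_study(cfg, seed = 12)
  avg <- window_averages(sim$cohort, sim$exposure)
  rho <- spearman_voc_matrix(avg, "preconception")
  blk <- cfg$voc_block
  off <- setdiff(cfg$vocs, blk)
  in_block <- rho[blk, blk][upper.tri(diag(length(blk)))]
  cross <- rho[blk, off]
  expect_lt(abs(mean(in_block) - cfg$block_correlation), 0.1)
  expect_lt(abs(mean(cross) - cfg$background_correlation), 0.1)
})
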