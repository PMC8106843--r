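sim_clustered <- function(n = 900, g = 12, re_sd = 0.4, seed = 21) {
  set.seed(seed)
  d <- tibble::tibble(
    region_id = sample(sprintf("R%02d", 1:g), n, TRUE),
    mother_id = sprintf("M%04d", seq_len(n)),
    x = rnorm(n),
    grp = factor(sample(c("a", "b", "c"), n, TRUE))
  )
  u <- setNames(rnorm(g, 0, re_sd), sprintf("R%02d", 1:g))
  eta <- -1.5 + 0.8 * d$x + 0.5 * (d$grp == "b") - 0.3 * (d$grp == "c") +
    u[d$region_id]
  d$y <- runif(n) < plogis(eta)
  d
}

test_that("laplace fit agrees with an independent glmer fit", {
  d <- sim_clustered()
  fit <- fit_hier_logit(d, y ~ x + grp)
  ref <- lme4::glmer(y ~ x + grp + (1 | region_id),
    data = d, family = binomial(), nAGQ = 1
  )
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(fit$re_sd, unname(attr(lme4::VarCorr(ref)$region_id, "stddev")),
    tolerance = 1e-2
  )
  expect_true(fit$converged)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(tidy(fit)$or, exp(tidy(fit)$estimate))
})

test_that("robust covariance is symmetric PSD and order-invariant", {
  d <- sim_clustered(seed = 22)
  fit <- fit_hier_logit(d, y ~ x + grp)
  v <- fit$vcov_robust
  expect_equal(v, t(v))
  expect_true(all(eigen(v, symmetric = TRUE, only.values = TRUE)$values > -1e-12))

  perm <- sample(nrow(d))
  fit_p <- fit_hier_logit(d[perm, ], y ~ x + grp)
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-6)
  expect_equal(sqrt(diag(fit$vcov_robust)), sqrt(diag(fit_p$vcov_robust)),
    tolerance = 1e-6
  )
})

test_that("repeat mothers change the clustered variance, singletons do not", {
  d <- sim_clustered(seed = 23)
  # duplicate a third of the records under their mother id: clustering must
  # matter once clusters are real
  dup <- d[sample(nrow(d), 300), ]
  d2 <- dplyr::bind_rows(d, dup)
  fit_cl <- fit_hier_logit(d2, y ~ x + grp, cluster = "mother_id")
  expect_gt(
    max(abs(fit_cl$vcov_robust - fit_cl$vcov_model)) /
      max(abs(fit_cl$vcov_model)),
    1e-4
  )
  expect_equal(fit_cl$n_clusters, dplyr::n_distinct(d2$mother_id))
})

test_that("complete separation is reported with the offending term", {
  d <- sim_clustered(seed = 24)
  d$sep <- factor(ifelse(d$y, "hi", "lo"))
  expect_error(
    fit_hier_logit(d, y ~ sep + x),
    "separation.*sep"
  )
})

test_that("fixing the random-intercept variance reduces to plain logit", {
  d <- sim_clustered(re_sd = 0, seed = 25)
  fit0 <- fit_hier_logit(d, y ~ x + grp, re_variance = 0)
  g <- glm(y ~ x + grp, data = d, family = binomial(),
    control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit0$coefficients), unname(coef(g)), tolerance = 1e-5)
  expect_error(
    fit_hier_logit(d, y ~ x, re_variance = 0, method = "pirls"),
    "laplace"
  )
})

test_that("BH step-up matches hand examples and the brute-force oracle", {
  got <- bh_adjust(c(0.01, 0.02, 0.2), q = 0.1)
  expect_equal(got$significant, c(TRUE, TRUE, FALSE))
  expect_equal(bh_adjust(rep(1, 5))$significant, rep(FALSE, 5))
  expect_equal(bh_adjust(rep(0, 5))$significant, rep(TRUE, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (i in 1:50) {
    p <- round(runif(sample(1:12, 1)), 3)
    expect_identical(bh_adjust(p, q = 0.1)$significant, oracle_bh(p, 0.1))
  }
})

test_that("joint model results carry per-window BH families and n by category", {
  imps <- impute_bmi(tiny_sim$cohort, m = 2, seed = 3)
  fj <- fit_joint_models(imps, tiny_joint, method = "pirls")
  expect_equal(nrow(fj$results), 2 * 2 * 3) # voc x window x contrast
  expect_setequal(
    unique(fj$results$category),
    c("LowVOC_NoEnclave", "HighVOC_Enclave", "HighVOC_NoEnclave")
  )
  # n per category matches the joint table
  r1 <- fj$results[1, ]
  expect_equal(
    r1$n,
    sum(tiny_joint$voc == r1$voc & tiny_joint$window == r1$window &
      tiny_joint$category == r1$category)
  )
  expect_length(fj$models, 4)
  expect_s3_class(fj$models[[1]], "evoc_pooled")
  # BH decisions recompute within window families
  for (w in unique(fj$results$window)) {
    sub <- fj$results[fj$results$window == w, ]
    expect_identical(sub$bh_significant, oracle_bh(sub$p.value, 0.1))
  }
})

test_that("component sensitivity models have the stated contrast structure", {
  cm <- attach_enclave_covariates(tiny_sim$cohort, tiny_labels, tiny_levels)
  imps <- impute_bmi(cm, m = 2, seed = 4)
  comp <- fit_component_models(imps, method = "pirls")
  expect_named(comp, c("enclave", "density", "dissimilarity", "isolation"))
  n_contrasts <- vapply(comp, function(m) {
    sum(grepl("enclave|tertile", names(m$coefficients)))
  }, integer(1))
  expect_equal(unname(n_contrasts), c(1L, 2L, 2L, 2L))
  # benzene adjustment terms present in every model
  for (m in comp) {
    expect_true(any(grepl("benzene_preconception", names(m$coefficients))))
    expect_true(any(grepl("benzene_first_trimester", names(m$coefficients))))
  }
})

test_that("PCA multi-VOC selection and the all-high rule behave as stated", {
  # 14 perfectly correlated VOCs: every VOC selected, flag equals any one VOC
  set.seed(51)
  base_val <- runif(300)
  avg <- tidyr::expand_grid(
    pregnancy_id = sprintf("P%03d", 1:300), voc = voc_names(),
    window = c("preconception", "first_trimester")
  ) |>
    dplyr::mutate(
      mean_ppb = rep(base_val, each = 28) * (1 + match(voc, voc_names())),
      n_points = 1
    )
  lv <- dichotomize_high(avg)
  cohort <- tibble::tibble(
    pregnancy_id = sprintf("P%03d", 1:300), region_id = "R1", period = "census2000"
  )
  labels <- tibble::tibble(
    region_id = "R1", period = "census2000", is_enclave = FALSE
  )
  hm <- high_multiple_voc(avg, lv, labels, cohort)
  expect_setequal(hm$selected, voc_names())
  one <- lv |>
    dplyr::filter(voc == "benzene", window == "preconception")
  got <- hm$flags |>
    dplyr::filter(window == "preconception") |>
    dplyr::arrange(pregnancy_id)
  expect_identical(
    got$high_multiple,
    (one$level == "high")[order(one$pregnancy_id)]
  )

  # high on 6 of 7 selected VOCs is not flagged: brute-force all-high rule
  lv2 <- lv |>
    dplyr::mutate(level = replace(
      level, pregnancy_id == "P001" & voc == "toluene", factor("low", levels(level))
    ))
  hm2 <- high_multiple_voc(avg, lv2, labels, cohort)
  brute <- lv2 |>
    dplyr::filter(voc %in% hm2$selected) |>
    dplyr::group_by(pregnancy_id, window) |>
    dplyr::summarise(flag = all(level == "high"), .groups = "drop")
  joined <- dplyr::inner_join(hm2$flags, brute, by = c("pregnancy_id", "window"))
  expect_identical(joined$high_multiple, joined$flag)

  # independent VOCs select nothing and error with diagnostics
  avg_ind <- dplyr::mutate(avg, mean_ppb = runif(dplyr::n()))
  lv_ind <- dichotomize_high(avg_ind)
  expect_error(
    high_multiple_voc(avg_ind, lv_ind, labels, cohort),
    "fewer than 2"
  )
})
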