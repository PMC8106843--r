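#' Random-intercept logistic regression with mother-clustered robust errors
#'
#' Fits a logistic regression with a region-level random intercept (women
#' nested in regions) by Laplace-approximate maximum likelihood, then applies
#' a cluster sandwich on the mother identifier so repeat births to the same
#' mother do not understate uncertainty. The sandwich uses fixed-effect
#' scores conditional on the fitted random intercepts around the model-based
#' fixed-effect covariance.
#'
#' @param data Data frame with the outcome, covariates, `region` and
#'   `cluster` columns.
#' @param formula Fixed-effects formula, e.g.
#'   `gdm ~ category + age_years + ...`; the random intercept is added
#'   internally.
#' @param region Name of the region (random-intercept) column.
#' @param cluster Name of the cluster column for the sandwich (mother id).
#' @param method `"laplace"` (glmmTMB, default) or `"pirls"` (lme4 `nAGQ = 0`,
#'   a fast approximation used for large simulation studies; fixed effects
#'   typically agree with Laplace to well under 1%).
#' @param cadjust Apply the `G/(G-1)` small-sample cluster correction
#'   (default `FALSE`, i.e. CR0, so singleton clusters reduce exactly to
#'   HC0 heteroskedasticity-robust errors).
#' @param re_variance `NULL` (default) to estimate the random-intercept
#'   variance by maximum likelihood, or a fixed nonnegative value to
#'   condition on (0 reduces the model to a plain logistic regression;
#'   Laplace method only).
#' @return An `evoc_fit` object: coefficients, model-based and cluster-robust
#'   covariance, random-intercept sd, convergence flag, sizes. Use [tidy()]
#'   for odds ratios with confidence intervals.
#' @export
fit_hier_logit <- function(data, formula, region = "region_id",
                           cluster = "mother_id",
                           method = c("laplace", "pirls"),
                           cadjust = FALSE, re_variance = NULL) {
  method <- match.arg(method)
  if (!is.null(re_variance) && method != "laplace") {
    abort("fixing `re_variance` is only supported with method = 'laplace'")
  }
  check_columns(data, c(region, cluster), "`data`")
  vars <- all.vars(formula)
  check_columns(data, vars, "`data`")
  y <- data[[vars[1]]]
  if (anyNA(y) || !all(as.numeric(y) %in% c(0, 1))) {
    abort("outcome must be binary (0/1 or logical) with no missing values")
  }
  if (dplyr::n_distinct(data[[region]]) < 2) {
    abort("need at least 2 regions for a region random intercept")
  }
  # the leading RHS term is the exposure: empty categories are an error
  # there; other factors just drop unused levels
  exposure_var <- vars[2]
  if (is.factor(data[[exposure_var]]) || is.character(data[[exposure_var]])) {
    tab <- table(factor(data[[exposure_var]]))
    if (any(tab == 0)) {
      abort(paste0(
        "empty exposure category in `", exposure_var, "`: ",
        paste(names(tab)[tab == 0], collapse = ", ")
      ))
    }
  }
  for (v in vars[-1]) {
    if (is.factor(data[[v]])) data[[v]] <- droplevels(data[[v]])
  }

  full <- as.formula(paste(
    paste(deparse(formula), collapse = " "), "+ (1 |", region, ")"
  ))
  if (method == "laplace") {
    args <- list(full, data = data, family = binomial())
    if (!is.null(re_variance)) {
      stopifnot(re_variance >= 0)
      # glmmTMB's theta is log(sd); condition on the supplied variance
      log_sd <- if (re_variance == 0) log(1e-8) else log(sqrt(re_variance))
      args$start <- list(theta = log_sd)
      args$map <- list(theta = factor(NA))
    }
    fit <- do.call(glmmTMB::glmmTMB, args)
    beta <- glmmTMB::fixef(fit)$cond
    vc <- as.matrix(vcov(fit)$cond)
    re_sd <- sqrt(glmmTMB::VarCorr(fit)$cond[[region]][1])
    converged <- isTRUE(fit$fit$convergence == 0) && !isTRUE(fit$sdr$pdHess == FALSE)
    mu <- predict(fit, type = "response")
  } else {
    fit <- suppressMessages(lme4::glmer(full,
      data = data, family = binomial(), nAGQ = 0
    ))
    beta <- lme4::fixef(fit)
    vc <- as.matrix(vcov(fit))
    re_sd <- sqrt(lme4::VarCorr(fit)[[region]][1])
    # lme4's post-hoc gradient checks routinely flag clean PIRLS fits;
    # only a nonzero optimizer code marks genuine failure
    converged <- is.null(fit@optinfo$conv$lme4$code) &&
      isTRUE(fit@optinfo$conv$opt == 0)
    mu <- stats::fitted(fit)
  }

  sep <- abs(beta) > 12
  if (any(sep[-1])) {
    abort(paste0(
      "apparent complete separation in covariate term(s): ",
      paste(names(beta)[-1][sep[-1]], collapse = ", ")
    ))
  }
  if (!converged) {
    warn("model fit did not converge cleanly; result flagged (converged = FALSE)")
  }

  x <- model.matrix(formula, data = data)
  stopifnot(identical(colnames(x), names(beta)))
  vr <- cluster_sandwich(x, as.numeric(y), mu, data[[cluster]], vc, cadjust)

  structure(
    list(
      coefficients = beta, vcov_model = vc, vcov_robust = vr,
      re_sd = re_sd, converged = converged,
      n = nrow(data), n_clusters = dplyr::n_distinct(data[[cluster]]),
      formula = formula, region = region, cluster = cluster, method = method
    ),
    class = "evoc_fit"
  )
}

# CR0/CR1 cluster sandwich from per-observation fixed-effect scores
# s_i = x_i (y_i - mu_i), mu conditional on the fitted random effects
cluster_sandwich <- function(x, y, mu, cluster, bread, cadjust = FALSE) {
  scores <- x * (y - mu)
  sg <- rowsum(scores, group = cluster, reorder = FALSE)
  meat <- crossprod(sg)
  g <- nrow(sg)
  if (cadjust) meat <- meat * g / (g - 1)
  v <- bread %*% meat %*% bread
  (v + t(v)) / 2
}

#' @export
print.evoc_fit <- function(x, ...) {
  cat("Random-intercept logistic fit (", x$method, ")\n", sep = "")
  cat("  n =", x$n, " clusters =", x$n_clusters,
    " RE sd =", signif(x$re_sd, 3),
    " converged =", x$converged, "\n"
  )
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate decisions
#'
#' Step-up multiple-testing control at FDR `q`: sort the p-values, find the
#' largest rank `k` with `p(k) <= k * q / m`, and reject every hypothesis
#' with rank at or below `k`.
#'
#' @param p P-values in \[0, 1\].
#' @param labels Optional test labels (default positional).
#' @param q Target false discovery rate (0.10 in this analysis).
#' @return Tibble `label`, `p`, `rank`, `bh_critical` (`rank * q / m`),
#'   `significant`, in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.2), q = 0.1)
#' @export
bh_adjust <- function(p, labels = NULL, q = 0.10) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (is.null(labels)) labels <- paste0("test", seq_along(p))
  stopifnot(length(labels) == length(p))
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  tibble::tibble(
    label = labels, p = p, rank = rk,
    bh_critical = rk * q / m,
    significant = p.adjust(p, method = "BH") <= q
  )
}

# covariate adjustment set shared by the joint-exposure models
adjustment_terms <- function() {
  c(
    "age_years", "marital_status", "insurance", "bmi_cat", "parity",
    "season", "hospital_type", "poverty_rate"
  )
}

joint_model_formula <- function(extra = "category") {
  as.formula(paste("gdm ~", paste(c(extra, adjustment_terms()), collapse = " + ")))
}

# fit + pool one model spec across a list of imputed datasets
fit_pooled <- function(imputations, formula, region, cluster, method, cadjust = FALSE) {
  fits <- lapply(imputations, fit_hier_logit,
    formula = formula, region = region, cluster = cluster,
    method = method, cadjust = cadjust
  )
  pool_rubin(fits)
}

#' Fit all per-VOC per-window joint-exposure models
#'
#' For every VOC and exposure window, merges the joint category into each
#' imputed dataset, fits the adjusted random-intercept logistic model, pools
#' across imputations by Rubin's rules, and applies Benjamini-Hochberg FDR
#' control across the joint-category contrasts within each window
#' (3 contrasts x number of VOCs per family).
#'
#' @param imputations List of completed cohort datasets from [impute_bmi()]
#'   (each must contain the outcome `gdm` and the adjustment covariates).
#' @param joint Joint categories from [joint_exposures()].
#' @param vocs,windows Which VOCs / windows to fit (default: all present).
#' @param q FDR level for [bh_adjust()].
#' @param bh_family `"window"` (default; one BH family per exposure window)
#'   or `"all"` (a single family across windows).
#' @inheritParams fit_hier_logit
#' @return List with `results` (tidy tibble: voc, window, category, n, OR,
#'   CI, p, `bh_significant`) and `models` (named list of `evoc_pooled`).
#' @export
fit_joint_models <- function(imputations, joint, vocs = NULL, windows = NULL,
                             region = "region_id", cluster = "mother_id",
                             method = c("laplace", "pirls"), q = 0.10,
                             bh_family = c("window", "all")) {
  method <- match.arg(method)
  bh_family <- match.arg(bh_family)
  check_columns(joint, c("pregnancy_id", "voc", "window", "category"), "`joint`")
  vocs <- vocs %||% unique(joint$voc)
  windows <- windows %||% unique(joint$window)
  grid <- tidyr::expand_grid(voc = vocs, window = windows)
  models <- list()
  rows <- purrr::pmap(grid, function(voc, window) {
    jc <- joint[joint$voc == voc & joint$window == window,
      c("pregnancy_id", "category")]
    if (any(table(jc$category) == 0)) {
      abort(paste0("empty joint exposure category for ", voc, "/", window))
    }
    imps <- lapply(imputations, function(d) {
      dplyr::inner_join(d, jc, by = "pregnancy_id")
    })
    pooled <- fit_pooled(imps, joint_model_formula(), region, cluster, method)
    models[[paste(voc, window, sep = ".")]] <<- pooled
    ns <- table(jc$category)
    tidy(pooled) |>
      dplyr::filter(grepl("^category", .data$term)) |>
      dplyr::mutate(
        voc = voc, window = window,
        category = sub("^category", "", .data$term),
        n = as.integer(ns[.data$category]),
        .before = 1
      )
  })
  results <- dplyr::bind_rows(rows)
  fam <- if (bh_family == "window") results$window else "all"
  results <- results |>
    dplyr::group_by(fam = fam) |>
    dplyr::mutate(bh_significant = bh_adjust(.data$p.value, q = q)$significant) |>
    dplyr::ungroup() |>
    dplyr::select(-"fam")
  list(results = results, models = models)
}

#' Enclave and component-measure sensitivity models
#'
#' Fits the four sensitivity models that unpack the enclave definition: the
#' binary enclave indicator (non-enclave reference) and each component
#' tertile (API density, dissimilarity, isolation; low reference), each
#' adjusted for the standard covariates plus dichotomized preconception and
#' first-trimester benzene.
#'
#' @param imputations List of completed cohort datasets; each must carry
#'   `is_enclave`, the three `*_tertile` factors, and `benzene_preconception`
#'   / `benzene_first_trimester` high/low factors (see
#'   [attach_enclave_covariates()]).
#' @inheritParams fit_hier_logit
#' @return Named list of four `evoc_pooled` models: `enclave`, `density`,
#'   `dissimilarity`, `isolation`.
#' @export
fit_component_models <- function(imputations, region = "region_id",
                                 cluster = "mother_id",
                                 method = c("laplace", "pirls")) {
  method <- match.arg(method)
  needed <- c(
    "is_enclave", "density_tertile", "dissimilarity_tertile",
    "isolation_tertile", "benzene_preconception", "benzene_first_trimester"
  )
  check_columns(imputations[[1]], needed, "`imputations[[1]]`")
  specs <- c(
    enclave = "enclave", density = "density_tertile",
    dissimilarity = "dissimilarity_tertile", isolation = "isolation_tertile"
  )
  base <- paste(
    c(adjustment_terms(), "benzene_preconception", "benzene_first_trimester"),
    collapse = " + "
  )
  lapply(specs, function(term) {
    imps <- lapply(imputations, function(d) {
      d$enclave <- factor(ifelse(d$is_enclave, "yes", "no"), levels = c("no", "yes"))
      d
    })
    f <- as.formula(paste("gdm ~", term, "+", base))
    fit_pooled(imps, f, region, cluster, method)
  })
}

#' High-multiple-VOC mixture flag via principal component analysis
#'
#' Identifies the subset of VOCs that move together by PCA on the
#' standardized per-pregnancy window-average matrix: VOCs whose first
#' principal component correlation (loading scaled by the component standard
#' deviation) is at least `loading_threshold` in absolute value, in every
#' requested window, form the selected set. A pregnancy is flagged "high
#' multiple VOC" in a window only when it is high on *all* selected VOCs.
#' Joint categories are rebuilt against a Not-High/Enclave reference and,
#' when imputed cohorts are supplied, the adjusted model is fitted per
#' window.
#'
#' @param averages Window averages from [window_averages()].
#' @param levels Dichotomized levels from [dichotomize_high()].
#' @param labels Enclave labels (see [joint_exposures()]).
#' @param cohort Cohort table (`pregnancy_id`, `region_id`, `period`).
#' @param imputations Optional list of completed datasets; if supplied the
#'   per-window models are fitted and pooled.
#' @param windows Exposure windows to use (selection must agree across them).
#' @param loading_threshold Minimum absolute first-component correlation.
#' @inheritParams fit_hier_logit
#' @return List: `selected` (VOC names), `loadings` (per-window component
#'   correlations), `flags` (pregnancy x window logical `high_multiple`),
#'   `joint` (categories), `models` (named list of `evoc_pooled`, possibly
#'   empty).
#' @export
high_multiple_voc <- function(averages, levels, labels, cohort,
                              imputations = NULL,
                              windows = c("preconception", "first_trimester"),
                              loading_threshold = 0.4,
                              region = "region_id", cluster = "mother_id",
                              method = c("laplace", "pirls")) {
  method <- match.arg(method)
  loadings <- lapply(setNames(windows, windows), function(w) {
    wide <- averages |>
      dplyr::filter(.data$window == w) |>
      tidyr::pivot_wider(
        id_cols = "pregnancy_id", names_from = "voc", values_from = "mean_ppb"
      )
    m <- as.matrix(wide[-1])
    pc <- prcomp(m, center = TRUE, scale. = TRUE)
    # component correlations: eigenvector entries scaled by component sd
    sort(abs(pc$rotation[, 1] * pc$sdev[1]), decreasing = TRUE)
  })
  per_window <- lapply(loadings, function(l) names(l)[l >= loading_threshold])
  selected <- Reduce(intersect, per_window)
  if (length(selected) < 2) {
    abort(paste0(
      "fewer than 2 VOCs selected at loading threshold ", loading_threshold,
      "; first-component correlations:\n",
      paste(vapply(names(loadings), function(w) {
        paste0(w, ": ", paste(names(loadings[[w]]), round(loadings[[w]], 2),
          sep = "=", collapse = ", "
        ))
      }, character(1)), collapse = "\n")
    ))
  }

  flags <- levels |>
    dplyr::filter(.data$voc %in% selected, .data$window %in% windows) |>
    dplyr::group_by(.data$pregnancy_id, .data$window) |>
    dplyr::summarise(
      high_multiple = all(.data$level == "high"), .groups = "drop"
    )

  enclave <- cohort |>
    dplyr::select("pregnancy_id", "region_id", "period") |>
    dplyr::left_join(labels[c("region_id", "period", "is_enclave")],
      by = c("region_id", "period")
    )
  joint <- flags |>
    dplyr::inner_join(enclave[c("pregnancy_id", "is_enclave")], by = "pregnancy_id") |>
    dplyr::mutate(category = factor(
      paste0(
        ifelse(.data$high_multiple, "HighMultiVOC", "NotHighMultiVOC"), "_",
        ifelse(.data$is_enclave, "Enclave", "NoEnclave")
      ),
      levels = c(
        "NotHighMultiVOC_Enclave", "NotHighMultiVOC_NoEnclave",
        "HighMultiVOC_Enclave", "HighMultiVOC_NoEnclave"
      )
    ))

  models <- list()
  if (!is.null(imputations)) {
    for (w in windows) {
      jc <- joint[joint$window == w, c("pregnancy_id", "category")]
      imps <- lapply(imputations, function(d) {
        dplyr::inner_join(d, jc, by = "pregnancy_id")
      })
      models[[w]] <- fit_pooled(
        imps, joint_model_formula(), region, cluster, method
      )
    }
  }
  list(
    selected = selected, loadings = loadings, flags = flags,
    joint = joint, models = models
  )
}
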