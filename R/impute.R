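#' BMI category bounds
#'
#' Cuts numeric pre-pregnancy BMI into the four analysis categories:
#' underweight (< 18.5), normal (18.5 to < 25, the reference), overweight
#' (25 to < 30), obese (>= 30).
#'
#' @param bmi Numeric BMI (kg/m^2), `NA` allowed.
#' @return Factor with levels `normal`, `underweight`, `overweight`, `obese`
#'   (reference first).
#' @examples
#' bmi_category(c(17, 22, 27, 33, NA))
#' @export
bmi_category <- function(bmi) {
  out <- cut(bmi,
    breaks = c(-Inf, 18.5, 25, 30, Inf),
    labels = c("underweight", "normal", "overweight", "obese"),
    right = FALSE
  )
  stats::relevel(out, ref = "normal")
}

#' Multiple imputation of BMI category
#'
#' Fills missing BMI categories by multiple imputation: within each of `m`
#' imputations, a multinomial logistic model for the observed BMI categories
#' is fitted on a bootstrap resample of the complete cases (so imputation
#' parameters vary across imputations), and each missing record's category is
#' drawn from its predicted distribution. Observed values are never altered.
#'
#' @param data Data frame containing `bmi_cat` (factor with `NA` for
#'   missing) and the predictors in `formula`.
#' @param m Number of imputations (>= 2), 10 by convention here.
#' @param formula Imputation model; default
#'   `bmi_cat ~ age_years + parity + insurance + marital_status`.
#' @param seed Optional integer seed fixing all draws.
#' @return List of `m` completed data frames (class `evoc_mi`), each with
#'   `bmi_cat` complete.
#' @export
impute_bmi <- function(data, m = 10,
                       formula = bmi_cat ~ age_years + parity + insurance + marital_status,
                       seed = NULL) {
  if (m < 2) abort("`m` must be at least 2")
  check_columns(data, "bmi_cat", "`data`")
  check_columns(data, all.vars(formula)[-1], "`data`")
  miss <- is.na(data$bmi_cat)
  if (all(miss)) abort("all BMI values are missing; nothing to fit the imputation model on")
  if (!is.null(seed)) set.seed(seed)
  if (!any(miss)) {
    out <- replicate(m, data, simplify = FALSE)
    class(out) <- c("evoc_mi", class(out))
    return(out)
  }
  obs <- data[!miss, , drop = FALSE]
  obs$bmi_cat <- droplevels(obs$bmi_cat)
  lev <- levels(data$bmi_cat)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    boot <- obs[sample.int(nrow(obs), replace = TRUE), , drop = FALSE]
    fit <- nnet::multinom(formula, data = boot, trace = FALSE, maxit = 200)
    pr <- predict(fit, newdata = data[miss, , drop = FALSE], type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, ncol = length(fit$lev), byrow = FALSE)
    draw <- apply(pr, 1, function(p) sample(fit$lev, 1, prob = p))
    completed <- data
    completed$bmi_cat[miss] <- factor(draw, levels = lev)
    out[[i]] <- completed
  }
  class(out) <- c("evoc_mi", class(out))
  out
}

#' Pool fitted models across imputations by Rubin's rules
#'
#' Combines `m` fits of the same model on multiply-imputed datasets: pooled
#' coefficients are the mean, total variance is the mean within-imputation
#' (robust) variance plus `(1 + 1/m)` times the between-imputation variance,
#' and confidence intervals / p-values use Rubin's degrees of freedom
#' `(m - 1) * (1 + W / ((1 + 1/m) B))^2` per coefficient (infinite, hence
#' normal, when the between-variance is zero).
#'
#' @param fits List of [fit_hier_logit()] results on identical formulas.
#' @param conf_level Confidence level for pooled intervals.
#' @return An object of class `evoc_pooled`; see [tidy.evoc_pooled()].
#' @export
pool_rubin <- function(fits, conf_level = 0.95) {
  if (length(fits) < 2) abort("need at least 2 fitted models to pool")
  if (!all(vapply(fits, inherits, logical(1), "evoc_fit"))) {
    abort("`fits` must be a list of evoc_fit objects")
  }
  terms_list <- lapply(fits, function(f) names(f$coefficients))
  if (!all(vapply(terms_list, identical, logical(1), terms_list[[1]]))) {
    abort("mismatched model formulas/terms across imputations")
  }
  m <- length(fits)
  cf <- do.call(rbind, lapply(fits, function(f) f$coefficients))
  qbar <- colMeans(cf)
  w_mat <- Reduce(`+`, lapply(fits, function(f) f$vcov_robust)) / m
  centered <- sweep(cf, 2, qbar)
  b_mat <- crossprod(centered) / (m - 1)
  t_mat <- w_mat + (1 + 1 / m) * b_mat
  w <- diag(w_mat)
  b <- diag(b_mat)
  df <- ifelse(b > 0, (m - 1) * (1 + w / ((1 + 1 / m) * b))^2, Inf)
  se <- sqrt(diag(t_mat))
  tq <- ifelse(is.finite(df), qt(1 - (1 - conf_level) / 2, df),
    qnorm(1 - (1 - conf_level) / 2)
  )
  stat <- qbar / se
  p <- ifelse(is.finite(df), 2 * pt(-abs(stat), df), 2 * pnorm(-abs(stat)))
  structure(
    list(
      coefficients = qbar, se = se, vcov = t_mat,
      within = w, between = b, df = df, statistic = stat, p.value = p,
      conf_low = qbar - tq * se, conf_high = qbar + tq * se,
      m = m, conf_level = conf_level,
      n = fits[[1]]$n, n_clusters = fits[[1]]$n_clusters,
      formula = fits[[1]]$formula,
      re_sd = mean(vapply(fits, function(f) f$re_sd, numeric(1))),
      converged = all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))
    ),
    class = "evoc_pooled"
  )
}

#' @export
print.evoc_pooled <- function(x, ...) {
  cat("Pooled random-intercept logistic fit (", x$m, " imputations)\n", sep = "")
  cat("  n =", x$n, " clusters =", x$n_clusters,
    " mean RE sd =", signif(x$re_sd, 3), "\n"
  )
  print(tidy(x), n = Inf)
  invisible(x)
}
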