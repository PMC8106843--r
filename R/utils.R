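#' Round half away from zero
#'
#' Fixed-precision rounding with the "half up" tie rule used for printed
#' percentages (base `round()` rounds half to even, which does not match
#' frequency-table conventions).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(0.125, 7.45), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared column-presence check with a caller-facing message
check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# linear-interpolation sample quantile, optionally weighted.
# Unweighted is stats::quantile type 7; the weighted form interpolates the
# weighted ecdf on the (n-1)-spaced plotting positions so that equal weights
# reduce to type 7 exactly.
weighted_quantile <- function(x, probs, weights = NULL) {
  if (is.null(weights)) {
    return(unname(quantile(x, probs, type = 7, names = FALSE)))
  }
  stopifnot(length(weights) == length(x), all(weights >= 0), sum(weights) > 0)
  ord <- order(x)
  x <- x[ord]
  w <- weights[ord]
  # cumulative weight positions mapped to [0, 1] like type-7 positions
  cw <- cumsum(w) - w / 2
  pos <- (cw - cw[1]) / (cw[length(cw)] - cw[1])
  vapply(probs, function(p) {
    if (p <= pos[1]) return(x[1])
    if (p >= pos[length(pos)]) return(x[length(x)])
    stats::approx(pos, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

# matrix square root via eigendecomposition: z %*% corr_sqrt(S) has
# covariance S even when S is singular (perfectly correlated blocks)
corr_sqrt <- function(s) {
  ev <- eigen(s, symmetric = TRUE)
  sqrt(pmax(ev$values, 0)) * t(ev$vectors)
}

# Dirichlet draws via independent gammas; rows are draws
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n, byrow = TRUE)
  g[g == 0] <- .Machine$double.xmin # guard all-zero rows at tiny alpha
  g / rowSums(g)
}
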