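# Shared fixtures: a small synthetic study reused across test files, plus
# hand-rolled oracles kept independent of the package implementation.

tiny_config <- function(...) {
  study_config(
    n_regions = 12, units_per_region = 10, n_mothers = 1800,
    vocs = c("benzene", "toluene"), voc_block = c("benzene", "toluene"),
    conception_range = as.Date(c("2004-01-01", "2005-06-01")),
    ...
  )
}

# computed once per test run; seed chosen up front for the whole suite
tiny_sim <- simulate_study(tiny_config(), seed = 5)
tiny_profiles <- region_profiles(tiny_sim$units, tiny_sim$crosswalk, tiny_sim$poverty)
tiny_labels <- tiny_profiles |>
  dplyr::group_split(period) |>
  purrr::map(classify_enclaves) |>
  dplyr::bind_rows()
tiny_averages <- window_averages(tiny_sim$cohort, tiny_sim$exposure)
tiny_levels <- dichotomize_high(tiny_averages)
tiny_joint <- joint_exposures(tiny_sim$cohort, tiny_levels, tiny_labels)

# independent linear-interpolation quantile (type 7 definition, written from
# the h = (n-1)p + 1 formula rather than stats::quantile)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force BH step-up: largest k with p(k) <= k q / m, scanning all k
oracle_bh <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  ks <- which(s <= seq_len(m) * q / m)
  if (length(ks) == 0) {
    return(rep(FALSE, m))
  }
  p <= s[max(ks)]
}

# build a minimal evoc_fit by hand for pooling tests
fake_fit <- function(coefs, vars, terms = names(coefs)) {
  names(coefs) <- terms
  structure(
    list(
      coefficients = coefs,
      vcov_robust = diag(vars, nrow = length(coefs)),
      re_sd = 0, converged = TRUE, n = 100, n_clusters = 100,
      formula = y ~ x, method = "laplace"
    ),
    class = "evoc_fit"
  )
}

# random valid region-count tables for property tests
random_region <- function(n_units = NULL) {
  n <- n_units %||% sample(2:8, 1)
  pop <- sample(50:500, n, replace = TRUE)
  api <- vapply(pop, function(p) sample.int(p, 1), integer(1))
  white <- vapply(pop - api, function(p) if (p == 0) 0L else sample.int(p, 1), integer(1))
  list(api = api, white = white, pop = pop)
}
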