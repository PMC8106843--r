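#' Read analysis input tables
#'
#' Schema-validated CSV readers for the three input tables. Dates are
#' ISO-8601, missing values are empty fields, and violations are reported
#' with their row number.
#'
#' @param path CSV file path.
#' @return A typed tibble.
#' @name readers
NULL

#' @rdname readers
#' @export
read_units <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(d, c("unit_id", "api_count", "white_count", "total_pop"),
    paste0("`", path, "`"))
  for (col in c("api_count", "white_count", "total_pop")) {
    bad <- which(is.na(d[[col]]) | d[[col]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("%s: missing/negative %s at row %d", path, col, bad[1]))
    }
  }
  over <- which(d$api_count > d$total_pop | d$white_count > d$total_pop)
  if (length(over) > 0) {
    abort(sprintf("%s: group count exceeds total_pop at row %d", path, over[1]))
  }
  d
}

#' @rdname readers
#' @export
read_crosswalk <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(d, c("unit_id", "region_id"), paste0("`", path, "`"))
  d
}

#' @rdname readers
#' @export
read_cohort <- function(path) {
  d <- readr::read_csv(path,
    show_col_types = FALSE,
    col_types = readr::cols(
      conception_date = readr::col_date(), delivery_date = readr::col_date()
    )
  )
  check_columns(d, c(
    "pregnancy_id", "mother_id", "region_id", "conception_date",
    "delivery_date", "gdm", "age_years", "marital_status", "insurance",
    "bmi", "parity", "hospital_type", "poverty_rate"
  ), paste0("`", path, "`"))
  for (col in c("conception_date", "delivery_date")) {
    bad <- which(is.na(d[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("%s: unparseable or missing %s at row %d", path, col, bad[1]))
    }
  }
  bad_age <- which(is.na(d$age_years) | d$age_years <= 0)
  if (length(bad_age) > 0) {
    abort(sprintf("%s: nonpositive/missing age_years at row %d", path, bad_age[1]))
  }
  if (anyDuplicated(d$pregnancy_id)) abort(sprintf("%s: duplicate pregnancy_id", path))
  d |>
    dplyr::mutate(
      gdm = as.logical(.data$gdm),
      season = season_of(.data$conception_date),
      period = period_of(.data$delivery_date),
      bmi_cat = bmi_category(.data$bmi),
      dplyr::across(
        c("marital_status", "insurance", "parity", "hospital_type"), as.factor
      )
    )
}

#' @rdname readers
#' @export
read_exposure <- function(path) {
  d <- readr::read_csv(path,
    show_col_types = FALSE,
    col_types = readr::cols(date = readr::col_date())
  )
  check_columns(d, c("region_id", "voc", "date", "ppb"), paste0("`", path, "`"))
  bad <- which(is.na(d$ppb) | d$ppb < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: missing/negative ppb at row %d", path, bad[1]))
  }
  bad_date <- which(is.na(d$date))
  if (length(bad_date) > 0) {
    abort(sprintf("%s: unparseable date at row %d", path, bad_date[1]))
  }
  d
}

#' Write simulated inputs to CSV
#'
#' Serializes a [simulate_study()] result to the pipeline's three input CSVs
#' (plus the crosswalk and poverty tables) and a `truth.json` ground-truth
#' file, so a simulated study can be round-tripped through [run_pipeline()].
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulated_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    units = file.path(dir, "units.csv"),
    crosswalk = file.path(dir, "crosswalk.csv"),
    poverty = file.path(dir, "poverty.csv"),
    cohort = file.path(dir, "cohort.csv"),
    exposure = file.path(dir, "exposure.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(sim$units, paths["units"])
  readr::write_csv(sim$crosswalk, paths["crosswalk"])
  readr::write_csv(sim$poverty, paths["poverty"])
  cohort_cols <- c(
    "pregnancy_id", "mother_id", "region_id", "conception_date",
    "delivery_date", "gdm", "age_years", "marital_status", "insurance",
    "bmi", "parity", "hospital_type", "poverty_rate"
  )
  readr::write_csv(sim$cohort[cohort_cols], paths["cohort"])
  readr::write_csv(sim$exposure, paths["exposure"])
  jsonlite::write_json(
    list(
      true_log_ors = as.list(sim$truth$true_log_ors),
      baseline_gdm_logit = sim$truth$baseline_gdm_logit,
      random_intercept_sd = sim$truth$random_intercept_sd,
      designated_enclaves = sim$regions$region_id[sim$regions$designated_enclave]
    ),
    paths["truth"],
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Configuration for a pipeline run
#'
#' @param units,crosswalk,cohort,exposure,poverty Input CSV paths.
#' @param out_dir Output directory for report CSVs and the run log.
#' @param vocs VOCs to model (default: all present in the exposure file).
#' @param windows Exposure windows.
#' @param m Number of BMI imputations.
#' @param q FDR level.
#' @param seed Integer seed (imputation draws).
#' @param method Model fitting method, see [fit_hier_logit()].
#' @param weighting Tertile weighting, see [classify_enclaves()].
#' @return A `evoc_run_config` list.
#' @export
run_config <- function(units, crosswalk, cohort, exposure, poverty = NULL,
                       out_dir = "results", vocs = NULL,
                       windows = c("preconception", "first_trimester"),
                       m = 10, q = 0.10, seed = 1,
                       method = c("laplace", "pirls"),
                       weighting = c("none", "population")) {
  structure(
    list(
      units = units, crosswalk = crosswalk, cohort = cohort,
      exposure = exposure, poverty = poverty, out_dir = out_dir,
      vocs = vocs, windows = windows, m = m, q = q, seed = seed,
      method = match.arg(method), weighting = match.arg(weighting)
    ),
    class = "evoc_run_config"
  )
}

#' Run the full joint-exposure analysis pipeline
#'
#' Executes the stages in order -- segregation profiles, enclave
#' classification (per census period), exposure-window averaging and
#' dichotomization, joint categories, tabulations, multiple imputation,
#' per-VOC hierarchical models with Rubin pooling and BH-FDR -- and writes
#' the report CSVs plus a machine-readable run log (seed, config hash,
#' package versions; no timestamps, so reruns are byte-identical).
#'
#' @param config An `evoc_run_config` from [run_config()].
#' @return Invisibly, a result bundle: `profiles`, `labels`, `averages`,
#'   `levels`, `spearman`, `joint`, `tab_enclave`, `tab_joint`, `results`,
#'   `models`, `paths`.
#' @export
run_pipeline <- function(config) {
  in_paths <- unlist(config[c("units", "crosswalk", "cohort", "exposure", "poverty")])
  missing <- in_paths[!file.exists(in_paths)]
  if (length(missing) > 0) {
    abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  units <- stage("read", read_units(config$units))
  crosswalk <- stage("read", read_crosswalk(config$crosswalk))
  cohort <- stage("read", read_cohort(config$cohort))
  exposure <- stage("read", read_exposure(config$exposure))
  poverty <- if (!is.null(config$poverty)) stage("read", read_crosswalk_poverty(config$poverty))

  profiles <- stage("segregation", region_profiles(units, crosswalk, poverty))
  labels <- stage("enclave", {
    profiles |>
      dplyr::group_split(.data$period) |>
      purrr::map(classify_enclaves, weighting = config$weighting) |>
      dplyr::bind_rows()
  })
  averages <- stage("exposure", window_averages(cohort, exposure, config$windows))
  levels <- stage("exposure", dichotomize_high(averages))
  spear <- stage("exposure", spearman_voc_matrix(averages, config$windows[1]))
  joint <- stage("joint", joint_exposures(cohort, levels, labels))

  enclave_by_preg <- joint |>
    dplyr::distinct(.data$pregnancy_id, .data$is_enclave)
  tab_enclave <- stage("report", {
    cohort |>
      dplyr::left_join(enclave_by_preg, by = "pregnancy_id") |>
      tabulate_outcome(.data$gdm, .data$is_enclave)
  })
  tab_joint <- stage("report", {
    joint |>
      dplyr::left_join(cohort[c("pregnancy_id", "gdm")], by = "pregnancy_id") |>
      tabulate_outcome(.data$gdm, .data$voc, .data$window, .data$category)
  })

  set.seed(config$seed)
  imputations <- stage("impute", impute_bmi(cohort, m = config$m))
  fits <- stage("inference", fit_joint_models(
    imputations, joint,
    vocs = config$vocs, windows = config$windows,
    method = config$method, q = config$q
  ))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    profiles = file.path(config$out_dir, "region_profiles.csv"),
    enclaves = file.path(config$out_dir, "enclave_labels.csv"),
    averages = file.path(config$out_dir, "window_averages.csv"),
    levels = file.path(config$out_dir, "exposure_levels.csv"),
    spearman = file.path(config$out_dir, "voc_spearman.csv"),
    tab_enclave = file.path(config$out_dir, "gdm_by_enclave.csv"),
    tab_joint = file.path(config$out_dir, "gdm_by_joint_category.csv"),
    results = file.path(config$out_dir, "model_results.csv"),
    log = file.path(config$out_dir, "run_log.json")
  )
  readr::write_csv(profiles, paths["profiles"])
  readr::write_csv(labels, paths["enclaves"])
  readr::write_csv(averages, paths["averages"])
  readr::write_csv(dplyr::select(levels, -"cutoff_ppb"), paths["levels"])
  readr::write_csv(
    tibble::as_tibble(spear, rownames = "voc"), paths["spearman"]
  )
  readr::write_csv(tab_enclave, paths["tab_enclave"])
  readr::write_csv(tab_joint, paths["tab_joint"])
  readr::write_csv(fits$results, paths["results"])

  cfg_plain <- unclass(config)
  jsonlite::write_json(
    list(
      seed = config$seed,
      config = cfg_plain,
      config_hash = unname(tools::md5sum(
        textConnection2file(jsonlite::toJSON(cfg_plain, auto_unbox = TRUE))
      )),
      versions = list(
        r = R.version.string,
        enclaveVOC = as.character(utils::packageVersion("enclaveVOC"))
      )
    ),
    paths["log"],
    auto_unbox = TRUE, digits = NA, null = "null"
  )

  invisible(list(
    profiles = profiles, labels = labels, averages = averages,
    levels = levels, spearman = spear, joint = joint,
    tab_enclave = tab_enclave, tab_joint = tab_joint,
    results = fits$results, models = fits$models, paths = paths
  ))
}

read_crosswalk_poverty <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(d, c("region_id", "poverty_rate"), paste0("`", path, "`"))
  d
}

# md5 of an in-memory string via a temp file (tools::md5sum is file-based)
textConnection2file <- function(txt) {
  f <- tempfile(fileext = ".json")
  writeLines(txt, f)
  f
}

#' Attach enclave and benzene covariates for the sensitivity models
#'
#' Joins the period-specific enclave label, the three component tertiles,
#' and dichotomized preconception / first-trimester benzene onto a cohort
#' table, as required by [fit_component_models()].
#'
#' @param cohort Cohort tibble with `pregnancy_id`, `region_id`, `period`.
#' @param labels Enclave labels from [classify_enclaves()] (all periods).
#' @param levels Dichotomized levels from [dichotomize_high()].
#' @return `cohort` plus `is_enclave`, `*_tertile`, `benzene_preconception`,
#'   `benzene_first_trimester`.
#' @export
attach_enclave_covariates <- function(cohort, labels, levels) {
  lab_cols <- c(
    "region_id", "period", "is_enclave", "density_tertile",
    "dissimilarity_tertile", "isolation_tertile"
  )
  benz <- levels |>
    dplyr::filter(.data$voc == "benzene") |>
    dplyr::mutate(col = paste0("benzene_", .data$window)) |>
    dplyr::select("pregnancy_id", "col", "level") |>
    tidyr::pivot_wider(names_from = "col", values_from = "level")
  cohort |>
    dplyr::left_join(labels[lab_cols], by = c("region_id", "period")) |>
    dplyr::left_join(benz, by = "pregnancy_id")
}
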