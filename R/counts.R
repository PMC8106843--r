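#' Published stratum counts from the Consortium on Safe Labor API sample
#'
#' GDM / no-GDM counts for the 9069-birth Asian/Pacific Islander analytic
#' sample of the Consortium on Safe Labor, as published: cohort
#' characteristics strata (`"characteristics"`) and the joint VOC-by-enclave
#' exposure strata for both exposure windows (`"joint"`). These counts let
#' the tabulation and crude-odds-ratio operations be exercised against
#' printed reference percentages without access to the restricted
#' individual-level data.
#'
#' @param table Which count table to load.
#' @return A tibble of stratum counts with `n_gdm` and `n_no_gdm` columns.
#' @examples
#' head(csl_counts("characteristics"))
#' @export
csl_counts <- function(table = c("characteristics", "joint")) {
  table <- match.arg(table)
  file <- switch(table,
    characteristics = "csl_table2_strata.csv",
    joint = "csl_table3_joint_strata.csv"
  )
  path <- system.file("extdata", file, package = "enclaveVOC", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Expand stratum counts to one row per birth
#'
#' Turns a counts table (with `n_gdm`, `n_no_gdm`) into unit records with a
#' logical `gdm` column, so count tables can feed [tabulate_outcome()]
#' exactly like individual-level data.
#'
#' @param counts Tibble with `n_gdm` and `n_no_gdm` plus stratum columns.
#' @return Tibble with the stratum columns and one row per birth.
#' @export
counts_to_records <- function(counts) {
  check_columns(counts, c("n_gdm", "n_no_gdm"), "`counts`")
  strata <- counts[setdiff(names(counts), c("n_gdm", "n_no_gdm"))]
  idx <- rep(seq_len(nrow(counts)), counts$n_gdm + counts$n_no_gdm)
  out <- strata[idx, , drop = FALSE]
  out$gdm <- unlist(Map(
    function(g, n) rep(c(TRUE, FALSE), c(g, n)),
    counts$n_gdm, counts$n_no_gdm
  ))
  tibble::as_tibble(out)
}
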