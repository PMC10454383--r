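#' Bundled summary data from a published large-scale FMR1 WGS screen
#'
#' The package ships the published summary tables of a large
#' ExpansionHunter-based *FMR1* CGG screen of the SSC and SPARK simplex-ASD
#' cohorts (whose individual-level data are access-restricted). They allow
#' the package's statistics to be exercised and checked against the
#' published values without restricted data:
#'
#' * `study_validation_calls()` — the PCR-validation families: per-sample
#'   PCR, off-target ExpansionHunter and region-only ExpansionHunter
#'   genotypes.
#' * `study_prevalence_counts(cohort)` — per-role processed/genotyped/
#'   carrier counts.
#' * `study_transmission_counts(cohort)` — the 20 transmission-category
#'   counts with the carrier-family offspring denominator.
#'
#' @param cohort `"ssc"` or `"spark"`.
#' @return A tibble (see above).
#' @name study_data
NULL

study_file <- function(name) {
  system.file("extdata", name, package = "fmrscreen", mustWork = TRUE)
}

#' @rdname study_data
#' @export
study_validation_calls <- function() {
  tibble::as_tibble(utils::read.delim(study_file("ssc_validation_calls.tsv"),
                                      stringsAsFactors = FALSE))
}

#' @rdname study_data
#' @export
study_prevalence_counts <- function(cohort = c("ssc", "spark")) {
  cohort <- match.arg(cohort)
  tibble::as_tibble(utils::read.delim(
    study_file(paste0(cohort, "_prevalence_counts.tsv")),
    stringsAsFactors = FALSE))
}

#' @rdname study_data
#' @export
study_transmission_counts <- function(cohort = c("ssc", "spark")) {
  cohort <- match.arg(cohort)
  tab <- utils::read.delim(
    study_file(paste0(cohort, "_transmission_counts.tsv")),
    stringsAsFactors = FALSE, na.strings = "NA")
  tibble::as_tibble(tab)
}

#' Convert a validation-call table to a genotype tibble
#'
#' Parses one genotype column of [study_validation_calls()] (conventional
#' `"Y/23"` / `"29/48"` notation) into the package's normalized genotype
#' tibble so it can flow through [classify_genotypes()],
#' [callset_concordance()] and [call_transmissions()].
#'
#' @param calls A tibble with columns `sample_id`, `sex` and the chosen
#'   genotype column.
#' @param mode Which column to parse: `"pcr"`, `"eh_offtarget"` or
#'   `"eh_region_only"`.
#' @param locus Locus id to record.
#' @return A genotype tibble.
#' @export
validation_genotypes <- function(calls, mode = c("pcr", "eh_offtarget",
                                                 "eh_region_only"),
                                 locus = "FMR1") {
  mode <- match.arg(mode)
  stopifnot(all(c("sample_id", "sex", mode) %in% names(calls)))
  rows <- purrr::pmap(list(calls$sample_id, calls$sex, calls[[mode]]),
                      function(sample_id, sex, gt) {
    alleles <- parse_genotype_string(sub("^Y/", "", gt), "",
                                     sample_id, locus, sex)
    genotype_row(sample_id, locus, sex, mode, alleles)
  })
  dplyr::bind_rows(empty_genotypes(), rows)
}
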