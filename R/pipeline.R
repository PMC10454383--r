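#' Validate genotype/pedigree inputs before analysis
#'
#' Report-only QC pass: lists orphan samples (genotyped but absent from
#' the pedigree), pedigree members without a genotype record, sex
#' mismatches between pedigree and genotype records, and per-role no-call
#' rates (samples processed but without a genotype call).
#'
#' @param genotypes Genotype tibble.
#' @param pedigree Pedigree tibble.
#' @return List of class `fmr_qc`: `issues` (tibble `type`, `sample_id`,
#'   `detail`), `role_summary` (per-role processed/genotyped/no-call
#'   rate), `n_processed`, `n_genotyped`, `pct_genotyped`.
#' @export
validate_inputs <- function(genotypes, pedigree) {
  issues <- tibble::tibble(type = character(), sample_id = character(),
                           detail = character())
  orphans <- setdiff(genotypes$sample_id, pedigree$sample_id)
  if (length(orphans) > 0) {
    issues <- dplyr::bind_rows(issues, tibble::tibble(
      type = "orphan_sample", sample_id = orphans,
      detail = "genotyped but not in pedigree"))
  }
  missing <- setdiff(pedigree$sample_id, genotypes$sample_id)
  if (length(missing) > 0) {
    issues <- dplyr::bind_rows(issues, tibble::tibble(
      type = "missing_genotype", sample_id = missing,
      detail = "pedigree member without genotype record"))
  }
  joined <- dplyr::inner_join(
    pedigree[, c("sample_id", "sex", "role")],
    genotypes[, c("sample_id", "sex", "allele1")],
    by = "sample_id", suffix = c("_ped", "_gt")
  )
  bad_sex <- joined[!is.na(joined$sex_gt) & joined$sex_ped != joined$sex_gt, ]
  if (nrow(bad_sex) > 0) {
    issues <- dplyr::bind_rows(issues, tibble::tibble(
      type = "sex_mismatch", sample_id = bad_sex$sample_id,
      detail = paste0("pedigree ", bad_sex$sex_ped, " vs genotype ",
                      bad_sex$sex_gt)))
  }
  role_summary <- joined |>
    dplyr::filter(!is.na(.data$role)) |>
    dplyr::group_by(role = .data$role) |>
    dplyr::summarise(processed = dplyr::n(),
                     genotyped = sum(!is.na(.data$allele1)),
                     .groups = "drop") |>
    dplyr::mutate(no_call_rate = ifelse(.data$processed > 0,
                                        1 - .data$genotyped / .data$processed,
                                        NA_real_))
  n_processed <- nrow(joined)
  n_genotyped <- sum(!is.na(joined$allele1))
  out <- list(
    issues = issues, role_summary = role_summary,
    n_processed = n_processed, n_genotyped = n_genotyped,
    pct_genotyped = if (n_processed > 0) 100 * n_genotyped / n_processed
                    else NA_real_
  )
  class(out) <- "fmr_qc"
  out
}

#' @export
print.fmr_qc <- function(x, ...) {
  cat(sprintf("Input QC: %d samples processed, %d genotyped (%.1f%%)\n",
              x$n_processed, x$n_genotyped, x$pct_genotyped))
  if (nrow(x$issues) == 0) cat("  no issues\n") else print(x$issues)
  invisible(x)
}

# Fig-1-style re-evaluation: samples flagged as expanded under the
# primary (off-target) calls are re-genotyped with the confirmatory
# (region-only) calls before final classification. Confirmation can only
# downgrade or retain a flag, never add one.
reevaluate_flagged <- function(primary, confirm, catalog) {
  status <- classify_genotypes(primary, catalog)
  flagged <- status$sample_id[!is.na(status$is_expanded) & status$is_expanded]
  replace <- intersect(flagged, confirm$sample_id)
  out <- primary
  idx <- match(replace, out$sample_id)
  cidx <- match(replace, confirm$sample_id)
  cols <- c("call_mode", "allele1", "allele2",
            "a1_ci_lo", "a1_ci_hi", "a2_ci_lo", "a2_ci_hi")
  out[idx, cols] <- confirm[cidx, cols]
  out
}

#' Run the full family-screening analysis
#'
#' End-to-end orchestration over one cohort: input QC, optional dual-mode
#' re-evaluation (samples flagged under the primary call set are
#' re-classified from the confirmatory call set — e.g. off-target calls
#' confirmed by region-only calls — which can only downgrade or confirm a
#' flag, never add carriers), carrier classification, per-role prevalence,
#' female Hardy-Weinberg QC, transmission calling and accounting,
#' sex-stratified proband-versus-sibling burden tests, and (when a PCR or
#' second call set is supplied) call-set concordance. Stages that lack
#' their inputs are skipped with an explicit notice in the log.
#'
#' @param genotypes Primary genotype tibble.
#' @param pedigree Pedigree tibble ([read_pedigree()]); `NULL` skips all
#'   pedigree-dependent stages.
#' @param catalog A [locus_catalog()].
#' @param confirm_genotypes Optional confirmatory call set for the
#'   dual-mode re-evaluation rule.
#' @param pcr_genotypes Optional PCR call set for concordance.
#' @param cohort_id Label recorded in the manifest.
#' @param out_dir Optional directory: writes TSV reports, a JSON summary
#'   and a plain-text log.
#' @return List of class `fmr_report`: `manifest`, `qc`, `genotypes_final`,
#'   `carrier_status`, `prevalence`, `hwe`, `burden`, `transmission_calls`,
#'   `transmission`, `concordance`, `log`.
#' @export
run_full_analysis <- function(genotypes, pedigree, catalog = locus_catalog(),
                              confirm_genotypes = NULL, pcr_genotypes = NULL,
                              cohort_id = "cohort", out_dir = NULL) {
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  note("cohort: ", cohort_id, "; locus: ", catalog$locus_id,
       "; samples: ", nrow(genotypes))
  qc <- if (!is.null(pedigree)) validate_inputs(genotypes, pedigree) else NULL
  if (!is.null(qc)) {
    note(sprintf("qc: %d/%d genotyped (%.2f%%); %d issue(s)",
                 qc$n_genotyped, qc$n_processed, qc$pct_genotyped,
                 nrow(qc$issues)))
  }

  final <- genotypes
  if (!is.null(confirm_genotypes)) {
    final <- reevaluate_flagged(genotypes, confirm_genotypes, catalog)
    note("dual-mode re-evaluation applied to flagged samples")
  }
  status <- classify_genotypes(final, catalog)
  note("expanded carriers after final classification: ",
       sum(status$is_expanded, na.rm = TRUE))

  prevalence <- NULL; hwe <- NULL; burden <- NULL
  calls <- NULL; transmission <- NULL
  if (is.null(pedigree)) {
    note("pedigree missing: prevalence/transmission/burden stages skipped")
  } else {
    prevalence <- summarize_prevalence(final, pedigree, catalog)
    fem <- status[status$sex %in% "female" & !is.na(status$longest_allele), ]
    if (nrow(fem) > 0) {
      a1_exp <- classify_allele_quiet(fem$allele1, catalog) >= "premutation"
      a2_exp <- classify_allele_quiet(fem$allele2, catalog) >= "premutation"
      hwe <- hwe_female_chi2(n_het = sum(xor(a1_exp, a2_exp)),
                             n_hom_carrier = sum(a1_exp & a2_exp),
                             n_females = nrow(fem))
      note(sprintf("female HWE: chi2 = %.3f, p = %.3f", hwe$chi2, hwe$p_value))
    } else note("no genotyped females: HWE stage skipped")

    calls <- call_transmissions(final, pedigree, catalog)
    transmission <- summarize_transmissions(calls, final, pedigree, catalog,
                                            cohort_id = cohort_id)
    note(sprintf("transmission: %d carrier families, %d offspring, %d inherited, %d de novo",
                 transmission$n_carrier_families,
                 transmission$n_offspring_in_carrier_families,
                 transmission$n_transmitted, transmission$n_de_novo))

    cell <- function(role, col) {
      v <- prevalence[[col]][prevalence$role == role]
      if (length(v) == 0) 0L else v
    }
    burden <- dplyr::bind_rows(
      dplyr::mutate(tidy(fisher_burden(cell("male_proband", "carriers"),
                                       cell("male_proband", "non_carriers"),
                                       cell("male_sibling", "carriers"),
                                       cell("male_sibling", "non_carriers"))),
                    comparison = "male_proband_vs_male_sibling"),
      dplyr::mutate(tidy(fisher_burden(cell("female_proband", "carriers"),
                                       cell("female_proband", "non_carriers"),
                                       cell("female_sibling", "carriers"),
                                       cell("female_sibling", "non_carriers"))),
                    comparison = "female_proband_vs_female_sibling")
    )
    note(sprintf("burden: male OR = %.2f (p = %.2f); female OR = %.2f (p = %.2f)",
                 burden$odds_ratio[1], burden$p_value[1],
                 burden$odds_ratio[2], burden$p_value[2]))
  }

  concordance <- NULL
  second <- pcr_genotypes %||% confirm_genotypes
  if (!is.null(second)) {
    concordance <- callset_concordance(genotypes, second, catalog)
    note(sprintf("concordance: %d flagged (primary) vs %d (comparison)",
                 concordance$n_flagged_a, concordance$n_flagged_b))
  } else note("no second call set: concordance stage skipped")

  manifest <- list(
    cohort_id = cohort_id, locus_id = catalog$locus_id,
    call_modes = unique(stats::na.omit(c(genotypes$call_mode,
                                         confirm_genotypes$call_mode,
                                         pcr_genotypes$call_mode))),
    n_samples = nrow(genotypes),
    tool_version = as.character(utils::packageVersion("fmrscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  report <- list(manifest = manifest, qc = qc, genotypes_final = final,
                 carrier_status = status, prevalence = prevalence, hwe = hwe,
                 burden = burden, transmission_calls = calls,
                 transmission = transmission, concordance = concordance,
                 log = log_lines)
  class(report) <- "fmr_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.fmr_report <- function(x, ...) {
  cat("fmrscreen analysis report:", x$manifest$cohort_id, "\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

# write the report bundle: per-stage TSVs, a JSON roll-up, a log
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    if (!is.null(x)) {
      utils::write.table(x, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(report$prevalence, "prevalence.tsv")
  wt(report$burden, "burden.tsv")
  wt(report$transmission_calls, "transmission_calls.tsv")
  if (!is.null(report$transmission)) {
    wt(report$transmission$rows, "transmission_summary.tsv")
  }
  if (!is.null(report$concordance)) {
    wt(report$concordance$samples, "concordance.tsv")
  }
  if (!is.null(report$qc)) wt(report$qc$issues, "qc_issues.tsv")
  summary <- list(
    manifest = report$manifest,
    hwe = if (!is.null(report$hwe)) glance(report$hwe) else NULL,
    transmission = if (!is.null(report$transmission))
      glance(report$transmission) else NULL,
    qc = if (!is.null(report$qc))
      list(n_processed = report$qc$n_processed,
           n_genotyped = report$qc$n_genotyped,
           pct_genotyped = report$qc$pct_genotyped) else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
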