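# shared fixtures and independent oracles

# quick genotype tibble from conventional strings: "Y/23" male, "29/70" female
gt_fixture <- function(sample_id, gt, call_mode = "pcr", locus = "FMR1") {
  rows <- lapply(seq_along(sample_id), function(i) {
    male <- grepl("^Y/", gt[i])
    vals <- as.integer(strsplit(sub("^Y/", "", gt[i]), "/")[[1]])
    vals <- sort(vals)
    tibble::tibble(
      sample_id = sample_id[i], locus_id = locus,
      sex = if (male) "male" else "female", call_mode = call_mode,
      allele1 = vals[1], allele2 = if (male) NA_integer_ else vals[2],
      a1_ci_lo = NA_integer_, a1_ci_hi = NA_integer_,
      a2_ci_lo = NA_integer_, a2_ci_hi = NA_integer_
    )
  })
  dplyr::bind_rows(rows)
}

# minimal annotated pedigree for one nuclear family
ped_fixture <- function(family_id, offspring) {
  # offspring: named list sample_id -> c(sex, affected)
  fid <- family_id
  k <- length(offspring)
  base <- tibble::tibble(
    family_id = fid,
    sample_id = c(paste0(fid, "_fa"), paste0(fid, "_mo"), names(offspring)),
    father_id = c(NA, NA, rep(paste0(fid, "_fa"), k)),
    mother_id = c(NA, NA, rep(paste0(fid, "_mo"), k)),
    sex = c("male", "female", vapply(offspring, `[[`, "", 1)),
    affected = c("unaffected", "unaffected", vapply(offspring, `[[`, "", 2))
  )
  fmrscreen:::annotate_pedigree(base)
}

# exhaustive two-sided Fisher p by hypergeometric enumeration (lchoose),
# matching the "at most as probable as observed" convention
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  x <- max(0, k - n):min(k, m)
  p <- exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  p_obs <- p[x == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# exhaustive daughter-allele partition oracle: only two assignments exist
oracle_partition <- function(daughter, father_allele, mother_alleles) {
  costs <- vapply(1:2, function(pat) {
    abs(daughter[pat] - father_allele) +
      min(abs(daughter[3 - pat] - mother_alleles))
  }, numeric(1))
  min(costs)
}

# handwritten ExpansionHunter-style JSON (kept independent of write_eh_json)
eh_json_text <- function(sample_id, sex, genotype, ci) {
  variant <- if (is.null(genotype)) "" else sprintf(
    '"FMR1": {"VariantId": "FMR1", "Genotype": "%s", "GenotypeConfidenceInterval": "%s"}',
    genotype, ci)
  sprintf('{
  "LocusResults": {
    "FMR1": {"LocusId": "FMR1", "Variants": {%s}}
  },
  "SampleParameters": {"SampleId": "%s", "Sex": "%s"}
}', variant, sample_id, sex)
}
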