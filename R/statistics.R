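#' Summarize carrier prevalence by family role
#'
#' Tabulates, for each family role, the number of processed samples (all
#' pedigree members with a genotype record, including no-calls), the
#' number with a genotype call, the number of expanded-allele carriers and
#' the carrier percentage (`100 * carriers / genotyped`). Pooled
#' male-offspring and female-offspring rows and a total row are appended.
#' A role with zero genotyped samples reports `NA` percent.
#'
#' @param genotypes Genotype tibble (no-calls have `NA` alleles).
#' @param pedigree Pedigree tibble with derived roles.
#' @param catalog A [locus_catalog()].
#' @param carrier_class Smallest range class counted as carrier; default
#'   `"premutation"` (so full-mutation alleles also count as expanded
#'   carriers).
#' @return Tibble with columns `role`, `processed`, `genotyped`,
#'   `carriers`, `non_carriers`, `percent`.
#' @export
summarize_prevalence <- function(genotypes, pedigree,
                                 catalog = locus_catalog(),
                                 carrier_class = "premutation") {
  status <- classify_genotypes(genotypes, catalog)
  joined <- dplyr::inner_join(
    pedigree[, c("sample_id", "role")],
    status[, c("sample_id", "longest_allele", "longest_class")],
    by = "sample_id"
  )
  per_role <- joined |>
    dplyr::filter(!is.na(.data$role)) |>
    dplyr::group_by(role = .data$role) |>
    dplyr::summarise(
      processed = dplyr::n(),
      genotyped = sum(!is.na(.data$longest_allele)),
      carriers = sum(.data$longest_class >= carrier_class, na.rm = TRUE),
      .groups = "drop"
    )
  role_order <- c("father", "mother", "male_proband", "male_sibling",
                  "female_proband", "female_sibling")
  per_role <- per_role[order(match(per_role$role, role_order)), ]
  pool <- function(label, roles) {
    sub <- per_role[per_role$role %in% roles, ]
    tibble::tibble(role = label,
                   processed = sum(sub$processed),
                   genotyped = sum(sub$genotyped),
                   carriers = sum(sub$carriers))
  }
  out <- dplyr::bind_rows(
    per_role,
    pool("male_offspring", c("male_proband", "male_sibling")),
    pool("female_offspring", c("female_proband", "female_sibling")),
    pool("total", role_order)
  )
  prevalence_percentages(out)
}

#' Compute carrier percentages from prevalence counts
#'
#' Adds `non_carriers = genotyped - carriers` and
#' `percent = 100 * carriers / genotyped` to a per-role count table
#' (`NA` percent when nothing was genotyped). Useful both on pipeline
#' output and on published count tables.
#'
#' @param counts Tibble with columns `genotyped` and `carriers` (other
#'   columns pass through).
#' @return The input with `non_carriers` and `percent` columns.
#' @export
prevalence_percentages <- function(counts) {
  dplyr::mutate(
    tibble::as_tibble(counts),
    non_carriers = .data$genotyped - .data$carriers,
    percent = ifelse(.data$genotyped > 0,
                     100 * .data$carriers / .data$genotyped, NA_real_)
  )
}

new_burden_result <- function(a, b, c, d, or, p, method) {
  out <- list(
    table = matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                   dimnames = list(c("group1", "group2"),
                                   c("carrier", "non_carrier"))),
    odds_ratio = or, p_value = p, method = method
  )
  class(out) <- "fmr_burden"
  out
}

#' Fisher exact carrier burden test on a 2x2 table
#'
#' Tests whether carriers are enriched in one group (e.g. probands) versus
#' another (e.g. unaffected siblings). The p-value is the two-sided Fisher
#' exact probability (sum of hypergeometric probabilities of tables at
#' most as probable as the observed one, at fixed margins). The reported
#' odds ratio is the sample cross-product `(a*d)/(b*c)` — not the
#' conditional MLE — because that is the conventional summary alongside
#' the exact p. A zero cell makes the cross-product degenerate: `Inf` when
#' `b*c == 0`, `0` when `a*d == 0` (and `NaN` when both), with the exact p
#' still defined; an empty margin yields `p = 1`.
#'
#' @param a,b Group-1 carriers and non-carriers.
#' @param c,d Group-2 carriers and non-carriers.
#' @return An object of class `fmr_burden` with elements `table`,
#'   `odds_ratio`, `p_value`, `method`; has `tidy()`/`glance()` methods.
#' @examples
#' fisher_burden(13, 2042, 8, 897)
#' @export
fisher_burden <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("fisher_burden needs non-negative integer counts", call. = FALSE)
  }
  or <- (a * d) / (b * c)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    p <- 1
  } else {
    p <- stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
  }
  new_burden_result(a, b, c, d, or, min(p, 1), "Fisher exact (two-sided)")
}

#' Compare carrier prevalence between two cohorts
#'
#' Convenience wrapper building the 2x2 table from carrier/total pairs
#' (e.g. mothers of one cohort versus an external reference sample) and
#' applying [fisher_burden()].
#'
#' @param carriers_a,total_a Carriers and total genotyped in cohort A.
#' @param carriers_b,total_b Same for cohort B.
#' @return An `fmr_burden` object.
#' @export
compare_prevalence <- function(carriers_a, total_a, carriers_b, total_b) {
  stopifnot(carriers_a <= total_a, carriers_b <= total_b)
  fisher_burden(carriers_a, total_a - carriers_a,
                carriers_b, total_b - carriers_b)
}

#' @export
print.fmr_burden <- function(x, ...) {
  cat(x$method, "\n")
  print(x$table)
  cat(sprintf("odds ratio (ad/bc) = %.4g, p = %.4g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' @export
tidy.fmr_burden <- function(x, ...) {
  tibble::tibble(
    carriers_group1 = x$table[1, 1], non_carriers_group1 = x$table[1, 2],
    carriers_group2 = x$table[2, 1], non_carriers_group2 = x$table[2, 2],
    odds_ratio = x$odds_ratio, p_value = x$p_value, method = x$method
  )
}

#' @export
glance.fmr_burden <- function(x, ...) {
  tibble::tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
                 n = sum(x$table))
}

#' Hardy-Weinberg equilibrium test for female carrier genotypes
#'
#' Pearson goodness-of-fit test of the female genotype distribution at a
#' chrX repeat locus against Hardy-Weinberg proportions, over the three
#' classes non-carrier, heterozygous carrier, homozygous carrier. The
#' expanded-allele frequency is estimated from the observed counts,
#' `q = (n_het + 2 * n_hom_carrier) / (2 * n_females)`, and expected
#' counts are `n * (1-q)^2`, `2*n*q*(1-q)`, `n*q^2`.
#'
#' The degrees of freedom used to convert the statistic to a p-value are
#' configurable. The textbook test with an estimated allele frequency uses
#' `df = 1`; the default here is `df = 2` (treating the three-class
#' comparison as fully specified), which is the convention this package's
#' reference analyses use. The statistic itself is identical under either
#' choice. Note that the sampling expectation of the statistic under the
#' null, with `q` estimated from the same data, is 1 — the `df = 2`
#' default only affects the tail conversion.
#'
#' @param n_het Observed heterozygous carrier females.
#' @param n_hom_carrier Observed homozygous carrier females.
#' @param n_females Total genotyped females.
#' @param df Degrees of freedom for the p-value (default 2).
#' @return Object of class `fmr_hwe`: `n_females`, `n_het`,
#'   `n_hom_carrier`, `allele_freq`, `chi2`, `df`, `p_value`, plus
#'   `observed`/`expected` class counts; `tidy()`/`glance()` methods.
#' @examples
#' hwe_female_chi2(n_het = 59, n_hom_carrier = 0, n_females = 3694)
#' @export
hwe_female_chi2 <- function(n_het, n_hom_carrier, n_females, df = 2) {
  if (n_females <= 0) stop("n_females must be positive", call. = FALSE)
  if (n_het + n_hom_carrier > n_females) {
    stop("carrier counts exceed n_females", call. = FALSE)
  }
  q <- (n_het + 2 * n_hom_carrier) / (2 * n_females)
  p <- 1 - q
  observed <- c(non_carrier = n_females - n_het - n_hom_carrier,
                het = n_het, hom = n_hom_carrier)
  expected <- n_females * c(non_carrier = p^2, het = 2 * p * q, hom = q^2)
  nz <- expected > 0
  chi2 <- sum((observed[nz] - expected[nz])^2 / expected[nz])
  out <- list(
    n_females = n_females, n_het = n_het, n_hom_carrier = n_hom_carrier,
    allele_freq = q, observed = observed, expected = expected,
    chi2 = chi2, df = df,
    p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE)
  )
  class(out) <- "fmr_hwe"
  out
}

#' @export
print.fmr_hwe <- function(x, ...) {
  cat("Hardy-Weinberg test (females, 3 genotype classes)\n")
  cat(sprintf("  n = %d, carrier allele frequency = %.5f\n",
              x$n_females, x$allele_freq))
  cat(sprintf("  chi2 = %.4g on %d df, p = %.4g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.fmr_hwe <- function(x, ...) {
  tibble::tibble(class = names(x$observed),
                 observed = as.numeric(x$observed),
                 expected = as.numeric(x$expected))
}

#' @export
glance.fmr_hwe <- function(x, ...) {
  tibble::tibble(n_females = x$n_females, allele_freq = x$allele_freq,
                 chi2 = x$chi2, df = x$df, p_value = x$p_value)
}

#' Two-sample Z-test for a difference in parental ages
#'
#' Compares the mean of two groups of ages (e.g. parents whose offspring
#' inherited an expanded allele versus parents of de novo offspring) with
#' a two-sample Z statistic using the pooled standard error of the mean
#' difference, `z = (mean1 - mean2) / sqrt(s1^2/n1 + s2^2/n2)`, and a
#' two-sided normal p-value.
#'
#' @param ages_group1,ages_group2 Numeric vectors (years), each of length
#'   at least 2 with non-zero variance.
#' @return Tibble with `n1`, `n2`, `mean1`, `mean2`, `z`, `p_value`.
#' @export
parental_age_ztest <- function(ages_group1, ages_group2) {
  g1 <- ages_group1[!is.na(ages_group1)]
  g2 <- ages_group2[!is.na(ages_group2)]
  if (length(g1) < 2 || length(g2) < 2) {
    stop("each group needs at least two ages", call. = FALSE)
  }
  se <- sqrt(stats::var(g1) / length(g1) + stats::var(g2) / length(g2))
  if (!is.finite(se) || se == 0) {
    stop("degenerate variance: Z statistic undefined", call. = FALSE)
  }
  z <- (mean(g1) - mean(g2)) / se
  tibble::tibble(
    n1 = length(g1), n2 = length(g2),
    mean1 = mean(g1), mean2 = mean(g2),
    z = z, p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Concordance between two repeat call sets
#'
#' Compares two call sets on the same samples (e.g. off-target
#' ExpansionHunter calls versus PCR, or off-target versus region-only) by
#' the class of each sample's longest allele. Samples present in only one
#' set are excluded with a warning.
#'
#' @param calls_a,calls_b Genotype tibbles for the same samples.
#' @param catalog A [locus_catalog()].
#' @return Object of class `fmr_concordance`: `samples` (per-sample
#'   tibble with genotypes, `class_a`, `class_b`, `agree`), `n_flagged_a`
#'   and `n_flagged_b` (samples with any allele at/above the premutation
#'   range per set), `n_class_discordant`; `tidy()`/`glance()` methods.
#' @export
callset_concordance <- function(calls_a, calls_b, catalog = locus_catalog()) {
  a <- classify_genotypes(calls_a, catalog)
  b <- classify_genotypes(calls_b, catalog)
  common <- intersect(a$sample_id, b$sample_id)
  dropped <- setdiff(union(a$sample_id, b$sample_id), common)
  if (length(dropped) > 0) {
    warning("samples present in only one call set excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "), call. = FALSE)
  }
  a <- a[match(common, a$sample_id), ]
  b <- b[match(common, b$sample_id), ]
  samples <- tibble::tibble(
    sample_id = common,
    sex = a$sex,
    genotype_a = format_genotype(a$sex, a$allele1, a$allele2),
    genotype_b = format_genotype(b$sex, b$allele1, b$allele2),
    class_a = a$longest_class,
    class_b = b$longest_class,
    expanded_a = a$is_expanded,
    expanded_b = b$is_expanded,
    agree = a$longest_class == b$longest_class
  )
  out <- list(
    samples = samples,
    n_flagged_a = sum(samples$expanded_a, na.rm = TRUE),
    n_flagged_b = sum(samples$expanded_b, na.rm = TRUE),
    n_class_discordant = sum(!samples$agree, na.rm = TRUE)
  )
  class(out) <- "fmr_concordance"
  out
}

#' @export
print.fmr_concordance <- function(x, ...) {
  cat("Call-set concordance over", nrow(x$samples), "samples\n")
  cat(sprintf("  expanded carriers: %d (set A) vs %d (set B); %d class-discordant\n",
              x$n_flagged_a, x$n_flagged_b, x$n_class_discordant))
  print(x$samples)
  invisible(x)
}

#' @export
tidy.fmr_concordance <- function(x, ...) x$samples

#' @export
glance.fmr_concordance <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$samples),
                 n_flagged_a = x$n_flagged_a,
                 n_flagged_b = x$n_flagged_b,
                 n_class_discordant = x$n_class_discordant)
}
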