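offspring_roles <- c("male_proband", "male_sibling",
                     "female_proband", "female_sibling")

# Assign parental origin for one offspring's chrX alleles by minimum
# absolute repeat-length difference.
#
# Sons carry a single maternal X: their allele is matched to the nearest
# maternal allele. Daughters carry one paternal and one maternal X: of the
# two possible assignments the one minimizing the total absolute
# difference wins (an exhaustive choice over the only two partitions).
# Ties are broken deterministically (paternal = the allele nearer the
# father, then the shorter allele) and flagged ambiguous.
#
# Returns a tibble: origin, offspring_allele, parent_allele, delta,
# ambiguous_match.
assign_origin_one <- function(offspring_alleles, offspring_sex,
                              father_allele, mother_alleles) {
  near <- function(o, parents) {
    d <- abs(o - parents)
    i <- which.min(d)
    list(allele = parents[i], delta = o - parents[i],
         ambiguous = sum(d == d[i]) > 1 && length(unique(parents)) > 1)
  }
  if (offspring_sex == "male") {
    m <- near(offspring_alleles[1], mother_alleles)
    return(tibble::tibble(
      origin = "maternal", offspring_allele = offspring_alleles[1],
      parent_allele = m$allele, delta = m$delta, ambiguous_match = m$ambiguous
    ))
  }
  o <- offspring_alleles
  cost <- function(pat_idx) {
    mat_idx <- 3L - pat_idx
    abs(o[pat_idx] - father_allele) +
      min(abs(o[mat_idx] - mother_alleles))
  }
  c1 <- cost(1L); c2 <- cost(2L)
  tie <- c1 == c2 && o[1] != o[2]
  pat_idx <- if (c1 < c2) 1L else if (c2 < c1) 2L else {
    # tie: prefer the allele nearer the father, then the shorter one
    d <- abs(o - father_allele)
    if (d[1] <= d[2]) 1L else 2L
  }
  mat_idx <- 3L - pat_idx
  mat <- near(o[mat_idx], mother_alleles)
  tibble::tibble(
    origin = c("paternal", "maternal"),
    offspring_allele = c(o[pat_idx], o[mat_idx]),
    parent_allele = c(father_allele, mat$allele),
    delta = c(o[pat_idx] - father_allele, mat$delta),
    ambiguous_match = tie | c(FALSE, mat$ambiguous)
  )
}

#' Assign parental origin to offspring repeat alleles
#'
#' Low-level single-family interface: given the offspring's alleles and
#' both parents' alleles at a chrX locus, assigns each offspring allele to
#' a parental allele by minimum absolute repeat-length difference. A son's
#' single allele is matched against the mother's two alleles; a daughter's
#' two alleles are split one-paternal/one-maternal by the partition with
#' the smaller total absolute difference (there are only two). Ties are
#' flagged `ambiguous_match`.
#'
#' @param offspring_alleles Integer vector: 1 allele (male) or 2 (female).
#' @param offspring_sex `"male"` or `"female"`.
#' @param father_allele The father's single chrX allele.
#' @param mother_alleles The mother's two chrX alleles.
#' @return Tibble with one row per offspring allele: `origin`,
#'   `offspring_allele`, `parent_allele`, `delta` (offspring - parent),
#'   `ambiguous_match`.
#' @examples
#' assign_parental_origin(48, "male", 23, c(29, 48))
#' @export
assign_parental_origin <- function(offspring_alleles, offspring_sex,
                                   father_allele, mother_alleles) {
  stopifnot(offspring_sex %in% c("male", "female"),
            length(mother_alleles) == 2, length(father_allele) == 1)
  n_expected <- if (offspring_sex == "male") 1L else 2L
  if (length(offspring_alleles) != n_expected) {
    stop("offspring allele count inconsistent with sex", call. = FALSE)
  }
  assign_origin_one(offspring_alleles, offspring_sex,
                    father_allele, mother_alleles)
}

#' Call parental transmissions and de novo expansions across families
#'
#' For every analysis-ready family with both parents genotyped, assigns a
#' parental origin to each genotyped offspring allele
#' ([assign_parental_origin()]) and classifies the transmission:
#'
#' * `premutation_transmitted` — offspring allele at/above the premutation
#'   range and the assigned parental allele also at/above it;
#' * `de_novo` — offspring allele at/above the premutation range while the
#'   assigned parental allele is below it (requires both parents
#'   genotyped);
#' * `normal_from_carrier` — offspring allele below the premutation range
#'   but the assigned (transmitting) parent carries an expanded allele;
#' * `normal_transmitted` — everything else.
#'
#' The transmitted class is the offspring's own allele class as observed.
#' QC flags: `poor_match` when `|delta| > tolerance`; `ambiguous_match` on
#' assignment ties; `contraction` when an expanded parental allele matches
#' a below-premutation offspring allele; `x_linkage_violation` for a son
#' whose expanded allele is only explainable by the father's expanded
#' allele (reported, never counted as a paternal transmission — sons
#' receive no paternal X).
#'
#' @param genotypes Genotype tibble (one locus).
#' @param pedigree Pedigree tibble from [read_pedigree()].
#' @param catalog A [locus_catalog()].
#' @param tolerance Repeat-unit mismatch beyond which a match is flagged
#'   `poor_match` (default 5; genotyping scatter grows with allele length).
#' @return Tibble of transmission calls, one row per offspring allele.
#' @export
call_transmissions <- function(genotypes, pedigree, catalog = locus_catalog(),
                               tolerance = 5) {
  stopifnot(is.data.frame(genotypes), is.data.frame(pedigree))
  gt <- genotypes[!duplicated(genotypes$sample_id), ]
  idx <- function(id) match(id, gt$sample_id)
  empty <- tibble::tibble(
    family_id = character(), offspring_id = character(),
    offspring_role = character(), offspring_sex = character(),
    origin = character(), offspring_allele = integer(),
    parent_allele = integer(), delta = integer(),
    transmitted_class = factor(character(), levels = range_classes, ordered = TRUE),
    parent_class = factor(character(), levels = range_classes, ordered = TRUE),
    parent_is_carrier = logical(), category = character(),
    ambiguous_match = logical(), poor_match = logical(),
    contraction = logical(), x_linkage_violation = logical()
  )
  fams <- split(pedigree, pedigree$family_id)
  calls <- purrr::map(fams, function(fam) {
    if (!any(fam$analysis_ready)) return(NULL)
    fa_id <- fam$sample_id[fam$role %in% "father"][1]
    mo_id <- fam$sample_id[fam$role %in% "mother"][1]
    fa <- gt[idx(fa_id), ]; mo <- gt[idx(mo_id), ]
    if (is.na(idx(fa_id)) || is.na(idx(mo_id)) ||
        is.na(fa$allele1) || is.na(mo$allele1)) {
      warning("family ", fam$family_id[1],
              " skipped: missing parental genotype", call. = FALSE)
      return(NULL)
    }
    offspring <- fam[fam$role %in% offspring_roles, ]
    purrr::pmap(offspring, function(family_id, sample_id, father_id, mother_id,
                                    sex, affected, role, analysis_ready) {
      o <- gt[idx(sample_id), ]
      if (is.na(idx(sample_id)) || is.na(o$allele1)) return(NULL)
      o_alleles <- stats::na.omit(c(o$allele1, o$allele2))
      asg <- assign_origin_one(as.integer(o_alleles), sex,
                               fa$allele1, c(mo$allele1, mo$allele2))
      premut_idx <- match("premutation", range_classes)
      cls <- function(x) classify_allele_quiet(x, catalog)
      fa_carrier <- cls(fa$allele1) >= "premutation"
      mo_carrier <- any(cls(c(mo$allele1, mo$allele2)) >= "premutation")
      dplyr::mutate(asg,
        family_id = family_id, offspring_id = sample_id,
        offspring_role = role, offspring_sex = sex,
        transmitted_class = cls(.data$offspring_allele),
        parent_class = cls(.data$parent_allele),
        parent_is_carrier = ifelse(.data$origin == "maternal",
                                   mo_carrier, fa_carrier),
        category = dplyr::case_when(
          .data$transmitted_class >= "premutation" &
            .data$parent_class >= "premutation" ~ "premutation_transmitted",
          .data$transmitted_class >= "premutation" ~ "de_novo",
          .data$parent_is_carrier ~ "normal_from_carrier",
          .default = "normal_transmitted"
        ),
        poor_match = abs(.data$delta) > tolerance,
        contraction = .data$parent_class >= "premutation" &
          .data$transmitted_class < "premutation",
        x_linkage_violation = sex == "male" &
          .data$category == "de_novo" & fa_carrier & !mo_carrier &
          abs(.data$offspring_allele - fa$allele1) <= tolerance &
          pmin(abs(.data$offspring_allele - mo$allele1),
               abs(.data$offspring_allele - mo$allele2)) > tolerance
      )
    })
  })
  flat <- unname(purrr::list_flatten(purrr::compact(calls)))
  out <- dplyr::bind_rows(empty, purrr::list_rbind(purrr::compact(flat)))
  out[, names(empty)]
}

# the 20 report rows in fixed order: 8 premutation-transmission rows,
# 8 normal-from-carrier rows, 4 de novo rows
transmission_rows <- function() {
  tibble::tibble(
    parent = c(rep(c(rep("mother", 4), rep("father", 4)), 2),
               rep(NA_character_, 4)),
    offspring_role = rep(offspring_roles, 5),
    allele_range = c(rep("premutation", 8), rep("normal", 8),
                     rep("de_novo", 4))
  )
}

#' Attach percentages to transmission category counts
#'
#' Completes a per-category count table to the full 20-row report layout
#' (mother/father x four offspring roles x premutation/normal transmitted
#' allele, plus four de novo rows) and computes each row's percentage of
#' offspring in expanded-carrier families. With a zero denominator all
#' percentages are reported as 0 and `percent_defined` is `FALSE`.
#'
#' @param counts Tibble with columns `parent` (`"mother"`/`"father"`, `NA`
#'   for de novo rows), `offspring_role`, `allele_range`
#'   (`"premutation"`/`"normal"`/`"de_novo"`) and `count`.
#' @param n_offspring Number of offspring in families with at least one
#'   expanded-allele carrier (the percentage denominator).
#' @return The 20-row tibble with `count`, `percentage`, `percent_defined`.
#' @examples
#' counts <- tibble::tibble(parent = "mother", offspring_role = "male_proband",
#'                          allele_range = "premutation", count = 10)
#' transmission_percentages(counts, n_offspring = 141)
#' @export
transmission_percentages <- function(counts, n_offspring) {
  rows <- transmission_rows() |>
    dplyr::left_join(counts, by = c("parent", "offspring_role", "allele_range")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0))
  defined <- n_offspring > 0
  rows$percentage <- if (defined) 100 * rows$count / n_offspring else 0
  rows$percent_defined <- defined
  rows
}

#' Summarize transmission calls into the per-cohort accounting
#'
#' Restricts transmission calls to families containing at least one
#' expanded-allele carrier, tabulates the 20 report categories
#' ([transmission_percentages()]) and the aggregate counts: offspring who
#' inherited an expanded allele, de novo expansions, and offspring of a
#' carrier parent who did not inherit the expanded allele. Percentages use
#' the number of genotyped offspring in carrier families as denominator.
#' Calls flagged `x_linkage_violation` are excluded from the category
#' counts and reported separately. A father-to-son transmission count
#' other than zero is structurally impossible for a chrX locus and raises
#' an error.
#'
#' @param calls Transmission calls from [call_transmissions()].
#' @param genotypes Genotype tibble used to identify carrier families.
#' @param pedigree Pedigree tibble.
#' @param catalog A [locus_catalog()].
#' @param cohort_id Label stored on the summary.
#' @return An object of class `fmr_transmission_summary`: list with `rows`
#'   (the 20-row table), `n_offspring_in_carrier_families`,
#'   `n_carrier_families`, `n_transmitted`, `n_de_novo`, `n_noninheriting`,
#'   `n_x_violations`. Has [generics::tidy()] and [generics::glance()]
#'   methods.
#' @export
summarize_transmissions <- function(calls, genotypes, pedigree,
                                    catalog = locus_catalog(),
                                    cohort_id = "cohort") {
  status <- classify_genotypes(genotypes, catalog)
  carriers <- status$sample_id[!is.na(status$is_expanded) & status$is_expanded]
  carrier_fams <- unique(pedigree$family_id[pedigree$sample_id %in% carriers])
  genotyped <- status$sample_id[!is.na(status$longest_allele)]
  n_offspring <- sum(pedigree$family_id %in% carrier_fams &
                       pedigree$role %in% offspring_roles &
                       pedigree$sample_id %in% genotyped)
  cc <- calls[calls$family_id %in% carrier_fams & !calls$x_linkage_violation, ]
  counted <- dplyr::bind_rows(
    cc |>
      dplyr::filter(.data$category == "premutation_transmitted") |>
      dplyr::mutate(parent = as.character(ifelse(.data$origin == "maternal",
                                               "mother", "father")),
                    allele_range = "premutation"),
    cc |>
      dplyr::filter(.data$category == "normal_from_carrier") |>
      dplyr::mutate(parent = as.character(ifelse(.data$origin == "maternal",
                                               "mother", "father")),
                    allele_range = "normal"),
    cc |>
      dplyr::filter(.data$category == "de_novo") |>
      dplyr::mutate(parent = NA_character_, allele_range = "de_novo")
  )
  counts <- counted |>
    dplyr::count(.data$parent, .data$offspring_role, .data$allele_range,
                 name = "count")
  rows <- transmission_percentages(counts, n_offspring)
  father_son_premut <- rows$count[rows$parent %in% "father" &
                                    rows$offspring_role %in%
                                      c("male_proband", "male_sibling") &
                                    rows$allele_range == "premutation"]
  if (any(father_son_premut != 0)) {
    stop("father-to-male-offspring premutation transmission counted: ",
         "impossible for a chrX locus; upstream genotypes are inconsistent",
         call. = FALSE)
  }
  out <- list(
    cohort_id = cohort_id,
    rows = rows,
    n_offspring_in_carrier_families = n_offspring,
    n_carrier_families = length(carrier_fams),
    n_transmitted = sum(rows$count[rows$allele_range == "premutation"]),
    n_de_novo = sum(rows$count[rows$allele_range == "de_novo"]),
    n_noninheriting = sum(rows$count[rows$allele_range == "normal"]),
    n_x_violations = sum(calls$x_linkage_violation)
  )
  class(out) <- "fmr_transmission_summary"
  out
}

#' @export
print.fmr_transmission_summary <- function(x, ...) {
  cat("Transmission summary:", x$cohort_id, "\n")
  cat(sprintf("  %d carrier families, %d offspring\n",
              x$n_carrier_families, x$n_offspring_in_carrier_families))
  cat(sprintf("  expanded allele inherited: %d; de novo: %d; not inherited from carrier parent: %d\n",
              x$n_transmitted, x$n_de_novo, x$n_noninheriting))
  if (x$n_x_violations > 0) {
    cat("  X-linkage violations flagged:", x$n_x_violations, "\n")
  }
  print(x$rows, n = 20)
  invisible(x)
}

#' @export
tidy.fmr_transmission_summary <- function(x, ...) x$rows

#' @export
glance.fmr_transmission_summary <- function(x, ...) {
  n <- x$n_offspring_in_carrier_families
  pct <- function(k) if (n > 0) 100 * k / n else NA_real_
  tibble::tibble(
    cohort_id = x$cohort_id,
    n_carrier_families = x$n_carrier_families,
    n_offspring = n,
    n_transmitted = x$n_transmitted,
    n_de_novo = x$n_de_novo,
    n_noninheriting = x$n_noninheriting,
    pct_transmitted = pct(x$n_transmitted),
    pct_de_novo = pct(x$n_de_novo),
    pct_noninheriting = pct(x$n_noninheriting)
  )
}
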