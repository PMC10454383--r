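#' Repeat range classes
#'
#' Ordered levels used throughout the package to classify repeat alleles:
#' `normal < gray < premutation < full`.
#'
#' @keywords internal
#' @export
range_classes <- c("normal", "gray", "premutation", "full")

#' Define a repeat-locus classification catalog
#'
#' A locus catalog holds the range thresholds that partition repeat lengths
#' into normal, gray-zone, premutation and full-mutation classes. The
#' defaults describe the CGG repeat in the 5' UTR of *FMR1* on the X
#' chromosome: normal alleles up to 40 repeat units, gray zone 41--54,
#' premutation 55--200, full mutation above 200. All boundaries are
#' inclusive upper limits of their class.
#'
#' @param locus_id Locus name, e.g. `"FMR1"`.
#' @param chromosome_type `"chrX"` (sex-aware ploidy: males hemizygous) or
#'   `"autosomal"`.
#' @param repeat_unit Repeat motif, e.g. `"CGG"`.
#' @param normal_max Largest repeat count classified `normal`.
#' @param gray_max Largest repeat count classified `gray`.
#' @param premutation_max Largest repeat count classified `premutation`;
#'   anything longer is `full`.
#'
#' @return A one-row tibble of class `fmr_catalog`.
#' @examples
#' locus_catalog()
#' @export
locus_catalog <- function(locus_id = "FMR1",
                          chromosome_type = c("chrX", "autosomal"),
                          repeat_unit = "CGG",
                          normal_max = 40L,
                          gray_max = 54L,
                          premutation_max = 200L) {
  chromosome_type <- match.arg(chromosome_type)
  normal_max <- as.integer(normal_max)
  gray_max <- as.integer(gray_max)
  premutation_max <- as.integer(premutation_max)
  if (anyNA(c(normal_max, gray_max, premutation_max))) {
    stop("catalog thresholds must be integers", call. = FALSE)
  }
  if (!(normal_max > 0 && normal_max < gray_max && gray_max < premutation_max)) {
    stop("catalog thresholds must satisfy 0 < normal_max < gray_max < premutation_max",
         call. = FALSE)
  }
  out <- tibble::tibble(
    locus_id = as.character(locus_id),
    chromosome_type = chromosome_type,
    repeat_unit = as.character(repeat_unit),
    normal_max = normal_max,
    gray_max = gray_max,
    premutation_max = premutation_max
  )
  class(out) <- c("fmr_catalog", class(out))
  out
}

#' Read a locus catalog from a config file
#'
#' The config format is a plain tab-separated table with one locus per row
#' and the columns `locus_id`, `chromosome_type`, `repeat_unit`,
#' `normal_max`, `gray_max`, `premutation_max`. A catalog for *FMR1* ships
#' with the package (see the example).
#'
#' @param path Path to the catalog file.
#' @param locus Optional locus id to select; required when the file holds
#'   more than one locus.
#' @return A `fmr_catalog` tibble (one row).
#' @examples
#' read_catalog(system.file("extdata", "fmr1_catalog.tsv", package = "fmrscreen"))
#' @export
read_catalog <- function(path, locus = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "chromosome_type", "repeat_unit",
            "normal_max", "gray_max", "premutation_max")
  if (!all(need %in% names(tab))) {
    stop("catalog file missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  if (!is.null(locus)) tab <- tab[tab$locus_id == locus, , drop = FALSE]
  if (nrow(tab) != 1L) {
    stop("catalog must resolve to exactly one locus; use `locus` to select",
         call. = FALSE)
  }
  locus_catalog(tab$locus_id, tab$chromosome_type, tab$repeat_unit,
                tab$normal_max, tab$gray_max, tab$premutation_max)
}

#' Classify repeat allele lengths into range classes
#'
#' Maps each repeat length to `normal` (<= `normal_max`), `gray`
#' (`normal_max` < length <= `gray_max`), `premutation`
#' (`gray_max` < length <= `premutation_max`) or `full`
#' (> `premutation_max`). Every non-negative length falls in exactly one
#' class and the mapping is monotone in length. Lengths below 5 repeat
#' units are unusually short for *FMR1* and are classified `normal` with a
#' warning.
#'
#' @param length Integer vector of repeat lengths (repeat units, >= 0).
#'   `NA` passes through as `NA` (no-call).
#' @param catalog A [locus_catalog()].
#' @return Ordered factor with levels `normal < gray < premutation < full`.
#' @examples
#' classify_allele(c(30, 48, 70, 281))
#' @export
classify_allele <- function(length, catalog = locus_catalog()) {
  stopifnot(inherits(catalog, "fmr_catalog"))
  length <- as.numeric(length)
  if (any(length < 0, na.rm = TRUE)) {
    stop("repeat length must be non-negative", call. = FALSE)
  }
  if (any(length < 5, na.rm = TRUE)) {
    warning("allele length(s) below 5 repeat units classified as normal",
            call. = FALSE)
  }
  cls <- cut(length,
             breaks = c(-Inf, catalog$normal_max, catalog$gray_max,
                        catalog$premutation_max, Inf),
             labels = range_classes,
             ordered_result = TRUE)
  cls
}

#' Classify genotypes into carrier statuses
#'
#' Adds per-individual carrier annotations to a genotype table: the longest
#' allele, its range class, and premutation / full-mutation / expanded
#' carrier flags. An individual is a premutation carrier when at least one
#' allele falls in the premutation range; `is_expanded` flags any allele at
#' or beyond the premutation range (the screening trigger used when
#' selecting samples for re-evaluation or validation). No-call records
#' (missing `allele1`) keep `NA` annotations.
#'
#' @param genotypes Genotype tibble as returned by the readers (see
#'   [read_eh_json()]): columns `sample_id`, `sex`, `allele1`, `allele2`.
#' @param catalog A [locus_catalog()].
#' @return The input tibble with columns `longest_allele`, `longest_class`,
#'   `is_premutation_carrier`, `is_full_carrier`, `is_expanded` appended.
#' @examples
#' g <- tibble::tibble(sample_id = c("A", "B"), sex = c("female", "male"),
#'                     allele1 = c(29L, 23L), allele2 = c(70L, NA))
#' classify_genotypes(g)
#' @export
classify_genotypes <- function(genotypes, catalog = locus_catalog()) {
  stopifnot(is.data.frame(genotypes))
  check_ploidy(genotypes, catalog)
  a1 <- classify_allele(genotypes$allele1, catalog)
  a2 <- classify_allele(genotypes$allele2, catalog)
  longest <- pmax(genotypes$allele1, genotypes$allele2, na.rm = TRUE)
  longest[is.na(genotypes$allele1)] <- NA
  premut <- (!is.na(a1) & a1 == "premutation") | (!is.na(a2) & a2 == "premutation")
  full <- (!is.na(a1) & a1 == "full") | (!is.na(a2) & a2 == "full")
  premut[is.na(genotypes$allele1)] <- NA
  full[is.na(genotypes$allele1)] <- NA
  out <- dplyr::mutate(
    tibble::as_tibble(genotypes),
    longest_allele = as.integer(longest),
    longest_class = classify_allele_quiet(longest, catalog),
    is_premutation_carrier = premut,
    is_full_carrier = full,
    is_expanded = premut | full
  )
  out
}

# classify without re-issuing the short-allele warning (already emitted on
# the per-allele pass)
classify_allele_quiet <- function(length, catalog) {
  suppressWarnings(classify_allele(length, catalog))
}

# sex/ploidy consistency for chrX loci: called males carry one allele,
# called females two; no-calls (allele1 NA) are exempt
check_ploidy <- function(genotypes, catalog) {
  if (catalog$chromosome_type != "chrX") return(invisible(TRUE))
  if (!all(c("sex", "allele1", "allele2") %in% names(genotypes))) {
    stop("genotype table needs columns sex, allele1, allele2", call. = FALSE)
  }
  called <- !is.na(genotypes$allele1)
  bad_m <- called & genotypes$sex == "male" & !is.na(genotypes$allele2)
  bad_f <- called & genotypes$sex == "female" & is.na(genotypes$allele2)
  if (any(bad_m | bad_f)) {
    offenders <- genotypes$sample_id[which(bad_m | bad_f)]
    stop("ploidy error for chrX locus (males: 1 allele, females: 2): ",
         paste(utils::head(offenders, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
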