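#' @importFrom rlang .data
NULL

# canonical column order of a genotype tibble; alleles sorted ascending,
# allele2/CI columns NA for hemizygous males and no-calls
genotype_cols <- c("sample_id", "locus_id", "sex", "call_mode",
                   "allele1", "allele2",
                   "a1_ci_lo", "a1_ci_hi", "a2_ci_lo", "a2_ci_hi")

empty_genotypes <- function() {
  tibble::tibble(
    sample_id = character(), locus_id = character(), sex = character(),
    call_mode = character(),
    allele1 = integer(), allele2 = integer(),
    a1_ci_lo = integer(), a1_ci_hi = integer(),
    a2_ci_lo = integer(), a2_ci_hi = integer()
  )
}

# assemble one genotype row from parsed alleles (list of c(val, lo, hi)),
# sorting ascending by repeat count and carrying CIs along
genotype_row <- function(sample_id, locus_id, sex, call_mode, alleles) {
  if (length(alleles) == 0) {
    row <- empty_genotypes()[NA_integer_, ]
    row$sample_id <- sample_id; row$locus_id <- locus_id
    row$sex <- sex; row$call_mode <- call_mode
    return(row)
  }
  ord <- order(vapply(alleles, `[[`, numeric(1), 1L))
  alleles <- alleles[ord]
  get <- function(i, j) {
    if (length(alleles) >= i) as.integer(alleles[[i]][j]) else NA_integer_
  }
  tibble::tibble(
    sample_id = sample_id, locus_id = locus_id, sex = sex,
    call_mode = call_mode,
    allele1 = get(1, 1), allele2 = get(2, 1),
    a1_ci_lo = get(1, 2), a1_ci_hi = get(1, 3),
    a2_ci_lo = get(2, 2), a2_ci_hi = get(2, 3)
  )
}

parse_repeat_number <- function(x, sample_id, locus_id) {
  n <- suppressWarnings(as.integer(x))
  if (is.na(n) || n < 0) {
    stop(sprintf("malformed genotype '%s' for sample %s at locus %s",
                 x, sample_id, locus_id), call. = FALSE)
  }
  n
}

parse_ci <- function(ci) {
  if (is.null(ci) || is.na(ci) || ci == "" || ci == ".") return(c(NA, NA))
  parts <- strsplit(ci, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(c(NA, NA))
  as.integer(parts)
}

# parse "29/70" (+ optional CI "29-29/59-82") into allele triples
parse_genotype_string <- function(gt, ci, sample_id, locus_id, sex) {
  vals <- strsplit(gt, "/", fixed = TRUE)[[1]]
  cis <- if (is.null(ci) || is.na(ci) || !nzchar(ci)) rep(".", length(vals)) else
    strsplit(ci, "/", fixed = TRUE)[[1]]
  if (length(cis) != length(vals)) cis <- rep(".", length(vals))
  n_expected <- if (identical(sex, "male")) 1L else 2L
  if (!is.na(sex) && length(vals) != n_expected) {
    stop(sprintf("ploidy error: sex=%s sample %s at %s has %d allele(s)",
                 sex, sample_id, locus_id, length(vals)), call. = FALSE)
  }
  purrr::map2(vals, cis, function(v, ci1) {
    n <- parse_repeat_number(v, sample_id, locus_id)
    civ <- parse_ci(ci1)
    if (!anyNA(civ) && !(civ[1] <= n && n <= civ[2])) {
      warning(sprintf("CI %s does not bracket allele %d for sample %s; dropped",
                      ci1, n, sample_id), call. = FALSE)
      civ <- c(NA, NA)
    }
    c(n, civ)
  })
}

#' Read ExpansionHunter-style JSON repeat genotypes
#'
#' Parses one JSON file per sample, following the public ExpansionHunter
#' output shape: `SampleParameters` (`SampleId`, `Sex`) plus `LocusResults`
#' with per-variant `Genotype` ("29/70" or "23") and
#' `GenotypeConfidenceInterval` ("29-29/59-82") strings. A present locus
#' with a missing genotype (e.g. insufficient coverage) yields an explicit
#' no-call record with `NA` alleles rather than an error; a file whose
#' variants block is empty contributes no rows.
#'
#' @param paths Character vector of JSON file paths (one sample each).
#' @param locus Locus id to extract (default `"FMR1"`).
#' @param call_mode Label recorded on each record: `"eh_offtarget"`
#'   (default; calls that used the full variant catalog including
#'   off-target regions) or `"eh_region_only"` (calls restricted to the
#'   locus reference region).
#' @return A genotype tibble (one row per sample x locus) with columns
#'   `sample_id`, `locus_id`, `sex`, `call_mode`, `allele1`, `allele2` and
#'   per-allele confidence bounds `a1_ci_lo`..`a2_ci_hi`. Alleles are sorted
#'   ascending; males carry a single allele at chrX loci.
#' @export
read_eh_json <- function(paths, locus = "FMR1",
                         call_mode = c("eh_offtarget", "eh_region_only")) {
  call_mode <- match.arg(call_mode)
  rows <- purrr::map(paths, function(p) {
    x <- jsonlite::read_json(p)
    sample_id <- x$SampleParameters$SampleId %||% basename(p)
    sex <- tolower(x$SampleParameters$Sex %||% NA_character_)
    lr <- x$LocusResults[[locus]]
    if (is.null(lr)) return(empty_genotypes())
    variants <- lr$Variants
    if (is.null(variants) || length(variants) == 0) return(empty_genotypes())
    v <- variants[[locus]] %||% variants[[1]]
    gt <- v$Genotype
    if (is.null(gt) || !nzchar(gt)) {
      return(genotype_row(sample_id, locus, sex, call_mode, list()))
    }
    alleles <- parse_genotype_string(gt, v$GenotypeConfidenceInterval %||% "",
                                     sample_id, locus, sex)
    genotype_row(sample_id, locus, sex, call_mode, alleles)
  })
  dplyr::bind_rows(empty_genotypes(), rows)
}

#' Read repeat genotypes from a VCF with per-sample repeat counts
#'
#' Expects the ExpansionHunter VCF convention: one STR record per locus
#' with per-sample `REPCN` (repeat counts, "29/70" or "23") and `REPCI`
#' (confidence intervals, "29-29/59-82") FORMAT fields. Sample sex is
#' inferred from ploidy at a chrX locus (one repeat count = male). Content
#' is identical to what [read_eh_json()] produces for the same calls.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @inheritParams read_eh_json
#' @return A genotype tibble; see [read_eh_json()].
#' @export
read_eh_vcf <- function(path, locus = "FMR1",
                        call_mode = c("eh_offtarget", "eh_region_only")) {
  call_mode <- match.arg(call_mode)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  if (nrow(vcf@gt) == 0 || ncol(vcf@gt) <= 1) return(empty_genotypes())
  ids <- vcf@fix[, "ID"]
  keep <- which(ids == locus)
  if (length(keep) == 0) return(empty_genotypes())
  fmt <- vcf@gt[keep[1], 1]
  if (!grepl("REPCN", fmt)) {
    stop("VCF format error: no REPCN repeat-count field at locus ", locus,
         call. = FALSE)
  }
  repcn <- vcfR::extract.gt(vcf, element = "REPCN")[keep[1], , drop = TRUE]
  repci <- if (grepl("REPCI", fmt)) {
    vcfR::extract.gt(vcf, element = "REPCI")[keep[1], , drop = TRUE]
  } else stats::setNames(rep(NA_character_, length(repcn)), names(repcn))
  rows <- purrr::imap(repcn, function(gt, sample_id) {
    if (is.na(gt) || gt == "." || !nzchar(gt)) {
      return(genotype_row(sample_id, locus, NA_character_, call_mode, list()))
    }
    sex <- if (grepl("/", gt, fixed = TRUE)) "female" else "male"
    alleles <- parse_genotype_string(gt, repci[[sample_id]], sample_id, locus, sex)
    genotype_row(sample_id, locus, sex, call_mode, alleles)
  })
  dplyr::bind_rows(empty_genotypes(), unname(rows))
}

#' Read a PCR genotype table
#'
#' Reads a tab-separated table of repeat-primed PCR results with columns
#' `sample_id`, `sex` and `genotype`, where genotypes use the conventional
#' chrX notation `"29/48"` for females and `"Y/39"` for hemizygous males.
#' PCR calls carry no confidence intervals.
#'
#' @param path Path to the TSV file.
#' @param locus Locus id to record (default `"FMR1"`).
#' @return A genotype tibble with `call_mode = "pcr"`; see [read_eh_json()].
#' @export
read_pcr_table <- function(path, locus = "FMR1") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "genotype")
  if (!all(need %in% names(tab))) {
    stop("PCR table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  rows <- purrr::pmap(tab[need], function(sample_id, sex, genotype) {
    sex <- tolower(sex)
    vals <- strsplit(genotype, "/", fixed = TRUE)[[1]]
    is_y <- vals == "Y"
    if (sum(is_y) > 1) {
      stop("malformed PCR genotype '", genotype, "' for sample ", sample_id,
           call. = FALSE)
    }
    if (any(is_y) && sex != "male") {
      stop("ploidy error: 'Y' allele in non-male sample ", sample_id,
           call. = FALSE)
    }
    vals <- vals[!is_y]
    alleles <- parse_genotype_string(paste(vals, collapse = "/"), "",
                                     sample_id, locus, sex)
    genotype_row(sample_id, locus, sex, "pcr", alleles)
  })
  dplyr::bind_rows(empty_genotypes(), rows)
}

#' Read a 6-column PED pedigree and derive family roles
#'
#' Reads whitespace-delimited PED (`family_id individual_id father_id
#' mother_id sex phenotype`; sex 1=male/2=female, phenotype 2=affected,
#' 1=unaffected, 0/-9=unknown) and derives the role of each member:
#' founders with offspring become `father`/`mother`; offspring become
#' `male_proband`/`female_proband` when affected and
#' `male_sibling`/`female_sibling` when unaffected. Families with both
#' parents present plus at least one offspring are flagged
#' `analysis_ready` (eligible for transmission analysis); an offspring
#' referencing a parent absent from the family triggers a warning and
#' leaves the family not analysis-ready. A parent reference of the wrong
#' sex is a structural error.
#'
#' @param path Path to the PED file.
#' @return A tibble with columns `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex`, `affected`, `role`, `analysis_ready`.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "sample_id", "father_id",
                                         "mother_id", "sex_code", "pheno_code"))
  ped <- tibble::tibble(
    family_id = as.character(tab$family_id),
    sample_id = as.character(tab$sample_id),
    father_id = dplyr::na_if(as.character(tab$father_id), "0"),
    mother_id = dplyr::na_if(as.character(tab$mother_id), "0"),
    sex = dplyr::case_match(as.character(tab$sex_code),
                            "1" ~ "male", "2" ~ "female",
                            .default = NA_character_),
    affected = dplyr::case_match(as.character(tab$pheno_code),
                                 "2" ~ "affected", "1" ~ "unaffected",
                                 .default = "unknown")
  )
  annotate_pedigree(ped)
}

# role derivation + analysis-ready flag; shared by read_pedigree() and the
# synthetic-cohort generator (which builds the tibble directly)
annotate_pedigree <- function(ped) {
  out <- ped |>
    dplyr::group_by(.data$family_id) |>
    dplyr::group_modify(function(fam, key) {
      is_offspring <- !is.na(fam$father_id) | !is.na(fam$mother_id)
      # wrong-sex parent references are structural errors
      for (i in which(is_offspring)) {
        fid <- fam$father_id[i]; mid <- fam$mother_id[i]
        if (!is.na(fid) && fid %in% fam$sample_id &&
            fam$sex[match(fid, fam$sample_id)] != "male") {
          stop("pedigree structure error: father_id ", fid,
               " refers to a non-male individual in family ", key$family_id,
               call. = FALSE)
        }
        if (!is.na(mid) && mid %in% fam$sample_id &&
            fam$sex[match(mid, fam$sample_id)] != "female") {
          stop("pedigree structure error: mother_id ", mid,
               " refers to a non-female individual in family ", key$family_id,
               call. = FALSE)
        }
      }
      missing_parent <- is_offspring &
        ((!is.na(fam$father_id) & !(fam$father_id %in% fam$sample_id)) |
           (!is.na(fam$mother_id) & !(fam$mother_id %in% fam$sample_id)) |
           is.na(fam$father_id) | is.na(fam$mother_id))
      if (any(missing_parent)) {
        warning("family ", key$family_id,
                " has offspring with missing/absent parent(s); ",
                "excluded from transmission analysis", call. = FALSE)
      }
      role <- dplyr::case_when(
        !is_offspring & fam$sex == "male" ~ "father",
        !is_offspring & fam$sex == "female" ~ "mother",
        is_offspring & fam$affected == "affected" & fam$sex == "male" ~ "male_proband",
        is_offspring & fam$affected == "affected" & fam$sex == "female" ~ "female_proband",
        is_offspring & fam$sex == "male" ~ "male_sibling",
        is_offspring & fam$sex == "female" ~ "female_sibling",
        .default = NA_character_
      )
      ready <- any(is_offspring) && !any(missing_parent) &&
        any(role == "father", na.rm = TRUE) && any(role == "mother", na.rm = TRUE)
      fam$role <- role
      fam$analysis_ready <- ready
      fam
    }) |>
    dplyr::ungroup()
  out[, c("family_id", "sample_id", "father_id", "mother_id",
          "sex", "affected", "role", "analysis_ready")]
}

# render alleles in the conventional chrX table notation: "Y/23" / "29/70"
format_genotype <- function(sex, allele1, allele2) {
  dplyr::case_when(
    is.na(allele1) ~ ".",
    sex == "male" & is.na(allele2) ~ paste0("Y/", allele1),
    .default = paste0(allele1, "/", allele2)
  )
}

format_ci <- function(a1lo, a1hi, a2lo, a2hi) {
  one <- function(lo, hi) ifelse(is.na(lo), ".", paste0(lo, "-", hi))
  ifelse(is.na(a1lo) & is.na(a2lo), ".",
         ifelse(is.na(a2lo) & is.na(a2hi),
                one(a1lo, a1hi),
                paste0(one(a1lo, a1hi), "/", one(a2lo, a2hi))))
}

#' Write / read a normalized genotype table
#'
#' `write_genotype_table()` serializes a genotype tibble to TSV with the
#' conventional notation (`Y/23` for hemizygous males, `.` for no-calls,
#' CIs as `lo-hi/lo-hi`); `read_genotype_table()` reads it back. The pair
#' round-trips: reading a written table reproduces the input tibble.
#'
#' @param genotypes A genotype tibble (see [read_eh_json()]).
#' @param path Output/input TSV path.
#' @return `write_genotype_table()` returns `path` invisibly;
#'   `read_genotype_table()` returns a genotype tibble.
#' @export
write_genotype_table <- function(genotypes, path) {
  tab <- tibble::tibble(
    sample_id = genotypes$sample_id,
    locus_id = genotypes$locus_id,
    sex = genotypes$sex,
    call_mode = genotypes$call_mode,
    genotype = format_genotype(genotypes$sex, genotypes$allele1, genotypes$allele2),
    ci = format_ci(genotypes$a1_ci_lo, genotypes$a1_ci_hi,
                   genotypes$a2_ci_lo, genotypes$a2_ci_hi)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  rows <- purrr::pmap(tab, function(sample_id, locus_id, sex, call_mode,
                                    genotype, ci) {
    if (is.na(genotype) || genotype == ".") {
      return(genotype_row(sample_id, locus_id, sex, call_mode, list()))
    }
    gt <- sub("^Y/", "", genotype)
    ci <- if (is.na(ci)) "" else ci
    alleles <- parse_genotype_string(gt, ci, sample_id, locus_id, sex)
    genotype_row(sample_id, locus_id, sex, call_mode, alleles)
  })
  dplyr::bind_rows(empty_genotypes(), rows)
}

#' Write genotypes as ExpansionHunter-style JSON files
#'
#' Emits one JSON file per sample (named `<sample_id>.json`) in the public
#' ExpansionHunter output shape, parseable by [read_eh_json()].
#'
#' @param genotypes A genotype tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_eh_json <- function(genotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::pmap_chr(genotypes, function(sample_id, locus_id, sex,
                                               call_mode, allele1, allele2,
                                               a1_ci_lo, a1_ci_hi,
                                               a2_ci_lo, a2_ci_hi) {
    path <- file.path(dir, paste0(sample_id, ".json"))
    # a no-call keeps an empty genotype so the record survives a round trip
    variants <- stats::setNames(
      list(list(VariantId = locus_id, Genotype = "",
                GenotypeConfidenceInterval = "")), locus_id)
    if (!is.na(allele1)) {
      gt <- paste(stats::na.omit(c(allele1, allele2)), collapse = "/")
      ci1 <- if (is.na(a1_ci_lo)) paste0(allele1, "-", allele1) else
        paste0(a1_ci_lo, "-", a1_ci_hi)
      ci <- if (is.na(allele2)) ci1 else {
        ci2 <- if (is.na(a2_ci_lo)) paste0(allele2, "-", allele2) else
          paste0(a2_ci_lo, "-", a2_ci_hi)
        paste0(ci1, "/", ci2)
      }
      variants[[locus_id]] <- list(VariantId = locus_id, Genotype = gt,
                                   GenotypeConfidenceInterval = ci)
    }
    x <- list(
      SampleParameters = list(SampleId = sample_id,
                              Sex = tools::toTitleCase(sex)),
      LocusResults = stats::setNames(
        list(list(LocusId = locus_id, Variants = variants)), locus_id)
    )
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
    path
  })
  invisible(paths)
}

#' Write genotypes as a repeat-count VCF
#'
#' Emits a single VCF with one STR record for the locus and per-sample
#' `GT:REPCN:REPCI` fields, parseable by [read_eh_vcf()].
#'
#' @param genotypes A genotype tibble (single locus).
#' @param path Output VCF path.
#' @return Invisibly, `path`.
#' @export
write_eh_vcf <- function(genotypes, path) {
  locus <- unique(genotypes$locus_id)
  stopifnot(length(locus) <= 1)
  if (length(locus) == 0) locus <- "FMR1"
  header <- c(
    "##fileformat=VCFv4.1",
    "##contig=<ID=chrX>",
    "##INFO=<ID=VARID,Number=1,Type=String,Description=\"Variant id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=REPCN,Number=1,Type=String,Description=\"Number of repeat units spanned by the allele\">",
    "##FORMAT=<ID=REPCI,Number=1,Type=String,Description=\"Confidence interval for REPCN\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_id), collapse = "\t")
  )
  fields <- purrr::pmap_chr(genotypes, function(sample_id, locus_id, sex,
                                                call_mode, allele1, allele2,
                                                a1_ci_lo, a1_ci_hi,
                                                a2_ci_lo, a2_ci_hi) {
    if (is.na(allele1)) return("./.:.:.")
    repcn <- paste(stats::na.omit(c(allele1, allele2)), collapse = "/")
    ci1 <- if (is.na(a1_ci_lo)) paste0(allele1, "-", allele1) else
      paste0(a1_ci_lo, "-", a1_ci_hi)
    repci <- if (is.na(allele2)) ci1 else {
      ci2 <- if (is.na(a2_ci_lo)) paste0(allele2, "-", allele2) else
        paste0(a2_ci_lo, "-", a2_ci_hi)
      paste0(ci1, "/", ci2)
    }
    gt <- if (is.na(allele2)) "1" else "1/1"
    paste(gt, repcn, repci, sep = ":")
  })
  record <- paste(c("chrX", "147912050", locus, "C", "<STR>", ".", "PASS",
                    paste0("VARID=", locus), "GT:REPCN:REPCI", fields),
                  collapse = "\t")
  writeLines(c(header, record), path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
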