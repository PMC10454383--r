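#' Configuration for the synthetic ASD-family cohort generator
#'
#' Builds the parameter set for [simulate_cohort()]. The defaults emulate
#' the statistical structure of large simplex-ASD WGS cohorts screened for
#' the *FMR1* CGG repeat: trio/quad nuclear families with a strong male
#' skew among probands and roughly balanced siblings; a founder allele
#' distribution with modes at 29 and 30 repeats, a thin gray-zone band and
#' a rare premutation tail (~0.8% allele frequency, giving ~1.6% female
#' and ~0.8% male carrier prevalence); rare length changes on
#' transmission, with instability increasing with the parental allele
#' class; and an ExpansionHunter-like measurement model in which long
#' alleles are occasionally inflated (off-target reads) and confidence
#' intervals broaden with repeat length.
#'
#' @param n_families Number of nuclear families.
#' @param quad_fraction Fraction of families with an unaffected sibling
#'   (the rest are trios).
#' @param proband_male_frac,sibling_male_frac Probability that a
#'   proband/sibling is male.
#' @param allele_lengths,allele_weights Founder allele mixture (discrete
#'   lengths and weights; weights are normalized).
#' @param instability_prob Named numeric: per-transmission probability of
#'   a length change, by the parental allele's range class.
#' @param step_lengths,step_weights Signed repeat-unit step distribution
#'   applied when a transmission is unstable (mostly small expansions,
#'   occasional large jumps, rare contractions).
#' @param measurement_mode `"none"` (observed = truth), `"eh_region_only"`
#'   or `"eh_offtarget"`. Off-target calling inflates alleles more often
#'   and by larger amounts than region-only calling.
#' @param inflation_prob Named numeric: probability that a measured allele
#'   is inflated, by true allele class, for the off-target mode.
#' @param inflation_max Largest inflation step (off-target mode); steps
#'   are drawn from a decreasing-weight distribution on
#'   `5:inflation_max`. Region-only calling uses the same shape scaled
#'   down (`region_only_shrink`).
#' @param region_only_shrink Multiplier (< 1) applied to both the
#'   inflation probability and step size under region-only calling.
#' @param ci_width_slope Confidence-interval half-width per repeat unit
#'   above 30 (CI width grows linearly with measured length).
#' @param no_call_rate Per-sample probability of a no-call.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return A list of class `fmr_sim_config`.
#' @export
cohort_config <- function(n_families = 500,
                          quad_fraction = 0.78,
                          proband_male_frac = 0.87,
                          sibling_male_frac = 0.47,
                          allele_lengths = NULL,
                          allele_weights = NULL,
                          instability_prob = c(normal = 0.002, gray = 0.04,
                                               premutation = 0.20, full = 0.20),
                          step_lengths = c(-3, -2, -1, 1, 2, 3, 5, 8, 15, 30),
                          step_weights = c(0.03, 0.05, 0.07, 0.30, 0.20,
                                           0.15, 0.08, 0.06, 0.04, 0.02),
                          measurement_mode = c("none", "eh_region_only",
                                               "eh_offtarget"),
                          inflation_prob = c(normal = 0.002, gray = 0.05,
                                             premutation = 0.5, full = 0.5),
                          inflation_max = 120,
                          region_only_shrink = 0.3,
                          ci_width_slope = 0.15,
                          no_call_rate = 0.002,
                          seed = 1L) {
  measurement_mode <- match.arg(measurement_mode)
  if (is.null(allele_lengths)) {
    normal_l <- c(20, 23, 27, 29, 30, 31, 32, 33, 36, 39, 40)
    normal_w <- c(0.02, 0.05, 0.03, 0.34, 0.30, 0.08, 0.05, 0.04,
                  0.03, 0.03, 0.03)
    gray_l <- 41:54
    premut_l <- 55:120
    allele_lengths <- c(normal_l, gray_l, premut_l)
    allele_weights <- c(normal_w / sum(normal_w) * 0.972,
                        rep(0.020 / length(gray_l), length(gray_l)),
                        rep(0.008 / length(premut_l), length(premut_l)))
  }
  if (length(allele_lengths) == 0 || length(allele_lengths) != length(allele_weights)) {
    stop("degenerate allele mixture", call. = FALSE)
  }
  if (any(allele_weights < 0) || sum(allele_weights) <= 0) {
    stop("allele weights must be non-negative and sum > 0", call. = FALSE)
  }
  probs <- c(quad_fraction, proband_male_frac, sibling_male_frac,
             instability_prob, inflation_prob, no_call_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(setequal(names(instability_prob), range_classes),
            setequal(names(inflation_prob), range_classes))
  out <- list(
    n_families = as.integer(n_families),
    quad_fraction = quad_fraction,
    proband_male_frac = proband_male_frac,
    sibling_male_frac = sibling_male_frac,
    allele_lengths = as.integer(allele_lengths),
    allele_weights = allele_weights / sum(allele_weights),
    instability_prob = instability_prob[range_classes],
    step_lengths = as.integer(step_lengths),
    step_weights = step_weights / sum(step_weights),
    measurement_mode = measurement_mode,
    inflation_prob = inflation_prob[range_classes],
    inflation_max = as.integer(inflation_max),
    region_only_shrink = region_only_shrink,
    ci_width_slope = ci_width_slope,
    no_call_rate = no_call_rate,
    seed = as.integer(seed)
  )
  class(out) <- "fmr_sim_config"
  out
}

#' Expected carrier prevalence implied by a generator configuration
#'
#' Closed-form expectation of the per-sex founder carrier prevalence
#' under the configured allele mixture (before transmission instability
#' and measurement error): a male founder is a carrier with probability
#' `q`, the mixture mass at or above the premutation threshold; a female
#' founder with probability `1 - (1 - q)^2`.
#'
#' @param config A [cohort_config()].
#' @param catalog A [locus_catalog()].
#' @return Named list with `allele_freq`, `male`, `female`.
#' @export
expected_carrier_prevalence <- function(config, catalog = locus_catalog()) {
  q <- sum(config$allele_weights[config$allele_lengths > catalog$gray_max])
  list(allele_freq = q, male = q, female = 1 - (1 - q)^2)
}

# draw founder alleles from the configured mixture
sample_alleles <- function(config, k) {
  if (k == 0) return(integer(0))
  sample(config$allele_lengths, k, replace = TRUE,
         prob = config$allele_weights)
}

# apply transmission instability to parental alleles (vectorized)
mutate_transmitted <- function(src, config, catalog) {
  k <- length(src)
  if (k == 0) return(integer(0))
  cls <- as.character(classify_allele_quiet(src, catalog))
  p <- unname(config$instability_prob[cls])
  event <- stats::runif(k) < p
  delta <- integer(k)
  if (any(event)) {
    delta[event] <- sample(config$step_lengths, sum(event), replace = TRUE,
                           prob = config$step_weights)
  }
  pmax(src + delta, 1L)
}

#' Apply the measurement model to true genotypes
#'
#' Transforms a table of true alleles into observed calls under the
#' configured measurement mode: no change (`"none"`), or random inflation
#' of alleles — with probability and magnitude increasing in true length —
#' emulating off-target-read overestimation (`"eh_offtarget"`) or its
#' milder region-only counterpart (`"eh_region_only"`). Inflation is
#' non-negative by construction, so an observed call never understates a
#' true expanded allele. Confidence intervals broaden linearly with the
#' measured length. Per-sample no-calls are introduced at
#' `config$no_call_rate`.
#'
#' This function draws from the current RNG stream; [simulate_cohort()]
#' seeds the stream from `config$seed` before calling it.
#'
#' @param truth Genotype tibble of true alleles.
#' @param config A [cohort_config()].
#' @param mode Measurement mode override (defaults to the config's).
#' @param catalog A [locus_catalog()].
#' @return Genotype tibble of observed calls (`call_mode` set to the mode,
#'   or `"truth"` when mode is `"none"`).
#' @export
measure_genotypes <- function(truth, config, mode = config$measurement_mode,
                              catalog = locus_catalog()) {
  obs <- tibble::as_tibble(truth)
  n <- nrow(obs)
  obs$call_mode <- if (mode == "none") "truth" else mode
  if (n == 0) return(obs[, genotype_cols])
  if (mode == "none") {
    # identity measurement: truth passes through untouched (incl. CIs);
    # only the no-call thinning below applies
    nocall <- stats::runif(n) < config$no_call_rate
    for (col in c("allele1", "allele2", "a1_ci_lo", "a1_ci_hi",
                  "a2_ci_lo", "a2_ci_hi")) {
      obs[[col]][nocall] <- NA_integer_
    }
    return(obs[, genotype_cols])
  }
  inflate <- function(len) {
    out <- len
    ok <- !is.na(len)
    if (mode != "none" && any(ok)) {
      shrink <- if (mode == "eh_region_only") config$region_only_shrink else 1
      cls <- as.character(classify_allele_quiet(len[ok], catalog))
      p <- unname(config$inflation_prob[cls]) * shrink
      event <- stats::runif(sum(ok)) < p
      steps <- 5:config$inflation_max
      w <- 1 / steps  # decreasing weight: small inflations more common
      k <- sum(event)
      add <- integer(sum(ok))
      if (k > 0) {
        add[event] <- pmax(1L, as.integer(round(
          sample(steps, k, replace = TRUE, prob = w) * shrink)))
      }
      out[ok] <- len[ok] + add
    }
    out
  }
  a1 <- inflate(obs$allele1)
  a2 <- inflate(obs$allele2)
  # keep alleles sorted ascending after inflation
  lo <- pmin(a1, a2, na.rm = FALSE)
  obs$allele1 <- ifelse(is.na(a2), a1, lo)
  obs$allele2 <- ifelse(is.na(a2), NA_integer_, pmax(a1, a2))
  hw <- function(len) as.integer(round(config$ci_width_slope * pmax(0, len - 30)))
  obs$a1_ci_lo <- pmax(obs$allele1 - hw(obs$allele1), 0L)
  obs$a1_ci_hi <- obs$allele1 + hw(obs$allele1)
  obs$a2_ci_lo <- pmax(obs$allele2 - hw(obs$allele2), 0L)
  obs$a2_ci_hi <- obs$allele2 + hw(obs$allele2)
  nocall <- stats::runif(n) < config$no_call_rate
  obs$allele1[nocall] <- NA_integer_
  obs$allele2[nocall] <- NA_integer_
  obs$a1_ci_lo[nocall] <- NA_integer_
  obs$a1_ci_hi[nocall] <- NA_integer_
  obs$a2_ci_lo[nocall] <- NA_integer_
  obs$a2_ci_hi[nocall] <- NA_integer_
  obs[, genotype_cols]
}

#' Simulate an ASD-family-style cohort with known ground truth
#'
#' Generates nuclear trio/quad families with X-linked transmission of a
#' single *FMR1*-like CGG repeat locus: founder alleles are drawn i.i.d.
#' from the configured mixture; each son receives one maternal allele
#' (picked uniformly) and each daughter the father's single allele plus
#' one maternal allele, each transmission subject to the instability
#' model; observed calls are the truth transformed by the measurement
#' model and no-calls. Sons never carry a paternal X by construction. The
#' run is deterministic for a fixed `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param catalog A [locus_catalog()].
#' @return Object of class `fmr_cohort`: list with `pedigree` (annotated
#'   pedigree tibble), `truth` (true genotype tibble), `observed`
#'   (genotype tibble after measurement), `truth_records` (one row per
#'   offspring allele: `origin`, `source_allele`, `true_allele`, `delta`,
#'   `de_novo`) and the `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_families = 20, seed = 7))
#' cohort$truth_records
#' @export
simulate_cohort <- function(config = cohort_config(),
                            catalog = locus_catalog()) {
  stopifnot(inherits(config, "fmr_sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_families
  fam <- sprintf("F%05d", seq_len(n))
  father_id <- paste0(fam, "_fa")
  mother_id <- paste0(fam, "_mo")
  is_quad <- stats::runif(n) < config$quad_fraction
  father_al <- sample_alleles(config, n)
  mother_a1 <- sample_alleles(config, n)
  mother_a2 <- sample_alleles(config, n)

  # offspring roster: one proband per family, one unaffected sibling in quads
  offspring <- dplyr::bind_rows(
    tibble::tibble(fi = seq_len(n), sample_id = paste0(fam, "_p1"),
                   affected = rep("affected", n),
                   sex = as.character(
                     ifelse(stats::runif(n) < config$proband_male_frac,
                            "male", "female"))),
    tibble::tibble(fi = which(is_quad),
                   sample_id = paste0(fam[is_quad], "_s1"),
                   affected = rep("unaffected", sum(is_quad)),
                   sex = as.character(
                     ifelse(stats::runif(sum(is_quad)) < config$sibling_male_frac,
                            "male", "female")))
  )
  k <- nrow(offspring)
  pick <- stats::runif(k) < 0.5
  src_mat <- ifelse(pick, mother_a1[offspring$fi], mother_a2[offspring$fi])
  mat_allele <- mutate_transmitted(as.integer(src_mat), config, catalog)
  is_f <- offspring$sex == "female"
  src_pat <- ifelse(is_f, father_al[offspring$fi], NA_integer_)
  pat_allele <- rep(NA_integer_, k)
  if (any(is_f)) {
    pat_allele[is_f] <- mutate_transmitted(as.integer(src_pat[is_f]),
                                           config, catalog)
  }

  cls <- function(x) classify_allele_quiet(x, catalog)
  premut <- function(x) !is.na(x) & cls(x) >= "premutation"
  truth_records <- dplyr::bind_rows(
    tibble::tibble(
      family_id = fam[offspring$fi], sample_id = offspring$sample_id,
      origin = "maternal", source_allele = as.integer(src_mat),
      true_allele = mat_allele
    ),
    tibble::tibble(
      family_id = fam[offspring$fi[is_f]],
      sample_id = offspring$sample_id[is_f],
      origin = "paternal", source_allele = as.integer(src_pat[is_f]),
      true_allele = pat_allele[is_f]
    )
  ) |>
    dplyr::mutate(delta = .data$true_allele - .data$source_allele,
                  de_novo = premut(.data$true_allele) &
                    !premut(.data$source_allele)) |>
    dplyr::arrange(.data$sample_id, .data$origin)

  locus <- catalog$locus_id
  truth <- dplyr::bind_rows(
    genotype_tbl(father_id, locus, "male", father_al, NA_integer_),
    genotype_tbl(mother_id, locus, "female", mother_a1, mother_a2),
    genotype_tbl(offspring$sample_id, locus, offspring$sex,
                 ifelse(is_f, pmin(pat_allele, mat_allele), mat_allele),
                 ifelse(is_f, pmax(pat_allele, mat_allele), NA_integer_))
  )
  observed <- measure_genotypes(truth, config, catalog = catalog)

  ped <- dplyr::bind_rows(
    tibble::tibble(family_id = fam, sample_id = father_id,
                   father_id = NA_character_, mother_id = NA_character_,
                   sex = "male", affected = "unaffected"),
    tibble::tibble(family_id = fam, sample_id = mother_id,
                   father_id = NA_character_, mother_id = NA_character_,
                   sex = "female", affected = "unaffected"),
    tibble::tibble(family_id = fam[offspring$fi],
                   sample_id = offspring$sample_id,
                   father_id = father_id[offspring$fi],
                   mother_id = mother_id[offspring$fi],
                   sex = offspring$sex, affected = offspring$affected)
  ) |> dplyr::arrange(.data$family_id)
  pedigree <- if (nrow(ped) > 0) annotate_pedigree(ped) else {
    dplyr::mutate(ped, role = character(0), analysis_ready = logical(0))
  }

  out <- list(pedigree = pedigree, truth = truth, observed = observed,
              truth_records = truth_records, config = config)
  class(out) <- "fmr_cohort"
  out
}

# truth genotype rows (alleles already sorted by caller), width-0 CIs
genotype_tbl <- function(sample_id, locus, sex, a1, a2) {
  tibble::tibble(
    sample_id = sample_id, locus_id = locus, sex = sex, call_mode = "truth",
    allele1 = as.integer(a1), allele2 = as.integer(a2),
    a1_ci_lo = as.integer(a1), a1_ci_hi = as.integer(a1),
    a2_ci_lo = as.integer(a2), a2_ci_hi = as.integer(a2)
  )
}

#' @export
print.fmr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d families, %d individuals (seed %d, measurement %s)\n",
              x$config$n_families, nrow(x$truth), x$config$seed,
              x$config$measurement_mode))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits a 6-column PED file, the true and observed genotype tables
#' (TSV), the per-allele truth records (TSV) and, optionally, the
#' observed calls as ExpansionHunter-style per-sample JSON or a merged
#' repeat-count VCF. All files parse cleanly through the package readers.
#'
#' @param cohort An `fmr_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param formats Extra observed-call formats to write: any of `"json"`,
#'   `"vcf"`.
#' @return Invisibly, a named list of written paths.
#' @export
write_cohort <- function(cohort, dir, formats = character()) {
  stopifnot(inherits(cohort, "fmr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- cohort$pedigree
  ped_tab <- data.frame(
    family_id = ped$family_id, sample_id = ped$sample_id,
    father_id = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother_id = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "male", 1L, 2L),
    pheno = dplyr::case_match(ped$affected, "affected" ~ 2L,
                              "unaffected" ~ 1L, .default = 0L)
  )
  paths <- list(
    pedigree = file.path(dir, "pedigree.ped"),
    truth = file.path(dir, "truth_genotypes.tsv"),
    observed = file.path(dir, "observed_genotypes.tsv"),
    truth_records = file.path(dir, "truth_records.tsv")
  )
  utils::write.table(ped_tab, paths$pedigree, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_genotype_table(cohort$truth, paths$truth)
  write_genotype_table(cohort$observed, paths$observed)
  utils::write.table(cohort$truth_records, paths$truth_records, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if ("json" %in% formats) {
    paths$json_dir <- file.path(dir, "eh_json")
    write_eh_json(cohort$observed, paths$json_dir)
  }
  if ("vcf" %in% formats) {
    paths$vcf <- file.path(dir, "observed.vcf")
    write_eh_vcf(cohort$observed, paths$vcf)
  }
  invisible(paths)
}
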