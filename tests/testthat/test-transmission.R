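# one-family scaffold: genotypes given as conventional strings
family_calls <- function(father, mother, offspring, tolerance = 5) {
  # offspring: named list sample_id -> list(gt, sex, affected)
  ped <- ped_fixture("FAM", lapply(offspring, function(o) c(o$sex, o$affected)))
  g <- dplyr::bind_rows(
    gt_fixture("FAM_fa", father), gt_fixture("FAM_mo", mother),
    dplyr::bind_rows(lapply(names(offspring), function(id) {
      gt_fixture(id, offspring[[id]]$gt)
    }))
  )
  list(calls = call_transmissions(g, ped, tolerance = tolerance),
       genotypes = g, pedigree = ped)
}

test_that("parental origin follows the minimum-distance rule", {
  # son matched to the exact maternal allele
  r <- assign_parental_origin(48, "male", 23, c(29, 48))
  expect_equal(r$origin, "maternal")
  expect_equal(r$parent_allele, 48)
  expect_equal(r$delta, 0)

  # daughter partitioned one-paternal/one-maternal at zero total cost
  r2 <- assign_parental_origin(c(27, 30), "female", 27, c(29, 30))
  expect_equal(r2$parent_allele[r2$origin == "paternal"], 27)
  expect_equal(r2$parent_allele[r2$origin == "maternal"], 30)
  expect_equal(r2$delta, c(0, 0))

  # distant allele still matched to the nearest, with a large delta
  r3 <- assign_parental_origin(80, "male", 30, c(29, 30))
  expect_equal(r3$parent_allele, 30)
  expect_equal(r3$delta, 50)

  expect_error(assign_parental_origin(c(30, 31), "male", 30, c(29, 30)),
               "inconsistent")
})

test_that("daughter partition equals the exhaustive two-assignment oracle", {
  set.seed(31)
  for (i in 1:200) {
    fa <- sample(20:90, 1)
    mo <- sort(sample(20:90, 2, replace = TRUE))
    dau <- sort(c(fa + sample(-3:3, 1), sample(mo, 1) + sample(-3:3, 1)))
    r <- assign_parental_origin(dau, "female", fa, mo)
    total <- sum(abs(r$delta))
    expect_equal(total, oracle_partition(dau, fa, mo))
  }
})

test_that("transmission categories cover inherited, de novo and carrier-parent cases", {
  # paternal premutation transmitted to a daughter
  f <- family_calls("Y/85", "29/30",
                    list(D1 = list(gt = "30/85", sex = "female",
                                   affected = "affected")))
  d <- f$calls
  pat <- d[d$origin == "paternal", ]
  expect_equal(pat$category, "premutation_transmitted")
  expect_equal(pat$parent_allele, 85L)
  mat <- d[d$origin == "maternal", ]
  expect_equal(mat$category, "normal_transmitted")

  # carrier mother transmitting her normal allele (non-inheriting offspring)
  f2 <- family_calls("Y/30", "29/98",
                     list(S1 = list(gt = "Y/29", sex = "male",
                                    affected = "affected")))
  expect_equal(f2$calls$category, "normal_from_carrier")
  expect_true(f2$calls$parent_is_carrier)

  # no parental premutation at all: de novo expansion, large delta
  f3 <- family_calls("Y/30", "29/30",
                     list(S1 = list(gt = "Y/80", sex = "male",
                                    affected = "affected")))
  expect_equal(f3$calls$category, "de_novo")
  expect_equal(f3$calls$delta, 50L)
  expect_true(f3$calls$poor_match)
  expect_false(f3$calls$x_linkage_violation)
})

test_that("a son matching only the father's expanded allele is flagged, not counted", {
  f <- family_calls("Y/85", "29/30",
                    list(S1 = list(gt = "Y/85", sex = "male",
                                   affected = "affected")))
  expect_equal(f$calls$origin, "maternal")  # sons have no paternal option
  expect_true(f$calls$x_linkage_violation)
  ts <- summarize_transmissions(f$calls, f$genotypes, f$pedigree)
  expect_equal(ts$n_x_violations, 1)
  expect_equal(sum(ts$rows$count), 0)  # reported, never counted
})

test_that("premutation contraction is counted as carrier-parent normal transmission", {
  f <- family_calls("Y/30", "29/60",
                    list(S1 = list(gt = "Y/52", sex = "male",
                                   affected = "affected")))
  expect_equal(f$calls$category, "normal_from_carrier")
  expect_true(f$calls$contraction)
})

test_that("families with a missing parent genotype are skipped with a warning", {
  ped <- ped_fixture("FAM", list(S1 = c("male", "affected")))
  g <- dplyr::bind_rows(gt_fixture("FAM_mo", "29/30"),
                        gt_fixture("S1", "Y/29"))
  expect_warning(calls <- call_transmissions(g, ped), "missing parental")
  expect_equal(nrow(calls), 0)
})

test_that("summary percentages use the carrier-family offspring denominator", {
  counts <- tibble::tibble(parent = "mother", offspring_role = "male_proband",
                           allele_range = "premutation", count = 10)
  rows <- transmission_percentages(counts, n_offspring = 141)
  expect_equal(nrow(rows), 20)
  expect_equal(round(rows$percentage[rows$parent %in% "mother" &
                                       rows$offspring_role == "male_proband" &
                                       rows$allele_range == "premutation"], 2),
               7.09)
  rows2 <- transmission_percentages(dplyr::mutate(counts, count = 15), 99)
  expect_equal(round(max(rows2$percentage), 2), 15.15)

  # zero denominator: all-zero summary, flagged as undefined
  rows0 <- transmission_percentages(counts[0, ], 0)
  expect_true(all(rows0$percentage == 0))
  expect_false(any(rows0$percent_defined))
})

test_that("with stable transmission and no measurement error, recovery is exact", {
  # instability off: every offspring allele equals a parental allele, so
  # minimum-distance assignment is exact and every call has delta 0
  cfg <- cohort_config(n_families = 1500, seed = 61,
                       measurement_mode = "none", no_call_rate = 0,
                       instability_prob = c(normal = 0, gray = 0,
                                            premutation = 0, full = 0))
  cohort <- simulate_cohort(cfg)
  calls <- call_transmissions(cohort$observed, cohort$pedigree)
  expect_true(all(calls$delta == 0))
  joined <- dplyr::inner_join(
    calls, cohort$truth_records,
    by = c("family_id", "offspring_id" = "sample_id", "origin"))
  expect_equal(nrow(joined), nrow(calls))
  expect_true(all(joined$offspring_allele == joined$true_allele))
  ts <- summarize_transmissions(calls, cohort$observed, cohort$pedigree)
  tr <- cohort$truth_records
  cls <- function(x) suppressWarnings(classify_allele(x))
  expect_equal(ts$n_transmitted,
               sum(cls(tr$true_allele) >= "premutation" &
                     cls(tr$source_allele) >= "premutation"))
  expect_equal(ts$n_de_novo, 0)
  expect_equal(sum(tr$de_novo), 0)
})

test_that("father-to-son premutation transmissions are structurally zero", {
  cohort <- simulate_cohort(cohort_config(n_families = 800, seed = 5,
                                          measurement_mode = "none",
                                          no_call_rate = 0))
  calls <- call_transmissions(cohort$observed, cohort$pedigree)
  sons <- calls[calls$offspring_sex == "male", ]
  expect_true(all(sons$origin == "maternal"))
  ts <- summarize_transmissions(calls, cohort$observed, cohort$pedigree)
  expect_equal(sum(ts$rows$count[ts$rows$parent %in% "father" &
                                   ts$rows$offspring_role %in%
                                     c("male_proband", "male_sibling")]), 0)
})
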