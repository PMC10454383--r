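test_that("configuration validation rejects degenerate inputs", {
  expect_error(cohort_config(allele_lengths = integer(0),
                             allele_weights = numeric(0)), "degenerate")
  expect_error(cohort_config(quad_fraction = 1.2), "probabilities")
  expect_error(cohort_config(no_call_rate = -0.1), "probabilities")
})

test_that("a mixture without a premutation tail yields zero carriers", {
  cfg <- cohort_config(n_families = 300, seed = 3,
                       allele_lengths = c(29, 30, 31),
                       allele_weights = c(0.4, 0.4, 0.2),
                       instability_prob = c(normal = 0, gray = 0,
                                            premutation = 0, full = 0))
  cohort <- simulate_cohort(cfg)
  st <- classify_genotypes(cohort$truth)
  expect_equal(sum(st$is_expanded), 0)
})

test_that("with measurement off the observed calls equal the truth", {
  cfg <- cohort_config(n_families = 150, seed = 21,
                       measurement_mode = "none", no_call_rate = 0)
  cohort <- simulate_cohort(cfg)
  expect_identical(cohort$observed, cohort$truth)
})

test_that("a fixed seed reproduces the cohort and its files byte-identically", {
  cfg <- cohort_config(n_families = 60, seed = 99,
                       measurement_mode = "eh_offtarget")
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1, formats = "vcf")
  write_cohort(c2, d2, formats = "vcf")
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the truth obeys X-linked inheritance by construction", {
  cohort <- simulate_cohort(cohort_config(n_families = 400, seed = 13))
  tr <- cohort$truth_records
  sons <- cohort$pedigree$sample_id[cohort$pedigree$sex == "male" &
                                      !is.na(cohort$pedigree$father_id)]
  expect_false(any(tr$origin == "paternal" & tr$sample_id %in% sons))
  # daughters carry exactly one paternal-origin allele each
  daughters <- cohort$pedigree$sample_id[cohort$pedigree$sex == "female" &
                                           !is.na(cohort$pedigree$father_id)]
  pat <- table(tr$sample_id[tr$origin == "paternal"])
  expect_setequal(names(pat), daughters)
  expect_true(all(pat == 1))
})

test_that("confidence-interval width is non-decreasing in allele length", {
  cohort <- simulate_cohort(cohort_config(n_families = 400, seed = 8,
                                          measurement_mode = "eh_offtarget",
                                          no_call_rate = 0))
  obs <- cohort$observed
  len <- c(obs$allele1, obs$allele2)
  width <- c(obs$a1_ci_hi - obs$a1_ci_lo, obs$a2_ci_hi - obs$a2_ci_lo)
  keep <- !is.na(len)
  ord <- order(len[keep])
  expect_true(all(diff(width[keep][ord]) >= 0 |
                    diff(len[keep][ord]) == 0))
  fit <- stats::coef(stats::lm(width[keep] ~ len[keep]))
  expect_gte(fit[2], 0)
})

test_that("founder carrier prevalence matches its analytic expectation", {
  cfg <- cohort_config(n_families = 3000, seed = 77,
                       measurement_mode = "none", no_call_rate = 0)
  expected <- expected_carrier_prevalence(cfg)
  cohort <- simulate_cohort(cfg)
  st <- classify_genotypes(cohort$truth)
  ped <- cohort$pedigree
  mothers <- st[st$sample_id %in% ped$sample_id[ped$role %in% "mother"], ]
  fathers <- st[st$sample_id %in% ped$sample_id[ped$role %in% "father"], ]
  for (grp in list(list(obs = mean(mothers$is_expanded), p = expected$female,
                        n = nrow(mothers)),
                   list(obs = mean(fathers$is_expanded), p = expected$male,
                        n = nrow(fathers)))) {
    se <- sqrt(grp$p * (1 - grp$p) / grp$n)
    expect_lt(abs(grp$obs - grp$p), 4 * se)
  }
})

test_that("a written cohort reads back through the io layer unchanged", {
  cohort <- simulate_cohort(cohort_config(n_families = 50, seed = 4,
                                          measurement_mode = "eh_offtarget"))
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir, formats = c("json", "vcf"))
  ped <- read_pedigree(paths$pedigree)
  expect_equal(nrow(ped), nrow(cohort$pedigree))
  expect_true(all(ped$analysis_ready))

  obs <- read_genotype_table(paths$observed)
  expect_equal(obs, cohort$observed)
  carriers_before <- sum(classify_genotypes(cohort$observed)$is_expanded,
                         na.rm = TRUE)
  expect_equal(sum(classify_genotypes(obs)$is_expanded, na.rm = TRUE),
               carriers_before)
  js <- read_eh_json(list.files(paths$json_dir, full.names = TRUE),
                     call_mode = "eh_offtarget")
  expect_equal(sum(classify_genotypes(js)$is_expanded, na.rm = TRUE),
               carriers_before)
})

test_that("an empty cohort is valid end to end", {
  cohort <- simulate_cohort(cohort_config(n_families = 0, seed = 1))
  expect_equal(nrow(cohort$truth), 0)
  expect_equal(nrow(cohort$pedigree), 0)
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir)
  expect_equal(nrow(read_genotype_table(paths$observed)), 0)
})
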