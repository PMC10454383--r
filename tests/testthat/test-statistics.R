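test_that("burden odds ratios and p-values match published sex-stratified tests", {
  male_ssc <- fisher_burden(13, 2042, 8, 897)
  expect_equal(round(male_ssc$odds_ratio, 2), 0.71)
  expect_equal(round(male_ssc$p_value, 2), 0.48)
  female_ssc <- fisher_burden(6, 315, 11, 997)
  expect_equal(round(female_ssc$odds_ratio, 2), 1.73)
  expect_equal(round(female_ssc$p_value, 2), 0.27)
})

test_that("degenerate burden tables follow the symmetry and zero-cell contracts", {
  same <- fisher_burden(5, 95, 5, 95)
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p_value, 1)
  zero <- compare_prevalence(42, 2365, 0, 500)
  expect_equal(zero$odds_ratio, Inf)
  expect_lt(zero$p_value, 1)
  expect_gt(zero$p_value, 0)
  empty_margin <- fisher_burden(0, 0, 3, 7)
  expect_equal(empty_margin$p_value, 1)
  expect_equal(compare_prevalence(2, 50, 2, 50)$p_value, 1)
})

test_that("odds-ratio invariances hold across random tables", {
  set.seed(91)
  for (i in 1:50) {
    x <- sample(1:40, 4, replace = TRUE)
    or1 <- fisher_burden(x[1], x[2], x[3], x[4])$odds_ratio
    # swapping both rows and both columns leaves the OR unchanged
    or2 <- fisher_burden(x[4], x[3], x[2], x[1])$odds_ratio
    expect_equal(or1, or2)
    # swapping rows inverts it
    or3 <- fisher_burden(x[3], x[4], x[1], x[2])$odds_ratio
    expect_equal(or3, 1 / or1)
  }
})

test_that("exact p equals the hypergeometric enumeration oracle (small sweep)", {
  for (tot in 2:12) {
    for (a in 0:tot) for (b in 0:(tot - a)) for (cc in 0:(tot - a - b)) {
      d <- tot - a - b - cc
      p <- fisher_burden(a, b, cc, d)$p_value
      expect_equal(p, oracle_fisher_p(a, b, cc, d), tolerance = 1e-10)
    }
  }
})

test_that("female HWE chi-square reproduces the published QC values", {
  ssc <- hwe_female_chi2(n_het = 59, n_hom_carrier = 0, n_females = 3694)
  expect_equal(round(ssc$chi2, 2), 0.24)
  expect_equal(round(ssc$p_value, 2), 0.89)
  spark <- hwe_female_chi2(n_het = 39, n_hom_carrier = 0, n_females = 4827)
  expect_equal(round(spark$chi2, 2), 0.08)
  expect_equal(round(spark$p_value, 2), 0.96)
  # df = 1 alternative only changes the tail conversion, not the statistic
  df1 <- hwe_female_chi2(59, 0, 3694, df = 1)
  expect_equal(df1$chi2, ssc$chi2)
  expect_lt(df1$p_value, ssc$p_value)
})

test_that("HWE statistic is zero at exact equilibrium and scales linearly", {
  # n chosen so expected counts are integers: q = 0.1, n = 100
  exact <- hwe_female_chi2(n_het = 18, n_hom_carrier = 1, n_females = 100)
  expect_equal(exact$allele_freq, 0.1)
  expect_equal(exact$chi2, 0, tolerance = 1e-12)
  expect_equal(exact$p_value, 1)

  base <- hwe_female_chi2(30, 2, 400)
  scaled <- hwe_female_chi2(30 * 7, 2 * 7, 400 * 7)
  expect_equal(scaled$chi2, 7 * base$chi2, tolerance = 1e-10)

  expect_error(hwe_female_chi2(5, 0, 0), "positive")
  expect_error(hwe_female_chi2(80, 30, 100), "exceed")
})

test_that("parental-age Z-test behaves at its limits and under the null", {
  ages <- c(30.5, 33.1, 28.9, 41.0, 35.2, 30.0)
  same <- parental_age_ztest(ages, ages)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  g1 <- rep(c(29.8, 30.2), 50)
  g2 <- g1 + 10 * sqrt(2 * stats::var(g1) / length(g1))
  expect_lt(parental_age_ztest(g1, g2)$p_value, 1e-12)

  expect_error(parental_age_ztest(30, c(31, 32)), "at least two")

  # p-values are uniform under the null (KS at alpha = 0.01)
  set.seed(17)
  pvals <- replicate(1000, {
    parental_age_ztest(stats::rnorm(60, 33, 5), stats::rnorm(60, 33, 5))$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("prevalence summaries count carriers per role with pooled rows", {
  g <- dplyr::bind_rows(
    gt_fixture("FAMA_fa", "Y/60"), gt_fixture("FAMA_mo", "29/30"),
    gt_fixture("p1", "Y/61"),
    gt_fixture("FAMB_fa", "Y/30"), gt_fixture("FAMB_mo", "29/70"),
    gt_fixture("p2", "29/30")
  )
  ped <- dplyr::bind_rows(
    ped_fixture("FAMA", list(p1 = c("male", "affected"))),
    ped_fixture("FAMB", list(p2 = c("female", "affected")))
  )
  prev <- summarize_prevalence(g, ped)
  expect_equal(prev$carriers[prev$role == "father"], 1)
  expect_equal(prev$carriers[prev$role == "mother"], 1)
  expect_equal(prev$percent[prev$role == "male_proband"], 100)
  expect_equal(prev$carriers[prev$role == "total"], 3)
  expect_equal(prev$genotyped[prev$role == "male_offspring"], 1)

  # a role with zero genotyped reports NA percent
  g2 <- g
  g2$allele1[g2$sample_id == "p2"] <- NA
  g2$allele2[g2$sample_id == "p2"] <- NA
  prev2 <- summarize_prevalence(g2, ped)
  expect_true(is.na(prev2$percent[prev2$role == "female_proband"]))
  expect_equal(prev2$processed[prev2$role == "female_proband"], 1)
  expect_equal(prev2$genotyped[prev2$role == "female_proband"], 0)
})

test_that("call-set concordance counts flags and discordance per sample", {
  eh <- validation_genotypes(study_validation_calls(), "eh_offtarget")
  pcr <- validation_genotypes(study_validation_calls(), "pcr")
  cc <- callset_concordance(eh, pcr)
  expect_equal(cc$n_flagged_a, 7)
  expect_equal(cc$n_flagged_b, 0)
  flagged <- tidy(cc)[tidy(cc)$expanded_a, ]
  expect_equal(sum(flagged$class_b == "gray"), 3)
  expect_equal(sum(flagged$class_b == "premutation"), 0)

  same <- callset_concordance(eh, eh)
  expect_equal(same$n_class_discordant, 0)

  expect_warning(callset_concordance(eh, pcr[-1, ]), "excluded")
})
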