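test_that("allele classification respects the FMR1 range boundaries", {
  cls <- classify_allele(c(30, 70, 48, 40, 41, 54, 55, 200, 201, 281))
  expect_equal(as.character(cls),
               c("normal", "premutation", "gray", "normal", "gray", "gray",
                 "premutation", "premutation", "full", "full"))
})

test_that("every length 0-500 maps to exactly one class, monotonically", {
  suppressWarnings(cls <- classify_allele(0:500))
  expect_false(anyNA(cls))
  expect_equal(nlevels(cls), 4)
  # monotone non-decreasing in the class order
  expect_true(all(diff(as.integer(cls)) >= 0))
  # partition sizes forced by the thresholds
  expect_equal(as.vector(table(cls)),
               c(41, 14, 146, 300))
})

test_that("degenerate and invalid lengths are handled", {
  expect_error(classify_allele(-1), "non-negative")
  expect_warning(classify_allele(3), "below 5")
  expect_true(is.na(classify_allele(NA)))
})

test_that("catalog construction validates its thresholds", {
  expect_error(locus_catalog(normal_max = 60, gray_max = 54), "normal_max")
  expect_error(locus_catalog(normal_max = 0), "normal_max")
  shipped <- read_catalog(system.file("extdata", "fmr1_catalog.tsv",
                                      package = "fmrscreen"))
  expect_equal(shipped$normal_max, 40L)
  expect_equal(shipped$gray_max, 54L)
  expect_equal(shipped$premutation_max, 200L)
  # custom thresholds shift the boundaries accordingly
  alt <- locus_catalog(normal_max = 30, gray_max = 44, premutation_max = 100)
  expect_equal(as.character(classify_allele(c(31, 45, 101), alt)),
               c("gray", "premutation", "full"))
})

test_that("individual carrier status follows the longer allele", {
  g <- gt_fixture(c("carrier_f", "noncarrier_m", "noncarrier_f", "full_m"),
                  c("29/70", "Y/23", "30/30", "Y/281"))
  st <- classify_genotypes(g)
  expect_equal(st$longest_allele, c(70L, 23L, 30L, 281L))
  expect_equal(as.character(st$longest_class),
               c("premutation", "normal", "normal", "full"))
  expect_equal(st$is_premutation_carrier, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(st$is_full_carrier, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(st$is_expanded, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("carrier status is invariant to allele order and NA-safe", {
  g <- gt_fixture("s1", "29/70")
  swapped <- g
  swapped$allele1 <- g$allele2
  swapped$allele2 <- g$allele1
  keep <- c("longest_allele", "longest_class", "is_premutation_carrier",
            "is_full_carrier", "is_expanded")
  expect_equal(classify_genotypes(g)[, keep],
               classify_genotypes(swapped)[, keep])
  nocall <- g
  nocall$allele1 <- NA_integer_
  nocall$allele2 <- NA_integer_
  st <- classify_genotypes(nocall)
  expect_true(is.na(st$longest_allele))
  expect_true(is.na(st$is_premutation_carrier))
})

test_that("sex/ploidy mismatches at a chrX locus are rejected", {
  g <- gt_fixture("m1", "Y/23")
  g$allele2 <- 30L  # male with two alleles
  expect_error(classify_genotypes(g), "ploidy")
  g2 <- gt_fixture("f1", "29/30")
  g2$allele2 <- NA_integer_  # female with one allele
  expect_error(classify_genotypes(g2), "ploidy")
})
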