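test_that("wattersonTheta and neFromTheta implement their formulas", {
  expect_equal(wattersonTheta(0, 10, 100), 0)
  expect_equal(wattersonTheta(5, 2, 1), 5)           # a_1 = 1
  expect_equal(wattersonTheta(7, 5, 100),
               7 / (sum(1 / 1:4) * 100))
  expect_error(wattersonTheta(5, 1), "integer")

  expect_equal(neFromTheta(0), 0)
  expect_equal(neFromTheta(4 * 3e-8), 1)
  # blackgrass-scale numbers: mean theta 0.0047 at the maize rate
  expect_equal(neFromTheta(0.0047, 3.0e-8), 39166.67, tolerance = 1e-4)
  expect_error(neFromTheta(0.01, 0), "mu")
  # homogeneity: linear in theta
  expect_equal(neFromTheta(0.002) * 3, neFromTheta(0.006))
})

test_that("nucleotideDiversity handles sequences and simulator samples", {
  x <- Biostrings::DNAStringSet(c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(nucleotideDiversity(x), 0)

  y <- Biostrings::DNAStringSet(c(paste(rep("A", 100), collapse = ""),
                                  paste(c(rep("A", 99), "G"),
                                        collapse = "")))
  expect_equal(nucleotideDiversity(y), 0.01)

  # ambiguous columns are excluded from the comparison
  z <- Biostrings::DNAStringSet(c("AANT", "AGNT"))
  expect_equal(nucleotideDiversity(z), 1 / 3)

  hs <- new("HaplotypeSample", n = 4L, L = 100L,
            siteList = list(c(1L, 5L), c(1L), integer(), c(7L)))
  # site 1: 2/4, site 5: 1/4, site 7: 1/4 -> (4 + 3 + 3) / 6 / 100
  expect_equal(nucleotideDiversity(hs), (4 + 3 + 3) / 6 / 100)
  expect_equal(segregatingSites(hs), 3L)
})

test_that("chi2Yates reproduces the shared-haplotype comparison and the
           closed form", {
  res <- chi2Yates(c(20, 42, 55, 133))
  expect_equal(res$p.value, 0.7736, tolerance = 5e-4)
  ora <- yatesOracle(20, 42, 55, 133)
  expect_equal(res$statistic, ora$statistic, tolerance = 1e-10)
  expect_equal(res$p.value, ora$p.value, tolerance = 1e-10)

  # perfectly proportional table: statistic 0 after correction
  prop <- chi2Yates(c(10, 10, 20, 20))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p.value, 1)

  # invariance under simultaneous row and column swaps
  sw <- chi2Yates(matrix(c(133, 55, 42, 20), 2, byrow = TRUE))
  expect_equal(sw$statistic, res$statistic)

  # uncorrected variant differs (and is larger)
  un <- chi2Yates(c(20, 42, 55, 133), correct = FALSE)
  expect_gt(un$statistic, res$statistic)

  expect_error(chi2Yates(c(0, 0, 5, 5)), "marginal")
  expect_error(chi2Yates(c(1, 2, 3)), "2x2")
})

test_that("the corrected p-value is consistent with a fixed-margin
           resampling null", {
  tab <- c(20, 42, 55, 133)
  obs <- chi2Yates(tab)
  set.seed(33)
  sims <- r2dtable(2e4, r = c(62, 188), c = c(75, 175))
  stats <- vapply(sims, function(m)
    yatesOracle(m[1, 1], m[1, 2], m[2, 1], m[2, 2])$statistic, numeric(1))
  pMC <- mean(stats >= obs$statistic - 1e-12)
  # chi-squared approximation vs exact conditional null: close, not equal
  expect_lt(abs(obs$p.value - pMC), 0.05)
})
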