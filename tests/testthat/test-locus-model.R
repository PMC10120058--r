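test_that("buildTemplate realises the requested gene architecture", {
  tmpl <- buildTemplate()
  ex <- exonIntervals(tmpl)
  expect_equal(sum(ex[, "end"] - ex[, "start"]), 6125)
  expect_equal(locusLength(tmpl), 12250L)
  expect_length(tsrSites(tmpl), 7L)
  expect_true(all(classifySite(tmpl, tsrSites(tmpl)) == "tsr_target"))

  # coding fraction is honoured to within one site for odd sizes
  for (cf in c(0.3, 0.5, 0.8)) {
    t2 <- buildTemplate(1001L, nExons = 3L, codingFraction = cf,
                        nTsrSites = 0L)
    ex2 <- exonIntervals(t2)
    expect_lte(abs(sum(ex2[, "end"] - ex2[, "start"]) / 1001 - cf),
               1 / 1001)
  }

  # degenerate single-exon template: every site exonic, no TSR targets
  t3 <- buildTemplate(200L, exonIntervals = cbind(0L, 200L),
                      tsrSites = integer())
  expect_true(all(classifySite(t3, 0:199) == "exonic"))

  # invalid constructions are rejected
  expect_error(buildTemplate(100L, exonIntervals = cbind(0L, 50L),
                             tsrSites = 75L), "exon")
  expect_error(buildTemplate(100L,
                             exonIntervals = rbind(c(0L, 60L),
                                                   c(40L, 80L))),
               "overlap")
})

test_that("classifySite is exhaustive with tsr > exonic > noncoding", {
  tmpl <- buildTemplate(200L, exonIntervals = cbind(0L, 100L),
                        tsrSites = 50L)
  expect_equal(classifySite(tmpl, c(10L, 50L, 150L)),
               c("exonic", "tsr_target", "noncoding"))
  expect_error(classifySite(tmpl, 200L), "range")
  expect_error(classifySite(tmpl, -1L), "range")
})

test_that("drawEffect follows the configured DFE", {
  tmpl <- buildTemplate(200L, exonIntervals = cbind(50L, 150L),
                        tsrSites = 100L)
  dfe <- dfeConfig()

  # noncoding sites are always neutral
  set.seed(1)
  eff <- drawEffect(tmpl, 10L, dfe, n = 50)
  expect_true(all(eff$s == 0))
  expect_true(all(eff$site_class == "noncoding_neutral"))

  # TSR target carries the pre-onset coefficient
  effT <- drawEffect(tmpl, 100L, dfeConfig(tsrSBefore = -1e-4), n = 5)
  expect_true(all(effT$site_class == "tsr_target"))
  expect_true(all(effT$s == -1e-4))

  # fully neutral variant: exonic draws are never deleterious
  effN <- drawEffect(tmpl, 60L, dfeConfig(pNeutralExon = 1), n = 200)
  expect_true(all(effN$s == 0))

  # Monte-Carlo check of the neutral/deleterious mixture and gamma mean
  set.seed(99)
  n <- 1e5
  eff2 <- drawEffect(tmpl, 60L, dfe, n = n)
  pNeut <- mean(eff2$site_class == "exon_neutral")
  seNeut <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(pNeut - 0.25), 3 * seNeut)
  del <- eff2$s[eff2$site_class == "exon_deleterious"]
  expect_true(all(del < 0))
  seMean <- sd(del) / sqrt(length(del))
  expect_lt(abs(mean(del) - (-0.000154)), 3 * seMean)
  # gamma second moment: var = mean^2 / shape
  seVar <- sd((del - mean(del))^2) / sqrt(length(del))
  expect_lt(abs(var(del) - 0.000154^2 / 0.245), 3 * seVar)
})

test_that("locus JSON configuration round-trips", {
  tmpl <- buildTemplate(1000L, nExons = 4L, codingFraction = 0.4,
                        nTsrSites = 3L, name = "toy")
  path <- tempfile(fileext = ".json")
  writeSimulationConfig(simulationConfig(N = 100), tmpl, dfeConfig(),
                        path)
  back <- readLocusConfig(path)
  expect_equal(exonIntervals(back), exonIntervals(tmpl))
  expect_equal(tsrSites(back), tsrSites(tmpl))
  expect_equal(locusLength(back), 1000L)
})
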