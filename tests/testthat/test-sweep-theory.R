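test_that("establishmentProb has the right limits and matches a
           Wright-Fisher oracle", {
  expect_equal(establishmentProb(0, 0.5, 100), 1 / 200)
  # weak selection: pi ~ 2hs
  expect_equal(establishmentProb(0.01, 0.5, 1e4), 0.00995, tolerance = 1e-3)
  # strong selection with large Ne: pi -> 1 - exp(-2hs)
  expect_equal(establishmentProb(1, 0.5, 1e6), 1 - exp(-1),
               tolerance = 1e-6)

  set.seed(21)
  trials <- 1e5
  sim <- wfFixationOracle(N = 100, s = 0.05, h = 0.5, trials = trials)
  ana <- establishmentProb(0.05, 0.5, 100)
  se <- sqrt(ana * (1 - ana) / trials)
  expect_lt(abs(sim - ana), 3 * se + 0.1 * ana)  # diffusion approximation
})

test_that("sweep probabilities respect their structural limits", {
  expect_equal(probSGV(sweepParams(uSite = 0)), 0)
  expect_equal(probSGV(sweepParams(sBen = 0)), 0)
  expect_equal(probDeNovo(sweepParams(uSite = 0)), 0)
  expect_equal(probDeNovo(sweepParams(Tgen = 0)), 0)
  expect_equal(probAdaptTotal(sweepParams(uSite = 0)), 0)

  # only the standing route exists when T = 0
  p0 <- sweepParams(Tgen = 0)
  expect_gt(probSGV(p0), 0)
  expect_equal(fractionSGV(p0), 1)
  expect_error(fractionSGV(sweepParams(uSite = 0)), "undefined")

  # strong prior cost extinguishes the standing route
  expect_lt(probSGV(sweepParams(sDel = 1e4)), 1e-4)

  # large Theta saturates the standing route
  expect_gt(probSGV(sweepParams(uSite = 1e-3)), 0.999)

  # P_total >= max of the components, with equality when one is absent
  p <- sweepParams()
  expect_gte(probAdaptTotal(p), max(probSGV(p), probDeNovo(p)))
  expect_equal(probAdaptTotal(p0), probSGV(p0))
})

test_that("gridEvaluate outputs probabilities with the expected
           monotonicities", {
  tab <- gridEvaluate(NeList = c(42000, 84000),
                      sBenGrid = exp(seq(log(0.01), log(1), length.out = 9)),
                      sDelGrid = c(1e-5, 1e-3))
  probCols <- c("P_sgv", "P_dn", "P_total", "fraction_sgv")
  expect_true(all(as.matrix(tab[probCols]) >= 0 &
                  as.matrix(tab[probCols]) <= 1))

  # P_total non-decreasing in s_ben within each (Ne, s_del) block
  for (blk in split(tab, list(tab$Ne, tab$s_del))) {
    blk <- blk[order(blk$s_ben), ]
    expect_true(all(diff(blk$P_total) >= -1e-12))
  }
  # doubling Ne raises the probability of adaptation pointwise
  t42 <- tab[tab$Ne == 42000, ]
  t84 <- tab[tab$Ne == 84000, ]
  expect_true(all(t84$P_total >= t42$P_total - 1e-12))
  # fraction_sgv non-increasing in the prior deleterious cost
  lo <- tab[tab$s_del == 1e-5, ]
  hi <- tab[tab$s_del == 1e-3, ]
  expect_true(all(hi$fraction_sgv <= lo$fraction_sgv + 1e-12))
})
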