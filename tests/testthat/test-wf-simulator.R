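test_that("configuration rescaling preserves the population-scaled
           parameters", {
  cfg <- simulationConfig(N = 42000L)
  r <- rescaleConfig(cfg, 20)
  expect_equal(r@N, 2100L)
  expect_equal(r@N * r@muSite, cfg@N * cfg@muSite, tolerance = 1e-3)
  expect_equal(r@N * r@recSite, cfg@N * cfg@recSite, tolerance = 1e-3)
  expect_equal(r@selGenerations, cfg@selGenerations)
  expect_equal(r@survivalRatio, cfg@survivalRatio)
  expect_identical(rescaleConfig(cfg, 1), cfg)
  expect_error(rescaleConfig(cfg, 1000), "below 50")
  expect_error(rescaleConfig(r, 2), "already rescaled")
})

test_that("the simulator is deterministic and conserves population size", {
  tmpl <- smallTemplate()
  cfg <- simulationConfig(N = 100L, muSite = 1e-5, recSite = 1e-6,
                          selGenerations = 10L)
  a <- runReplicates(cfg, tmpl, dfeConfig(), nReps = 3, baseSeed = 7)
  b <- runReplicates(cfg, tmpl, dfeConfig(), nReps = 3, baseSeed = 7)
  expect_identical(a$summaries, b$summaries)
  expect_identical(a$trajectories, b$trajectories)

  set.seed(1)
  pop <- runBurnin(cfg, tmpl, dfeConfig(), nGenerations = 200)
  expect_length(pop@haplotypes, 200L)
  expect_true(all(pop@registry$count >= 1 & pop@registry$count <= 200))
  sel <- runSelectionPhase(pop, cfg)
  expect_length(sel$state@haplotypes, 200L)
})

test_that("no mutational input leaves the population empty", {
  tmpl <- smallTemplate()
  cfg <- simulationConfig(N = 60L, muSite = 0, recSite = 1e-6)
  set.seed(2)
  pop <- runBurnin(cfg, tmpl, dfeConfig(), nGenerations = 300)
  expect_equal(nrow(pop@registry), 0L)
  sel <- runSelectionPhase(pop, cfg)
  expect_equal(nrow(sel$trajectory), 0L)
  expect_equal(classifyReplicate(sel$trajectory, N = 60L)$classification,
               "none")
})

test_that("a neutral allele drifts as a martingale", {
  tmpl <- smallTemplate()
  cfg <- simulationConfig(N = 100L, muSite = 0, recSite = 0,
                          survivalRatio = 1, selGenerations = 10L)
  set.seed(3)
  base <- runBurnin(cfg, tmpl, dfeConfig(), nGenerations = 1)
  finals <- replicate(300, {
    pop <- injectMutation(base, site = tsrSites(tmpl)[1], count = 100L)
    res <- runSelectionPhase(pop, cfg)
    fin <- res$trajectory[res$trajectory$generation == 10L, ]
    if (nrow(fin)) sum(fin$frequency) else 0
  })
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.5), 3 * se)
})

test_that("under herbicide selection the mean TSR frequency is
           non-decreasing across generations", {
  tmpl <- smallTemplate()
  cfg <- simulationConfig(N = 150L, muSite = 0, recSite = 0,
                          survivalRatio = 20, selGenerations = 15L)
  set.seed(4)
  base <- runBurnin(cfg, tmpl, dfeConfig(), nGenerations = 1)
  agg <- matrix(0, nrow = 200, ncol = 16)
  for (r in 1:200) {
    pop <- injectMutation(base, site = tsrSites(tmpl)[1], count = 6L)
    res <- runSelectionPhase(pop, cfg)
    tr <- res$trajectory
    for (g in 0:15) {
      rows <- tr$generation == g
      agg[r, g + 1] <- sum(tr$frequency[rows])
    }
  }
  ensemble <- colMeans(agg)
  expect_true(all(diff(ensemble) > -0.01))
  expect_gt(ensemble[16], ensemble[1])
})

test_that("neutral stationarity: Watterson's theta and pi match 4 N mu", {
  tmpl <- buildTemplate(200L, nExons = 1L, codingFraction = 0.99,
                        nTsrSites = 0L)
  cfg <- simulationConfig(N = 500L, muSite = 2.5e-6, recSite = 0)
  set.seed(5)
  th <- pi_ <- numeric(12)
  for (i in seq_along(th)) {
    pop <- runBurnin(cfg, tmpl, neutralDfe(), nGenerations = 5000)
    s <- sampleHaplotypes(pop, 40)
    th[i] <- wattersonTheta(segregatingSites(s), 40, 200)
    pi_[i] <- nucleotideDiversity(s)
  }
  target <- 4 * 500 * 2.5e-6
  expect_lt(abs(mean(th) - target), 3 * sd(th) / sqrt(length(th)))
  expect_lt(abs(mean(pi_) - target), 3 * sd(pi_) / sqrt(length(pi_)))
})

test_that("standing TSR variation matches the neutral
           segregating-sites expectation", {
  # boosted mutation supply at a 3-site neutral target
  N <- 300L; mu <- 2e-5; target <- 3L
  tmpl <- buildTemplate(600L, nExons = 2L, codingFraction = 0.5,
                        nTsrSites = target)
  cfg <- simulationConfig(N = N, muSite = mu, recSite = 0)
  set.seed(6)
  counts <- numeric(60)
  for (i in seq_along(counts)) {
    pop <- runBurnin(cfg, tmpl, neutralDfe(), nGenerations = 10L * N)
    counts[i] <- sum(pop@registry$class == "tsr_target" &
                     pop@registry$count < 2L * N)
  }
  expected <- expectedSegregating(N, mu, target)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("the linked and freq engines agree on neutral diversity and on
           TSR establishment", {
  tmpl <- buildTemplate(300L, nExons = 1L, codingFraction = 0.99,
                        nTsrSites = 1L)
  thetaOf <- function(engine, reps, seed) {
    cfg <- simulationConfig(N = 300L, muSite = 4e-6, recSite = 0,
                            engine = engine)
    set.seed(seed)
    vapply(seq_len(reps), function(i) {
      pop <- runBurnin(cfg, tmpl, neutralDfe(), nGenerations = 3000)
      sum(pop@registry$count > 0 & pop@registry$count < 600) /
        sum(1 / seq_len(599)) / 300
    }, numeric(1))
  }
  a <- thetaOf("linked", 15, 11)
  b <- thetaOf("freq", 15, 12)
  sePool <- sqrt(var(a) / 15 + var(b) / 15)
  expect_lt(abs(mean(a) - mean(b)), 3 * sePool)

  # establishment of a dominant beneficial from one copy, both engines
  estab <- function(engine, trials, seed) {
    cfg <- simulationConfig(N = 200L, muSite = 0, recSite = 0,
                            survivalRatio = 1.5, selGenerations = 120L,
                            engine = engine, pruneEvery = 10L)
    set.seed(seed)
    base <- runBurnin(cfg, tmpl, dfeConfig(), nGenerations = 1)
    hits <- 0L
    for (i in seq_len(trials)) {
      pop <- injectMutation(base, site = tsrSites(tmpl)[1], count = 1L)
      res <- runSelectionPhase(pop, cfg)
      fin <- res$trajectory[res$trajectory$generation == 120L, ]
      if (nrow(fin) && sum(fin$frequency) >= 0.1) hits <- hits + 1L
    }
    hits / trials
  }
  pa <- estab("linked", 400, 13)
  pb <- estab("freq", 400, 14)
  sePool <- sqrt(pa * (1 - pa) / 400 + pb * (1 - pb) / 400)
  expect_lt(abs(pa - pb), 3 * sePool + 0.02)
})
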