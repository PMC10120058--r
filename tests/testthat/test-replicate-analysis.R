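toyTraj <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(generation = r[[1]], origin_id = r[[2]], frequency = r[[3]],
               origin_gen = r[[4]],
               origin_phase = ifelse(r[[4]] >= 1, "selection", "burnin"),
               site = 1L)))
}

test_that("classifyReplicate applies the origin-phase rules", {
  # one surviving standing origin
  tr <- toyTraj(list(30L, 1L, 0.4, -5L))
  expect_equal(classifyReplicate(tr, N = 100)$classification, "sgv")

  # mixed standing + de novo counts as standing variation
  tr2 <- toyTraj(list(30L, 1L, 0.4, -5L), list(30L, 2L, 0.1, 12L))
  sm2 <- classifyReplicate(tr2, N = 100)
  expect_equal(sm2$classification, "sgv")
  expect_equal(sm2$n_origins_final, 2L)

  # de novo only
  tr3 <- toyTraj(list(30L, 2L, 0.2, 3L))
  expect_equal(classifyReplicate(tr3, N = 100)$classification,
               "de_novo_only")

  # nothing surviving the threshold
  tr4 <- toyTraj(list(30L, 1L, 0.001, -5L))
  sm4 <- classifyReplicate(tr4, N = 100, threshold = 0.01)
  expect_equal(sm4$classification, "none")
  expect_equal(sm4$n_origins_final, 0L)
  expect_equal(sm4$n_origins_ever, 1L)

  # empty trajectory
  sm5 <- classifyReplicate(tr4[0, ], N = 100)
  expect_equal(sm5$classification, "none")

  # invariant to row order
  tr6 <- tr2[sample(nrow(tr2)), ]
  expect_equal(classifyReplicate(tr6, N = 100),
               classifyReplicate(tr2, N = 100))

  expect_error(classifyReplicate(data.frame(x = 1), N = 100), "malformed")
})

test_that("aggregateReplicates conserves proportions and rejects mixed
           configurations", {
  sm <- do.call(rbind, lapply(1:10, function(i)
    data.frame(classification = c("sgv", "de_novo_only", "none")[1 +
                 (i %% 3)],
               n_origins_final = i %% 4, n_origins_ever = i %% 4,
               aggregate_tsr_freq_final = 0.1,
               replicate_id = i, seed = i, config_hash = 1)))
  agg <- aggregateReplicates(sm)
  expect_equal(agg$proportion_sgv + agg$proportion_de_novo_only +
               agg$proportion_none, 1)
  expect_equal(agg$n_reps, 10L)
  expect_equal(agg$prop_multi_origin,
               mean(sm$n_origins_final >= 2))

  allNone <- sm
  allNone$classification <- "none"
  expect_equal(aggregateReplicates(allNone)$proportion_none, 1)

  mixed <- sm
  mixed$config_hash[3] <- 2
  expect_error(aggregateReplicates(mixed), "different configurations")
})

test_that("neutralCensus counts simultaneous standing TSR origins", {
  tmpl <- smallTemplate()
  cfgOff <- simulationConfig(N = 80L, muSite = 0, herbicideOn = FALSE)
  out0 <- neutralCensus(cfgOff, tmpl, dfeConfig(), nReps = 5,
                        sampleEvery = 50, baseSeed = 1)
  expect_equal(out0$max_overall, 0L)
  expect_error(neutralCensus(simulationConfig(N = 80L), tmpl, dfeConfig(),
                             nReps = 2), "herbicideOn")

  # stationary mean simultaneous count ~ Theta * a_{2N-1}
  N <- 250L; mu <- 2e-5; target <- 3L
  tmpl2 <- buildTemplate(600L, nExons = 2L, codingFraction = 0.5,
                         nTsrSites = target)
  cfg <- simulationConfig(N = N, muSite = mu, recSite = 0,
                          herbicideOn = FALSE)
  out <- neutralCensus(cfg, tmpl2, neutralDfe(), nReps = 40,
                       sampleEvery = 500, baseSeed = 22)
  # use the final (stationary) sample of each replicate
  finals <- vapply(out$census, function(cs) cs$n_tsr_origins[nrow(cs)],
                   integer(1))
  expect_true(all(finals >= 0))
  expected <- expectedSegregating(N, mu, target)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
})
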