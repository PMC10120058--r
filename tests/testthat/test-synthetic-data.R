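test_that("generatePanel is deterministic and realises divergences
           exactly", {
  cfg <- panelConfig(gene = "ACCase", nBackbones = 4L,
                     backboneDivergence = 5L,
                     populations = c("p1", "p2"), seed = 77L)
  a <- generatePanel(cfg)
  b <- generatePanel(cfg)
  expect_identical(as.character(a$haps), as.character(b$haps))
  expect_identical(a$truth, b$truth)

  # every backbone pair differs at exactly 2 * divergence sites
  chars <- strsplit(as.character(a$haps[!duplicated(a$truth$backbone)]), "")
  for (i in seq_along(chars))
    for (j in seq_len(i - 1L))
      expect_equal(sum(chars[[i]] != chars[[j]]), 10L)

  expect_error(generatePanel(panelConfig(nBackbones = 600L,
                                         backboneDivergence = 10L)),
               "infeasible")
})

test_that("planted TSR events and recombinants are encoded as configured", {
  cfg <- panelConfig(gene = "ACCase", nBackbones = 2L,
                     backboneDivergence = 6L, populations = "f",
                     sharing = list("f", "f"),
                     tsrEvents = data.frame(label = "ACCase Ile1781Leu",
                                            backbone = 1:2,
                                            populations = "f"),
                     recombinants = data.frame(event = 1L,
                                               wtBackbone = 2L,
                                               breakpoint = 900L,
                                               population = "f"),
                     seed = 3L)
  panel <- generatePanel(cfg)
  truth <- panel$truth
  expect_equal(sum(truth$recombinant), 1L)
  expect_equal(sum(!is.na(truth$tsr_label)), 3L)

  # typing the panel recovers the planted TSR calls exactly
  calls <- callTSR(panel$haps, "ACCase")
  byHap <- tapply(calls$status == "resistant", calls$hap, any)
  expect_equal(as.vector(byHap[truth$hap]),
               !is.na(truth$tsr_label))

  # recombinants with the codon on the wild-type side are rejected
  expect_error(generatePanel(panelConfig(
    gene = "ACCase", nBackbones = 2L, backboneDivergence = 6L,
    populations = "f", sharing = list("f", "f"),
    tsrEvents = data.frame(label = "ACCase Ile1781Leu", backbone = 1L,
                           populations = "f"),
    recombinants = data.frame(event = 1L, wtBackbone = 2L,
                              breakpoint = 100L, population = "f"),
    seed = 3L)), "right of the mutated codon")
})

test_that("the fixture suite regenerates identically and passes its own
           truth checks", {
  d1 <- tempfile("fx1"); d2 <- tempfile("fx2")
  p1 <- makeFixtureSuite(d1)
  p2 <- makeFixtureSuite(d2)
  expect_identical(readLines(p1$sharing_fasta), readLines(p2$sharing_fasta))
  expect_identical(readLines(p1$origin_fasta), readLines(p2$origin_fasta))

  manifest <- jsonlite::fromJSON(p1$manifest)
  expect_equal(manifest$sharing_expected_2x2$tsr_shared, 20)

  # the bundled simulation config round-trips through JSON
  sim <- readSimulationConfig(p1$sim_config)
  expect_equal(sim$config@N, 2100L)
  expect_equal(sim$config@muSite, 6e-7)
  expect_equal(sim$config@rescaleLambda, 20)
  expect_equal(locusLength(sim$template), 12250L)
  expect_equal(sim$dfe@gammaShape, 0.245)

  # truth tables carry everything needed to score downstream calls
  truth <- read.delim(p1$origin_truth)
  expect_true(all(c("hap", "population", "backbone", "tsr_label",
                    "origin_event", "recombinant", "breakpoint") %in%
                  names(truth)))
})
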