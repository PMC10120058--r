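test_that("callTSR types codons against the reference", {
  ref <- mockReference("ACCase")
  tab <- tsrCodonTable("ACCase")

  # the reference itself is wild type at every codon
  calls <- callTSR(Biostrings::DNAStringSet(ref), "ACCase")
  expect_true(all(calls$status == "wild_type"))

  # plant Ile1781Leu (ATA -> CTA) at the 1781 codon position
  s <- strsplit(as.character(ref), "")[[1]]
  pos <- tab$pos[tab$codon == 1781]
  expect_equal(paste(s[pos + 0:2], collapse = ""), "ATA")
  s[pos] <- "C"
  mut <- Biostrings::DNAStringSet(paste(s, collapse = ""))
  callsM <- callTSR(mut, "ACCase")
  hit <- callsM[callsM$status == "resistant", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$label, "ACCase Ile1781Leu")

  # an N in one codon makes that codon uncallable, others still called
  s2 <- strsplit(as.character(ref), "")[[1]]
  s2[tab$pos[tab$codon == 2078]] <- "N"
  callsN <- callTSR(Biostrings::DNAStringSet(paste(s2, collapse = "")),
                    "ACCase")
  expect_equal(callsN$status[callsN$codon == 2078], "uncallable")
  expect_true(all(callsN$status[callsN$codon != 2078] == "wild_type"))

  # indel upstream of the codon: alignment anchoring still calls it
  s3 <- strsplit(as.character(mut[[1]]), "")[[1]]
  del <- paste(s3[-10], collapse = "")
  callsD <- callTSR(Biostrings::DNAStringSet(del), "ACCase")
  expect_true("ACCase Ile1781Leu" %in% callsD$label)
})

test_that("ALS1 codons are typed with the same machinery", {
  ref <- mockReference("ALS1")
  tab <- tsrCodonTable("ALS1")
  s <- strsplit(as.character(ref), "")[[1]]
  pos <- tab$pos[tab$codon == 574]  # TGG -> TTG = Trp574Leu
  s[pos + 1] <- "T"
  calls <- callTSR(Biostrings::DNAStringSet(paste(s, collapse = "")),
                   "ALS1", table = tab, reference = ref)
  expect_equal(calls$label[calls$codon == 574], "ALS1 Trp574Leu")
})

test_that("dedupeHaplotypes clusters exact sequences and tracks sharing", {
  cfg <- panelConfig(gene = "ACCase", nBackbones = 3L,
                     backboneDivergence = 4L,
                     populations = c("p1", "p2"),
                     sharing = list(c("p1", "p2"), "p1", "p2"),
                     seed = 5L)
  panel <- generatePanel(cfg)
  cl <- dedupeHaplotypes(panel$haps)
  expect_equal(nrow(cl), 3L)
  expect_equal(sum(cl$shared), 1L)
  expect_equal(sum(cl$count), length(panel$haps))

  # deduplication is idempotent and order-invariant
  perm <- sample(length(panel$haps))
  cl2 <- dedupeHaplotypes(panel$haps[perm])
  expect_equal(sort(cl2$count), sort(cl$count))
  expect_equal(sum(cl2$shared), sum(cl$shared))

  # sequences differing at one site form distinct clusters
  two <- Biostrings::DNAStringSet(c(a = "ACGTACGT", b = "ACGTACGA"))
  expect_equal(nrow(dedupeHaplotypes(two,
                                     populations = c("x", "x"))), 2L)

  # gap/case normalisation merges equivalent records
  three <- Biostrings::DNAStringSet(c(a = "ACGTACGT", b = "ACGT-ACGT"))
  expect_equal(nrow(dedupeHaplotypes(three,
                                     populations = c("x", "y"))), 1L)
})

test_that("shared2x2 reproduces the Europe-wide sharing table from the
           fixture panel", {
  dir <- tempfile("fixtures")
  paths <- makeFixtureSuite(dir)
  haps <- readAmpliconFasta(paths$sharing_fasta)
  cl <- dedupeHaplotypes(haps, gene = "ACCase")
  expect_equal(nrow(cl), 250L)
  tab <- shared2x2(cl)
  expect_equal(as.vector(t(tab)), c(20L, 42L, 55L, 133L))
  expect_equal(sum(tab), 250L)
  # composed with the chi-squared test this gives the printed p-value
  expect_equal(chi2Yates(tab)$p.value, 0.7736, tolerance = 5e-4)
})

test_that("countOrigins separates independent origins from recombinant
           transfers", {
  dir <- tempfile("fixtures")
  paths <- makeFixtureSuite(dir)
  haps <- readAmpliconFasta(paths$origin_fasta)
  rep_ <- countOrigins(haps, gene = "ACCase")
  expect_equal(unname(rep_$n_independent["ACCase Ile1781Leu"]), 2L)
  expect_equal(sum(rep_$per_mutation$call == "putative_recombinant"), 1L)
  expect_equal(rep_$total_independent, 2L)

  # a single TSR haplotype is one independent origin
  cfg1 <- panelConfig(gene = "ACCase", nBackbones = 2L,
                      backboneDivergence = 6L, populations = "f",
                      sharing = list("f", "f"),
                      tsrEvents = data.frame(label = "ACCase Ile1781Leu",
                                             backbone = 1L,
                                             populations = "f"),
                      seed = 9L)
  p1 <- generatePanel(cfg1)
  r1 <- countOrigins(p1$haps, gene = "ACCase")
  expect_equal(r1$total_independent, 1L)
  expect_true(all(r1$per_mutation$call == "independent_origin"))

  # mixed populations are rejected
  cfg2 <- panelConfig(gene = "ACCase", nBackbones = 1L,
                      backboneDivergence = 2L,
                      populations = c("f", "g"), seed = 2L)
  p2 <- generatePanel(cfg2)
  expect_error(countOrigins(p2$haps, gene = "ACCase"), "single population")
})

test_that("unambiguous synthetic panels recover the planted origin count
           exactly", {
  # parameterised truth-recovery sweep: no recombinants, backbones far
  # apart -> the planted number of origins is always recovered
  for (k in 1:4) {
    cfg <- panelConfig(gene = "ACCase", nBackbones = k + 1L,
                       backboneDivergence = 8L, populations = "f",
                       sharing = rep(list("f"), k + 1L),
                       tsrEvents = data.frame(
                         label = "ACCase Ile1781Leu",
                         backbone = seq_len(k), populations = "f"),
                       seed = 100L + k)
    p <- generatePanel(cfg)
    r <- countOrigins(p$haps, gene = "ACCase")
    expect_equal(unname(r$n_independent["ACCase Ile1781Leu"]), k)
  }
})
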