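## Linkage-free "freq" engine: every mutation evolves as an independent
## biallelic Wright-Fisher locus (deterministic selection on genotype
## frequencies under Hardy-Weinberg, then binomial resampling). Used for
## fast property tests and as a semi-independent cross-check of the linked
## engine; it ignores interference and hitch-hiking, and treats each TSR
## locus' dominant survival benefit marginally (accurate while TSR alleles
## are rare).

.freqRun <- function(pop, config, template, dfe, nGens, selection,
                     censusEvery = 0L) {
  N <- config@N
  twoN <- 2L * N
  L <- template@lengthBp
  lam <- config@rescaleLambda

  if (is.null(pop)) {
    reg <- data.frame(site = integer(), s = numeric(), h = numeric(),
                      class = character(), origin_gen = integer(),
                      origin_phase = character(), count = integer())
    ids <- integer()
    gen <- -nGens
    fixed <- data.frame(site = integer(), s = numeric(), cls = character(),
                        origin_gen = integer(), fixed_gen = integer())
  } else {
    reg <- pop@registry
    ids <- seq_len(nrow(reg))
    gen <- pop@generation
    fixed <- pop@fixed
  }
  nextId <- length(ids) + 1L

  trGen <- list(); trId <- list(); trCount <- list()
  trOgen <- list(); trSite <- list()
  csGen <- integer(); csN <- integer()
  recordTsr <- function(g) {
    k <- which(reg$class == "tsr_target" & reg$count > 0L)
    if (length(k)) {
      i <- length(trGen) + 1L
      trGen[[i]] <<- rep(g, length(k)); trId[[i]] <<- ids[k]
      trCount[[i]] <<- reg$count[k]; trOgen[[i]] <<- reg$origin_gen[k]
      trSite[[i]] <<- reg$site[k]
    }
  }
  if (selection) recordTsr(gen)

  gen0 <- gen
  last <- gen + nGens
  while (gen < last) {
    gen <- gen + 1L
    n <- nrow(reg)
    if (n) {
      p <- reg$count / twoN
      s <- reg$s
      h <- reg$h
      wAA <- 1 + s
      wAa <- 1 + h * s
      waa <- rep(1, n)
      if (selection && config@survivalRatio != 1) {
        tsr <- reg$class == "tsr_target"
        wAA[tsr] <- wAA[tsr] * config@survivalRatio
        wAa[tsr] <- wAa[tsr] * config@survivalRatio
      }
      wA <- p * wAA + (1 - p) * wAa
      wbar <- p^2 * wAA + 2 * p * (1 - p) * wAa + (1 - p)^2 * waa
      pPrime <- pmin(1, pmax(0, p * wA / wbar))
      reg$count <- rbinom(n, twoN, pPrime)
    }
    # new mutations, one copy each
    nNew <- rpois(1L, twoN * config@muSite * L)
    if (nNew > 0L) {
      sites <- as.integer(floor(runif(nNew) * L))
      sites[sites >= L] <- L - 1L
      eff <- drawEffect(template, sites, dfe)
      eff$s <- pmax(-0.999999, eff$s * lam)
      newRows <- data.frame(site = eff$site, s = eff$s, h = eff$h,
                            class = eff$site_class,
                            origin_gen = gen,
                            origin_phase = ifelse(gen >= 1L, "selection",
                                                  "burnin"),
                            count = 1L)
      reg <- rbind(reg, newRows)
      ids <- c(ids, seq.int(nextId, length.out = nNew))
      nextId <- nextId + nNew
    }
    # prune lost, archive fixed non-TSR (fixed TSR stay tracked at 2N)
    if (nrow(reg)) {
      lost <- reg$count == 0L
      fixNow <- reg$count == twoN & reg$class != "tsr_target"
      if (any(fixNow))
        fixed <- rbind(fixed,
                       data.frame(site = reg$site[fixNow],
                                  s = reg$s[fixNow],
                                  cls = reg$class[fixNow],
                                  origin_gen = reg$origin_gen[fixNow],
                                  fixed_gen = gen))
      keep <- !(lost | fixNow)
      reg <- reg[keep, , drop = FALSE]
      ids <- ids[keep]
    }
    if (selection) recordTsr(gen)
    if (!selection && censusEvery > 0L &&
        ((gen - gen0) %% censusEvery == 0L || gen == last)) {
      csGen <- c(csGen, gen)
      csN <- c(csN, sum(reg$class == "tsr_target" & reg$count > 0L))
    }
  }

  rownames(reg) <- NULL
  st <- new("PopulationState", generation = as.integer(gen), N = N,
            haplotypes = list(), registry = reg, fixed = fixed,
            template = template, dfe = dfe, engine = "freq")
  if (!selection) {
    if (censusEvery > 0L)
      attr(st, "census") <- data.frame(generation = csGen,
                                       n_tsr_origins = csN)
    return(st)
  }
  traj <- data.frame(
    generation = unlist(trGen) %||% integer(),
    origin_id = unlist(trId) %||% integer(),
    frequency = (unlist(trCount) %||% integer()) / twoN,
    origin_gen = unlist(trOgen) %||% integer(),
    origin_phase = ifelse((unlist(trOgen) %||% integer()) >= 1L,
                          "selection", "burnin"),
    site = unlist(trSite) %||% integer())
  list(state = st, trajectory = traj)
}
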