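#' Construct a simulation configuration
#'
#' Defaults reproduce the blackgrass herbicide-resistance protocol: a
#' diploid population of 42,000 individuals, per-site mutation rate
#' 3.0e-8 and recombination rate 7.4e-9 (both adopted from maize), a
#' 10 x N generation burn-in, and 30 generations of herbicide selection in
#' which individuals carrying at least one TSR allele (dominant) have a
#' 20-fold higher parental sampling weight (soft viability selection at
#' constant N).
#'
#' @param N diploid population size.
#' @param muSite per-site per-generation mutation rate.
#' @param recSite per-site per-generation recombination rate.
#' @param burninMultiplier burn-in length in units of N generations.
#' @param selGenerations number of herbicide-selection generations.
#' @param survivalRatio survival advantage of TSR carriers.
#' @param herbicideOn if `FALSE` the selection phase is skipped.
#' @param seed integer seed or `NA` to use the current RNG stream.
#' @param engine `"linked"` (exact) or `"freq"` (linkage-free).
#' @param pruneEvery generations between bookkeeping sweeps.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(N = 42000L, muSite = 3.0e-8, recSite = 7.4e-9,
                             burninMultiplier = 10, selGenerations = 30L,
                             survivalRatio = 20, herbicideOn = TRUE,
                             seed = NA_integer_, engine = "linked",
                             pruneEvery = 150L) {
  new("SimulationConfig", N = .assertCount(N, "N", 2L),
      muSite = as.numeric(muSite), recSite = as.numeric(recSite),
      burninMultiplier = as.numeric(burninMultiplier),
      selGenerations = .assertCount(selGenerations, "selGenerations"),
      survivalRatio = as.numeric(survivalRatio),
      herbicideOn = isTRUE(herbicideOn), rescaleLambda = 1,
      seed = as.integer(seed), engine = match.arg(engine,
                                                  c("linked", "freq")),
      pruneEvery = .assertCount(pruneEvery, "pruneEvery", 1L))
}

#' Rescale a simulation configuration
#'
#' Standard population-genetic rescaling that keeps N*mu, N*r and N*s
#' constant while shrinking the population: N' = round(N/lambda),
#' mu' = mu*lambda, r' = r*lambda; selection coefficients are multiplied by
#' lambda at draw time inside the engine. The burn-in is
#' `burninMultiplier * N'` generations. `selGenerations` and
#' `survivalRatio` are deliberately left unchanged: the selection phase is
#' a fixed 30-generation window of the model, and the survival ratio is a
#' bounded viability ratio, not a small coefficient.
#'
#' @param config a [SimulationConfig-class] (not yet rescaled).
#' @param lambda rescaling factor >= 1.
#' @return the rescaled [SimulationConfig-class].
#' @examples
#' cfg <- rescaleConfig(simulationConfig(N = 42000), 20)
#' cfg
#' @export
rescaleConfig <- function(config, lambda) {
  stopifnot(is(config, "SimulationConfig"))
  if (lambda < 1) stop("lambda must be >= 1")
  if (lambda == 1) return(config)
  if (config@rescaleLambda != 1)
    stop("config is already rescaled; rescale the original configuration")
  Nprime <- as.integer(round(config@N / lambda))
  if (Nprime < 50L)
    stop("rescaling would drive N below 50; use a smaller lambda")
  cfg <- config
  cfg@N <- Nprime
  cfg@muSite <- config@muSite * lambda
  cfg@recSite <- config@recSite * lambda
  cfg@rescaleLambda <- as.numeric(lambda)
  validObject(cfg)
  cfg
}

## ---- internal: marshalling between R state objects and the C++ engine ----

.cppTemplate <- function(template) {
  ex <- exonIntervals(template)
  list(length_bp = template@lengthBp,
       exon_start = as.integer(ex[, "start"]),
       exon_end = as.integer(ex[, "end"]),
       tsr_sites = template@tsrSites)
}

.cppDfe <- function(dfe) {
  list(p_neutral_exon = dfe@pNeutralExon, gamma_shape = dfe@gammaShape,
       gamma_scale = abs(dfe@gammaMeanS) / dfe@gammaShape,
       h_del = dfe@hDel, tsr_s_before = dfe@tsrSBefore)
}

.cppConfig <- function(config) {
  list(N = config@N, mu_site = config@muSite, rec_site = config@recSite,
       survival_ratio = config@survivalRatio,
       lambda = config@rescaleLambda, prune_every = config@pruneEvery)
}

.registryFromCpp <- function(reg) {
  data.frame(site = reg$site, s = reg$s, h = reg$h,
             class = .classLabel(reg$cls), origin_gen = reg$origin_gen,
             origin_phase = ifelse(reg$origin_gen >= 1L, "selection",
                                   "burnin"),
             count = reg$count)
}

.registryToCpp <- function(registry) {
  list(site = as.integer(registry$site), s = as.numeric(registry$s),
       h = as.numeric(registry$h), cls = .classCode(registry$class),
       origin_gen = as.integer(registry$origin_gen))
}

.fixedFromCpp <- function(fx) {
  data.frame(site = fx$site, s = fx$s, cls = .classLabel(fx$cls),
             origin_gen = fx$origin_gen, fixed_gen = fx$fixed_gen)
}

.trajectoryFromCpp <- function(tr, N) {
  data.frame(generation = tr$generation, origin_id = tr$origin_id,
             frequency = tr$count / (2 * N),
             origin_gen = tr$origin_gen,
             origin_phase = ifelse(tr$origin_gen >= 1L, "selection",
                                   "burnin"),
             site = tr$site)
}

.stateFromCpp <- function(res, config, template, dfe) {
  new("PopulationState", generation = as.integer(res$generation),
      N = config@N, haplotypes = res$haplotypes,
      registry = .registryFromCpp(res$registry),
      fixed = .fixedFromCpp(res$fixed),
      template = template, dfe = dfe, engine = "linked")
}

.stateToCpp <- function(pop) {
  list(generation = pop@generation, haplotypes = pop@haplotypes,
       registry = .registryToCpp(pop@registry))
}

.checkScaledS <- function(config, dfe) {
  if (abs(dfe@tsrSBefore * config@rescaleLambda) > 1)
    stop("|tsrSBefore * lambda| exceeds 1; choose a smaller lambda")
}

.maybeSeed <- function(config) {
  if (!is.na(config@seed)) set.seed(config@seed)
}

## ---- user-facing simulation steps ----

#' Run the neutral-plus-background-selection burn-in
#'
#' Starts from a mutation-free population and iterates
#' `burninMultiplier * N` Wright-Fisher generations of mutation (per-gamete
#' Poisson(mu*L) events at uniform sites), recombination (Poisson(r*(L-1))
#' crossovers), multiplicative viability selection (per-site fitness 1 /
#' 1+hs / 1+s) and resampling to constant N. Returns the population state
#' at generation 0, the onset of herbicide selection. Lost and fixed
#' mutations are swept from the haplotypes at `pruneEvery`-generation
#' intervals (fixed records are archived; fixed TSR alleles stay tracked).
#'
#' @param config a [SimulationConfig-class].
#' @param template a [LocusTemplate-class].
#' @param dfe a [DFEConfig-class].
#' @param nGenerations override the burn-in length (default
#'   `round(burninMultiplier * N)`).
#' @param censusEvery if > 0, record the number of simultaneously
#'   segregating TSR origins every `censusEvery` generations (see
#'   [neutralCensus()]).
#' @return a [PopulationState-class]; when `censusEvery > 0` the census
#'   data.frame is attached as `attr(, "census")`.
#' @examples
#' cfg <- simulationConfig(N = 100, selGenerations = 5, seed = 1)
#' tmpl <- buildTemplate(500, nExons = 2, nTsrSites = 2)
#' pop <- runBurnin(cfg, tmpl, dfeConfig(), nGenerations = 50)
#' pop
#' @export
runBurnin <- function(config, template, dfe, nGenerations = NULL,
                      censusEvery = 0L) {
  stopifnot(is(config, "SimulationConfig"), is(template, "LocusTemplate"),
            is(dfe, "DFEConfig"))
  .checkScaledS(config, dfe)
  if (is.null(nGenerations))
    nGenerations <- as.integer(round(config@burninMultiplier * config@N))
  .maybeSeed(config)
  if (config@engine == "freq")
    return(.freqRun(NULL, config, template, dfe, nGenerations,
                    selection = FALSE, censusEvery = censusEvery))
  res <- cpp_wf_run(NULL, .cppTemplate(template), .cppDfe(dfe),
                    .cppConfig(config), as.integer(nGenerations),
                    FALSE, as.integer(censusEvery), FALSE, 0L, TRUE)
  st <- .stateFromCpp(res, config, template, dfe)
  if (censusEvery > 0L)
    attr(st, "census") <- data.frame(generation = res$census$generation,
                                     n_tsr_origins = res$census$n_tsr_origins)
  st
}

#' Run the herbicide-selection phase
#'
#' Continues a generation-0 population for `selGenerations` generations.
#' Each generation the parental sampling weight of an individual is its
#' background fitness multiplied by `survivalRatio` if it carries at least
#' one TSR allele (dominant resistance). Mutation and recombination
#' continue, so de novo TSR origins can arise during the phase. Every
#' segregating TSR origin's frequency is recorded every generation
#' (including the onset snapshot at generation 0).
#'
#' @param pop a [PopulationState-class] at generation 0 (or later).
#' @param config a [SimulationConfig-class] (consistent `N`).
#' @param nGenerations override for `selGenerations`.
#' @return list with elements `state` (final [PopulationState-class]) and
#'   `trajectory` (data.frame: generation, origin_id, frequency,
#'   origin_gen, origin_phase, site).
#' @export
runSelectionPhase <- function(pop, config, nGenerations = NULL) {
  stopifnot(is(pop, "PopulationState"), is(config, "SimulationConfig"))
  if (config@N != pop@N)
    stop("config N (", config@N, ") does not match state N (", pop@N, ")")
  if (is.null(nGenerations)) nGenerations <- config@selGenerations
  if (pop@engine == "freq" || config@engine == "freq")
    return(.freqRun(pop, config, pop@template, pop@dfe,
                    as.integer(nGenerations), selection = TRUE))
  res <- cpp_wf_run(.stateToCpp(pop), .cppTemplate(pop@template),
                    .cppDfe(pop@dfe), .cppConfig(config),
                    as.integer(nGenerations), TRUE, 0L, TRUE, 0L, TRUE)
  st <- .stateFromCpp(res, config, pop@template, pop@dfe)
  st@fixed <- rbind(pop@fixed, st@fixed)
  list(state = st, trajectory = .trajectoryFromCpp(res$trajectory,
                                                   config@N))
}

#' Run independent simulation replicates
#'
#' Each replicate seeds the RNG with `baseSeed + i`, runs the burn-in and
#' (unless `herbicideOn` is `FALSE`) the selection phase, and classifies
#' the outcome with [classifyReplicate()]. Deterministic given
#' `(config, template, dfe, baseSeed)`.
#'
#' @param config a [SimulationConfig-class].
#' @param template a [LocusTemplate-class].
#' @param dfe a [DFEConfig-class].
#' @param nReps number of replicates.
#' @param baseSeed integer base seed.
#' @param keepTrajectories keep each replicate's TSR trajectory table
#'   (default `TRUE`; set `FALSE` to save memory in large sweeps).
#' @param threshold presence threshold passed to [classifyReplicate()]
#'   (default one copy, `1/(2N)`).
#' @return list with `summaries` (data.frame, one row per replicate; see
#'   [classifyReplicate()]) and `trajectories` (list of data.frames or
#'   `NULL`).
#' @examples
#' cfg <- simulationConfig(N = 100, muSite = 1e-5, selGenerations = 10)
#' tmpl <- buildTemplate(500, nExons = 2, nTsrSites = 2)
#' out <- runReplicates(cfg, tmpl, dfeConfig(), nReps = 3, baseSeed = 42)
#' out$summaries
#' @export
runReplicates <- function(config, template, dfe, nReps, baseSeed,
                          keepTrajectories = TRUE, threshold = NULL) {
  nReps <- .assertCount(nReps, "nReps", 1L)
  baseSeed <- .assertCount(baseSeed, "baseSeed", 0L)
  cfgHash <- .configHash(config, template, dfe)
  summaries <- vector("list", nReps)
  trajectories <- if (keepTrajectories) vector("list", nReps)
  doSel <- config@herbicideOn && config@selGenerations > 0L
  burninGens <- as.integer(round(config@burninMultiplier * config@N))
  for (i in seq_len(nReps)) {
    seed <- baseSeed + i
    set.seed(seed)
    cfg <- config
    cfg@seed <- NA_integer_  # seed already applied; keep phases coupled
    if (config@engine == "freq") {
      pop <- runBurnin(cfg, template, dfe)
      if (doSel) {
        sel <- runSelectionPhase(pop, cfg)
        traj <- sel$trajectory
      } else {
        traj <- .onsetTrajectory(pop)
      }
    } else {
      # single engine call: burn-in then selection, no state marshalling
      res <- cpp_wf_run(NULL, .cppTemplate(template), .cppDfe(dfe),
                        .cppConfig(cfg), burninGens, FALSE, 0L, TRUE,
                        if (doSel) cfg@selGenerations else 0L, FALSE)
      traj <- if (doSel) .trajectoryFromCpp(res$trajectory, cfg@N)
              else .onsetTrajectoryCpp(res, cfg@N)
    }
    sm <- classifyReplicate(traj, N = config@N, threshold = threshold,
                            finalGeneration = if (doSel)
                              config@selGenerations else 0L)
    sm$replicate_id <- i
    sm$seed <- seed
    sm$config_hash <- cfgHash
    summaries[[i]] <- sm
    if (keepTrajectories) trajectories[[i]] <- traj
  }
  list(summaries = do.call(rbind, summaries), trajectories = trajectories)
}

# trajectory-shaped snapshot from a raw engine result (herbicide off)
.onsetTrajectoryCpp <- function(res, N) {
  reg <- res$registry
  keep <- which(reg$cls == 0L)
  data.frame(generation = rep(as.integer(res$generation), length(keep)),
             origin_id = keep,
             frequency = reg$count[keep] / (2 * N),
             origin_gen = reg$origin_gen[keep],
             origin_phase = ifelse(reg$origin_gen[keep] >= 1L,
                                   "selection", "burnin"),
             site = reg$site[keep])
}

# trajectory-shaped snapshot of TSR alleles at the current generation,
# used when the selection phase is skipped (herbicide off)
.onsetTrajectory <- function(pop) {
  reg <- pop@registry
  keep <- which(reg$class == "tsr_target")
  data.frame(generation = rep(pop@generation, length(keep)),
             origin_id = keep,
             frequency = reg$count[keep] / (2 * pop@N),
             origin_gen = reg$origin_gen[keep],
             origin_phase = reg$origin_phase[keep],
             site = reg$site[keep])
}

.configHash <- function(config, template, dfe) {
  key <- paste(config@N, config@muSite, config@recSite,
               config@burninMultiplier, config@selGenerations,
               config@survivalRatio, config@herbicideOn,
               config@rescaleLambda, config@engine,
               template@lengthBp, paste(template@tsrSites, collapse = ","),
               paste(exonIntervals(template), collapse = ","),
               dfe@pNeutralExon, dfe@gammaMeanS, dfe@gammaShape, dfe@hDel,
               dfe@tsrSBefore, sep = "|")
  # small stable checksum; no digest dependency
  sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 1000000007
}

## ---- state utilities ----

#' Allele frequencies of tracked mutations
#'
#' @param pop a [PopulationState-class].
#' @param class optional site-class filter, e.g. `"tsr_target"`.
#' @return named numeric vector (names = registry row ids).
#' @export
alleleFrequencies <- function(pop, class = NULL) {
  reg <- pop@registry
  keep <- if (is.null(class)) seq_len(nrow(reg)) else
    which(reg$class %in% class)
  stats::setNames(reg$count[keep] / (2 * pop@N), keep)
}

#' Inject a mutation into a population state at a given count
#'
#' Adds a new mutation record and places single copies on `count` distinct
#' haplotypes (the first `count` haplotypes, which are exchangeable under
#' the Wright-Fisher model). Intended for constructing controlled initial
#' conditions in tests and establishment-probability experiments.
#'
#' @param pop a [PopulationState-class]; with the freq engine only the
#'   registry is updated.
#' @param site 0-based site index.
#' @param s selection coefficient on the simulation scale (i.e. already
#'   rescaled if the configuration is).
#' @param h dominance coefficient.
#' @param class site class label (default `"tsr_target"`).
#' @param count number of copies to place (1..2N).
#' @param originGen origin generation to record.
#' @return the modified [PopulationState-class].
#' @export
injectMutation <- function(pop, site, s = 0, h = 0.5,
                           class = "tsr_target", count = 1L,
                           originGen = pop@generation) {
  stopifnot(is(pop, "PopulationState"))
  count <- .assertCount(count, "count", 1L)
  if (count > 2L * pop@N) stop("count exceeds 2N")
  rec <- data.frame(site = as.integer(site), s = as.numeric(s),
                    h = as.numeric(h), class = class,
                    origin_gen = as.integer(originGen),
                    origin_phase = ifelse(originGen >= 1L, "selection",
                                          "burnin"),
                    count = as.integer(count))
  pop@registry <- rbind(pop@registry, rec)
  if (pop@engine == "linked") {
    id <- nrow(pop@registry)
    for (k in seq_len(count))
      pop@haplotypes[[k]] <- c(pop@haplotypes[[k]], id)
  }
  validObject(pop)
  pop
}

#' Sample haplotypes from a population state
#'
#' Draws `n` haplotypes without replacement and returns their derived-site
#' sets, the input for [nucleotideDiversity()] and
#' [segregatingSites()].
#'
#' @param pop a linked-engine [PopulationState-class].
#' @param n number of haplotypes to sample (2..2N).
#' @return a [HaplotypeSample-class].
#' @export
sampleHaplotypes <- function(pop, n) {
  stopifnot(is(pop, "PopulationState"), pop@engine == "linked")
  n <- .assertCount(n, "n", 2L)
  if (n > 2L * pop@N) stop("cannot sample more than 2N haplotypes")
  idx <- sample.int(2L * pop@N, n)
  sites <- lapply(pop@haplotypes[idx], function(ids)
    sort(unique(pop@registry$site[ids])))
  new("HaplotypeSample", n = n, L = pop@template@lengthBp,
      siteList = sites)
}
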