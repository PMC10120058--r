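#' @import methods
#' @importFrom IRanges IRanges start end width overlapsAny
#' @importFrom stats rbinom rpois runif rgamma pchisq setNames
#' @importFrom utils head tail
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet pairwiseAlignment alignedPattern alignedSubject
#'   consensusMatrix GENETIC_CODE
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @useDynLib herbisweep, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Locus template for the herbicide-target gene model
#'
#' Describes the simulated locus: total length in base pairs, the exon
#' intervals (0-based, half-open, stored as an [IRanges::IRanges] over
#' 1-based closed coordinates internally), and the set of target-site
#' resistance (TSR) nucleotide positions. The default dimensions emulate the
#' ACCase locus (12,250 bp) with a mutational target of seven TSR
#' nucleotides.
#'
#' @slot lengthBp single integer, locus length in bp.
#' @slot exonIntervals an `IRanges` of exon intervals (1-based, closed).
#' @slot tsrSites integer vector of 0-based TSR site indices, all exonic.
#' @slot name free-text label.
#'
#' @seealso [buildTemplate()]
#' @export
setClass("LocusTemplate",
  representation(lengthBp = "integer", exonIntervals = "ANY",
                 tsrSites = "integer", name = "character"))

setValidity("LocusTemplate", function(object) {
  msg <- character()
  L <- object@lengthBp
  if (length(L) != 1L || is.na(L) || L < 1L)
    msg <- c(msg, "lengthBp must be a single positive integer")
  ex <- object@exonIntervals
  if (!is(ex, "IRanges"))
    msg <- c(msg, "exonIntervals must be an IRanges")
  else if (length(ex)) {
    if (any(IRanges::start(ex) < 1L) || any(IRanges::end(ex) > L))
      msg <- c(msg, "exon intervals must lie within [0, lengthBp)")
    if (is.unsorted(IRanges::start(ex), strictly = TRUE))
      msg <- c(msg, "exon intervals must be sorted")
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exon intervals must be disjoint")
  }
  ts <- object@tsrSites
  if (length(ts)) {
    if (any(is.na(ts)) || any(ts < 0L) || any(ts >= L))
      msg <- c(msg, "tsrSites must be valid 0-based site indices")
    if (anyDuplicated(ts))
      msg <- c(msg, "tsrSites must be unique")
    if (is(ex, "IRanges") &&
        !all(IRanges::overlapsAny(IRanges::IRanges(ts + 1L, ts + 1L), ex)))
      msg <- c(msg, "every TSR site must lie inside an exon interval")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LocusTemplate", function(object) {
  cat("LocusTemplate '", object@name, "': ", object@lengthBp, " bp, ",
      length(object@exonIntervals), " exon(s) (",
      sum(IRanges::width(object@exonIntervals)), " bp coding), ",
      length(object@tsrSites), " TSR site(s)\n", sep = "")
})

#' Distribution of fitness effects for new mutations
#'
#' Exonic mutations are neutral with probability `pNeutralExon` and
#' otherwise deleterious with selection coefficients drawn from a gamma
#' distribution whose mean (for the deleterious class itself) is
#' `gammaMeanS` and whose shape is `gammaShape`. Intronic and intergenic
#' mutations are neutral. Mutations at TSR target nucleotides carry
#' `tsrSBefore` before herbicide onset (0 = neutral standing variation).
#'
#' @slot pNeutralExon probability that an exonic mutation is neutral.
#' @slot gammaMeanS mean selection coefficient of deleterious mutations
#'   (negative; default -1.54e-4).
#' @slot gammaShape gamma shape parameter (default 0.245).
#' @slot hDel dominance coefficient of deleterious mutations.
#' @slot tsrSBefore selection coefficient of TSR alleles before herbicide
#'   onset.
#'
#' @seealso [dfeConfig()], [drawEffect()]
#' @export
setClass("DFEConfig",
  representation(pNeutralExon = "numeric", gammaMeanS = "numeric",
                 gammaShape = "numeric", hDel = "numeric",
                 tsrSBefore = "numeric"))

setValidity("DFEConfig", function(object) {
  msg <- character()
  if (object@pNeutralExon < 0 || object@pNeutralExon > 1)
    msg <- c(msg, "pNeutralExon must be in [0, 1]")
  if (object@gammaShape <= 0)
    msg <- c(msg, "gammaShape must be positive")
  if (object@gammaMeanS > 0)
    msg <- c(msg, "gammaMeanS must be <= 0 (deleterious)")
  if (object@hDel < 0 || object@hDel > 1)
    msg <- c(msg, "hDel must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DFEConfig", function(object) {
  cat("DFEConfig: P(neutral | exon) =", object@pNeutralExon,
      "; deleterious ~ -Gamma(shape =", object@gammaShape,
      ", mean =", -object@gammaMeanS, "); h =", object@hDel,
      "; TSR s before onset =", object@tsrSBefore, "\n")
})

#' Configuration of a Wright-Fisher simulation run
#'
#' @slot N diploid population size.
#' @slot muSite per-site per-generation mutation rate.
#' @slot recSite per-site per-generation recombination rate.
#' @slot burninMultiplier burn-in length in units of N generations.
#' @slot selGenerations length of the herbicide-selection phase.
#' @slot survivalRatio relative survival (parental sampling weight) of
#'   individuals carrying at least one TSR allele; resistance is dominant.
#' @slot herbicideOn if `FALSE`, the selection phase is skipped entirely
#'   (neutral census runs).
#' @slot rescaleLambda population-rescaling factor already applied
#'   (see [rescaleConfig()]); drawn selection coefficients are multiplied
#'   by this factor.
#' @slot seed integer seed (NA = use the current RNG stream).
#' @slot engine `"linked"` (exact haplotype model, compiled) or `"freq"`
#'   (linkage-free per-mutation binomial updates).
#' @slot pruneEvery bookkeeping interval (generations) at which lost and
#'   fixed mutations are swept from the haplotype lists.
#'
#' @seealso [simulationConfig()], [rescaleConfig()]
#' @export
setClass("SimulationConfig",
  representation(N = "integer", muSite = "numeric", recSite = "numeric",
                 burninMultiplier = "numeric", selGenerations = "integer",
                 survivalRatio = "numeric", herbicideOn = "logical",
                 rescaleLambda = "numeric", seed = "integer",
                 engine = "character", pruneEvery = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@N < 2L) msg <- c(msg, "N must be >= 2")
  if (object@muSite < 0) msg <- c(msg, "muSite must be >= 0")
  if (object@recSite < 0) msg <- c(msg, "recSite must be >= 0")
  if (object@survivalRatio < 1) msg <- c(msg, "survivalRatio must be >= 1")
  if (object@rescaleLambda < 1) msg <- c(msg, "rescaleLambda must be >= 1")
  if (object@burninMultiplier < 0)
    msg <- c(msg, "burninMultiplier must be >= 0")
  if (object@selGenerations < 0L)
    msg <- c(msg, "selGenerations must be >= 0")
  if (!object@engine %in% c("linked", "freq"))
    msg <- c(msg, "engine must be 'linked' or 'freq'")
  if (object@pruneEvery < 1L) msg <- c(msg, "pruneEvery must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: N =", object@N,
      "| mu/site =", object@muSite, "| r/site =", object@recSite, "\n",
      " burn-in =", object@burninMultiplier, "x N generations;",
      "selection =", object@selGenerations, "generations x",
      object@survivalRatio, "survival ratio",
      if (!object@herbicideOn) "(herbicide OFF)", "\n",
      " engine =", object@engine, "| lambda =", object@rescaleLambda, "\n")
})

#' State of a simulated population
#'
#' Holds the population at one generation: for the linked engine, 2N sparse
#' haplotypes (integer vectors of 1-based mutation ids into the registry);
#' for the freq engine only the registry with per-mutation allele counts.
#' The locus template and DFE travel with the state so the selection phase
#' can continue mutating.
#'
#' @slot generation generation index (<= 0 during burn-in; 0 is the onset
#'   of herbicide selection).
#' @slot N diploid population size.
#' @slot haplotypes list of 2N integer vectors (linked engine) or an empty
#'   list (freq engine).
#' @slot registry data.frame of segregating (and fixed TSR) mutation
#'   records: site, s, h, class, origin_gen, origin_phase, count.
#' @slot fixed data.frame archive of fixed non-TSR mutations.
#' @slot template the [LocusTemplate-class] used.
#' @slot dfe the [DFEConfig-class] used.
#' @slot engine engine that produced the state.
#'
#' @seealso [runBurnin()], [runSelectionPhase()], [alleleFrequencies()]
#' @export
setClass("PopulationState",
  representation(generation = "integer", N = "integer",
                 haplotypes = "list", registry = "data.frame",
                 fixed = "data.frame", template = "LocusTemplate",
                 dfe = "DFEConfig", engine = "character"))

setValidity("PopulationState", function(object) {
  msg <- character()
  if (object@engine == "linked" &&
      length(object@haplotypes) != 2L * object@N)
    msg <- c(msg, "linked state must have exactly 2N haplotypes")
  nreg <- nrow(object@registry)
  if (object@engine == "linked" && length(object@haplotypes)) {
    ids <- unlist(object@haplotypes, use.names = FALSE)
    if (length(ids) && (min(ids) < 1L || max(ids) > nreg))
      msg <- c(msg, "haplotype mutation ids must exist in the registry")
  }
  if (nreg && any(object@registry$count < 1L))
    msg <- c(msg, "registry counts must be >= 1 (lost mutations are pruned)")
  if (nreg && any(object@registry$count > 2L * object@N))
    msg <- c(msg, "registry counts cannot exceed 2N")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PopulationState", function(object) {
  reg <- object@registry
  cat("PopulationState at generation ", object@generation, " (",
      object@engine, " engine): N = ", object@N, ", ",
      nrow(reg), " tracked mutation(s), of which ",
      sum(reg$class == "tsr_target"), " TSR\n", sep = "")
})

#' Sample of haplotypes drawn from a simulated population
#'
#' A sparse representation of `n` sampled haplotypes over a locus of `L`
#' sites: per haplotype, the 0-based sites at which it carries a derived
#' allele.
#'
#' @slot n number of sampled haplotypes.
#' @slot L number of sites surveyed.
#' @slot siteList list of n integer vectors of derived-allele sites.
#' @seealso [sampleHaplotypes()], [nucleotideDiversity()]
#' @export
setClass("HaplotypeSample",
  representation(n = "integer", L = "integer", siteList = "list"))

setValidity("HaplotypeSample", function(object) {
  if (length(object@siteList) != object@n)
    return("siteList must have one entry per sampled haplotype")
  if (object@n < 2L) return("at least 2 haplotypes are required")
  TRUE
})

setMethod("show", "HaplotypeSample", function(object) {
  cat("HaplotypeSample:", object@n, "haplotypes over", object@L, "sites;",
      length(unique(unlist(object@siteList))), "segregating site(s)\n")
})
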