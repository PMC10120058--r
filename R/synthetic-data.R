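## Synthetic amplicon-haplotype panels with machine-readable truth tables.
## Backbones use a fixed-divergence star design (each backbone carries its
## own disjoint set of private substitutions), so planted pairwise
## divergences are realized exactly and downstream typing logic can be
## scored against construction truth.

#' Configuration of a synthetic haplotype panel
#'
#' @param gene `"ACCase"` or `"ALS1"`.
#' @param nBackbones number of wild-type backbones.
#' @param backboneDivergence number of private substitutions per backbone;
#'   every pair of backbones then differs at exactly
#'   `2 * backboneDivergence` sites.
#' @param populations population labels.
#' @param sharing list (length `nBackbones`) of population-label vectors
#'   giving where each backbone occurs; default: every backbone in every
#'   population.
#' @param emitWildType logical vector: emit wild-type copies of each
#'   backbone (default all `TRUE`).
#' @param tsrEvents data.frame with columns `label` (e.g.
#'   `"ACCase Ile1781Leu"`), `backbone` (index) and `populations`
#'   (comma-separated labels); each row is one independent origin event.
#' @param recombinants data.frame with columns `event` (row index into
#'   `tsrEvents`), `wtBackbone`, `breakpoint` (1-based; left of the
#'   breakpoint comes from the TSR carrier, which must contain the mutated
#'   codon) and `population`.
#' @param wtCopies,tsrCopies copies emitted per backbone/event and
#'   population.
#' @param seed integer seed; the panel is deterministic given the config.
#' @return list of class `"PanelConfig"`.
#' @export
panelConfig <- function(gene = "ACCase", nBackbones = 3L,
                        backboneDivergence = 6L,
                        populations = c("pop1", "pop2"),
                        sharing = NULL, emitWildType = NULL,
                        tsrEvents = NULL, recombinants = NULL,
                        wtCopies = 1L, tsrCopies = 1L, seed = 1L) {
  nBackbones <- .assertCount(nBackbones, "nBackbones", 1L)
  if (is.null(sharing))
    sharing <- rep(list(populations), nBackbones)
  if (length(sharing) != nBackbones)
    stop("sharing must have one entry per backbone")
  if (is.null(emitWildType)) emitWildType <- rep(TRUE, nBackbones)
  if (!is.null(tsrEvents)) {
    if (any(tsrEvents$backbone < 1L | tsrEvents$backbone > nBackbones))
      stop("tsrEvents reference non-existing backbones")
  }
  structure(list(gene = gene, nBackbones = nBackbones,
                 backboneDivergence =
                   .assertCount(backboneDivergence, "backboneDivergence"),
                 populations = populations, sharing = sharing,
                 emitWildType = emitWildType, tsrEvents = tsrEvents,
                 recombinants = recombinants,
                 wtCopies = .assertCount(wtCopies, "wtCopies", 1L),
                 tsrCopies = .assertCount(tsrCopies, "tsrCopies", 1L),
                 seed = .assertCount(seed, "seed", 0L)),
            class = "PanelConfig")
}

# parse "ACCase Ile1781Leu" -> list(gene, ref_aa, codon, res_aa)
.parseTsrLabel <- function(label) {
  m <- regmatches(label,
                  regexec("^(\\S+) ([A-Za-z]{3})(\\d+)([A-Za-z]{3})$",
                          label))[[1]]
  if (length(m) != 5L) stop("cannot parse TSR label: ", label)
  list(gene = m[2], ref_aa = m[3], codon = as.integer(m[4]),
       res_aa = m[5])
}

# codon encoding `aa3` with the fewest changes from `refCodon`
.resistantCodon <- function(refCodon, aa3) {
  gc <- Biostrings::GENETIC_CODE
  cands <- sort(names(gc)[.AA3[gc] == aa3])
  if (!length(cands)) stop("no codon encodes ", aa3)
  ref <- strsplit(refCodon, "")[[1]]
  dist <- vapply(cands, function(cd)
    sum(strsplit(cd, "")[[1]] != ref), integer(1))
  cands[which.min(dist)]
}

#' Generate a synthetic amplicon haplotype panel
#'
#' Builds wild-type backbones around the bundled mock reference, plants
#' TSR codon substitutions for each configured origin event, constructs
#' single-crossover recombinants, and assigns haplotypes to populations.
#' Deterministic given `config$seed`.
#'
#' @param config a [panelConfig()] object.
#' @return list with `haps` (a [Biostrings::DNAStringSet] named
#'   `sampleID|populationID|gene|phase`) and `truth` (data.frame: `hap`,
#'   `population`, `backbone`, `tsr_label`, `origin_event`, `recombinant`,
#'   `breakpoint`).
#' @examples
#' cfg <- panelConfig(nBackbones = 2, backboneDivergence = 6,
#'                    tsrEvents = data.frame(
#'                      label = "ACCase Ile1781Leu",
#'                      backbone = 1:2, populations = "pop1"))
#' panel <- generatePanel(cfg)
#' length(panel$haps)
#' @export
generatePanel <- function(config) {
  stopifnot(inherits(config, "PanelConfig"))
  gene <- config$gene
  ref <- strsplit(toupper(as.character(mockReference(gene))), "")[[1]]
  L <- length(ref)
  tab <- tsrCodonTable(gene)
  codonPos <- unlist(lapply(tab$pos, function(p) p + 0:2))
  free <- setdiff(seq_len(L), codonPos)
  need <- config$nBackbones * config$backboneDivergence
  if (need > length(free))
    stop("infeasible divergence: not enough non-codon sites")

  # stratified placement: one private site per equal-width window, so
  # planted substitutions are spread evenly along the sequence (keeps
  # recombinant fixtures unambiguous for any central breakpoint)
  sites <- .withSeed(config$seed, {
    if (need > 0L) {
      bounds <- round(seq(0, length(free), length.out = need + 1L))
      picks <- integer(need)
      for (k in seq_len(need))
        picks[k] <- if (bounds[k + 1L] > bounds[k])
          sample(seq.int(bounds[k] + 1L, bounds[k + 1L]), 1L)
        else max(1L, bounds[k])
      free[sample(picks)]  # shuffle window assignment across backbones
    } else integer()
  })
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  backbones <- vector("list", config$nBackbones)
  for (b in seq_len(config$nBackbones)) {
    seqb <- ref
    if (config$backboneDivergence > 0L) {
      own <- sites[seq.int((b - 1L) * config$backboneDivergence + 1L,
                           length.out = config$backboneDivergence)]
      seqb[own] <- flip[seqb[own]]
    }
    backbones[[b]] <- seqb
  }

  haps <- character(0); nms <- character(0)
  truth <- list()
  counter <- 0L
  emit <- function(seqChars, pop, backbone, label, event, recomb, bp) {
    counter <<- counter + 1L
    nm <- sprintf("S%04d|%s|%s|1", counter, pop, gene)
    haps <<- c(haps, paste(seqChars, collapse = ""))
    nms <<- c(nms, nm)
    truth[[counter]] <<- data.frame(
      hap = nm, population = pop, backbone = backbone,
      tsr_label = label, origin_event = event, recombinant = recomb,
      breakpoint = bp)
  }

  for (b in seq_len(config$nBackbones)) {
    if (!config$emitWildType[b]) next
    for (pop in config$sharing[[b]])
      for (k in seq_len(config$wtCopies))
        emit(backbones[[b]], pop, b, NA_character_, NA_character_,
             FALSE, NA_integer_)
  }

  tsrSeqs <- list()
  ev <- config$tsrEvents
  if (!is.null(ev) && nrow(ev)) {
    for (e in seq_len(nrow(ev))) {
      info <- .parseTsrLabel(ev$label[e])
      k <- match(info$codon, tab$codon)
      if (is.na(k)) stop("codon ", info$codon, " not in table for ", gene)
      seqe <- backbones[[ev$backbone[e]]]
      refCodon <- paste(seqe[tab$pos[k] + 0:2], collapse = "")
      mutCodon <- strsplit(.resistantCodon(refCodon, info$res_aa), "")[[1]]
      seqe[tab$pos[k] + 0:2] <- mutCodon
      tsrSeqs[[e]] <- seqe
      pops <- strsplit(ev$populations[e], ",")[[1]]
      for (pop in pops)
        for (kk in seq_len(config$tsrCopies))
          emit(seqe, pop, ev$backbone[e], ev$label[e], paste0("E", e),
               FALSE, NA_integer_)
    }
  }

  rc <- config$recombinants
  if (!is.null(rc) && nrow(rc)) {
    for (r in seq_len(nrow(rc))) {
      e <- rc$event[r]
      info <- .parseTsrLabel(ev$label[e])
      k <- match(info$codon, tab$codon)
      bp <- rc$breakpoint[r]
      if (bp <= tab$pos[k] + 2L)
        stop("breakpoint must lie right of the mutated codon")
      if (bp > L) stop("breakpoint beyond sequence length")
      seqr <- c(tsrSeqs[[e]][seq_len(bp - 1L)],
                backbones[[rc$wtBackbone[r]]][bp:L])
      emit(seqr, rc$population[r], rc$wtBackbone[r], ev$label[e],
           paste0("E", e), TRUE, as.integer(bp))
    }
  }

  out <- Biostrings::DNAStringSet(haps)
  names(out) <- nms
  parts <- strsplit(nms, "|", fixed = TRUE)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    sample_id = vapply(parts, `[`, "", 1L),
    population_id = vapply(parts, `[`, "", 2L),
    gene = vapply(parts, `[`, "", 3L),
    phase = vapply(parts, `[`, "", 4L))
  list(haps = out, truth = do.call(rbind, truth))
}

#' Write the canned fixture suite
#'
#' Generates the standard test inputs: (1) a Europe-wide sharing panel
#' whose nonredundant clusters reproduce the shared-versus-private table
#' (TSR 20 shared / 42 private; wild type 55 shared / 133 private), (2) an
#' unambiguous origin-counting panel for a single field (the same TSR
#' mutation on two backbones 12 sites apart plus one single-crossover
#' recombinant), and (3) a small rescaled simulation configuration. Every
#' file is accompanied by its construction truth.
#'
#' @param outDir writable output directory (created if missing).
#' @param seed integer seed.
#' @return invisible named list of file paths.
#' @export
makeFixtureSuite <- function(outDir, seed = 20230412L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  ## 1) sharing panel: 250 nonredundant clusters, (20,42,55,133)
  nB <- 250L
  pops <- paste0("pop", 1:6)
  sharing <- vector("list", nB)
  emitWT <- rep(TRUE, nB)
  # backbones 1..62 carry the TSR event (their wild-type version is not
  # emitted, keeping the cluster count at 250)
  emitWT[1:62] <- FALSE
  tsrPops <- character(62)
  for (i in 1:62) {
    sharing[[i]] <- "unused"
    tsrPops[i] <- if (i <= 20)  # shared TSR clusters
      paste(pops[c((i %% 6) + 1L, ((i + 2L) %% 6) + 1L)], collapse = ",")
    else pops[(i %% 6) + 1L]
  }
  for (i in 63:250) {
    sharing[[i]] <- if (i <= 62 + 55)  # shared wild-type clusters
      pops[c((i %% 6) + 1L, ((i + 3L) %% 6) + 1L)]
    else pops[(i %% 6) + 1L]
  }
  cfgShare <- panelConfig(
    gene = "ACCase", nBackbones = nB, backboneDivergence = 2L,
    populations = pops, sharing = sharing, emitWildType = emitWT,
    tsrEvents = data.frame(label = "ACCase Ile1781Leu",
                           backbone = 1:62, populations = tsrPops),
    seed = seed)
  panel <- generatePanel(cfgShare)
  paths$sharing_fasta <- file.path(outDir, "accase_sharing_panel.fa")
  Biostrings::writeXStringSet(panel$haps, paths$sharing_fasta)
  paths$sharing_truth <- file.path(outDir, "accase_sharing_truth.tsv")
  utils::write.table(panel$truth, paths$sharing_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## 2) origin-counting panel: one field, 2 independent origins + 1
  ##    recombinant
  cfgOrigin <- panelConfig(
    gene = "ACCase", nBackbones = 3L, backboneDivergence = 8L,
    populations = "fieldA",
    sharing = rep(list("fieldA"), 3L),
    tsrEvents = data.frame(label = "ACCase Ile1781Leu",
                           backbone = c(1L, 2L),
                           populations = "fieldA"),
    recombinants = data.frame(event = 1L, wtBackbone = 3L,
                              breakpoint = 1000L,
                              population = "fieldA"),
    seed = seed + 1L)
  origin <- generatePanel(cfgOrigin)
  paths$origin_fasta <- file.path(outDir, "accase_origin_panel.fa")
  Biostrings::writeXStringSet(origin$haps, paths$origin_fasta)
  paths$origin_truth <- file.path(outDir, "accase_origin_truth.tsv")
  utils::write.table(origin$truth, paths$origin_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## 3) small rescaled simulation configuration
  cfgSim <- rescaleConfig(simulationConfig(N = 42000L, seed = seed), 20)
  paths$sim_config <- file.path(outDir, "sim_config.json")
  writeSimulationConfig(cfgSim, buildTemplate(), dfeConfig(),
                        paths$sim_config)

  paths$manifest <- file.path(outDir, "fixture_manifest.json")
  jsonlite::write_json(
    list(seed = seed,
         sharing_expected_2x2 = list(tsr_shared = 20, tsr_private = 42,
                                     wt_shared = 55, wt_private = 133),
         origin_expected = list(independent_origins = 2,
                                recombinants = 1)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
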