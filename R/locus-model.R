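#' Build a locus template
#'
#' Constructs an ACCase-like gene model: `nExons` exons of (near) equal
#' size, evenly separated by introns and flanked by noncoding sequence, with
#' a total coding length of `round(codingFraction * lengthBp)`. TSR target
#' nucleotides are placed evenly across the coding sequence unless given
#' explicitly. All coordinates are 0-based and intervals half-open.
#'
#' The default locus length (12,250 bp) and the 7-nucleotide TSR target
#' match the ACCase template; exon count and coding fraction are generic
#' model choices — users modelling a real gene should set `exonIntervals`
#' from an annotation.
#'
#' @param lengthBp locus length in bp.
#' @param nExons number of exons (ignored when `exonIntervals` is given).
#' @param codingFraction fraction of the locus that is coding, in (0, 1).
#' @param tsrSites optional integer vector of 0-based TSR sites (must be
#'   exonic); `nTsrSites` evenly spread exonic sites are used by default.
#' @param nTsrSites number of TSR target nucleotides placed by default.
#' @param exonIntervals optional explicit exon intervals: a 2-column matrix
#'   of 0-based half-open `[start, end)` rows, or an `IRanges` (1-based).
#' @param name label for the template.
#' @return a [LocusTemplate-class].
#' @examples
#' tmpl <- buildTemplate()
#' tmpl
#' classifySite(tmpl, tsrSites(tmpl)[1])
#' @export
buildTemplate <- function(lengthBp = 12250L, nExons = 10L,
                          codingFraction = 0.5, tsrSites = NULL,
                          nTsrSites = 7L, exonIntervals = NULL,
                          name = "ACCase-like") {
  lengthBp <- .assertCount(lengthBp, "lengthBp", min = 1L)
  if (is.null(exonIntervals)) {
    nExons <- .assertCount(nExons, "nExons", min = 1L)
    if (codingFraction <= 0 || codingFraction >= 1)
      stop("codingFraction must be in (0, 1)")
    exonTotal <- round(codingFraction * lengthBp)
    if (exonTotal < nExons)
      stop("coding fraction too small to host ", nExons, " exons")
    # equal-size exons, gaps (flanks + introns) as equal as possible
    exLen <- diff(round(seq(0, exonTotal, length.out = nExons + 1L)))
    gapTotal <- lengthBp - exonTotal
    gapLen <- diff(round(seq(0, gapTotal, length.out = nExons + 2L)))
    starts <- integer(nExons)
    pos <- 0L
    for (i in seq_len(nExons)) {
      pos <- pos + gapLen[i]
      starts[i] <- pos
      pos <- pos + exLen[i]
    }
    ir <- IRanges::IRanges(start = starts + 1L, width = exLen)
  } else {
    if (is(exonIntervals, "IRanges")) {
      ir <- exonIntervals
    } else {
      m <- as.matrix(exonIntervals)
      if (ncol(m) != 2L) stop("exonIntervals must have two columns")
      if (any(m[, 2L] <= m[, 1L]))
        stop("exon intervals must be non-empty half-open [start, end)")
      ir <- IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L])
    }
    ir <- ir[order(IRanges::start(ir))]
    if (length(ir) > 1L &&
        any(IRanges::start(ir)[-1L] <= IRanges::end(ir)[-length(ir)]))
      stop("explicit exon intervals overlap")
  }

  if (is.null(tsrSites)) {
    nTsrSites <- .assertCount(nTsrSites, "nTsrSites")
    # 0-based exonic coordinate space, TSR sites at interior quantiles
    exonic <- unlist(lapply(seq_along(ir), function(i)
      seq.int(IRanges::start(ir)[i] - 1L, IRanges::end(ir)[i] - 1L)))
    if (nTsrSites > 0L) {
      idx <- unique(round(seq_along(exonic)[1] - 1 +
                          (seq_len(nTsrSites) / (nTsrSites + 1)) *
                          length(exonic)))
      tsrSites <- sort(exonic[pmax(1L, pmin(length(exonic), idx))])
      if (length(tsrSites) != nTsrSites)
        stop("could not place ", nTsrSites, " distinct TSR sites")
    } else {
      tsrSites <- integer()
    }
  }
  new("LocusTemplate", lengthBp = lengthBp, exonIntervals = ir,
      tsrSites = as.integer(sort(tsrSites)), name = as.character(name))
}

#' @describeIn buildTemplate accessor for the TSR site indices (0-based).
#' @param template a `LocusTemplate`.
#' @export
tsrSites <- function(template) template@tsrSites

#' @describeIn buildTemplate accessor for the exon intervals as a 0-based
#'   half-open 2-column matrix.
#' @export
exonIntervals <- function(template) {
  cbind(start = IRanges::start(template@exonIntervals) - 1L,
        end = IRanges::end(template@exonIntervals))
}

#' @describeIn buildTemplate accessor for the locus length in bp.
#' @export
locusLength <- function(template) template@lengthBp

#' Classify sites of a locus template
#'
#' Site classes are exhaustive and mutually exclusive, with precedence
#' `tsr_target` > `exonic` > `noncoding`.
#'
#' @param template a [LocusTemplate-class].
#' @param site integer vector of 0-based site indices.
#' @return character vector with values `"tsr_target"`, `"exonic"` or
#'   `"noncoding"`.
#' @export
classifySite <- function(template, site) {
  if (any(is.na(site)) || any(site < 0L) || any(site >= template@lengthBp))
    stop("site index out of range [0, ", template@lengthBp, ")")
  site <- as.integer(site)
  out <- rep("noncoding", length(site))
  hits <- IRanges::overlapsAny(IRanges::IRanges(site + 1L, site + 1L),
                               template@exonIntervals)
  out[hits] <- "exonic"
  out[site %in% template@tsrSites] <- "tsr_target"
  out
}

#' Construct a distribution of fitness effects
#'
#' Defaults follow the blackgrass ACCase model: exonic mutations neutral
#' with probability 0.25, otherwise deleterious with selection coefficients
#' drawn from a gamma distribution with mean -1.54e-4 and shape 0.245
#' (the mean refers to the deleterious class itself), codominant
#' (`hDel = 0.5`); TSR target alleles neutral before herbicide onset.
#' Setting `pNeutralExon = 1` reproduces the fully neutral model variant.
#'
#' @param pNeutralExon probability that an exonic mutation is neutral.
#' @param gammaMeanS mean deleterious selection coefficient (<= 0).
#' @param gammaShape gamma shape parameter (> 0).
#' @param hDel dominance of deleterious mutations.
#' @param tsrSBefore selection coefficient of TSR alleles before onset.
#' @return a [DFEConfig-class].
#' @export
dfeConfig <- function(pNeutralExon = 0.25, gammaMeanS = -0.000154,
                      gammaShape = 0.245, hDel = 0.5, tsrSBefore = 0) {
  new("DFEConfig", pNeutralExon = as.numeric(pNeutralExon),
      gammaMeanS = as.numeric(gammaMeanS),
      gammaShape = as.numeric(gammaShape), hDel = as.numeric(hDel),
      tsrSBefore = as.numeric(tsrSBefore))
}

#' Draw fitness effects for new mutations
#'
#' Noncoding (intron/intergenic) mutations are neutral; TSR target sites
#' receive `tsrSBefore`; exonic sites are neutral with probability
#' `pNeutralExon` and otherwise get `s = -G`, `G ~ Gamma(shape, mean =
#' |gammaMeanS|)` with dominance `hDel`. Draws consume the current RNG
#' stream; use `set.seed()` for reproducibility.
#'
#' @param template a [LocusTemplate-class].
#' @param site integer vector of 0-based sites (recycled against `n`).
#' @param dfe a [DFEConfig-class].
#' @param n number of draws (defaults to `length(site)`).
#' @return data.frame with columns `site`, `s`, `h`, `site_class`.
#' @examples
#' tmpl <- buildTemplate(200, nExons = 1, codingFraction = 0.99,
#'                       nTsrSites = 0)
#' set.seed(1)
#' head(drawEffect(tmpl, 10, dfeConfig(), n = 5))
#' @export
drawEffect <- function(template, site, dfe, n = length(site)) {
  n <- .assertCount(n, "n", min = 1L)
  site <- rep_len(as.integer(site), n)
  base <- classifySite(template, site)
  s <- numeric(n)
  h <- rep(0.5, n)
  cls <- character(n)
  cls[base == "noncoding"] <- "noncoding_neutral"
  cls[base == "tsr_target"] <- "tsr_target"
  s[base == "tsr_target"] <- dfe@tsrSBefore
  h[base == "tsr_target"] <- dfe@hDel
  ex <- which(base == "exonic")
  if (length(ex)) {
    neutral <- runif(length(ex)) < dfe@pNeutralExon
    cls[ex[neutral]] <- "exon_neutral"
    del <- ex[!neutral]
    cls[del] <- "exon_deleterious"
    if (length(del)) {
      scale <- abs(dfe@gammaMeanS) / dfe@gammaShape
      s[del] <- -rgamma(length(del), shape = dfe@gammaShape, scale = scale)
      h[del] <- dfe@hDel
    }
  }
  data.frame(site = site, s = s, h = h, site_class = cls)
}

#' Read a locus template from a JSON configuration
#'
#' Reads the `locus` block of a JSON configuration file:
#' `{"locus": {"length_bp", "n_exons" | "exon_intervals", "coding_fraction",
#' "tsr_sites", "name"}}`. Note: the shipped exon-count and coding-fraction
#' defaults are generic placeholders; set them from a genome annotation
#' when modelling a real locus.
#'
#' @param path path to a JSON file.
#' @return a [LocusTemplate-class].
#' @export
readLocusConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  loc <- if (!is.null(cfg$locus)) cfg$locus else cfg
  buildTemplate(
    lengthBp = loc$length_bp %||% 12250L,
    nExons = loc$n_exons %||% 10L,
    codingFraction = loc$coding_fraction %||% 0.5,
    tsrSites = loc$tsr_sites,
    nTsrSites = loc$n_tsr_sites %||% 7L,
    exonIntervals = if (!is.null(loc$exon_intervals)) {
      ei <- loc$exon_intervals
      if (is.matrix(ei)) ei
      else matrix(unlist(ei), ncol = 2L, byrow = TRUE)
    },
    name = loc$name %||% "ACCase-like")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
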