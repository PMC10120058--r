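#' Parameters for analytic sweep-probability calculations
#'
#' Bundles the quantities entering the closed-form probabilities of
#' adaptation via a selective sweep at a herbicide-target locus: effective
#' population size, per-site beneficial-target mutation rate, mutational
#' target size (7 TSR nucleotides by default), the beneficial selection
#' coefficient during the herbicide phase (`sBen`), the deleterious
#' coefficient of TSR alleles before onset (`sDel`, as a positive cost),
#' dominances, and the length `T` of the selection window (30 generations).
#'
#' @param Ne effective population size.
#' @param uSite per-site beneficial-target mutation rate.
#' @param targetSize mutational target size in nucleotides.
#' @param sBen beneficial selection coefficient (>= 0).
#' @param sDel deleterious cost before onset (>= 0).
#' @param hBen,hDel dominance coefficients in \[0, 1\].
#' @param Tgen generations of herbicide selection.
#' @return a validated list of class `"SweepParams"`.
#' @export
sweepParams <- function(Ne = 42000, uSite = 3.0e-8, targetSize = 7,
                        sBen = 1, sDel = 1e-5, hBen = 0.5, hDel = 0.5,
                        Tgen = 30) {
  stopifnot(Ne >= 1, uSite >= 0, targetSize >= 0, sBen >= 0, sDel >= 0,
            hBen >= 0, hBen <= 1, hDel >= 0, hDel <= 1, Tgen >= 0)
  structure(list(Ne = Ne, uSite = uSite, targetSize = targetSize,
                 sBen = sBen, sDel = sDel, hBen = hBen, hDel = hDel,
                 Tgen = Tgen),
            class = "SweepParams")
}

#' Establishment (fixation) probability of a single new copy
#'
#' Diffusion approximation for a beneficial mutation with heterozygous
#' advantage `h*s`: `pi = (1 - exp(-2hs)) / (1 - exp(-4 Ne h s))`, with the
#' neutral limit `1/(2 Ne)` taken analytically as `s -> 0`. For weak
#' selection and large `Ne` this approaches the classic `2hs`.
#'
#' @param s selection coefficient (>= 0).
#' @param h dominance coefficient.
#' @param Ne effective population size.
#' @return establishment probability (vectorised over `s`).
#' @examples
#' establishmentProb(0.01, 0.5, 1e4)  # ~ 2hs = 0.01
#' establishmentProb(0, 0.5, 100)     # 1/(2*100)
#' @export
establishmentProb <- function(s, h = 0.5, Ne) {
  stopifnot(all(s >= 0), Ne >= 1)
  hs <- h * s
  num <- -expm1(-2 * hs)
  den <- -expm1(-4 * Ne * hs)
  out <- ifelse(hs > 0 & den > 0, num / den, NA_real_)
  out[hs == 0] <- 1 / (2 * Ne)
  # guard against den underflow for strong selection: den -> 1
  big <- hs > 0 & den == 0
  out[big] <- num[big]
  out
}

#' Probability of adaptation from standing genetic variation
#'
#' Probability that at least one copy of the mutation-selection-drift
#' standing variation present at the onset of herbicide selection escapes
#' stochastic loss and sweeps:
#' `P_sgv = 1 - exp(-Theta * log(1 + R_alpha))` with
#' `R_alpha = alpha_b / (alpha_d + 1)`, `alpha_b = 4 Ne hBen sBen`,
#' `alpha_d = 4 Ne hDel sDel` and `Theta = 4 Ne uSite targetSize`.
#'
#' @param params a [sweepParams()] object.
#' @return probability in \[0, 1\].
#' @export
probSGV <- function(params) {
  p <- params
  theta <- 4 * p$Ne * p$uSite * p$targetSize
  if (theta == 0 || p$sBen == 0) return(0)
  alphaB <- 4 * p$Ne * p$hBen * p$sBen
  alphaD <- 4 * p$Ne * p$hDel * p$sDel
  Ralpha <- alphaB / (alphaD + 1)
  -expm1(-theta * log1p(Ralpha))
}

#' Probability of adaptation from de novo mutation within the selection
#' window
#'
#' Probability that at least one new TSR mutation arising during the
#' `Tgen` selection generations establishes:
#' `P_dn = 1 - exp(-2 Ne uSite targetSize Tgen pi_est)` with `pi_est` the
#' [establishmentProb()] of the beneficial allele.
#'
#' @param params a [sweepParams()] object.
#' @return probability in \[0, 1\].
#' @export
probDeNovo <- function(params) {
  p <- params
  if (p$uSite == 0 || p$Tgen == 0 || p$targetSize == 0) return(0)
  piEst <- establishmentProb(p$sBen, p$hBen, p$Ne)
  -expm1(-2 * p$Ne * p$uSite * p$targetSize * p$Tgen * piEst)
}

#' Total probability of adaptation via a selective sweep
#'
#' Combines the standing-variation and de novo routes assuming
#' independence: `P_total = 1 - (1 - P_sgv)(1 - P_dn)`.
#'
#' @param params a [sweepParams()] object.
#' @return probability in \[0, 1\].
#' @examples
#' # strong selection: adaptation is highly likely
#' probAdaptTotal(sweepParams(Ne = 42000, sBen = 1, sDel = 1e-5))
#' @export
probAdaptTotal <- function(params) {
  ps <- probSGV(params)
  pd <- probDeNovo(params)
  1 - (1 - ps) * (1 - pd)
}

#' Conditional probability that adaptation stems from standing variation
#'
#' `P_sgv / P_total`; errors when `P_total = 0` (the conditioning event
#' has probability zero).
#'
#' @param params a [sweepParams()] object.
#' @return probability in \[0, 1\].
#' @export
fractionSGV <- function(params) {
  pt <- probAdaptTotal(params)
  if (pt == 0) stop("fractionSGV is undefined when P_total = 0")
  probSGV(params) / pt
}

#' Evaluate the sweep probabilities over a parameter grid
#'
#' One row per (Ne, sBen, sDel) combination, with all four probabilities.
#' The default grids span the beneficial coefficients bracketing weak to
#' very strong herbicide selection (0.01..1, log-spaced) and prior
#' deleterious costs 1e-6..1e-2.
#'
#' @param NeList effective population sizes.
#' @param sBenGrid beneficial-coefficient grid.
#' @param sDelGrid deleterious-cost grid.
#' @param params template [sweepParams()] supplying the remaining fields.
#' @return data.frame with columns Ne, s_ben, s_del, P_sgv, P_dn, P_total,
#'   fraction_sgv.
#' @examples
#' tab <- gridEvaluate(NeList = 42000,
#'                     sBenGrid = c(0.01, 0.1, 1),
#'                     sDelGrid = c(1e-5, 1e-3))
#' tab
#' @export
gridEvaluate <- function(NeList = c(42000, 84000),
                         sBenGrid = exp(seq(log(0.01), log(1),
                                            length.out = 25)),
                         sDelGrid = exp(seq(log(1e-6), log(1e-2),
                                            length.out = 25)),
                         params = sweepParams()) {
  stopifnot(length(NeList) > 0, length(sBenGrid) > 0, length(sDelGrid) > 0)
  grid <- expand.grid(Ne = NeList, s_ben = sBenGrid, s_del = sDelGrid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- t(apply(grid, 1L, function(row) {
    p <- sweepParams(Ne = row[["Ne"]], uSite = params$uSite,
                     targetSize = params$targetSize, sBen = row[["s_ben"]],
                     sDel = row[["s_del"]], hBen = params$hBen,
                     hDel = params$hDel, Tgen = params$Tgen)
    ps <- probSGV(p); pd <- probDeNovo(p)
    pt <- 1 - (1 - ps) * (1 - pd)
    c(P_sgv = ps, P_dn = pd, P_total = pt,
      fraction_sgv = if (pt > 0) ps / pt else NA_real_)
  }))
  cbind(grid, as.data.frame(res))
}
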