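#' Watterson's theta per site
#'
#' `theta_W = S / (a_{n-1} * L)` with `a_{n-1} = sum_{i=1}^{n-1} 1/i`. At
#' neutral equilibrium `E[theta_W] = 4 Ne mu` per site.
#'
#' @param S number of segregating sites.
#' @param n number of sequences (>= 2).
#' @param L surveyed length in bp.
#' @return theta per site.
#' @examples
#' wattersonTheta(S = 5, n = 2, L = 1)  # a_1 = 1, so 5
#' @export
wattersonTheta <- function(S, n, L = 1) {
  n <- .assertCount(n, "n", 2L)
  if (L < 1) stop("L must be >= 1")
  if (S < 0) stop("S must be >= 0")
  S / (sum(1 / seq_len(n - 1L)) * L)
}

#' Effective population size from Watterson's theta
#'
#' Diploid estimator `Ne = theta / (4 mu)`. With the blackgrass mean
#' theta_W of 0.0047 and the maize mutation rate 3.0e-8 this gives about
#' 39,167 individuals.
#'
#' @param theta per-site diversity estimate (>= 0).
#' @param mu per-site per-generation mutation rate (> 0), default 3.0e-8.
#' @return effective population size estimate.
#' @examples
#' neFromTheta(0.0047)  # ~ 39167
#' @export
neFromTheta <- function(theta, mu = 3.0e-8) {
  if (mu <= 0) stop("mu must be > 0")
  if (any(theta < 0)) stop("theta must be >= 0")
  theta / (4 * mu)
}

#' Nucleotide diversity (pi)
#'
#' Average number of pairwise differences per site across all sequence
#' pairs. Methods exist for aligned sequence sets
#' ([Biostrings::DNAStringSet]; columns containing characters other than
#' A/C/G/T are excluded from the comparison) and for sparse simulator
#' samples ([HaplotypeSample-class]).
#'
#' @param x sequences or a haplotype sample.
#' @param ... unused.
#' @return pi per site.
#' @export
setGeneric("nucleotideDiversity",
           function(x, ...) standardGeneric("nucleotideDiversity"))

#' @rdname nucleotideDiversity
#' @export
setMethod("nucleotideDiversity", "DNAStringSet", function(x, ...) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 sequences")
  if (length(unique(Biostrings::width(x))) != 1L)
    stop("sequences must be aligned to equal length")
  cm <- Biostrings::consensusMatrix(x)
  cm <- cm[intersect(c("A", "C", "G", "T"), rownames(cm)), , drop = FALSE]
  ok <- colSums(cm) == n
  L <- sum(ok)
  if (L == 0L) stop("no fully resolved columns")
  cm <- cm[, ok, drop = FALSE]
  npairs <- choose(n, 2)
  same <- colSums(choose(cm, 2))
  sum(npairs - same) / npairs / L
})

#' @rdname nucleotideDiversity
#' @export
setMethod("nucleotideDiversity", "HaplotypeSample", function(x, ...) {
  n <- x@n
  # per-site derived-allele counts -> average pairwise difference
  counts <- table(unlist(x@siteList))
  k <- as.numeric(counts)
  sum(k * (n - k)) / choose(n, 2) / x@L
})

#' Segregating sites in a haplotype sample
#'
#' @param x a [HaplotypeSample-class].
#' @return number of sites at which the sample is polymorphic.
#' @export
segregatingSites <- function(x) {
  stopifnot(is(x, "HaplotypeSample"))
  counts <- table(unlist(x@siteList))
  sum(counts > 0 & counts < x@n)
}

#' Chi-squared test for a 2x2 contingency table
#'
#' Thin wrapper around [stats::chisq.test()] with Yates' continuity
#' correction (the default; set `correct = FALSE` for the uncorrected
#' statistic). The corrected form reproduces the shared-versus-private
#' haplotype comparison (TSR 20/42 vs wild type 55/133 -> p = 0.7736).
#'
#' @param table a 2x2 matrix, or a vector of 4 counts (a, b, c, d filled
#'   by row).
#' @param correct apply the continuity correction (default `TRUE`).
#' @return list with `statistic`, `p.value`, `df` and the input `table`.
#' @examples
#' chi2Yates(c(20, 42, 55, 133))$p.value  # 0.7736
#' @export
chi2Yates <- function(table, correct = TRUE) {
  if (is.vector(table) && length(table) == 4L)
    table <- matrix(table, nrow = 2L, byrow = TRUE)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("cell counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-squared test undefined with a zero marginal")
  ht <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter), table = table,
       corrected = correct)
}
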