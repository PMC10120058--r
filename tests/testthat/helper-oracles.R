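# Independent single-locus Wright-Fisher oracle: deterministic selection
# on Hardy-Weinberg genotype frequencies followed by binomial resampling,
# vectorised over trials. Used as an external reference for establishment
# probabilities; it shares no code with the linked engine.
wfFixationOracle <- function(N, s, h, trials, maxGen = 100 * N,
                             p0 = 1 / (2 * N)) {
  p <- rep(p0, trials)
  for (g in seq_len(maxGen)) {
    act <- which(p > 0 & p < 1)
    if (!length(act)) break
    pa <- p[act]
    wAA <- 1 + s
    wAa <- 1 + h * s
    wbar <- pa^2 * wAA + 2 * pa * (1 - pa) * wAa + (1 - pa)^2
    pp <- (pa^2 * wAA + pa * (1 - pa) * wAa) / wbar
    p[act] <- rbinom(length(act), 2 * N, pp) / (2 * N)
  }
  mean(p == 1)
}

# closed-form Yates chi-squared, written from the textbook definition as
# an oracle for the chisq.test-backed implementation
yatesOracle <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- max(0, abs(a * d - b * c) - n / 2)^2 * n
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- num / den
  list(statistic = stat, p.value = pchisq(stat, 1, lower.tail = FALSE))
}

# small locus/DFE fixtures shared across tests
smallTemplate <- function(L = 500L, nTsr = 2L)
  buildTemplate(L, nExons = 2L, codingFraction = 0.5, nTsrSites = nTsr)

neutralDfe <- function() dfeConfig(pNeutralExon = 1)

# expected number of segregating sites at a neutral target:
# Theta * a_{2N-1} with Theta = 4 N mu * targetSize
expectedSegregating <- function(N, mu, targetSize)
  4 * N * mu * targetSize * sum(1 / seq_len(2 * N - 1))
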