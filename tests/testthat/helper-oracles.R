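# Independent oracles used across the suite. These deliberately avoid the
# package's own likelihood arithmetic: genotype-conditional probabilities
# come from dbinom, posteriors from brute-force enumeration.

# P(nA, nB | genotype) via the binomial error model, genotype = A-count
oracleReadLik <- function(nA, nB, g, errate) {
  pB <- switch(as.character(g), "2" = errate, "1" = 0.5, "0" = 1 - errate)
  dbinom(nB, nA + nB, pB)
}

# exact Bayes over the four ordered haplotype-allele configurations
oracleBayesPair <- function(p1, p2, nA, nB, errate) {
  num1 <- 0; num2 <- 0; den <- 0
  for (a1 in c(1, 0)) for (a2 in c(1, 0)) {
    pr <- (if (a1 == 1) p1 else 1 - p1) * (if (a2 == 1) p2 else 1 - p2)
    lik <- oracleReadLik(nA, nB, a1 + a2, errate)
    den <- den + pr * lik
    if (a1 == 1) num1 <- num1 + pr * lik
    if (a2 == 1) num2 <- num2 + pr * lik
  }
  c(p1 = num1 / den, p2 = num2 / den)
}

# HWE genotype posterior by direct enumeration (p = A-allele frequency)
oracleGenoPost <- function(p, nA, nB, errate) {
  pri <- c(AA = p^2, AB = 2 * p * (1 - p), BB = (1 - p)^2)
  lik <- c(oracleReadLik(nA, nB, 2, errate),
           oracleReadLik(nA, nB, 1, errate),
           oracleReadLik(nA, nB, 0, errate))
  j <- pri * lik
  j / sum(j)
}

# literal reimplementation of the pseudo-chip design rules as plain loops
oracleMarkerFilter <- function(geno, pos, targetCount, maxR = 0.9,
                               minMaf = 0.12, minSpacing = 100,
                               gapFill = 500) {
  keep <- integer(0)
  for (j in seq_len(nrow(geno))) {
    if (length(keep) && pos[j] - pos[keep[length(keep)]] < minSpacing) next
    red <- FALSE
    for (k in keep) {
      r <- suppressWarnings(cor(geno[j, ], geno[k, ]))
      if (!is.na(r) && abs(r) > maxR) red <- TRUE
    }
    if (!red) keep <- c(keep, j)
  }
  maf <- pmin(rowMeans(geno) / 2, 1 - rowMeans(geno) / 2)
  elig <- keep[maf[keep] > minMaf]
  elig <- elig[order(-maf[elig], pos[elig])]
  sel <- sort(elig[seq_len(min(targetCount, length(elig)))])
  avail <- setdiff(keep, sel)
  repeat {
    if (length(sel) < 2 || !length(avail)) break
    added <- FALSE
    for (gi in which(diff(pos[sel]) > gapFill)) {
      inside <- avail[pos[avail] > pos[sel[gi]] & pos[avail] < pos[sel[gi + 1]]]
      if (!length(inside)) next
      best <- inside[which.max(maf[inside])]
      sel <- sort(c(sel, best)); avail <- setdiff(avail, best)
      added <- TRUE
      break
    }
    if (!added) break
  }
  sel
}

# small simulated dataset shared by several tests
tinySim <- function(seed = 7, nSeq = 12, nArray = 4, nSites = 200,
                    chipSize = 20, meanDepth = 8, errate = 0.01,
                    includeHd = TRUE, ...) {
  simulateDataset(SimConfig(nSeq = nSeq, nArray = nArray, nSites = nSites,
                            chipSize = chipSize, meanDepth = meanDepth,
                            errate = errate, includeHd = includeHd,
                            nGenerations = 3, nSires = 3, seed = seed, ...))
}
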