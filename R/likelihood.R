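## Per-locus probability arithmetic on allele read counts. All functions are
## vectorized over loci; likelihood triples are (sites x 3) matrices with
## columns lAA, lAB, lBB.

.clamp01 <- function(p, clamp) pmin(pmax(p, clamp), 1 - clamp)

#' Read-count likelihoods given the three genotypes
#'
#' Computes P(nA, nB | AA), P(nA, nB | AB) and P(nA, nB | BB) under the
#' binomial read model: each of the nA + nB reads is drawn from one of the
#' two true alleles with equal probability and is misread with probability
#' \code{errate}. For a true AA genotype the chance of observing a B read
#' is \code{errate}; for AB it is 0.5 regardless of the error rate.
#'
#' The binomial coefficient choose(nA + nB, nA) is shared by all three
#' likelihoods and cancels from every ratio and posterior; it is included
#' by default (\code{coef = TRUE}) and can be dropped without changing any
#' downstream result.
#'
#' @param nA,nB non-negative integer vectors of A and B read counts.
#' @param errate per-read error probability in [0, 0.5).
#' @param coef include the shared binomial coefficient.
#' @return numeric matrix with columns \code{lAA}, \code{lAB}, \code{lBB}.
#' @examples
#' readLikelihoods(4, 0, errate = 0)["lAB"]  # 0.5^4 = 0.0625
#' @export
readLikelihoods <- function(nA, nB, errate, coef = TRUE) {
  if (any(nA < 0) || any(nB < 0))
    stop("read counts must be non-negative")
  if (any(errate < 0) || any(errate >= 0.5))
    stop("'errate' must be in [0, 0.5)")
  n <- length(nA)
  stopifnot(length(nB) == n)
  errate <- rep_len(errate, n)
  tot <- nA + nB
  C <- if (coef) choose(tot, nA) else rep(1, n)
  big <- tot > 30L
  lAA <- (1 - errate)^nA * errate^nB        # 0^0 == 1 covers errate = 0
  lBB <- errate^nA * (1 - errate)^nB
  lAB <- 0.5^tot
  if (any(big)) {
    # log-space evaluation for deep piles to avoid underflow
    lg <- function(k, e) ifelse(k == 0, 0, k * log(e))
    lAA[big] <- exp(lg(nA[big], 1 - errate[big]) + lg(nB[big], errate[big]))
    lBB[big] <- exp(lg(nA[big], errate[big]) + lg(nB[big], 1 - errate[big]))
    lAB[big] <- exp(tot[big] * log(0.5))
  }
  out <- cbind(lAA = C * lAA, lAB = C * lAB, lBB = C * lBB)
  if (n == 1L) out[1L, ] else out
}

.asLikMat <- function(L) {
  if (is.null(dim(L))) matrix(L, nrow = 1L, dimnames = list(NULL, names(L)))
  else L
}

#' Probability of the observed counts given one haplotype allele
#'
#' P(nA, nB | h1 = A) when the other haplotype carries A with probability
#' \code{pOther}: \code{pOther * lAA + (1 - pOther) * lAB}.
#'
#' @param L likelihood triple(s) from \code{\link{readLikelihoods}}.
#' @param pOther probability that the other haplotype carries A.
#' @return numeric vector of conditional observation probabilities.
#' @examples
#' L <- readLikelihoods(2, 0, errate = 0)
#' hapConditional(L, 0.5)  # 0.625
#' @export
hapConditional <- function(L, pOther) {
  L <- .asLikMat(L)
  unname(pOther * L[, "lAA"] + (1 - pOther) * L[, "lAB"])
}

#' Unconditional probability of the observed counts
#'
#' Sums the three genotype-conditional likelihoods weighted by the
#' probabilities that two haplotypes with A-allele probabilities \code{p1}
#' and \code{p2} form each genotype. Substituting the population frequency
#' for both arguments gives the population-level probability used as the
#' denominator of selection ratios.
#'
#' @param L likelihood triple(s) from \code{\link{readLikelihoods}}.
#' @param p1,p2 per-haplotype probabilities of carrying A.
#' @return numeric vector of observation probabilities.
#' @examples
#' L <- readLikelihoods(2, 0, errate = 0)
#' jointUnconditional(L, 0.5, 0.5)  # 0.375
#' @export
jointUnconditional <- function(L, p1, p2) {
  L <- .asLikMat(L)
  unname(p1 * p2 * L[, "lAA"] + (1 - p1) * (1 - p2) * L[, "lBB"] +
           (p1 + p2 - 2 * p1 * p2) * L[, "lAB"])
}

#' Posterior allele probabilities of the two selected haplotypes
#'
#' Bayesian update of the pair (p1, p2) of haplotype A-allele probabilities
#' given the observed read counts. Priors are clamped into
#' \code{[clamp, 1 - clamp]} so that no observation has probability exactly
#' zero; loci with no reads (nA = nB = 0) are missing observations and
#' leave the priors untouched.
#'
#' @param p1,p2 prior probabilities that haplotypes 1 and 2 carry A.
#' @param L likelihood triple(s) from \code{\link{readLikelihoods}}.
#' @param nA,nB the read counts behind \code{L}, used to detect missing
#'   loci; if omitted, no locus is treated as missing.
#' @param clamp prior clamp (default 1e-6).
#' @return list with numeric vectors \code{p1} and \code{p2} of posteriors.
#' @examples
#' L <- readLikelihoods(2, 0, errate = 0)
#' posteriorPairUpdate(0.5, 0.5, L)  # both 0.8333...
#' @export
posteriorPairUpdate <- function(p1, p2, L, nA = NULL, nB = NULL,
                                clamp = 1e-6) {
  L <- .asLikMat(L)
  p1c <- .clamp01(p1, clamp)
  p2c <- .clamp01(p2, clamp)
  den <- jointUnconditional(L, p1c, p2c)
  post1 <- pmin(pmax((p2c * L[, "lAA"] + (1 - p2c) * L[, "lAB"]) * p1c / den,
                     0), 1)
  post2 <- pmin(pmax((p1c * L[, "lAA"] + (1 - p1c) * L[, "lAB"]) * p2c / den,
                     0), 1)
  if (!is.null(nA)) {
    miss <- (nA + nB) == 0L
    post1[miss] <- rep_len(p1, length(post1))[miss]
    post2[miss] <- rep_len(p2, length(post2))[miss]
  }
  list(p1 = unname(post1), p2 = unname(post2))
}

#' Hardy-Weinberg genotype posteriors from read counts
#'
#' Combines the read-count likelihoods with Hardy-Weinberg genotype priors
#' computed from the A-allele frequency \code{p}: P(AA) = p^2,
#' P(AB) = 2p(1-p), P(BB) = (1-p)^2. (Equivalently, with q = 1 - p the
#' frequency of the alternate B allele, the priors are (1-q)^2, 2q(1-q)
#' and q^2.) Loci where all three joint terms vanish are returned as NA
#' (missing-site signal).
#'
#' @param L likelihood triple(s) from \code{\link{readLikelihoods}}.
#' @param p A-allele (reference) frequency per locus, in [0, 1].
#' @return matrix with columns \code{pAA}, \code{pAB}, \code{pBB}, rows
#'   summing to 1 (or NA).
#' @examples
#' genotypePosteriors(readLikelihoods(1, 1, errate = 0), 0.3)  # (0, 1, 0)
#' @export
genotypePosteriors <- function(L, p) {
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
  L <- .asLikMat(L)
  jAA <- p^2 * L[, "lAA"]
  jAB <- 2 * p * (1 - p) * L[, "lAB"]
  jBB <- (1 - p)^2 * L[, "lBB"]
  tot <- jAA + jAB + jBB
  tot[tot == 0] <- NA_real_
  out <- cbind(pAA = jAA / tot, pAB = jAB / tot, pBB = jBB / tot)
  if (nrow(L) == 1L) out[1L, ] else out
}

#' Convert an array genotype to pseudo read counts
#'
#' A called genotype becomes a count pair at the configured pseudo depth:
#' AA (2 copies of A) becomes (depth, 0), BB becomes (0, depth), AB becomes
#' (depth/2, depth/2) and missing becomes (0, 0). Such loci should be
#' evaluated with the array error rate rather than the sequencing error
#' rate (see \linkS4class{ModelConfig}).
#'
#' @param g integer vector of A-allele counts (0, 1, 2) with NA = missing.
#' @param cfg a \linkS4class{ModelConfig} supplying the pseudo depth.
#' @return integer matrix with columns \code{nA}, \code{nB}.
#' @examples
#' countsFromArray(c(2L, 1L, 0L, NA), ModelConfig())
#' @export
countsFromArray <- function(g, cfg = ModelConfig()) {
  stopifnot(all(g %in% c(0L, 1L, 2L) | is.na(g)))
  d <- cfg@arrayPseudoDepth
  half <- d %/% 2L
  nA <- ifelse(is.na(g), 0L, ifelse(g == 2L, d, ifelse(g == 1L, half, 0L)))
  nB <- ifelse(is.na(g), 0L, ifelse(g == 0L, d, ifelse(g == 1L, d - half, 0L)))
  cbind(nA = as.integer(nA), nB = as.integer(nB))
}
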