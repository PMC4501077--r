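## Gene-drop simulator: founder allele frequencies, founder haplotypes with
## linkage disequilibrium, transmission with recombination, Poisson read
## depths with per-read error, and SNP-array subsets.

#' Founder allele-frequency transform
#'
#' Maps a uniform deviate onto an allele frequency with a density
#' concentrated near 0 and 1 (4|p - 0.5|), so that sequence variants have
#' predominantly low minor allele frequencies: \code{p = 0.5 +
#' sign(u - 0.5) * sqrt(|u - 0.5| / 2)}, spanning [0, 1]. With
#' \code{literal = TRUE} the alternative scaled form
#' \code{(0.5 +/- 0.25 sqrt(|u - 0.5|)) / sqrt(0.5)} (range [0.457,
#' 0.957]) is used instead. Chip markers are conventionally given plain
#' uniform frequencies rather than this transform.
#'
#' @param u uniform deviates in [0, 1].
#' @param literal use the alternative scaled form.
#' @return allele frequencies.
#' @examples
#' founderFrequency(c(0, 0.5, 1))  # 0, 0.5, 1
#' @export
founderFrequency <- function(u, literal = FALSE) {
  if (any(u < 0 | u > 1)) stop("'u' must be in [0, 1]")
  if (literal) {
    s <- ifelse(u > 0.5, 1, -1)
    (0.5 + s * 0.25 * sqrt(abs(u - 0.5))) / sqrt(0.5)
  } else {
    0.5 + sign(u - 0.5) * sqrt(abs(u - 0.5) / 2)
  }
}

#' Simulate a discrete-generation pedigree
#'
#' Generations of (nearly) equal size; each non-founder draws its sire
#' from the first \code{nSires} individuals of the previous generation
#' (mimicking heavy sire usage in livestock) and its dam uniformly from
#' the rest of that generation. Birth order is the generation index.
#'
#' @param nInd total number of individuals.
#' @param nGenerations number of discrete generations.
#' @param nSires sires available per generation.
#' @return data.frame with columns \code{id}, \code{sire}, \code{dam},
#'   \code{birth}.
#' @export
simulatePedigree <- function(nInd, nGenerations = 5L, nSires = 10L) {
  sizes <- rep(nInd %/% nGenerations, nGenerations)
  extra <- nInd - sum(sizes)
  if (extra > 0)
    sizes[nGenerations] <- sizes[nGenerations] + extra
  id <- paste0("ind", seq_len(nInd))
  sire <- rep(NA_character_, nInd)
  dam <- rep(NA_character_, nInd)
  birth <- rep(seq_len(nGenerations), sizes)
  offset <- cumsum(c(0, sizes))
  for (g in seq_len(nGenerations)[-1]) {
    prev <- (offset[g - 1] + 1):offset[g]
    cur <- (offset[g] + 1):offset[g + 1]
    sires <- prev[seq_len(min(nSires, length(prev)))]
    for (i in cur) {
      s <- if (length(sires) == 1L) sires else sample(sires, 1L)
      pool <- setdiff(prev, s)
      if (!length(pool)) pool <- prev
      m <- if (length(pool) == 1L) pool else sample(pool, 1L)
      sire[i] <- id[s]
      dam[i] <- id[m]
    }
  }
  data.frame(id = id, sire = sire, dam = dam, birth = birth)
}

#' Generate founder haplotypes with linkage disequilibrium
#'
#' Haplotypes are thresholded latent Gaussian AR(1) processes (a Gaussian
#' copula): the per-site marginal probability of carrying the A allele is
#' exactly \code{p}, and adjacent sites are correlated through the latent
#' autocorrelation \code{rho}.
#'
#' @param nHap number of haplotypes.
#' @param p per-site A-allele frequencies.
#' @param rho latent adjacent-site correlation in [0, 1).
#' @return integer matrix (sites x haplotypes); 1 = A allele, 0 = B.
#' @export
founderHaplotypes <- function(nHap, p, rho = 0.98) {
  nSites <- length(p)
  thr <- stats::qnorm(pmin(pmax(p, 0), 1))
  z <- matrix(NA_real_, nSites, nHap)
  z[1L, ] <- stats::rnorm(nHap)
  if (nSites > 1L) {
    sd <- sqrt(1 - rho^2)
    for (j in 2:nSites)
      z[j, ] <- rho * z[j - 1L, ] + sd * stats::rnorm(nHap)
  }
  h <- (z <= thr) * 1L
  storage.mode(h) <- "integer"
  h
}

#' Drop founder haplotypes through a pedigree with recombination
#'
#' Each transmitted gamete is a crossover mosaic of the parent's two
#' haplotypes: the crossover count is Poisson with mean equal to the map
#' length in Morgans (Haldane, no interference) and crossover positions
#' are uniform along the chromosome.
#'
#' @param ped pedigree data.frame (see \code{\link{simulatePedigree}}).
#' @param founderHaps integer matrix (sites x haplotypes) of founder
#'   haplotypes; if its column count equals twice the number of founders,
#'   haplotypes are assigned to founders in order, otherwise each founder
#'   samples a pair with replacement.
#' @param mapLengthCm genetic map length in centimorgans.
#' @return list with matrices \code{mat} and \code{pat} (sites x
#'   individuals; 1 = A allele): maternal and paternal haplotypes.
#' @export
geneDrop <- function(ped, founderHaps, mapLengthCm = 100) {
  nInd <- nrow(ped)
  nSites <- nrow(founderHaps)
  ord <- orderIndividuals(ped)
  pidx <- .parentIdx(ped)
  mat <- matrix(NA_integer_, nSites, nInd)
  pat <- matrix(NA_integer_, nSites, nInd)
  founders <- which(is.na(pidx$sire) & is.na(pidx$dam))
  nH <- ncol(founderHaps)
  if (nH == 2L * length(founders)) {
    hapOf <- cbind(2L * seq_along(founders) - 1L, 2L * seq_along(founders))
  } else {
    hapOf <- matrix(sample.int(nH, 2L * length(founders), replace = TRUE),
                    ncol = 2L)
  }
  morgans <- mapLengthCm / 100
  gamete <- function(h1, h2) {
    k <- stats::rpois(1L, morgans)
    cur <- sample(1:2, 1L)
    if (k == 0L) return(if (cur == 1L) h1 else h2)
    bp <- sort(ceiling(stats::runif(k) * (nSites - 1L)))
    out <- integer(nSites)
    prev <- 1L
    for (b in c(bp, nSites)) {
      if (prev <= b)
        out[prev:b] <- if (cur == 1L) h1[prev:b] else h2[prev:b]
      cur <- 3L - cur
      prev <- b + 1L
    }
    out
  }
  for (i in ord) {
    s <- pidx$sire[i]; d <- pidx$dam[i]
    if (is.na(s) && is.na(d)) {
      f <- match(i, founders)
      mat[, i] <- founderHaps[, hapOf[f, 1L]]
      pat[, i] <- founderHaps[, hapOf[f, 2L]]
    } else {
      # parents missing from the pedigree get fresh random founder haps
      ph <- function(par) {
        if (is.na(par))
          founderHaps[, sample.int(nH, 2L, replace = TRUE), drop = FALSE]
        else cbind(mat[, par], pat[, par])
      }
      dh <- ph(d); sh <- ph(s)
      mat[, i] <- gamete(dh[, 1L], dh[, 2L])
      pat[, i] <- gamete(sh[, 1L], sh[, 2L])
    }
  }
  list(mat = mat, pat = pat)
}

#' Sample sequencing reads for true genotypes
#'
#' Per entry, total depth is Poisson(\code{meanDepth}); each read picks one
#' of the two true alleles with probability 0.5 and is misread with
#' probability \code{errate}, so the chance of an A read is
#' \code{(g/2)(1 - errate) + (1 - g/2) errate} for a true A-allele count g.
#'
#' @param g matrix (or vector) of true A-allele counts (0, 1, 2).
#' @param meanDepth mean read depth.
#' @param errate per-read error rate.
#' @return list of integer matrices \code{nA}, \code{nB} shaped like
#'   \code{g}.
#' @export
sampleReads <- function(g, meanDepth, errate = 0) {
  depth <- stats::rpois(length(g), meanDepth)
  prA <- (g / 2) * (1 - errate) + (1 - g / 2) * errate
  nA <- stats::rbinom(length(g), depth, as.vector(prA))
  nB <- depth - nA
  shape <- function(v) {
    v <- as.integer(v)
    if (!is.null(dim(g))) dim(v) <- dim(g)
    v
  }
  list(nA = shape(nA), nB = shape(nB))
}

.arrayGenotype <- function(g, errRate) {
  flip <- stats::runif(length(g)) < errRate
  if (any(flip)) {
    idx <- which(flip)
    cur <- g[idx]
    # single-step genotype-swap errors: AA<->AB<->BB
    up <- stats::runif(length(idx)) < 0.5
    newg <- ifelse(cur == 2L, 1L,
                   ifelse(cur == 0L, 1L, ifelse(up, 2L, 0L)))
    g[idx] <- newg
  }
  g
}

#' Simulate a complete read-depth dataset
#'
#' Builds the full study design: pedigree, founder haplotypes with LD,
#' gene drop with recombination, Poisson read counts with per-read error
#' for the sequenced class, and array genotypes (error rate
#' \code{arrayErrate}) at the chip subset for the array class. When
#' \code{includeHd} is set, chip loci of sequenced individuals are
#' overridden with array-derived pseudo counts at depth 32. Sequence
#' variants get the quadratic founder-frequency transform; chip markers
#' get uniform frequencies. The true diplotypes are kept in
#' \code{metadata()} for evaluation.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return A \linkS4class{SeqDepthSet}.
#' @examples
#' sds <- simulateDataset(SimConfig(nSeq = 10, nArray = 5, nSites = 100,
#'                                  chipSize = 10, meanDepth = 4, seed = 1))
#' sds
#' @export
simulateDataset <- function(cfg = SimConfig()) {
  set.seed(cfg@seed)
  nInd <- cfg@nSeq + cfg@nArray + cfg@nNone
  nSites <- cfg@nSites
  ped <- simulatePedigree(nInd, cfg@nGenerations, cfg@nSires)
  chipIdx <- unique(as.integer(round(seq(1, nSites,
                                         length.out = cfg@chipSize))))
  p <- founderFrequency(stats::runif(nSites),
                        literal = cfg@literalFreqTransform)
  p[chipIdx] <- stats::runif(length(chipIdx))
  pidx <- .parentIdx(ped)
  nFounders <- sum(is.na(pidx$sire) & is.na(pidx$dam))
  nH <- if (cfg@nFounderHaplotypes > 0L) cfg@nFounderHaplotypes
        else 2L * nFounders
  fh <- founderHaplotypes(nH, p, cfg@ldRho)
  truth <- geneDrop(ped, fh, cfg@mapLengthCm)
  g <- truth$mat + truth$pat
  ord <- orderIndividuals(ped)
  seqIdx <- ord[seq_len(cfg@nSeq)]
  arrIdx <- if (cfg@nArray > 0L) ord[(nInd - cfg@nArray + 1L):nInd]
            else integer(0)
  nA <- matrix(0L, nSites, nInd)
  nB <- matrix(0L, nSites, nInd)
  arrFlag <- matrix(FALSE, nSites, nInd)
  if (length(seqIdx)) {
    reads <- sampleReads(g[, seqIdx, drop = FALSE], cfg@meanDepth,
                         cfg@errate)
    nA[, seqIdx] <- reads$nA
    nB[, seqIdx] <- reads$nB
  }
  mc <- ModelConfig(errate = cfg@errate, arrayErrate = cfg@arrayErrate)
  if (cfg@includeHd && length(seqIdx) && length(chipIdx)) {
    ag <- .arrayGenotype(g[chipIdx, seqIdx, drop = FALSE], cfg@arrayErrate)
    cnt <- countsFromArray(as.vector(ag), mc)
    nA[chipIdx, seqIdx] <- cnt[, "nA"]
    nB[chipIdx, seqIdx] <- cnt[, "nB"]
    arrFlag[chipIdx, seqIdx] <- TRUE
  }
  if (length(arrIdx) && length(chipIdx)) {
    ag <- .arrayGenotype(g[chipIdx, arrIdx, drop = FALSE], cfg@arrayErrate)
    cnt <- countsFromArray(as.vector(ag), mc)
    nA[chipIdx, arrIdx] <- cnt[, "nA"]
    nB[chipIdx, arrIdx] <- cnt[, "nB"]
    arrFlag[chipIdx, arrIdx] <- TRUE
  }
  ped$dataClass <- ifelse(seq_len(nInd) %in% seqIdx, "seq",
                          ifelse(seq_len(nInd) %in% arrIdx, "array",
                                 "none"))
  siteMap <- DataFrame(pos = seq_len(nSites) * 100L,
                       ref = rep("A", nSites), alt = rep("C", nSites),
                       chip = seq_len(nSites) %in% chipIdx,
                       founderFreq = p)
  SeqDepthSet(nA, nB, siteMap = siteMap, pedigree = ped,
              arrayDerived = arrFlag, truth = truth, simConfig = cfg)
}

#' Greedy SNP-array design filter
#'
#' Reproduces a pseudo-chip design pipeline: walk sites in ascending
#' position, dropping any site whose genotypes correlate more strongly
#' than \code{maxR} (absolute) with an already-kept site and any site
#' closer than \code{minSpacing} bp to the last kept one; rank the
#' survivors by minor allele frequency, keeping those above \code{minMaf}
#' up to \code{targetCount}; finally insert the best-MAF available
#' survivors into any residual inter-marker gap larger than \code{gapFill}
#' bp.
#'
#' @param geno genotype matrix (sites x individuals) of A-allele counts.
#' @param pos per-site bp positions, sorted ascending.
#' @param targetCount number of markers wanted before gap filling.
#' @param maxR correlation-pruning threshold.
#' @param minMaf minimum minor allele frequency.
#' @param minSpacing minimum spacing in bp.
#' @param gapFill maximum tolerated gap in bp.
#' @return sorted integer vector of selected site indices.
#' @export
selectArrayMarkers <- function(geno, pos, targetCount, maxR = 0.90,
                               minMaf = 0.12, minSpacing = 100,
                               gapFill = 500) {
  if (is.unsorted(pos)) stop("'pos' must be sorted ascending")
  nSites <- nrow(geno)
  keep <- integer(0)
  lastPos <- -Inf
  for (j in seq_len(nSites)) {
    if (pos[j] - lastPos < minSpacing) next
    redundant <- FALSE
    for (k in keep) {
      r <- suppressWarnings(stats::cor(geno[j, ], geno[k, ]))
      if (!is.na(r) && abs(r) > maxR) { redundant <- TRUE; break }
    }
    if (redundant) next
    keep <- c(keep, j)
    lastPos <- pos[j]
  }
  maf <- pmin(rowMeans(geno) / 2, 1 - rowMeans(geno) / 2)
  eligible <- keep[maf[keep] > minMaf]
  eligible <- eligible[order(-maf[eligible], pos[eligible])]
  sel <- sort(eligible[seq_len(min(targetCount, length(eligible)))])
  avail <- setdiff(keep, sel)
  repeat {
    if (length(sel) < 2L || !length(avail)) break
    gaps <- which(diff(pos[sel]) > gapFill)
    added <- FALSE
    for (gi in gaps) {
      inside <- avail[pos[avail] > pos[sel[gi]] &
                        pos[avail] < pos[sel[gi + 1L]]]
      if (!length(inside)) next
      best <- inside[which.max(maf[inside])]
      sel <- sort(c(sel, best))
      avail <- setdiff(avail, best)
      added <- TRUE
      break
    }
    if (!added) break
  }
  sel
}
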