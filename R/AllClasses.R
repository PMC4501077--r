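#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Model configuration for read-count likelihoods
#'
#' Holds the per-read error rate and the conventions used to convert array
#' genotypes into pseudo read counts. Array-derived loci are treated as very
#' deep, very accurate "reads": a called genotype becomes a count pair at
#' depth \code{arrayPseudoDepth} and is evaluated with \code{arrayErrate}
#' instead of the sequencing error rate.
#'
#' @slot errate per-read sequencing error probability, in [0, 0.5).
#' @slot arrayErrate error rate assumed for array-derived pseudo counts.
#' @slot arrayPseudoDepth read depth assigned to array-derived loci.
#' @slot clamp haplotype probabilities are kept in
#'   \code{[clamp, 1 - clamp]} inside all Bayesian updates so that no
#'   observation is ever treated as strictly impossible.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    errate = "numeric",
    arrayErrate = "numeric",
    arrayPseudoDepth = "integer",
    clamp = "numeric"
  ),
  prototype(
    errate = 0.01,
    arrayErrate = 0.001,
    arrayPseudoDepth = 32L,
    clamp = 1e-6
  )
)

setValidity("ModelConfig", function(object) {
  msg <- NULL
  if (length(object@errate) != 1L || is.na(object@errate) ||
      object@errate < 0 || object@errate >= 0.5)
    msg <- c(msg, "'errate' must be a single value in [0, 0.5)")
  if (object@arrayErrate < 0 || object@arrayErrate >= 0.5)
    msg <- c(msg, "'arrayErrate' must be in [0, 0.5)")
  if (object@arrayPseudoDepth < 1L)
    msg <- c(msg, "'arrayPseudoDepth' must be >= 1")
  if (object@clamp <= 0 || object@clamp >= 0.5)
    msg <- c(msg, "'clamp' must be in (0, 0.5)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ModelConfig
#'
#' @param errate per-read sequencing error probability in [0, 0.5).
#' @param arrayErrate error rate assumed for array-derived pseudo counts.
#' @param arrayPseudoDepth pseudo read depth assigned to array loci.
#' @param clamp probability clamp applied inside Bayesian updates.
#' @return A \linkS4class{ModelConfig} object.
#' @examples
#' ModelConfig(errate = 0.01)
#' @export
ModelConfig <- function(errate = 0.01, arrayErrate = 0.001,
                        arrayPseudoDepth = 32L, clamp = 1e-6) {
  new("ModelConfig", errate = as.numeric(errate),
      arrayErrate = as.numeric(arrayErrate),
      arrayPseudoDepth = as.integer(arrayPseudoDepth),
      clamp = as.numeric(clamp))
}

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig: errate =", object@errate,
      "| array errate =", object@arrayErrate,
      "| array pseudo-depth =", object@arrayPseudoDepth, "\n")
})

#' Per-segment haplotype library
#'
#' A library of haplotype probability tracks for one chromosome segment
#' (window of variant indices, 0-based half-open). Each track stores, per
#' site, the probability that the haplotype carries the reference A allele;
#' tracks are kept sorted by descending usage count (number of
#' individual-haplotype assignments pointing at them) between population
#' passes.
#'
#' @slot start,end segment bounds in variant indices, 0-based half-open.
#' @slot probs numeric matrix, sites x tracks, of P(h = A).
#' @slot usage integer vector of per-track usage counts.
#' @slot freqs numeric vector of per-site A-allele frequencies.
#' @exportClass HaplotypeLibrary
setClass("HaplotypeLibrary",
  representation(
    start = "integer",
    end = "integer",
    probs = "matrix",
    usage = "integer",
    freqs = "numeric"
  )
)

setValidity("HaplotypeLibrary", function(object) {
  msg <- NULL
  len <- object@end - object@start
  if (len < 1L) msg <- c(msg, "'end' must exceed 'start'")
  if (nrow(object@probs) != len)
    msg <- c(msg, "nrow(probs) must equal end - start")
  if (ncol(object@probs) != length(object@usage))
    msg <- c(msg, "ncol(probs) must equal length(usage)")
  if (length(object@freqs) != len)
    msg <- c(msg, "length(freqs) must equal end - start")
  if (length(object@usage) && any(object@usage < 0L))
    msg <- c(msg, "usage counts must be non-negative")
  if (length(object@probs) &&
      (anyNA(object@probs) || any(object@probs < 0 | object@probs > 1)))
    msg <- c(msg, "track probabilities must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Construct an empty HaplotypeLibrary
#'
#' @param start,end segment bounds in variant indices (0-based half-open).
#' @param freqs per-site A-allele frequencies used as priors for newly
#'   admitted haplotypes.
#' @return A \linkS4class{HaplotypeLibrary} with zero tracks.
#' @examples
#' lib <- HaplotypeLibrary(0, 5, freqs = rep(0.5, 5))
#' nTracks(lib)
#' @export
HaplotypeLibrary <- function(start, end, freqs) {
  start <- as.integer(start); end <- as.integer(end)
  new("HaplotypeLibrary", start = start, end = end,
      probs = matrix(numeric(0), nrow = end - start, ncol = 0),
      usage = integer(0), freqs = as.numeric(freqs))
}

setMethod("show", "HaplotypeLibrary", function(object) {
  cat("HaplotypeLibrary: segment [", object@start, ", ", object@end,
      "), ", ncol(object@probs), " track(s), total usage ",
      sum(object@usage), "\n", sep = "")
})

#' Segment iteration schedule
#'
#' Window lengths form a geometric ladder from \code{maxLen} down to
#' \code{minLen} (ratio 4), each visited \code{itersPerStep} times. At each
#' length the chromosome is tiled by non-overlapping half-open windows; a
#' short terminal remainder is merged into the preceding window.
#'
#' @slot minLen,maxLen minimum and maximum window length in variants.
#' @slot itersPerStep population passes per window length.
#' @slot nSites number of variants on the chromosome.
#' @slot lengths the realized ladder of window lengths.
#' @slot windows list (one element per length) of integer matrices with
#'   columns \code{start}, \code{end} (0-based half-open).
#' @exportClass SegmentPlan
setClass("SegmentPlan",
  representation(
    minLen = "integer",
    maxLen = "integer",
    itersPerStep = "integer",
    nSites = "integer",
    lengths = "integer",
    windows = "list"
  )
)

setValidity("SegmentPlan", function(object) {
  msg <- NULL
  if (object@minLen < 2L) msg <- c(msg, "'minLen' must be >= 2")
  if (object@maxLen < object@minLen) msg <- c(msg, "'maxLen' must be >= 'minLen'")
  if (object@itersPerStep < 1L) msg <- c(msg, "'itersPerStep' must be >= 1")
  for (w in object@windows) {
    if (nrow(w) && (w[1L, 1L] != 0L || w[nrow(w), 2L] != object@nSites ||
        (nrow(w) > 1L && any(w[-1L, 1L] != w[-nrow(w), 2L]))))
      msg <- c(msg, "windows must tile [0, nSites) without gaps or overlap")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a SegmentPlan
#'
#' @param nSites number of variants on the chromosome.
#' @param minLen minimum window length in variants (default 100).
#' @param maxLen maximum window length in variants (default 20000).
#' @param itersPerStep population passes per window length (default 6).
#' @return A \linkS4class{SegmentPlan}.
#' @examples
#' SegmentPlan(5000)
#' @export
SegmentPlan <- function(nSites, minLen = 100L, maxLen = 20000L,
                        itersPerStep = 6L) {
  nSites <- as.integer(nSites)
  minLen <- as.integer(min(minLen, nSites))
  maxLen <- as.integer(min(maxLen, nSites))
  if (minLen < 2L) minLen <- 2L
  if (maxLen < minLen) maxLen <- minLen
  lens <- maxLen
  while (lens[length(lens)] %/% 4L > minLen)
    lens <- c(lens, lens[length(lens)] %/% 4L)
  if (lens[length(lens)] > minLen) lens <- c(lens, minLen)
  windows <- lapply(lens, function(len) {
    starts <- seq.int(0L, nSites - 1L, by = len)
    ends <- pmin(starts + len, nSites)
    # merge a short terminal remainder into the last full window
    n <- length(starts)
    if (n > 1L && (ends[n] - starts[n]) < len %/% 2L) {
      ends[n - 1L] <- ends[n]
      starts <- starts[-n]; ends <- ends[-n]
    }
    cbind(start = as.integer(starts), end = as.integer(ends))
  })
  new("SegmentPlan", minLen = minLen, maxLen = maxLen,
      itersPerStep = as.integer(itersPerStep), nSites = nSites,
      lengths = as.integer(lens), windows = windows)
}

setMethod("show", "SegmentPlan", function(object) {
  cat("SegmentPlan:", object@nSites, "sites; window ladder",
      paste(object@lengths, collapse = " -> "),
      "with", object@itersPerStep, "pass(es) per length\n")
})

#' Simulation configuration
#'
#' Describes a synthetic pedigreed population with true diplotypes, Poisson
#' read depths and optional SNP-array subsets. Defaults emulate one
#' chromosome of a livestock-style population at desk scale: 20,000
#' variants on a 100 cM map, a chip covering 2\% of sites, Poisson read
#' depths with per-read error, and array genotypes with error 0.001.
#'
#' @slot nSeq number of sequenced individuals (the oldest ones).
#' @slot nArray number of array-only individuals (the youngest ones).
#' @slot nNone number of pedigree members with no observations at all
#'   (unsequenced, ungenotyped ancestors and relatives linking the rest).
#' @slot nSites number of biallelic variant sites.
#' @slot chipSize number of sites on the SNP array subset.
#' @slot meanDepth mean Poisson read depth for sequenced individuals.
#' @slot errate per-read sequencing error rate.
#' @slot includeHd if TRUE, chip loci of sequenced individuals are overridden
#'   with array-derived pseudo counts at depth 32.
#' @slot arrayErrate genotype error rate of simulated array calls.
#' @slot mapLengthCm genetic map length in centimorgans.
#' @slot nGenerations,nSires pedigree structure: discrete generations, with
#'   each non-founder's sire drawn from the first \code{nSires} of the
#'   previous generation.
#' @slot nFounderHaplotypes size of the founder haplotype pool (0 means two
#'   distinct haplotypes per founder).
#' @slot ldRho adjacent-site correlation of the Gaussian copula generating
#'   founder haplotypes with linkage disequilibrium.
#' @slot literalFreqTransform use the literal printed form of the
#'   founder-frequency transform (see \code{\link{founderFrequency}}).
#' @slot seed RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nSeq = "integer", nArray = "integer", nNone = "integer",
    nSites = "integer",
    chipSize = "integer", meanDepth = "numeric", errate = "numeric",
    includeHd = "logical", arrayErrate = "numeric", mapLengthCm = "numeric",
    nGenerations = "integer", nSires = "integer",
    nFounderHaplotypes = "integer", ldRho = "numeric",
    literalFreqTransform = "logical", seed = "integer"
  ),
  prototype(
    nSeq = 250L, nArray = 250L, nNone = 0L, nSites = 20000L, chipSize = 400L,
    meanDepth = 8, errate = 0.01, includeHd = TRUE, arrayErrate = 0.001,
    mapLengthCm = 100, nGenerations = 5L, nSires = 10L,
    nFounderHaplotypes = 0L, ldRho = 0.98,
    literalFreqTransform = FALSE, seed = 1L
  )
)

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (object@nSeq + object@nArray + object@nNone < 1L)
    msg <- c(msg, "population is empty")
  if (object@nSites < 2L) msg <- c(msg, "'nSites' must be >= 2")
  if (object@chipSize > object@nSites)
    msg <- c(msg, "'chipSize' cannot exceed 'nSites'")
  if (object@meanDepth < 0) msg <- c(msg, "'meanDepth' must be >= 0")
  if (object@errate < 0 || object@errate >= 0.5)
    msg <- c(msg, "'errate' must be in [0, 0.5)")
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "'ldRho' must be in [0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SimConfig
#'
#' @param nSeq,nArray,nNone,nSites,chipSize,meanDepth,errate,includeHd
#'   see \linkS4class{SimConfig}.
#' @param arrayErrate see \linkS4class{SimConfig}.
#' @param mapLengthCm,nGenerations,nSires,nFounderHaplotypes,ldRho
#'   see \linkS4class{SimConfig}.
#' @param literalFreqTransform,seed see \linkS4class{SimConfig}.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' SimConfig(nSeq = 20, nArray = 0, nSites = 200, chipSize = 20, seed = 7)
#' @export
SimConfig <- function(nSeq = 250L, nArray = 250L, nNone = 0L,
                      nSites = 20000L,
                      chipSize = 400L, meanDepth = 8, errate = 0.01,
                      includeHd = TRUE, arrayErrate = 0.001,
                      mapLengthCm = 100, nGenerations = 5L, nSires = 10L,
                      nFounderHaplotypes = 0L, ldRho = 0.98,
                      literalFreqTransform = FALSE, seed = 1L) {
  new("SimConfig",
      nSeq = as.integer(nSeq), nArray = as.integer(nArray),
      nNone = as.integer(nNone),
      nSites = as.integer(nSites), chipSize = as.integer(chipSize),
      meanDepth = as.numeric(meanDepth), errate = as.numeric(errate),
      includeHd = as.logical(includeHd), arrayErrate = as.numeric(arrayErrate),
      mapLengthCm = as.numeric(mapLengthCm),
      nGenerations = as.integer(nGenerations), nSires = as.integer(nSires),
      nFounderHaplotypes = as.integer(nFounderHaplotypes),
      ldRho = as.numeric(ldRho),
      literalFreqTransform = as.logical(literalFreqTransform),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSeq, "sequenced +", object@nArray,
      "array-only +", object@nNone, "data-free individuals;",
      object@nSites, "sites (chip",
      object@chipSize, ");", object@meanDepth, "x depth, errate",
      object@errate, "; HD embedded:", object@includeHd, "\n")
})

#' Read-depth dataset container
#'
#' A \linkS4class{SummarizedExperiment} with sites as rows and individuals
#' as columns. Assays: \code{nA} and \code{nB} (integer counts of reads
#' supporting the reference A and alternate B alleles; a (0,0) pair means
#' the site is missing for that individual) and \code{arrayDerived}
#' (logical, TRUE where the counts are pseudo counts converted from an
#' array genotype). \code{rowData} carries the site map (position, ref,
#' alt, chip membership); \code{colData} carries the pedigree (sire, dam,
#' birth order, data class). Simulated datasets additionally keep the true
#' diplotypes and the \linkS4class{SimConfig} in \code{metadata()}.
#'
#' @exportClass SeqDepthSet
setClass("SeqDepthSet", contains = "SummarizedExperiment")

setValidity("SeqDepthSet", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("nA", "nB") %in% an))
    msg <- c(msg, "assays 'nA' and 'nB' are required")
  else {
    nA <- SummarizedExperiment::assay(object, "nA")
    nB <- SummarizedExperiment::assay(object, "nB")
    if (anyNA(nA) || anyNA(nB) || any(nA < 0L) || any(nB < 0L))
      msg <- c(msg, "read counts must be non-negative and non-missing")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a SeqDepthSet
#'
#' @param nA,nB integer matrices (sites x individuals) of reads supporting
#'   the A (reference) and B (alternate) alleles.
#' @param siteMap data.frame/DataFrame of per-site columns (e.g. pos, ref,
#'   alt, chip); defaults to a minimal map.
#' @param pedigree data.frame with columns \code{id}, \code{sire},
#'   \code{dam}, \code{birth} (NA for unknown parents); defaults to an
#'   unrelated population.
#' @param arrayDerived logical matrix marking array-derived pseudo counts.
#' @param truth optional list with matrices \code{mat} and \code{pat}
#'   (1 = A allele) of true diplotypes.
#' @param simConfig optional \linkS4class{SimConfig} that generated the data.
#' @return A \linkS4class{SeqDepthSet}.
#' @examples
#' nA <- matrix(c(2L, 0L, 1L, 3L), 2)
#' nB <- matrix(c(0L, 2L, 1L, 0L), 2)
#' SeqDepthSet(nA, nB)
#' @export
SeqDepthSet <- function(nA, nB, siteMap = NULL, pedigree = NULL,
                        arrayDerived = NULL, truth = NULL, simConfig = NULL) {
  nA <- as.matrix(nA); storage.mode(nA) <- "integer"
  nB <- as.matrix(nB); storage.mode(nB) <- "integer"
  stopifnot(identical(dim(nA), dim(nB)))
  if (is.null(arrayDerived))
    arrayDerived <- matrix(FALSE, nrow(nA), ncol(nA))
  if (is.null(siteMap))
    siteMap <- DataFrame(pos = seq_len(nrow(nA)) * 100L,
                         ref = rep("A", nrow(nA)), alt = rep("C", nrow(nA)),
                         chip = rep(FALSE, nrow(nA)))
  if (is.null(pedigree))
    pedigree <- data.frame(id = paste0("ind", seq_len(ncol(nA))),
                           sire = NA_character_, dam = NA_character_,
                           birth = seq_len(ncol(nA)))
  cd <- DataFrame(sire = pedigree$sire, dam = pedigree$dam,
                  birth = pedigree$birth,
                  dataClass = if (!is.null(pedigree$dataClass))
                    pedigree$dataClass else rep("seq", nrow(pedigree)),
                  row.names = pedigree$id)
  colnames(nA) <- colnames(nB) <- colnames(arrayDerived) <- pedigree$id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(nA = nA, nB = nB, arrayDerived = arrayDerived),
    rowData = siteMap, colData = cd)
  md <- list()
  if (!is.null(truth)) md$truth <- truth
  if (!is.null(simConfig)) md$simConfig <- simConfig
  metadata(se) <- md
  new("SeqDepthSet", se)
}

#' Genotype call set
#'
#' A \linkS4class{SummarizedExperiment} (sites x individuals) produced by
#' \code{\link{callGenotypes}}. Assays: \code{genotype} (integer count of
#' reference A alleles, 0/1/2, NA = missing), \code{dosage} (posterior
#' expected A-allele count, in [0, 2]) and the genotype posterior triple
#' \code{pAA}, \code{pAB}, \code{pBB}. The final haplotype libraries and
#' assignments are kept in \code{metadata()}.
#'
#' @exportClass GenotypeCalls
setClass("GenotypeCalls", contains = "SummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  need <- c("genotype", "dosage", "pAA", "pAB", "pBB")
  if (!all(need %in% an))
    return(paste("assays", paste(setdiff(need, an), collapse = ", "),
                 "are required"))
  ds <- SummarizedExperiment::assay(object, "dosage")
  if (any(ds < -1e-9 | ds > 2 + 1e-9, na.rm = TRUE))
    return("dosage must lie in [0, 2]")
  TRUE
})

setMethod("show", "SeqDepthSet", function(object) {
  cat("SeqDepthSet:", nrow(object), "sites x", ncol(object), "individuals;",
      sum(SummarizedExperiment::assay(object, "arrayDerived")),
      "array-derived entries\n")
  classes <- table(SummarizedExperiment::colData(object)$dataClass)
  cat("  data classes:",
      paste(names(classes), classes, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "GenotypeCalls", function(object) {
  g <- SummarizedExperiment::assay(object, "genotype")
  cat("GenotypeCalls:", nrow(object), "sites x", ncol(object),
      "individuals;", sum(is.na(g)), "missing call(s)\n")
})
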