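test_that("individuals are processed oldest to youngest", {
  ped <- data.frame(id = c("kid", "founder"), sire = c("founder", NA),
                    dam = NA, birth = c(2, 1))
  expect_identical(orderIndividuals(ped), c(2L, 1L))

  # equal birth keys: the parent still precedes the child
  ped <- data.frame(id = c("kid", "pa"), sire = c("pa", NA),
                    dam = NA, birth = c(1, 1))
  expect_identical(orderIndividuals(ped), c(2L, 1L))

  # cycle detection names the individuals
  ped <- data.frame(id = c("A", "B"), sire = c("B", "A"), dam = NA,
                    birth = 1:2)
  expect_error(orderIndividuals(ped), "cycle")
})

test_that("candidate order leads with parental then grandparental tracks", {
  # individual 3 has parents 1 and 2; grandparent 4 is dam of 1
  sire <- c(NA, NA, 1L, NA)
  dam <- c(4L, NA, 2L, NA)
  h1 <- c(3L, 5L, NA, 7L)
  h2 <- c(4L, 6L, NA, 7L)
  ord <- candidateOrder(3L, h1, h2, sire, dam, nTracks = 8L)
  expect_identical(ord[1:4], c(3L, 4L, 5L, 6L))   # sire pair, dam pair
  expect_identical(ord[5], 7L)                    # grandparent, deduplicated
  expect_identical(sort(ord), 1:8)

  # no pedigree: pure frequency order
  expect_identical(candidateOrder(2L, h1, h2, rep(NA_integer_, 4),
                                  rep(NA_integer_, 4), 4L), 1:4)
})

test_that("processing an individual updates the selected tracks", {
  cfg <- ModelConfig(errate = 0.01)
  # no observed sites: tracks unchanged, two most frequent assigned
  lib <- HaplotypeLibrary(0, 4, freqs = rep(0.5, 4))
  lib <- admitHaplotype(lib)$library
  lib <- admitHaplotype(lib)$library
  lib@usage <- c(1L, 3L)
  res <- processIndividual(lib, rep(0L, 4), rep(0L, 4), cfg)
  expect_identical(c(res$h1, res$h2), c(2L, 1L))
  expect_equal(trackProbs(res$library), trackProbs(lib))

  # singleton with strong homozygous reads at one site, empty library:
  # two admitted tracks saturate at that site
  lib <- HaplotypeLibrary(0, 3, freqs = rep(0.5, 3))
  res <- processIndividual(lib, c(8L, 0L, 0L), c(0L, 0L, 0L), cfg)
  expect_identical(nTracks(res$library), 2L)
  expect_gt(trackProbs(res$library)[1, res$h1], 0.99)
  expect_gt(trackProbs(res$library)[1, res$h2], 0.99)

  # a second identical homozygous individual reuses the same tracks
  res2 <- processIndividual(res$library, c(8L, 0L, 0L), c(0L, 0L, 0L), cfg)
  expect_identical(nTracks(res2$library), 2L)
  expect_identical(sum(usageCounts(res2$library)), 4L)
})

test_that("usage counts total twice the number of assigned individuals", {
  sim <- tinySim(seed = 21)
  calls <- runPipeline(sim, SegmentPlan(200, minLen = 50, maxLen = 200,
                                        itersPerStep = 2))
  md <- S4Vectors::metadata(calls)
  for (w in seq_along(md$libraries)) {
    expect_identical(sum(usageCounts(md$libraries[[w]])), 2L * ncol(sim))
    expect_false(is.unsorted(rev(usageCounts(md$libraries[[w]]))))
    pr <- trackProbs(md$libraries[[w]])
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("the pipeline is deterministic", {
  sim <- tinySim(seed = 31)
  plan <- SegmentPlan(200, minLen = 50, maxLen = 200, itersPerStep = 2)
  c1 <- runPipeline(sim, plan)
  c2 <- runPipeline(sim, plan)
  expect_identical(genotypeMatrix(c1), genotypeMatrix(c2))
  expect_identical(dosageMatrix(c1), dosageMatrix(c2))
})

test_that("high-depth error-free calls equal raw majority genotypes", {
  sim <- tinySim(seed = 13, nSeq = 6, nArray = 0, nSites = 120,
                 chipSize = 10, meanDepth = 16, errate = 0,
                 includeHd = FALSE)
  calls <- runPipeline(sim, SegmentPlan(120, minLen = 40, maxLen = 120,
                                        itersPerStep = 2),
                       ModelConfig(errate = 0))
  g <- genotypeMatrix(calls)
  nA <- depthA(sim); nB <- depthB(sim)
  covered <- nA > 0 & nB > 0           # both alleles seen: certain het
  expect_true(all(g[covered] == 1L))
  # error-free reads can never contradict the truth
  tr <- trueGenotypes(sim)
  expect_true(all(nB[tr == 2L] == 0L))
  expect_gt(percentCorrect(g, tr), 99)
})

test_that("founder haplotypes are recovered from shared segments", {
  # 4 founder haplotypes, no recombination, 8x depth, 1% error
  sim <- simulateDataset(SimConfig(nSeq = 24, nArray = 0, nSites = 150,
                                   chipSize = 2, meanDepth = 8,
                                   errate = 0.01, includeHd = FALSE,
                                   nGenerations = 2, nSires = 4,
                                   nFounderHaplotypes = 4, mapLengthCm = 0,
                                   seed = 8))
  calls <- runPipeline(sim, SegmentPlan(150, minLen = 150, maxLen = 150,
                                        itersPerStep = 4),
                       ModelConfig(errate = 0.01))
  md <- S4Vectors::metadata(calls)
  lib <- md$libraries[[1]]
  truth <- S4Vectors::metadata(sim)$truth
  hapPool <- unique(cbind(truth$mat, truth$pat), MARGIN = 2)
  topTracks <- which(usageCounts(lib) >= 4L)
  agree <- vapply(topTracks, function(t) {
    tr <- round(trackProbs(lib)[, t])
    max(vapply(seq_len(ncol(hapPool)),
               function(h) mean(tr == hapPool[, h]), numeric(1)))
  }, numeric(1))
  expect_true(all(agree >= 0.99))
})

test_that("array-only individuals gain from sequenced relatives", {
  # same array individuals scored with and without the sequenced
  # reference in the population
  cfgWith <- SimConfig(nSeq = 30, nArray = 10, nSites = 400, chipSize = 40,
                       meanDepth = 8, errate = 0.01, includeHd = FALSE,
                       nGenerations = 4, nSires = 4, seed = 77)
  sim <- simulateDataset(cfgWith)
  plan <- SegmentPlan(400, minLen = 100, maxLen = 400, itersPerStep = 3)
  mc <- ModelConfig(errate = 0.01)
  callsWith <- runPipeline(sim, plan, mc)
  arrIdx <- which(pedigree(sim)$dataClass == "array")
  alone <- sim[, arrIdx]
  callsAlone <- runPipeline(as(alone, "SeqDepthSet"), plan, mc)
  truth <- trueGenotypes(sim)
  tot <- rowSums(depthA(sim)) + rowSums(depthB(sim))
  freqs <- ifelse(tot > 0, rowSums(depthA(sim)) / tot, 0.5)
  rWith <- centeredCorrelation(dosageMatrix(callsWith)[, arrIdx],
                               truth[, arrIdx], freqs)
  rAlone <- centeredCorrelation(dosageMatrix(callsAlone),
                                truth[, arrIdx], freqs)
  expect_gt(rWith, rAlone)
})

test_that("an exported library reruns incrementally with identical calls", {
  sim <- tinySim(seed = 55, nSeq = 10, nArray = 0, nSites = 150,
                 chipSize = 15, meanDepth = 8)
  plan <- SegmentPlan(150, minLen = 50, maxLen = 150, itersPerStep = 2)
  calls <- runPipeline(sim, plan)
  md <- S4Vectors::metadata(calls)

  # pretend one individual is new: select against the frozen library
  aug <- augmentPipeline(sim, md$libraries, md$assignments)
  expect_identical(genotypeMatrix(aug), genotypeMatrix(calls))

  old <- colnames(sim)[1:9]
  asnOld <- list(h1 = md$assignments$h1[, old, drop = FALSE],
                 h2 = md$assignments$h2[, old, drop = FALSE])
  aug <- augmentPipeline(sim, md$libraries, asnOld)
  expect_identical(genotypeMatrix(aug)[, old], genotypeMatrix(calls)[, old])
  newId <- setdiff(colnames(sim), old)
  expect_false(anyNA(genotypeMatrix(aug)[, newId]))

  # the library file itself round-trips into the same selection machinery
  path <- tempfile()
  exportLibrary(md$libraries, path)
  libs2 <- importLibrary(path)
  expect_length(libs2, length(md$libraries))
})

test_that("genotype calls combine haplotype priors with read likelihoods", {
  lib <- HaplotypeLibrary(0, 3, freqs = rep(0.5, 3))
  lib <- admitHaplotype(lib, prior = c(1, 1, 0.5))$library
  lib <- admitHaplotype(lib, prior = c(1, 0, 0.5))$library
  lib@usage <- c(1L, 1L)
  x <- SeqDepthSet(matrix(c(0L, 0L, 1L), 3), matrix(0L, 3, 1))
  asn <- list(h1 = matrix(1L, 1, 1), h2 = matrix(2L, 1, 1))
  calls <- callGenotypes(x, list(lib), asn, ModelConfig(errate = 0))
  g <- genotypeMatrix(calls); d <- dosageMatrix(calls)
  expect_identical(unname(g[1, 1]), 2L)             # h1 = h2 = A, no reads -> AA
  expect_equal(unname(d[1, 1]), 2, tolerance = 1e-2)
  expect_identical(unname(g[2, 1]), 1L)             # opposite haplotypes -> AB
  expect_equal(unname(d[2, 1]), 1, tolerance = 1e-2)
  # uninformative pair, one A read at p = 0.5: dosage 1.5
  expect_equal(unname(d[3, 1]), 1.5, tolerance = 1e-9)
  # dosage identity 2 pAA + pAB
  pAA <- SummarizedExperiment::assay(calls, "pAA")
  pAB <- SummarizedExperiment::assay(calls, "pAB")
  expect_equal(d, 2 * pAA + pAB, tolerance = 1e-9)
})

test_that("exported genotype probabilities follow the HWE posterior", {
  x <- SeqDepthSet(matrix(c(1L, 1L, 0L), 3), matrix(c(1L, 0L, 0L), 3))
  path <- tempfile()
  exportGenotypeProbabilities(x, path, ModelConfig(errate = 0),
                              freqs = rep(0.5, 3))
  gp <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(gp$pAB[1], 1)                       # both alleles seen
  expect_equal(unlist(gp[2, 3:5]), c(pAA = 0.5, pAB = 0.5, pBB = 0),
               tolerance = 1e-6)
  expect_equal(unlist(gp[3, 3:5]), c(pAA = 0.25, pAB = 0.5, pBB = 0.25),
               tolerance = 1e-6)                   # missing -> HWE priors
  expect_equal(rowSums(gp[, 3:5]), rep(1, 3), tolerance = 1e-6)
})
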