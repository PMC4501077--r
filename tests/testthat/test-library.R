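mkLib <- function(freqs, tracks = list(), usage = NULL) {
  lib <- HaplotypeLibrary(0, length(freqs), freqs = freqs)
  for (t in tracks) lib <- admitHaplotype(lib, prior = t)$library
  if (!is.null(usage)) lib@usage <- as.integer(usage)
  lib
}

test_that("joint likelihood ratio matches hand-computed values", {
  cfg0 <- ModelConfig(errate = 0)
  # single observed locus, candidate carries A for sure, counts (2,0)
  lib <- mkLib(0.5, tracks = list(1))
  r <- jointLikelihoodRatio(lib, 1, nA = 2L, nB = 0L, cfg = cfg0)
  expect_equal(r$ratio, 0.625 / 0.375, tolerance = 1e-4)
  expect_false(r$discarded)
  expect_equal(r$threshold, 1)

  # track identical to the population frequencies: ratio exactly 1
  lib <- mkLib(c(0.2, 0.7, 0.4), tracks = list(c(0.2, 0.7, 0.4)))
  r <- jointLikelihoodRatio(lib, 1, nA = c(1L, 2L, 0L), nB = c(1L, 0L, 3L),
                            cfg = ModelConfig(errate = 0.01))
  expect_equal(r$ratio, 1, tolerance = 1e-12)

  # strongly conflicting locus among ten observed: per-locus dip below 1/n
  freqs <- rep(0.5, 10)
  track <- c(rep(0.5, 9), 1)            # matches freq except the last site
  lib <- mkLib(freqs, tracks = list(track))
  nA <- c(rep(1L, 9), 0L)
  nB <- c(rep(1L, 9), 5L)
  r <- jointLikelihoodRatio(lib, 1, nA, nB, cfg = cfg0)
  expect_true(r$discarded)
  # the dip is the hand value 0.015625 / 0.265625 = 0.0588 < 1/10
  expect_equal(r$ratio, prod(rep(1, 9)) * 0.015625 / 0.265625,
               tolerance = 1e-3)
})

test_that("pruned and unpruned ratio scans agree on the discard decision", {
  set.seed(42)
  for (rep in 1:20) {
    L <- 30
    freqs <- runif(L, 0.05, 0.95)
    lib <- mkLib(freqs, tracks = list(round(runif(L))))
    d <- sampleReads(matrix(sample(0:2, L, TRUE), ncol = 1), 2, 0.01)
    a <- jointLikelihoodRatio(lib, 1, d$nA[, 1], d$nB[, 1],
                              ModelConfig(errate = 0.01), prune = TRUE)
    b <- jointLikelihoodRatio(lib, 1, d$nA[, 1], d$nB[, 1],
                              ModelConfig(errate = 0.01), prune = FALSE)
    expect_identical(a$discarded, b$discarded)
    if (!a$discarded) expect_equal(a$ratio, b$ratio)
  }
})

test_that("H1 selection returns the first qualifying candidate", {
  cfg0 <- ModelConfig(errate = 0)
  expect_identical(selectH1(mkLib(rep(0.5, 4)), rep(1L, 4), rep(0L, 4),
                            cfg0), NA_integer_)

  # single qualifying track
  L <- 5
  lib <- mkLib(rep(0.5, L), tracks = list(rep(1, L)))
  h <- selectH1(lib, nA = rep(2L, L), nB = rep(0L, L), cfg0)
  expect_identical(h, 1L)

  # an ancestor candidate listed first wins over an equally good,
  # more frequent track
  lib <- mkLib(rep(0.5, L), tracks = list(rep(1, L), rep(1, L)))
  lib@usage <- c(5L, 1L)
  expect_identical(selectH1(lib, rep(2L, L), rep(0L, L), cfg0), 1L)
  expect_identical(selectH1(lib, rep(2L, L), rep(0L, L), cfg0,
                            candidates = 2L), 2L)

  # selection is consistent with exhaustive threshold evaluation
  set.seed(99)
  for (rep in 1:10) {
    L <- 40
    freqs <- runif(L, 0.1, 0.9)
    tracks <- lapply(1:6, function(i) round(runif(L)))
    lib <- mkLib(freqs, tracks = tracks)
    d <- sampleReads(matrix(tracks[[3]] + tracks[[5]], ncol = 1), 3, 0.01)
    cfg <- ModelConfig(errate = 0.01)
    sel <- selectH1(lib, d$nA[, 1], d$nB[, 1], cfg)
    pass <- vapply(1:6, function(t) {
      r <- jointLikelihoodRatio(lib, t, d$nA[, 1], d$nB[, 1], cfg)
      !r$discarded && r$ratio > r$threshold
    }, logical(1))
    expect_identical(sel, if (any(pass)) which(pass)[1L] else NA_integer_)
  }
})

test_that("H2 selection conditions on H1 and uses the relaxed threshold", {
  # thresholds printed for n = 100 and n = 50
  n <- 100L
  lib <- mkLib(rep(0.5, n), tracks = list(rep(0.5, n)))
  r <- jointLikelihoodRatio(lib, 1, rep(1L, n), rep(0L, n),
                            ModelConfig(errate = 0.01), h1 = 1)
  expect_equal(r$threshold, 1 / 200)
  r <- jointLikelihoodRatio(mkLib(rep(0.5, 50), tracks = list(rep(0.5, 50))),
                            1, rep(1L, 50), rep(0L, 50),
                            ModelConfig(errate = 0.01))
  expect_equal(r$threshold, 1 / 50)

  # homozygous-consistent data prefer the matching H2 (H1 itself is
  # excluded: the complement is a distinct track)
  L <- 8
  cfg <- ModelConfig(errate = 0.01)
  lib <- mkLib(rep(0.5, L), tracks = list(rep(1, L), rep(0, L), rep(1, L)))
  h2 <- selectH2(lib, rep(4L, L), rep(0L, L), h1 = 1L, cfg)
  expect_identical(h2, 3L)   # all-A beats all-B for all-A reads
  rB <- jointLikelihoodRatio(lib, 2, rep(4L, L), rep(0L, L), cfg, h1 = 1L)
  expect_true(rB$discarded || rB$ratio < 1 / L)
})

test_that("admission seeds new tracks with the site frequencies", {
  lib <- HaplotypeLibrary(0, 3, freqs = c(0.2, 0.5, 0.9))
  a <- admitHaplotype(lib)
  expect_identical(a$id, 1L)
  expect_equal(trackProbs(a$library)[, 1], c(0.2, 0.5, 0.9))
  b <- admitHaplotype(a$library)
  expect_identical(b$id, 2L)
  expect_identical(usageCounts(b$library), c(1L, 1L))

  # admission followed by a strong homozygous update saturates the site
  lib1 <- admitHaplotype(HaplotypeLibrary(0, 1, freqs = 0.5))$library
  L <- readLikelihoods(8, 0, 0.01, coef = FALSE)
  u <- posteriorPairUpdate(trackProbs(lib1)[1, 1], 0.5, L)
  expect_gt(u$p1, 0.99)
})

test_that("resorting orders by usage, stably, and remaps assignments", {
  lib <- mkLib(rep(0.5, 2), tracks = rep(list(rep(0.5, 2)), 3),
               usage = c(1L, 5L, 3L))
  rs <- resortLibrary(lib, assignments = c(1L, 2L, 3L, NA))
  expect_identical(rs$perm, c(2L, 3L, 1L))
  expect_identical(usageCounts(rs$library), c(5L, 3L, 1L))
  expect_identical(rs$assignments, c(3L, 1L, 2L, NA))

  # ties preserve the original order
  lib <- mkLib(rep(0.5, 2), tracks = rep(list(rep(0.5, 2)), 2),
               usage = c(2L, 2L))
  expect_identical(resortLibrary(lib)$perm, c(1L, 2L))

  # already sorted: identity permutation
  lib@usage <- c(9L, 1L)
  expect_identical(resortLibrary(lib)$perm, c(1L, 2L))
})

test_that("library export/import round-trips within quantization error", {
  set.seed(5)
  lib <- mkLib(runif(12), tracks = list(runif(12), runif(12)),
               usage = c(4L, 2L))
  path <- tempfile(fileext = ".tsv")
  exportLibrary(lib, path)
  back <- importLibrary(path)
  expect_length(back, 1L)
  expect_identical(segmentBounds(back[[1]]), segmentBounds(lib))
  expect_identical(usageCounts(back[[1]]), usageCounts(lib))
  expect_lte(max(abs(trackProbs(back[[1]]) - trackProbs(lib))), 1 / 65535)
  expect_lte(max(abs(siteFrequencies(back[[1]]) - siteFrequencies(lib))),
             1 / 65535)

  # empty file imports as an empty library list
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_identical(importLibrary(empty), list())

  # malformed input names the offending line
  bad <- tempfile()
  writeLines(c("SEG\t0\t2\t1", "FREQ\tzzzz"), bad)
  expect_error(importLibrary(bad), "line")

  # assignments round trip
  asn <- data.frame(individual = c("a", "b"), segment = c(0L, 0L),
                    h1 = c(1L, 2L), h2 = c(1L, NA))
  p2 <- tempfile(fileext = ".tsv")
  exportAssignments(asn, p2)
  expect_identical(importAssignments(p2), asn)
})
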