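test_that("percent correct scores matches and missing calls", {
  calls <- matrix(c(0L, 1L, 2L, 1L), 2)
  expect_equal(percentCorrect(calls, calls), 100)
  truth <- matrix(c(0L, 1L, 2L, 2L), 2)
  expect_equal(percentCorrect(calls, truth), 75)
  allNA <- matrix(NA_integer_, 2, 2)
  expect_equal(percentCorrect(allNA, truth), 0)
  # diagnostic mode scores non-missing entries only
  some <- matrix(c(0L, NA, 2L, NA), 2)
  expect_equal(percentCorrect(some, truth, countMissing = FALSE), 100)
  expect_error(percentCorrect(calls, truth[1, , drop = FALSE]),
               "dimensions")
})

test_that("centered correlation matches a textbook Pearson computation", {
  truth <- matrix(c(0L, 1L, 2L, 1L), 1)
  dos <- matrix(c(0, 1, 2, 0), 1)
  r <- centeredCorrelation(dos, truth, freqs = 0.5)
  x <- c(0, 1, 2, 0) - 1; y <- c(0, 1, 2, 1) - 1
  expect_equal(r, sum(x * y) / sqrt(sum(x^2) * sum(y^2)))

  # perfect dosages give correlation 1
  tr <- matrix(sample(0:2, 40, TRUE), 4)
  expect_equal(centeredCorrelation(tr * 1.0, tr, runif(4)), 1)

  # zero variance is flagged, not silently coerced
  expect_warning(r0 <- centeredCorrelation(matrix(1, 1, 4),
                                           matrix(1L, 1, 4), 0.5),
                 "variance")
  expect_true(is.na(r0))
})

test_that("monomorphic loci never change the centered correlation", {
  set.seed(11)
  tr <- matrix(sample(0:2, 60, TRUE), 6)
  dos <- tr + matrix(rnorm(60, 0, 0.3), 6)
  f <- runif(6)
  r1 <- centeredCorrelation(dos, tr, f)
  # append a monomorphic locus: truth all AA, dosage equal, freq 1
  tr2 <- rbind(tr, rep(2L, 10))
  dos2 <- rbind(dos, rep(2, 10))
  r2 <- centeredCorrelation(dos2, tr2, c(f, 1))
  expect_identical(r1, r2)
})

test_that("metrics are invariant to a global allele relabeling", {
  set.seed(12)
  tr <- matrix(sample(0:2, 80, TRUE), 8)
  dos <- pmin(pmax(tr + rnorm(80, 0, 0.4), 0), 2)
  calls <- matrix(as.integer(round(dos)), 8)
  f <- runif(8)
  expect_equal(percentCorrect(calls, tr),
               percentCorrect(2L - calls, 2L - tr))
  expect_equal(centeredCorrelation(dos, tr, f),
               centeredCorrelation(2 - dos, 2L - tr, 1 - f),
               tolerance = 1e-12)
})

test_that("MAF-binned correlations partition the global metric", {
  set.seed(13)
  tr <- matrix(sample(0:2, 100, TRUE), 10)
  dos <- tr * 1.0
  f <- runif(10, 0.05, 0.95)
  one <- mafBinnedCorrelation(dos, tr, f, binEdges = c(0, 0.5))
  expect_equal(one$r, centeredCorrelation(dos, tr, f))
  two <- mafBinnedCorrelation(dos, tr, f, binEdges = c(0, 0.25, 0.5))
  expect_true(all(two$r[two$nSites > 0] == 1))
  # empty bins are NA, not zero
  narrow <- mafBinnedCorrelation(dos, tr, rep(0.5, 10),
                                 binEdges = c(0, 0.1, 0.5))
  expect_true(is.na(narrow$r[1]))
  expect_identical(narrow$nSites[1], 0L)
})

test_that("low-MAF sites impute worse than common sites at low depth", {
  rs <- sapply(1:5, function(s) {
    sim <- simulateDataset(SimConfig(nSeq = 40, nArray = 0, nSites = 500,
                                     chipSize = 10, meanDepth = 2,
                                     errate = 0.01, includeHd = FALSE,
                                     nGenerations = 3, nSires = 4,
                                     seed = 100 + s))
    calls <- runPipeline(sim, SegmentPlan(500, minLen = 125, maxLen = 500,
                                          itersPerStep = 2),
                         ModelConfig(errate = 0.01))
    truth <- trueGenotypes(sim)
    f <- rowMeans(truth) / 2
    b <- mafBinnedCorrelation(dosageMatrix(calls), truth, f,
                              binEdges = c(0.01, 0.1, 0.5))
    b$r
  })
  expect_gt(mean(rs[2, ] - rs[1, ], na.rm = TRUE), 0)
})

test_that("the grid runner reproduces direct pipeline runs", {
  base <- SimConfig(nSeq = 10, nArray = 4, nSites = 150, chipSize = 15,
                    meanDepth = 8, errate = 0.01, nGenerations = 3,
                    nSires = 2, seed = 1)
  plan <- SegmentPlan(150, minLen = 50, maxLen = 150, itersPerStep = 2)
  grid <- data.frame(meanDepth = c(8, 8), seed = c(21, 22))
  res <- runGrid(grid, base, plan = plan)
  expect_identical(nrow(res), 4L)            # two cells x two classes
  expect_true(all(is.na(res$error)))
  expect_true(all(res$cost == 80))
  # cell 1 equals a direct run
  cfg1 <- base; cfg1@seed <- 21L
  direct <- evaluateCalls(runPipeline(simulateDataset(cfg1), plan,
                                      ModelConfig(errate = 0.01)),
                          simulateDataset(cfg1))
  got <- res[res$seed == 21 & res$dataClass == "seq", "percentCorrect"]
  expect_equal(got, direct$percentCorrect[direct$dataClass == "seq"])
  # distinct seeds give distinct stochastic results
  expect_false(isTRUE(all.equal(
    res$percentCorrect[res$seed == 21 & res$dataClass == "seq"],
    res$percentCorrect[res$seed == 22 & res$dataClass == "seq"])))
  # per-cell failure is recorded, not fatal
  bad <- data.frame(meanDepth = -1, seed = 1)
  resBad <- suppressWarnings(runGrid(bad, base, plan = plan))
  expect_false(is.na(resBad$error[1]))
})

test_that("calling accuracy is non-decreasing in read depth", {
  acc <- sapply(c(2, 8), function(depth) {
    mean(sapply(1:2, function(s) {
      sim <- simulateDataset(SimConfig(nSeq = 25, nArray = 0, nSites = 300,
                                       chipSize = 10, meanDepth = depth,
                                       errate = 0.01, includeHd = FALSE,
                                       nGenerations = 3, nSires = 3,
                                       seed = 400 + s))
      calls <- runPipeline(sim, SegmentPlan(300, minLen = 100, maxLen = 300,
                                            itersPerStep = 2),
                           ModelConfig(errate = 0.01))
      percentCorrect(genotypeMatrix(calls), trueGenotypes(sim))
    }))
  })
  expect_gt(acc[2], acc[1])
})
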