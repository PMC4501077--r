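## Accuracy evaluation: percent-correct calls, frequency-centered dosage
## correlations (overall and by MAF bin), and the design-grid runner.

#' Percentage of correctly called genotypes
#'
#' 100 x matches / scored entries. By default missing calls are scored as
#' incorrect (every locus counts); set \code{countMissing = FALSE} to
#' score non-missing calls only (diagnostic mode).
#'
#' @param calls integer matrix of called genotypes (NA = missing).
#' @param truth integer matrix of true genotypes, same shape, complete.
#' @param countMissing score missing calls as incorrect.
#' @return percentage in [0, 100].
#' @examples
#' percentCorrect(matrix(c(0L, 1L, 2L, NA), 2), matrix(c(0L, 1L, 1L, 2L), 2))
#' @export
percentCorrect <- function(calls, truth, countMissing = TRUE) {
  if (!identical(dim(calls), dim(truth)))
    stop("'calls' and 'truth' must have identical dimensions")
  match <- sum(calls == truth, na.rm = TRUE)
  denom <- if (countMissing) length(truth) else sum(!is.na(calls))
  if (denom == 0) return(NA_real_)
  100 * match / denom
}

#' Frequency-centered genotype/dosage correlation
#'
#' Correlation between called dosages and true genotypes after subtracting
#' twice the per-site reference-allele frequency from both (genotypes
#' coded 0, 1, 2 copies of the reference allele), pooled over all
#' (individual, site) pairs without per-site standardization. The
#' frequency centering replaces mean centering, so the statistic is
#' computed as \code{sum(xy) / sqrt(sum(x^2) sum(y^2))} on the centered
#' values; monomorphic loci then contribute exactly zero to both numerator
#' and denominator and cannot affect the result.
#'
#' @param dosages numeric matrix (sites x individuals) of called dosages.
#' @param truth integer matrix of true genotypes, same shape.
#' @param freqs per-site reference-allele frequencies in [0, 1].
#' @return Pearson correlation, or NA (with a warning) when either
#'   centered vector has zero variance.
#' @export
centeredCorrelation <- function(dosages, truth, freqs) {
  if (!identical(dim(dosages), dim(truth)))
    stop("'dosages' and 'truth' must have identical dimensions")
  if (any(freqs < 0 | freqs > 1)) stop("'freqs' must be in [0, 1]")
  cd <- dosages - 2 * freqs
  ct <- truth - 2 * freqs
  ok <- !is.na(cd) & !is.na(ct)
  x <- cd[ok]; y <- ct[ok]
  den <- sqrt(sum(x^2) * sum(y^2))
  if (length(x) < 2L || den == 0) {
    warning("centered correlation undefined (zero variance)")
    return(NA_real_)
  }
  sum(x * y) / den
}

#' Centered correlation by minor-allele-frequency bin
#'
#' Splits sites into MAF bins over (0, 0.5] and computes the centered
#' correlation within each bin. Empty bins are reported as NA rather than
#' zero.
#'
#' @inheritParams centeredCorrelation
#' @param binEdges bin edges covering (0, 0.5].
#' @return data.frame with columns \code{lo}, \code{hi}, \code{nSites},
#'   \code{r}.
#' @export
mafBinnedCorrelation <- function(dosages, truth, freqs,
                                 binEdges = seq(0, 0.5, by = 0.05)) {
  maf <- pmin(freqs, 1 - freqs)
  bins <- cut(maf, binEdges, right = TRUE)
  out <- data.frame(lo = binEdges[-length(binEdges)], hi = binEdges[-1L],
                    nSites = NA_integer_, r = NA_real_)
  for (b in seq_len(nlevels(bins))) {
    rows <- which(as.integer(bins) == b)
    out$nSites[b] <- length(rows)
    if (!length(rows)) next
    out$r[b] <- suppressWarnings(
      centeredCorrelation(dosages[rows, , drop = FALSE],
                          truth[rows, , drop = FALSE], freqs[rows]))
  }
  out
}

#' Evaluate a call set against simulated truth
#'
#' Convenience wrapper computing, separately for the sequenced and
#' array-only classes, the percent-correct and centered-correlation
#' metrics. Percent correct is reported across all loci and, for sequenced
#' individuals with embedded HD data, also excluding the chip loci.
#'
#' @param calls a \linkS4class{GenotypeCalls}.
#' @param x the \linkS4class{SeqDepthSet} that produced them (must carry
#'   truth).
#' @return data.frame with one row per data class.
#' @export
evaluateCalls <- function(calls, x) {
  truth <- trueGenotypes(x)
  if (is.null(truth)) stop("'x' carries no true genotypes")
  g <- genotypeMatrix(calls)
  d <- dosageMatrix(calls)
  cls <- pedigree(x)$dataClass
  tot <- rowSums(depthA(x)) + rowSums(depthB(x))
  freqs <- ifelse(tot > 0, rowSums(depthA(x)) / tot, 0.5)
  chip <- SummarizedExperiment::rowData(x)$chip
  res <- lapply(unique(cls), function(cl) {
    idx <- which(cls == cl)
    pc <- percentCorrect(g[, idx, drop = FALSE], truth[, idx, drop = FALSE])
    pcNoChip <- if (any(chip))
      percentCorrect(g[!chip, idx, drop = FALSE],
                     truth[!chip, idx, drop = FALSE]) else pc
    r <- suppressWarnings(
      centeredCorrelation(d[, idx, drop = FALSE],
                          truth[, idx, drop = FALSE], freqs))
    data.frame(dataClass = cl, n = length(idx), percentCorrect = pc,
               percentCorrectNonChip = pcNoChip, correlation = r)
  })
  do.call(rbind, res)
}

#' Run a design grid of simulations and pipeline evaluations
#'
#' One simulation + pipeline + evaluation per grid row. Recognized grid
#' columns override the corresponding \linkS4class{SimConfig} slots
#' (\code{meanDepth}, \code{errate}, \code{nSeq}, \code{nArray},
#' \code{includeHd}, \code{chipSize}, \code{seed}); other slots come from
#' \code{base}. Per-cell failures are recorded in the \code{error} column
#' and the grid continues.
#'
#' @param grid data.frame of design points.
#' @param base a \linkS4class{SimConfig} supplying defaults.
#' @param plan optional \linkS4class{SegmentPlan}; default ladder for the
#'   cell's site count.
#' @param engine pipeline engine ("cpp" or "r").
#' @return long-format data.frame: the grid columns, a \code{cost} column
#'   (sequenced individuals x depth) and per-class accuracy metrics.
#' @export
runGrid <- function(grid, base = SimConfig(), plan = NULL,
                    engine = "cpp") {
  out <- vector("list", nrow(grid))
  slots <- c("meanDepth", "errate", "nSeq", "nArray", "includeHd",
             "chipSize", "seed")
  for (r in seq_len(nrow(grid))) {
    cfg <- base
    for (s in intersect(slots, names(grid)))
      slot(cfg, s) <- as(grid[[s]][r], class(slot(base, s)))
    cell <- grid[r, , drop = FALSE]
    rownames(cell) <- NULL
    res <- tryCatch({
      sds <- simulateDataset(cfg)
      pl <- if (is.null(plan)) SegmentPlan(cfg@nSites) else plan
      calls <- runPipeline(sds, pl, ModelConfig(errate = cfg@errate,
                                                arrayErrate = cfg@arrayErrate),
                           engine = engine)
      ev <- evaluateCalls(calls, sds)
      cbind(cell[rep(1L, nrow(ev)), , drop = FALSE],
            cost = cfg@nSeq * cfg@meanDepth, ev,
            error = NA_character_)
    }, error = function(e) {
      cbind(cell, cost = cfg@nSeq * cfg@meanDepth,
            dataClass = NA_character_, n = NA_integer_,
            percentCorrect = NA_real_, percentCorrectNonChip = NA_real_,
            correlation = NA_real_, error = conditionMessage(e))
    })
    out[[r]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
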