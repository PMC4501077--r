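## Haplotype-library operations: likelihood-ratio selection of H1/H2 with
## early pruning, admission of new haplotypes, resorting by usage, and the
## TSV import/export used for incremental runs.

#' Joint likelihood ratio of a candidate haplotype
#'
#' For each locus with observed reads the ratio of the probability of the
#' observation given the candidate haplotype (its per-site A probability
#' used directly, with the partner haplotype drawn from the population) to
#' the probability under two population-random haplotypes. The per-locus
#' ratios are multiplied in site order; scanning stops and the candidate is
#' discarded as soon as the running product falls below 1/n, where n is the
#' number of observed loci. A candidate qualifies as H1 when the full
#' product exceeds 1/n.
#'
#' When \code{h1} is given, the ratio instead compares the joint
#' probability given both haplotypes to the probability given H1 alone;
#' the acceptance threshold for H2 is \code{1 / (n * (1 + n / 100))}.
#'
#' @param lib a \linkS4class{HaplotypeLibrary}.
#' @param track candidate track index (1-based).
#' @param nA,nB read counts over the segment's sites for the focal
#'   individual.
#' @param cfg a \linkS4class{ModelConfig}.
#' @param arrayFlags logical vector marking array-derived loci (evaluated
#'   with the array error rate).
#' @param h1 optional track index of the already-selected H1; switches to
#'   the H2 ratio.
#' @param prune stop at the first locus where the running product drops
#'   below 1/n (the result records the same discard decision either way;
#'   pruning only avoids computing the remaining loci).
#' @return list with \code{ratio} (the product over the loci scanned),
#'   \code{discarded} (logical), \code{n} (observed loci) and
#'   \code{threshold} (the acceptance threshold for this test).
#' @examples
#' lib <- HaplotypeLibrary(0, 1, freqs = 0.5)
#' lib <- admitHaplotype(lib, prior = 1)$library
#' jointLikelihoodRatio(lib, 1, nA = 2L, nB = 0L,
#'                      cfg = ModelConfig(errate = 0))$ratio  # 1.6667
#' @export
jointLikelihoodRatio <- function(lib, track, nA, nB, cfg = ModelConfig(),
                                 arrayFlags = NULL, h1 = NULL,
                                 prune = TRUE) {
  len <- lib@end - lib@start
  stopifnot(length(nA) == len, length(nB) == len)
  if (is.null(arrayFlags)) arrayFlags <- rep(FALSE, len)
  obs <- which(nA + nB > 0L)
  n <- length(obs)
  threshold <- if (is.null(h1)) 1 / n else 1 / (n * (1 + n / 100))
  if (n == 0L)
    return(list(ratio = 1, discarded = FALSE, n = 0L, threshold = NA_real_))
  err <- ifelse(arrayFlags[obs], cfg@arrayErrate, cfg@errate)
  L <- .asLikMat(readLikelihoods(nA[obs], nB[obs], err, coef = FALSE))
  p <- .clamp01(lib@freqs[obs], cfg@clamp)
  q <- .clamp01(lib@probs[obs, track], cfg@clamp)
  if (is.null(h1)) {
    num <- jointUnconditional(L, q, p)
    den <- jointUnconditional(L, p, p)
  } else {
    q1 <- .clamp01(lib@probs[obs, h1], cfg@clamp)
    num <- jointUnconditional(L, q1, q)
    den <- jointUnconditional(L, q1, p)
  }
  r <- num / den
  cp <- cumprod(r)
  dip <- which(cp < 1 / n)
  if (length(dip)) {
    stopAt <- if (prune) dip[1L] else n
    return(list(ratio = cp[stopAt], discarded = TRUE, n = n,
                threshold = threshold))
  }
  list(ratio = cp[n], discarded = FALSE, n = n, threshold = threshold)
}

#' Select the first haplotype H1 for an individual
#'
#' Scans candidates (ancestor tracks first, then all tracks in stored
#' frequency order) and returns the first whose joint likelihood ratio is
#' not discarded and exceeds 1/n. Returns NA when no track qualifies.
#'
#' @inheritParams jointLikelihoodRatio
#' @param candidates track indices to check before the frequency-ordered
#'   scan (typically parental and grandparental haplotypes).
#' @return selected track index, or \code{NA_integer_}.
#' @export
selectH1 <- function(lib, nA, nB, cfg = ModelConfig(), arrayFlags = NULL,
                     candidates = integer(0)) {
  K <- nTracks(lib)
  if (K == 0L) return(NA_integer_)
  order <- unique(c(as.integer(candidates), seq_len(K)))
  order <- order[order >= 1L & order <= K]
  for (t in order) {
    res <- jointLikelihoodRatio(lib, t, nA, nB, cfg, arrayFlags)
    if (res$n == 0L) return(NA_integer_)
    if (!res$discarded && res$ratio > res$threshold) return(t)
  }
  NA_integer_
}

#' Select the complement haplotype H2 given H1
#'
#' Same candidate scan as \code{\link{selectH1}}, but each per-locus ratio
#' conditions on the selected H1 and the acceptance threshold is
#' \code{1 / (n * (1 + n / 100))}. The H1 track itself is excluded: the
#' complement is a second haplotype, so an individual always holds two
#' distinct tracks.
#'
#' @inheritParams selectH1
#' @param h1 track index of the selected H1.
#' @return selected track index, or \code{NA_integer_}.
#' @export
selectH2 <- function(lib, nA, nB, h1, cfg = ModelConfig(),
                     arrayFlags = NULL, candidates = integer(0)) {
  K <- nTracks(lib)
  if (K == 0L) return(NA_integer_)
  order <- unique(c(as.integer(candidates), seq_len(K)))
  order <- order[order >= 1L & order <= K & order != h1]
  for (t in order) {
    res <- jointLikelihoodRatio(lib, t, nA, nB, cfg, arrayFlags, h1 = h1)
    if (res$n == 0L) return(NA_integer_)
    if (!res$discarded && res$ratio > res$threshold) return(t)
  }
  NA_integer_
}

#' Admit a new haplotype into the library
#'
#' Appends a track whose prior allele probabilities are the current site
#' frequencies (or a supplied prior, e.g. the complement of H1 at
#' array-called loci) with a usage count of 1. Resorting is deferred to
#' the end of the population pass.
#'
#' @param lib a \linkS4class{HaplotypeLibrary}.
#' @param prior optional numeric vector of prior A probabilities.
#' @return list with the updated \code{library} and the new track \code{id}.
#' @examples
#' lib <- HaplotypeLibrary(0, 3, freqs = c(0.2, 0.5, 0.9))
#' admitHaplotype(lib)$id  # 1
#' @export
admitHaplotype <- function(lib, prior = NULL) {
  if (is.null(prior)) prior <- lib@freqs
  stopifnot(length(prior) == lib@end - lib@start,
            all(prior >= 0 & prior <= 1))
  lib@probs <- cbind(lib@probs, prior, deparse.level = 0)
  lib@usage <- c(lib@usage, 1L)
  list(library = lib, id = ncol(lib@probs))
}

#' Resort the library by descending usage
#'
#' Tracks are reordered by non-increasing usage count (stable for ties) and
#' any assignment codes are remapped to the new indices.
#'
#' @param lib a \linkS4class{HaplotypeLibrary}.
#' @param assignments optional integer vector/matrix of track indices to
#'   remap (NAs pass through).
#' @return list with \code{library}, the permutation \code{perm} (new order
#'   as old indices) and remapped \code{assignments}.
#' @export
resortLibrary <- function(lib, assignments = NULL) {
  K <- nTracks(lib)
  perm <- order(-lib@usage)           # stable radix sort for integer keys
  lib@probs <- lib@probs[, perm, drop = FALSE]
  lib@usage <- lib@usage[perm]
  if (!is.null(assignments)) {
    map <- integer(K)
    map[perm] <- seq_len(K)
    old <- assignments
    assignments[] <- ifelse(is.na(old), NA_integer_, map[old])
  }
  list(library = lib, perm = perm, assignments = assignments)
}

.packHex <- function(p) {
  paste(sprintf("%04x", as.integer(round(p * 65535))), collapse = "")
}

.unpackHex <- function(s, path = "<stream>", line = NA) {
  if (nchar(s) %% 4L != 0L)
    stop("malformed probability string at ", path, " line ", line)
  starts <- seq(1L, nchar(s), by = 4L)
  strtoi(substring(s, starts, starts + 3L), base = 16L) / 65535
}

#' Export haplotype libraries for incremental runs
#'
#' Writes one or more segment libraries as TSV: a \code{SEG} header row per
#' segment (start, end, track count) followed by one row per track (id,
#' usage count, hex-packed 16-bit fixed-point probabilities) and a
#' \code{FREQ} row with the segment's site frequencies. Probabilities are
#' quantized to 1/65535, mirroring 2-byte probability storage.
#'
#' @param libs a \linkS4class{HaplotypeLibrary} or list of them.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @seealso \code{\link{importLibrary}}, \code{\link{exportAssignments}}
#' @export
exportLibrary <- function(libs, path) {
  if (is(libs, "HaplotypeLibrary")) libs <- list(libs)
  con <- file(path, "w")
  on.exit(close(con))
  for (lib in libs) {
    writeLines(paste("SEG", lib@start, lib@end, nTracks(lib), sep = "\t"),
               con)
    writeLines(paste("FREQ", .packHex(lib@freqs), sep = "\t"), con)
    for (t in seq_len(nTracks(lib)))
      writeLines(paste(t, lib@usage[t], .packHex(lib@probs[, t]),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Import haplotype libraries written by exportLibrary
#'
#' @param path file written by \code{\link{exportLibrary}}.
#' @return list of \linkS4class{HaplotypeLibrary} objects (empty list for
#'   an empty file). Malformed input raises an error naming the line.
#' @export
importLibrary <- function(path) {
  lines <- readLines(path)
  libs <- list()
  i <- 1L
  while (i <= length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 4L || f[1L] != "SEG")
      stop("expected SEG header at ", path, " line ", i)
    start <- as.integer(f[2L]); end <- as.integer(f[3L])
    K <- as.integer(f[4L])
    if (anyNA(c(start, end, K)) || end <= start || K < 0L)
      stop("malformed SEG header at ", path, " line ", i)
    i <- i + 1L
    ff <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(ff) != 2L || ff[1L] != "FREQ")
      stop("expected FREQ row at ", path, " line ", i)
    freqs <- .unpackHex(ff[2L], path, i)
    if (length(freqs) != end - start)
      stop("frequency row of wrong length at ", path, " line ", i)
    lib <- HaplotypeLibrary(start, end, freqs)
    probs <- matrix(NA_real_, end - start, K)
    usage <- integer(K)
    for (t in seq_len(K)) {
      i <- i + 1L
      tf <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(tf) != 3L)
        stop("malformed track row at ", path, " line ", i)
      pv <- .unpackHex(tf[3L], path, i)
      if (length(pv) != end - start)
        stop("track row of wrong length at ", path, " line ", i)
      probs[, as.integer(tf[1L])] <- pv
      usage[as.integer(tf[1L])] <- as.integer(tf[2L])
    }
    lib@probs <- probs
    lib@usage <- usage
    libs[[length(libs) + 1L]] <- lib
    i <- i + 1L
  }
  libs
}

#' Export or import haplotype assignment codes
#'
#' Assignments record which two library tracks form each individual's
#' genotype in each segment, as a TSV with columns individual, segment,
#' h1, h2 (NA for unassigned).
#'
#' @param assignments data.frame with columns \code{individual},
#'   \code{segment}, \code{h1}, \code{h2}.
#' @param path file path.
#' @return \code{exportAssignments}: invisibly, \code{path};
#'   \code{importAssignments}: the assignments data.frame.
#' @export
exportAssignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname exportAssignments
#' @export
importAssignments <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
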