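## Population-scale phasing and imputation: pedigree-aware processing order,
## per-individual H1/H2 selection and posterior updating, the window-ladder
## iteration schedule, and final genotype calling.

#' Pedigree processing order (oldest to youngest)
#'
#' Topological order consistent with parent-before-child; among available
#' individuals the order is by birth key, then pedigree depth, then input
#' position. Cycles raise an error naming the individuals involved.
#'
#' @param ped data.frame with columns \code{id}, \code{sire}, \code{dam}
#'   (NA, "0" or "." for unknown) and optionally \code{birth}.
#' @return integer vector: row indices of \code{ped} in processing order.
#' @examples
#' ped <- data.frame(id = c("kid", "pa"), sire = c("pa", NA),
#'                   dam = NA, birth = c(1, 1))
#' ped$id[orderIndividuals(ped)]
#' @export
orderIndividuals <- function(ped) {
  n <- nrow(ped)
  norm <- function(v) {
    v <- as.character(v)
    v[v %in% c("0", ".", "")] <- NA_character_
    v
  }
  sire <- match(norm(ped$sire), ped$id)
  dam <- match(norm(ped$dam), ped$id)
  birth <- if (is.null(ped$birth)) rep(0, n) else as.numeric(ped$birth)
  # pedigree depth with cycle detection (iterative DFS)
  depth <- rep(NA_integer_, n)
  state <- integer(n)                     # 0 unseen, 1 on stack, 2 done
  for (root in seq_len(n)) {
    if (state[root] == 2L) next
    stack <- root
    while (length(stack)) {
      i <- stack[length(stack)]
      if (state[i] == 2L) { stack <- stack[-length(stack)]; next }
      par <- c(sire[i], dam[i]); par <- par[!is.na(par)]
      if (any(state[par] == 1L & !(par %in% c(i))) ||
          any(par == i)) {
        cyc <- unique(ped$id[c(i, par[state[par] == 1L | par == i])])
        stop("pedigree cycle involving: ", paste(cyc, collapse = ", "))
      }
      todo <- par[state[par] == 0L]
      if (length(todo)) {
        state[i] <- 1L
        if (any(state[todo] == 1L)) {
          cyc <- unique(ped$id[c(i, todo[state[todo] == 1L])])
          stop("pedigree cycle involving: ", paste(cyc, collapse = ", "))
        }
        stack <- c(stack, todo)
      } else {
        pd <- depth[par]
        depth[i] <- if (length(pd)) max(pd, 0L) + 1L else 0L
        if (!length(par)) depth[i] <- 0L
        state[i] <- 2L
        stack <- stack[-length(stack)]
      }
    }
  }
  ord <- order(birth, depth, seq_len(n))
  pos <- integer(n); pos[ord] <- seq_len(n)
  ok <- all(is.na(sire) | pos[sire] < pos, na.rm = TRUE) &&
    all(is.na(dam) | pos[dam] < pos, na.rm = TRUE)
  if (ok) return(ord)
  # rare: birth keys conflict with pedigree links; priority Kahn
  key <- rank(birth, ties.method = "min") * (n + 1)^2 +
    depth * (n + 1) + seq_len(n)
  done <- logical(n)
  indeg <- (!is.na(sire)) + (!is.na(dam))
  ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!done & indeg == 0L)
    if (!length(ready))
      stop("pedigree cycle involving: ",
           paste(ped$id[!done], collapse = ", "))
    i <- ready[which.min(key[ready])]
    done[i] <- TRUE
    ord <- c(ord, i)
    indeg[which(sire == i)] <- indeg[which(sire == i)] - 1L
    indeg[which(dam == i)] <- indeg[which(dam == i)] - 1L
  }
  ord
}

.parentIdx <- function(ped) {
  norm <- function(v) {
    v <- as.character(v)
    v[v %in% c("0", ".", "")] <- NA_character_
    v
  }
  list(sire = match(norm(ped$sire), ped$id),
       dam = match(norm(ped$dam), ped$id))
}

#' Candidate track order for an individual
#'
#' The up-to-four parental tracks (sire's pair, then dam's pair), then
#' grandparental tracks not already listed, then all remaining tracks in
#' stored frequency order, without duplicates.
#'
#' @param ind individual index (column position).
#' @param h1,h2 integer vectors of current track assignments per individual
#'   (NA if unassigned).
#' @param sireIdx,damIdx integer vectors mapping each individual to its
#'   parents' indices (NA if unknown).
#' @param nTracks number of tracks in the library.
#' @return integer vector of candidate track indices.
#' @export
candidateOrder <- function(ind, h1, h2, sireIdx, damIdx, nTracks) {
  anc <- integer(0)
  s <- sireIdx[ind]; d <- damIdx[ind]
  if (!is.na(s)) anc <- c(anc, h1[s], h2[s])
  if (!is.na(d)) anc <- c(anc, h1[d], h2[d])
  for (g in c(if (!is.na(s)) c(sireIdx[s], damIdx[s]),
              if (!is.na(d)) c(sireIdx[d], damIdx[d]))) {
    if (!is.na(g)) anc <- c(anc, h1[g], h2[g])
  }
  anc <- unique(anc[!is.na(anc)])
  anc <- anc[anc >= 1L & anc <= nTracks]
  c(anc, setdiff(seq_len(nTracks), anc))
}

#' Process one individual in one segment
#'
#' Selects H1 (admitting a new haplotype when no track qualifies), then H2
#' conditional on H1, then applies the posterior pair update at every
#' observed locus, writing the posteriors back into the two tracks so they
#' serve as priors for the next individual sharing them.
#'
#' @param lib a \linkS4class{HaplotypeLibrary}.
#' @param nA,nB read counts over the segment's sites.
#' @param cfg a \linkS4class{ModelConfig}.
#' @param arrayFlags logical vector marking array-derived loci.
#' @param candidates ancestor track indices to try first.
#' @param previous length-2 integer of the individual's previous (h1, h2)
#'   assignment in this segment (usage is released before reselection).
#' @return list with the updated \code{library} and the selected \code{h1}
#'   and \code{h2} track indices.
#' @export
processIndividual <- function(lib, nA, nB, cfg = ModelConfig(),
                              arrayFlags = NULL,
                              candidates = integer(0),
                              previous = c(NA_integer_, NA_integer_)) {
  len <- lib@end - lib@start
  if (is.null(arrayFlags)) arrayFlags <- rep(FALSE, len)
  if (!is.na(previous[1L])) {
    lib@usage[previous[1L]] <- lib@usage[previous[1L]] - 1L
    lib@usage[previous[2L]] <- lib@usage[previous[2L]] - 1L
  }
  obs <- which(nA + nB > 0L)
  if (length(obs) == 0L) {
    if (nTracks(lib) == 0L) {
      a1 <- admitHaplotype(lib); lib <- a1$library
      a2 <- admitHaplotype(lib); lib <- a2$library
      return(list(library = lib, h1 = a1$id, h2 = a2$id))
    }
    top <- order(-lib@usage)
    h1 <- top[1L]
    h2 <- if (length(top) > 1L) top[2L] else top[1L]
    lib@usage[h1] <- lib@usage[h1] + 1L
    lib@usage[h2] <- lib@usage[h2] + 1L
    return(list(library = lib, h1 = h1, h2 = h2))
  }
  h1 <- selectH1(lib, nA, nB, cfg, arrayFlags, candidates)
  if (is.na(h1)) {
    adm <- admitHaplotype(lib)
    lib <- adm$library
    h1 <- adm$id
  } else {
    lib@usage[h1] <- lib@usage[h1] + 1L
  }
  h2 <- selectH2(lib, nA, nB, h1, cfg, arrayFlags, candidates)
  if (is.na(h2)) {
    prior <- lib@freqs
    arrObs <- obs[arrayFlags[obs]]
    if (length(arrObs)) {
      # complement seeding: remove H1's allele from the called genotype
      # (floor(x + 0.5): a half-certain H1 allele counts as A)
      g <- floor(2 * nA[arrObs] / (nA[arrObs] + nB[arrObs]) + 0.5)
      a1 <- floor(lib@probs[arrObs, h1] + 0.5)
      prior[arrObs] <- pmin(pmax(g - a1, 0), 1)
    }
    adm <- admitHaplotype(lib, prior = prior)
    lib <- adm$library
    h2 <- adm$id
  } else {
    lib@usage[h2] <- lib@usage[h2] + 1L
  }
  err <- ifelse(arrayFlags[obs], cfg@arrayErrate, cfg@errate)
  L <- .asLikMat(readLikelihoods(nA[obs], nB[obs], err, coef = FALSE))
  upd <- posteriorPairUpdate(lib@probs[obs, h1], lib@probs[obs, h2], L,
                             clamp = cfg@clamp)
  lib@probs[obs, h1] <- upd$p1
  lib@probs[obs, h2] <- upd$p2
  if (h1 == h2) lib@probs[obs, h1] <- upd$p1   # symmetric; single write
  list(library = lib, h1 = h1, h2 = h2)
}

## One population pass over a window, R reference engine. lib is a plain
## list(probs, usage); h1/h2 are per-individual assignments for this window.
.windowPassR <- function(nAw, nBw, arrW, ord, sireIdx, damIdx,
                         probs, usage, h1, h2, freqs, cfg) {
  lib <- new("HaplotypeLibrary", start = 0L, end = nrow(nAw),
             probs = probs, usage = usage, freqs = freqs)
  for (i in ord) {
    cand <- candidateOrder(i, h1, h2, sireIdx, damIdx, nTracks(lib))
    prev <- c(h1[i], h2[i])
    res <- processIndividual(lib, nAw[, i], nBw[, i], cfg, arrW[, i],
                             candidates = cand, previous = prev)
    lib <- res$library
    h1[i] <- res$h1
    h2[i] <- res$h2
  }
  list(probs = lib@probs, usage = lib@usage, h1 = h1, h2 = h2)
}

.initialFrequencies <- function(nA, nB, errate) {
  sA <- rowSums(nA)
  sB <- rowSums(nB)
  tot <- sA + sB
  freq <- ifelse(tot > 0, sA / tot, 0.5)
  minor <- pmin(sA, sB)
  snap <- tot > 0 & minor <= errate * tot
  list(freq = freq, snapIdx = which(snap), snapVal = round(freq[snap]))
}

#' Run the full phasing and imputation pipeline
#'
#' Initializes site frequencies from simple allele counts, then for each
#' window length of the schedule runs \code{itersPerStep} passes over the
#' individuals in pedigree order. In every pass each individual's H1 and H2
#' are (re)selected from the window's haplotype library and updated with
#' its read data; after each pass site frequencies are re-estimated as the
#' usage-weighted mean of track posteriors (with near-monomorphic sites
#' pinned, since observed minor alleles at or below the error expectation
#' carry no evidence of polymorphism) and libraries are resorted by
#' descending usage. Final genotypes are called from the last (shortest)
#' window length's libraries.
#'
#' @param x a \linkS4class{SeqDepthSet}.
#' @param plan a \linkS4class{SegmentPlan}; default ladder over
#'   \code{nrow(x)} sites.
#' @param cfg a \linkS4class{ModelConfig}.
#' @param engine "cpp" (compiled fast path) or "r" (reference
#'   implementation of the identical algorithm).
#' @param verbose log one line per pass (window length, library sizes,
#'   admissions).
#' @return A \linkS4class{GenotypeCalls}; \code{metadata()} carries the
#'   final \code{libraries} (list of \linkS4class{HaplotypeLibrary}),
#'   \code{assignments} (list of h1/h2 matrices, windows x individuals),
#'   \code{windows}, \code{frequencies}, \code{plan} and \code{cfg}.
#' @examples
#' sim <- simulateDataset(SimConfig(nSeq = 8, nArray = 0, nSites = 60,
#'                                  chipSize = 6, meanDepth = 16,
#'                                  errate = 0, nGenerations = 2,
#'                                  nSires = 2, seed = 4))
#' calls <- runPipeline(sim, SegmentPlan(60, minLen = 30, maxLen = 60,
#'                                       itersPerStep = 2),
#'                      ModelConfig(errate = 1e-4))
#' percentCorrect(genotypeMatrix(calls), trueGenotypes(sim))
#' @export
runPipeline <- function(x, plan = NULL, cfg = ModelConfig(),
                        engine = c("cpp", "r"), verbose = FALSE) {
  engine <- match.arg(engine)
  if (is.null(plan)) plan <- SegmentPlan(nrow(x))
  stopifnot(plan@nSites == nrow(x))
  nA <- depthA(x); nB <- depthB(x); arr <- arrayDerived(x)
  ped <- pedigree(x)
  nInd <- ncol(x)
  ord <- orderIndividuals(ped)
  pidx <- .parentIdx(ped)
  init <- .initialFrequencies(nA, nB, cfg@errate)
  freq <- init$freq
  state <- NULL
  for (li in seq_along(plan@lengths)) {
    wins <- plan@windows[[li]]
    nW <- nrow(wins)
    state <- list(
      probs = vector("list", nW),
      usage = vector("list", nW),
      h1 = matrix(NA_integer_, nW, nInd,
                  dimnames = list(NULL, colnames(x))),
      h2 = matrix(NA_integer_, nW, nInd,
                  dimnames = list(NULL, colnames(x)))
    )
    for (w in seq_len(nW)) {
      len <- wins[w, 2L] - wins[w, 1L]
      state$probs[[w]] <- matrix(numeric(0), len, 0)
      state$usage[[w]] <- integer(0)
    }
    for (it in seq_len(plan@itersPerStep)) {
      admitted <- 0L
      for (w in seq_len(nW)) {
        rows <- (wins[w, 1L] + 1L):wins[w, 2L]
        before <- length(state$usage[[w]])
        res <- if (engine == "cpp") {
          cpp_window_pass(nA[rows, , drop = FALSE],
                          nB[rows, , drop = FALSE],
                          arr[rows, , drop = FALSE],
                          ord - 1L,
                          ifelse(is.na(pidx$sire), -1L, pidx$sire - 1L),
                          ifelse(is.na(pidx$dam), -1L, pidx$dam - 1L),
                          state$probs[[w]], state$usage[[w]],
                          ifelse(is.na(state$h1[w, ]), -1L,
                                 state$h1[w, ] - 1L),
                          ifelse(is.na(state$h2[w, ]), -1L,
                                 state$h2[w, ] - 1L),
                          freq[rows], cfg@errate, cfg@arrayErrate,
                          cfg@clamp)
        } else {
          .windowPassR(nA[rows, , drop = FALSE], nB[rows, , drop = FALSE],
                       arr[rows, , drop = FALSE], ord, pidx$sire,
                       pidx$dam, state$probs[[w]], state$usage[[w]],
                       state$h1[w, ], state$h2[w, ], freq[rows], cfg)
        }
        if (engine == "cpp") {
          res$h1 <- ifelse(res$h1 < 0L, NA_integer_, res$h1 + 1L)
          res$h2 <- ifelse(res$h2 < 0L, NA_integer_, res$h2 + 1L)
        }
        state$probs[[w]] <- res$probs
        state$usage[[w]] <- as.integer(res$usage)
        state$h1[w, ] <- res$h1
        state$h2[w, ] <- res$h2
        admitted <- admitted + length(res$usage) - before
        # usage-weighted frequency re-estimation for this window's sites
        tu <- sum(res$usage)
        if (tu > 0)
          freq[rows] <- as.vector(res$probs %*% res$usage) / tu
      }
      freq[init$snapIdx] <- init$snapVal
      freq <- pmin(pmax(freq, 0), 1)
      # resort libraries by descending usage, remapping assignments
      for (w in seq_len(nW)) {
        lib <- new("HaplotypeLibrary", start = wins[w, 1L],
                   end = wins[w, 2L], probs = state$probs[[w]],
                   usage = state$usage[[w]],
                   freqs = freq[(wins[w, 1L] + 1L):wins[w, 2L]])
        rs <- resortLibrary(lib, rbind(state$h1[w, ], state$h2[w, ]))
        state$probs[[w]] <- rs$library@probs
        state$usage[[w]] <- rs$library@usage
        state$h1[w, ] <- rs$assignments[1L, ]
        state$h2[w, ] <- rs$assignments[2L, ]
      }
      if (verbose)
        message(sprintf(
          "pass: len=%d iter=%d windows=%d tracks=%d admitted=%d",
          plan@lengths[li], it, nW,
          sum(vapply(state$usage, length, 1L)), admitted))
    }
  }
  wins <- plan@windows[[length(plan@lengths)]]
  libs <- lapply(seq_len(nrow(wins)), function(w) {
    new("HaplotypeLibrary", start = wins[w, 1L], end = wins[w, 2L],
        probs = state$probs[[w]], usage = state$usage[[w]],
        freqs = freq[(wins[w, 1L] + 1L):wins[w, 2L]])
  })
  assignments <- list(h1 = state$h1, h2 = state$h2)
  calls <- callGenotypes(x, libs, assignments, cfg)
  md <- metadata(calls)
  md$libraries <- libs
  md$assignments <- assignments
  md$windows <- wins
  md$frequencies <- freq
  md$plan <- plan
  md$cfg <- cfg
  metadata(calls) <- md
  calls
}

#' Call genotypes from haplotype assignments and read counts
#'
#' Per site and individual, the two assigned tracks give the genotype prior
#' (P(AA) = q1 q2 etc.); it is combined with the individual's own
#' read-count likelihoods by Bayes' rule. The best call is the posterior
#' argmax (ties broken toward the heterozygote); a call is missing when the
#' posterior is essentially uniform. Dosage is the posterior expected count
#' of A alleles.
#'
#' @param x a \linkS4class{SeqDepthSet}.
#' @param libs list of \linkS4class{HaplotypeLibrary} objects tiling the
#'   chromosome.
#' @param assignments list with matrices \code{h1}, \code{h2} (windows x
#'   individuals) of track indices.
#' @param cfg a \linkS4class{ModelConfig}.
#' @param priorFloor floor applied to the track probabilities when forming
#'   the genotype prior at call time. Tracks saturate towards 0/1 as
#'   evidence accumulates, but a track can be locally wrong for an
#'   individual (e.g. across a crossover boundary inside a window), so the
#'   prior odds contributed by the haplotype pair are capped at roughly
#'   \code{1/priorFloor}; a handful of error-free reads can then still
#'   override a locally wrong prior. Selection and updating are unaffected.
#' @return A \linkS4class{GenotypeCalls}.
#' @export
callGenotypes <- function(x, libs, assignments, cfg = ModelConfig(),
                          priorFloor = 1e-3) {
  nA <- depthA(x); nB <- depthB(x); arr <- arrayDerived(x)
  nInd <- ncol(x); nSites <- nrow(x)
  q1 <- matrix(NA_real_, nSites, nInd)
  q2 <- matrix(NA_real_, nSites, nInd)
  for (w in seq_along(libs)) {
    lib <- libs[[w]]
    rows <- (lib@start + 1L):lib@end
    fw <- lib@freqs
    base <- matrix(fw, length(rows), nInd)
    i1 <- assignments$h1[w, ]; i2 <- assignments$h2[w, ]
    ok1 <- !is.na(i1); ok2 <- !is.na(i2)
    if (any(ok1)) base[, ok1] <- lib@probs[, i1[ok1], drop = FALSE]
    q1[rows, ] <- base
    base <- matrix(fw, length(rows), nInd)
    if (any(ok2)) base[, ok2] <- lib@probs[, i2[ok2], drop = FALSE]
    q2[rows, ] <- base
  }
  q1 <- .clamp01(q1, max(cfg@clamp, priorFloor))
  q2 <- .clamp01(q2, max(cfg@clamp, priorFloor))
  e <- ifelse(arr, cfg@arrayErrate, cfg@errate)
  lAA <- (1 - e)^nA * e^nB
  lAB <- 0.5^(nA + nB)
  lBB <- e^nA * (1 - e)^nB
  jAA <- q1 * q2 * lAA
  jAB <- (q1 + q2 - 2 * q1 * q2) * lAB
  jBB <- (1 - q1) * (1 - q2) * lBB
  tot <- jAA + jAB + jBB
  tot[tot == 0] <- NA_real_
  pAA <- jAA / tot; pAB <- jAB / tot; pBB <- jBB / tot
  dosage <- 2 * pAA + pAB
  mx <- pmax(pAA, pAB, pBB)
  geno <- ifelse(pAB >= mx, 1L, ifelse(pAA >= pBB, 2L, 0L))
  geno[is.na(tot) | mx < 1 / 3 + 1e-9] <- NA_integer_
  dimnames(geno) <- dimnames(dosage) <- dimnames(nA)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = geno, dosage = dosage,
                  pAA = pAA, pAB = pAB, pBB = pBB),
    rowData = SummarizedExperiment::rowData(x),
    colData = SummarizedExperiment::colData(x))
  new("GenotypeCalls", se)
}

#' Impute additional individuals against a frozen haplotype library
#'
#' Incremental mode: the exported libraries from a previous run are used as
#' a fixed reference panel. Individuals without an assignment are given H1
#' and H2 by the usual likelihood-ratio selection (admitting a private
#' track when nothing qualifies), but no posterior updates are written, so
#' calls for previously processed individuals are unchanged.
#'
#' @param x a \linkS4class{SeqDepthSet} containing both old and new
#'   individuals.
#' @param libs list of \linkS4class{HaplotypeLibrary} objects (e.g. from
#'   \code{\link{importLibrary}} or \code{metadata(calls)$libraries}).
#' @param assignments assignment matrices from the previous run; columns
#'   are matched to \code{colnames(x)} by name.
#' @param cfg a \linkS4class{ModelConfig}.
#' @return A \linkS4class{GenotypeCalls} for all individuals in \code{x}.
#' @export
augmentPipeline <- function(x, libs, assignments, cfg = ModelConfig()) {
  nA <- depthA(x); nB <- depthB(x); arr <- arrayDerived(x)
  nInd <- ncol(x)
  nW <- length(libs)
  h1 <- matrix(NA_integer_, nW, nInd, dimnames = list(NULL, colnames(x)))
  h2 <- h1
  oldIds <- intersect(colnames(assignments$h1), colnames(x))
  h1[, oldIds] <- assignments$h1[, oldIds]
  h2[, oldIds] <- assignments$h2[, oldIds]
  ped <- pedigree(x)
  pidx <- .parentIdx(ped)
  newIdx <- which(!(colnames(x) %in% oldIds))
  for (w in seq_len(nW)) {
    lib <- libs[[w]]
    rows <- (lib@start + 1L):lib@end
    for (i in newIdx) {
      cand <- candidateOrder(i, h1[w, ], h2[w, ], pidx$sire, pidx$dam,
                             nTracks(lib))
      s1 <- selectH1(lib, nA[rows, i], nB[rows, i], cfg, arr[rows, i],
                     cand)
      if (is.na(s1)) {
        adm <- admitHaplotype(lib); lib <- adm$library; s1 <- adm$id
      }
      s2 <- selectH2(lib, nA[rows, i], nB[rows, i], s1, cfg, arr[rows, i],
                     cand)
      if (is.na(s2)) {
        adm <- admitHaplotype(lib); lib <- adm$library; s2 <- adm$id
      }
      h1[w, i] <- s1; h2[w, i] <- s2
    }
    libs[[w]] <- lib
  }
  calls <- callGenotypes(x, libs, list(h1 = h1, h2 = h2), cfg)
  md <- metadata(calls)
  md$libraries <- libs
  md$assignments <- list(h1 = h1, h2 = h2)
  metadata(calls) <- md
  calls
}

#' Export Hardy-Weinberg genotype probabilities
#'
#' Writes per-(individual, site) genotype posterior triples computed from
#' the read counts and per-site allele frequencies under Hardy-Weinberg
#' priors (the input format expected by genotype-probability based
#' imputation software). Missing sites receive the HWE priors themselves.
#'
#' @param x a \linkS4class{SeqDepthSet}.
#' @param path output TSV path (columns: individual, site, pAA, pAB, pBB).
#' @param cfg a \linkS4class{ModelConfig}.
#' @param freqs per-site A-allele frequencies; default: simple allele
#'   counts pooled over individuals.
#' @return invisibly, \code{path}.
#' @export
exportGenotypeProbabilities <- function(x, path, cfg = ModelConfig(),
                                        freqs = NULL) {
  nA <- depthA(x); nB <- depthB(x); arr <- arrayDerived(x)
  if (is.null(freqs)) {
    tot <- rowSums(nA) + rowSums(nB)
    freqs <- ifelse(tot > 0, rowSums(nA) / tot, 0.5)
  }
  p <- pmin(pmax(freqs, 0), 1)
  e <- ifelse(arr, cfg@arrayErrate, cfg@errate)
  lAA <- (1 - e)^nA * e^nB
  lAB <- 0.5^(nA + nB)
  lBB <- e^nA * (1 - e)^nB
  jAA <- p^2 * lAA
  jAB <- 2 * p * (1 - p) * lAB
  jBB <- (1 - p)^2 * lBB
  tot <- jAA + jAB + jBB
  out <- data.frame(
    individual = rep(colnames(x), each = nrow(x)),
    site = rep(seq_len(nrow(x)) - 1L, ncol(x)),
    pAA = as.vector(jAA / tot),
    pAB = as.vector(jAB / tot),
    pBB = as.vector(jBB / tot)
  )
  utils::write.table(format(out, digits = 6), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
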