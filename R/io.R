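## File formats: native TSV dialects (counts, pedigree, site map) and
## VCF 4.2 (AD in; GT:DS:GP out). Internal coordinates are 0-based
## half-open; VCF I/O is 1-based. Allele orientation is fixed at load:
## REF -> A, ALT -> B.

#' Read a sparse allele-depth table
#'
#' TSV with columns \code{individual}, \code{site} (0-based index),
#' \code{nA}, \code{nB}; absent (individual, site) pairs are missing
#' (0, 0). Malformed rows are rejected with their line number.
#'
#' @param path TSV path (a header row is detected and skipped).
#' @return data.frame with columns \code{individual}, \code{site},
#'   \code{nA}, \code{nB}.
#' @export
readCountsTsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty counts file: ", path)
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  skip <- if (any(is.na(suppressWarnings(as.integer(first[2:4]))))) 1L else 0L
  df <- utils::read.table(path, sep = "\t", header = skip == 1L,
                          stringsAsFactors = FALSE,
                          col.names = c("individual", "site", "nA", "nB"))
  bad <- which(is.na(df$site) | is.na(df$nA) | is.na(df$nB) |
                 df$nA < 0 | df$nB < 0 | df$site < 0)
  if (length(bad))
    stop("invalid counts at ", path, " line ", bad[1L] + skip)
  df
}

#' Assemble count matrices from a sparse table
#'
#' @param df data.frame from \code{\link{readCountsTsv}}.
#' @param individuals individual ids defining column order.
#' @param nSites number of sites.
#' @return list of integer matrices \code{nA}, \code{nB}.
#' @export
countsToMatrices <- function(df, individuals, nSites) {
  col <- match(df$individual, individuals)
  if (anyNA(col))
    stop("unknown individual: ", df$individual[which(is.na(col))[1L]])
  if (any(df$site >= nSites))
    stop("site index out of range: ", max(df$site))
  nA <- matrix(0L, nSites, length(individuals),
               dimnames = list(NULL, individuals))
  nB <- nA
  idx <- cbind(df$site + 1L, col)
  nA[idx] <- as.integer(df$nA)
  nB[idx] <- as.integer(df$nB)
  list(nA = nA, nB = nB)
}

#' Read allele depths from a VCF
#'
#' Uses the per-sample AD field: the first value maps to the A (REF)
#' count, the second to the B (ALT) count. Sites or samples without AD
#' become missing (0, 0).
#'
#' @param path VCF path (plain text or gzipped).
#' @return list with integer matrices \code{nA}, \code{nB} (sites x
#'   samples) and a \code{siteMap} data.frame (pos, ref, alt).
#' @export
readVcfCounts <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  split2 <- function(k) {
    v <- suppressWarnings(
      as.integer(vapply(strsplit(ifelse(is.na(ad), "0,0", ad), ",",
                                 fixed = TRUE),
                        function(z) if (length(z) >= k) z[k] else "0",
                        character(1L))))
    v[is.na(v)] <- 0L
    matrix(v, nrow(ad), ncol(ad), dimnames = dimnames(ad))
  }
  nA <- split2(1L)
  nB <- split2(2L)
  map <- data.frame(pos = as.integer(vcf@fix[, "POS"]),
                    ref = vcf@fix[, "REF"], alt = vcf@fix[, "ALT"])
  list(nA = nA, nB = nB, siteMap = map)
}

#' Read and validate a pedigree file
#'
#' TSV with columns \code{id}, \code{sire}, \code{dam}, \code{birth};
#' "0", "." or empty mean unknown parent. Duplicate ids and pedigree
#' cycles are errors; a shared sire/dam raises a warning.
#'
#' @param path TSV path (a header row is detected and skipped).
#' @return validated pedigree data.frame.
#' @export
readPedigree <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty pedigree file: ", path)
  hasHeader <- grepl("^id\\b", lines[1L])
  if (hasHeader) {
    ped <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("id", "sire", "dam")
    if (!all(need %in% names(ped)))
      stop("pedigree header must name columns id, sire, dam")
    if (is.null(ped$birth)) ped$birth <- seq_len(nrow(ped))
    ped$birth <- as.numeric(ped$birth)
  } else {
    ped <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("id", "sire", "dam", "birth"),
                             colClasses = c("character", "character",
                                            "character", "numeric"))
  }
  norm <- function(v) { v[v %in% c("0", ".", "")] <- NA_character_; v }
  ped$sire <- norm(ped$sire)
  ped$dam <- norm(ped$dam)
  dup <- duplicated(ped$id)
  if (any(dup))
    stop("duplicate individual id at ", path, " line ",
         which(dup)[1L] + hasHeader, ": ", ped$id[dup][1L])
  shared <- !is.na(ped$sire) & !is.na(ped$dam) & ped$sire == ped$dam
  if (any(shared))
    warning("sire equals dam for: ",
            paste(ped$id[shared], collapse = ", "))
  orderIndividuals(ped)   # cycle check
  ped
}

#' Write genotype calls as VCF 4.2
#'
#' FORMAT GT:DS:GP with DS the dosage of the ALT allele (2 minus the
#' reference-allele dosage) and GP the genotype probability triple in
#' 0/0, 0/1, 1/1 order. Positions come from the site map (1-based).
#'
#' @param calls a \linkS4class{GenotypeCalls}.
#' @param path output path.
#' @param chrom chromosome label.
#' @return invisibly, \code{path}.
#' @export
writeVcf <- function(calls, path, chrom = "1") {
  g <- genotypeMatrix(calls)
  ds <- 2 - dosageMatrix(calls)
  pAA <- SummarizedExperiment::assay(calls, "pAA")
  pAB <- SummarizedExperiment::assay(calls, "pAB")
  pBB <- SummarizedExperiment::assay(calls, "pBB")
  rd <- SummarizedExperiment::rowData(calls)
  pos <- if (!is.null(rd$pos)) rd$pos else seq_len(nrow(g))
  ref <- if (!is.null(rd$ref)) rd$ref else rep("A", nrow(g))
  alt <- if (!is.null(rd$alt)) rd$alt else rep("C", nrow(g))
  gt <- matrix("./.", nrow(g), ncol(g))
  gt[!is.na(g) & g == 2L] <- "0/0"
  gt[!is.na(g) & g == 1L] <- "0/1"
  gt[!is.na(g) & g == 0L] <- "1/1"
  fmt3 <- function(x) ifelse(is.na(x), ".", sprintf("%.4f", x))
  cells <- matrix(paste0(gt, ":", fmt3(ds), ":", fmt3(pAA), ",",
                         fmt3(pAB), ",", fmt3(pBB)),
                  nrow(g), ncol(g))
  body <- paste(chrom, pos, paste0("site", seq_len(nrow(g)) - 1L),
                ref, alt, ".", "PASS", ".", "GT:DS:GP",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,Description=",
           "\"Dosage of the ALT allele\">"),
    paste0("##FORMAT=<ID=GP,Number=G,Type=Float,Description=",
           "\"Genotype posterior probabilities\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write called genotypes and dosages as TSV
#'
#' @param calls a \linkS4class{GenotypeCalls}.
#' @param prefix output path prefix; writes \code{<prefix>_calls.tsv} and
#'   \code{<prefix>_dosage.tsv} (sites x individuals, site index in the
#'   first column).
#' @return invisibly, the two paths.
#' @export
writeCallsTsv <- function(calls, prefix) {
  g <- genotypeMatrix(calls)
  d <- dosageMatrix(calls)
  p1 <- paste0(prefix, "_calls.tsv")
  p2 <- paste0(prefix, "_dosage.tsv")
  utils::write.table(data.frame(site = seq_len(nrow(g)) - 1L, g,
                                check.names = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(site = seq_len(nrow(d)) - 1L,
                                round(d, 4), check.names = FALSE),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
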