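# FASTQ input and paired-end overlap merging.
#
# Parsing goes through Biostrings; reads are carried as
# QualityScaledDNAStringSet (Phred+33). Merging is an overlap-consensus
# join in the style of fastq-join: the best overlap (minimum mismatch
# fraction, ties to the longest) is accepted when its mismatch fraction
# stays within a bound, and disagreements are resolved toward the
# higher-quality base.

#' Read a FASTQ file
#'
#' Reads plain or gzip-compressed FASTQ with Phred+33 qualities.
#'
#' @param path FASTQ(.gz) file.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastqReads <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  # cheap structural sanity check up front: Biostrings quietly tolerates
  # a trailing truncated record, which must instead be a hard error
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  nlines <- length(readLines(con, warn = FALSE))
  close(con)
  if (nlines %% 4L != 0L)
    stop("truncated FASTQ record at record ", nlines %/% 4L + 1L,
         " in ", path)
  x <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred"),
      error = function(e)
        stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
             call. = FALSE)),
    # benign internal notice when qualities are attached to the set
    warning = function(w) {
      if (grepl("metadata columns.*dropped", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  bad <- which(BiocGenerics::width(x) !=
                 BiocGenerics::width(Biostrings::quality(x)))
  if (length(bad))
    stop("sequence/quality length mismatch at record ", bad[1L],
         " in ", path)
  x
}

# per-read integer Phred scores from a QualityScaledDNAStringSet
phredScores <- function(reads) {
  as(Biostrings::quality(reads), "IntegerList")
}

#' Merge one read pair by overlap consensus
#'
#' Reverse-complements the second read (reversing its qualities), then
#' scans every overlap length from \code{minOverlap} up to the shorter
#' read length for the overlap minimizing the mismatch fraction (ties
#' broken toward the longest overlap). The pair is merged when the best
#' mismatch fraction is at most \code{maxMismatchFrac}; at disagreeing
#' overlap positions the higher-quality base wins (tie: read 1's base)
#' and the consensus quality is the maximum of the two.
#'
#' Rejections carry a reason: \code{"no_overlap"} when no candidate
#' overlap exists or the best overlap is indistinguishable from chance
#' (mismatch fraction \eqn{\ge} 0.5), otherwise \code{"mismatch"}.
#'
#' @param bases1,bases2 Read sequences (character scalars).
#' @param quals1,quals2 Integer Phred scores, same lengths as the bases.
#' @param minOverlap Minimum overlap length (default 6).
#' @param maxMismatchFrac Maximum mismatch fraction in the overlap
#'   (default 0.08).
#' @return A list: \code{status} (\code{"merged"}, \code{"no_overlap"} or
#'   \code{"mismatch"}); on success also \code{bases}, \code{quals} and
#'   \code{overlap}.
#' @export
mergePair <- function(bases1, quals1, bases2, quals2,
                      minOverlap = 6L, maxMismatchFrac = 0.08) {
  n1 <- nchar(bases1); n2 <- nchar(bases2)
  if (n1 == 0L || n2 == 0L) stop("reads must be non-empty")
  stopifnot(length(quals1) == n1, length(quals2) == n2)
  b2 <- revcompChar(bases2)
  q2 <- rev(quals2)
  maxO <- min(n1, n2)
  if (maxO < minOverlap)
    return(list(status = "no_overlap"))
  c1 <- strsplit(bases1, "")[[1L]]
  c2 <- strsplit(b2, "")[[1L]]
  bestFrac <- Inf; bestO <- 0L
  for (o in minOverlap:maxO) {
    mm <- sum(c1[(n1 - o + 1L):n1] != c2[1L:o])
    frac <- mm / o
    if (frac < bestFrac || (frac == bestFrac && o > bestO)) {
      bestFrac <- frac; bestO <- o
    }
  }
  if (bestFrac > maxMismatchFrac) {
    return(list(status = if (bestFrac >= 0.5) "no_overlap" else "mismatch",
                overlap = bestO, mismatch_frac = bestFrac))
  }
  o <- bestO
  i1 <- (n1 - o + 1L):n1   # overlap indices in read 1
  i2 <- 1L:o               # overlap indices in revcomp'd read 2
  consBase <- c1[i1]
  consQual <- pmax(quals1[i1], q2[i2])
  dis <- which(c1[i1] != c2[i2])
  if (length(dis)) {
    useR2 <- q2[i2][dis] > quals1[i1][dis]
    consBase[dis[useR2]] <- c2[i2][dis[useR2]]
  }
  bases <- paste0(substr(bases1, 1L, n1 - o),
                  paste(consBase, collapse = ""),
                  substr(b2, o + 1L, n2))
  quals <- c(quals1[seq_len(n1 - o)], consQual,
             q2[seq(o + 1L, length.out = n2 - o)])
  list(status = "merged", bases = bases, quals = quals, overlap = o)
}

#' Merge paired-end FASTQ read sets
#'
#' Applies [mergePair()] to each read pair; unmergeable pairs are
#' dropped and counted by reason.
#'
#' @param r1,r2 [Biostrings::QualityScaledDNAStringSet] (same length),
#'   or FASTQ(.gz) paths.
#' @param minOverlap,maxMismatchFrac See [mergePair()].
#' @return A list: \code{reads} (merged
#'   [Biostrings::QualityScaledDNAStringSet], named by read 1 ids) and
#'   \code{report} (integer vector \code{pairs_in}, \code{merged},
#'   \code{rejected_no_overlap}, \code{rejected_mismatch}).
#' @export
mergePairs <- function(r1, r2, minOverlap = 6L, maxMismatchFrac = 0.08) {
  if (is.character(r1)) r1 <- readFastqReads(r1)
  if (is.character(r2)) r2 <- readFastqReads(r2)
  if (length(r1) != length(r2))
    stop("paired FASTQ files must contain the same number of reads")
  b1 <- as.character(r1); b2 <- as.character(r2)
  q1 <- phredScores(r1); q2 <- phredScores(r2)
  ids <- if (!is.null(names(r1))) names(r1) else
    paste0("read_", seq_along(r1))
  outBases <- character(0); outQuals <- list(); outIds <- character(0)
  nNoOv <- 0L; nMm <- 0L
  for (i in seq_along(b1)) {
    m <- mergePair(b1[i], q1[[i]], b2[i], q2[[i]],
                   minOverlap = minOverlap,
                   maxMismatchFrac = maxMismatchFrac)
    if (m$status == "merged") {
      outBases <- c(outBases, m$bases)
      outQuals[[length(outQuals) + 1L]] <- m$quals
      outIds <- c(outIds, ids[i])
    } else if (m$status == "no_overlap") nNoOv <- nNoOv + 1L
    else nMm <- nMm + 1L
  }
  reads <- makeQualityReads(outBases, outQuals, outIds)
  list(reads = reads,
       report = c(pairs_in = length(b1), merged = length(outBases),
                  rejected_no_overlap = nNoOv, rejected_mismatch = nMm))
}

# build a QualityScaledDNAStringSet from character bases + integer quals
makeQualityReads <- function(bases, quals, ids = NULL) {
  if (length(bases) == 0L) {
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0))))
  }
  qstr <- vapply(quals, function(q)
    rawToChar(as.raw(pmin(pmax(q, 0L), 93L) + 33L)), character(1L))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(bases), Biostrings::PhredQuality(qstr))
  if (!is.null(ids)) names(x) <- ids
  x
}

#' Write reads to FASTQ
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output path; \code{.gz} suffix triggers compression.
#' @export
writeFastqReads <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}
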