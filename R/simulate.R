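# Synthetic fixtures: toy genomes with planted off-target sites and
# simulated base-edited amplicon reads with known ground truth. All
# randomness is drawn from R's Mersenne-Twister generator under a caller
# seed; the caller's RNG state is restored afterwards.

withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

randomDna <- function(n) {
  paste(sample(ACGT, n, replace = TRUE), collapse = "")
}

# mutate exactly `k` distinct spacer positions, each to a different base
mutateSpacer <- function(spacer, k) {
  chars <- strsplit(spacer, "")[[1L]]
  if (k > length(chars)) stop("more mismatches requested than spacer bases")
  if (k > 0L) {
    at <- sample(seq_along(chars), k)
    for (i in at)
      chars[i] <- sample(setdiff(ACGT, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a toy genome with planted off-target sites
#'
#' Builds random ACGT records and writes each requested site (spacer +
#' PAM, with exactly the requested number of spacer mismatches) at a
#' recorded, non-overlapping coordinate on the requested strand. The
#' returned truth table gives each planted protospacer's forward-strand
#' position in the convention of [findOffTargets()].
#'
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param nRecords Number of FASTA records.
#' @param recordLength Length of each record (nt).
#' @param plantedSites List of \code{list(spacer=, pam=, mismatches=,
#'   strand=)}; \code{pam} must be a concrete ACGT realization of the
#'   profile's PAM pattern.
#' @param profile [NucleaseProfile-class] or registry name (fixes the
#'   PAM side for site layout).
#' @param path Optional path; when given the genome is written there as
#'   FASTA and the path is returned in the result.
#' @return A list: \code{genome} ([Biostrings::DNAStringSet]),
#'   \code{truth} (data.frame \code{seq_name}, \code{position} (0-based
#'   forward-strand protospacer start), \code{strand},
#'   \code{mismatches}, \code{site_spacer}, \code{site_pam}) and
#'   \code{path} (or \code{NA}).
#' @export
makeToyGenome <- function(seed, nRecords = 1L, recordLength = 10000L,
                          plantedSites = list(), profile = "SpCas9",
                          path = NULL) {
  if (is.character(profile)) profile <- nucleaseProfile(profile)
  threePrime <- profile@pamSide == "three_prime"
  withSeed(seed, {
    records <- vapply(seq_len(nRecords), function(i)
      randomDna(recordLength), character(1L))
    names(records) <- paste0("rec", seq_len(nRecords))
    truth <- list()
    occupied <- vector("list", nRecords)
    for (site in plantedSites) {
      siteLen <- nchar(site$spacer) + nchar(site$pam)
      if (siteLen > recordLength)
        stop("planted site longer than record")
      rec <- sample.int(nRecords, 1L)
      # rejection-sample a non-overlapping placement
      for (try in 1:1000) {
        p <- sample.int(recordLength - siteLen + 1L, 1L)
        iv <- p:(p + siteLen - 1L)
        if (!any(iv %in% occupied[[rec]])) break
        if (try == 1000L) stop("could not place site without overlap")
      }
      occupied[[rec]] <- c(occupied[[rec]], iv)
      mutSpacer <- mutateSpacer(site$spacer, site$mismatches)
      onStrand <- if (threePrime) paste0(mutSpacer, site$pam) else
        paste0(site$pam, mutSpacer)
      written <- if (site$strand == "+") onStrand else revcompChar(onStrand)
      substr(records[rec], p, p + siteLen - 1L) <- written
      pamLen <- nchar(site$pam)
      spacerStart0 <- if (site$strand == "+") {
        if (threePrime) p - 1L else p - 1L + pamLen
      } else {
        if (threePrime) p - 1L + pamLen else p - 1L
      }
      truth[[length(truth) + 1L]] <- data.frame(
        seq_name = names(records)[rec], position = spacerStart0,
        strand = site$strand, mismatches = as.integer(site$mismatches),
        site_spacer = mutSpacer, site_pam = site$pam,
        stringsAsFactors = FALSE)
    }
    genome <- Biostrings::DNAStringSet(records)
    truthDf <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seq_name = character(), position = integer(),
                 strand = character(), mismatches = integer(),
                 site_spacer = character(), site_pam = character(),
                 stringsAsFactors = FALSE)
    if (!is.null(path)) Biostrings::writeXStringSet(genome, path)
    list(genome = genome, truth = truthDf,
         path = if (is.null(path)) NA_character_ else path)
  })
}

#' Simulate base-edited amplicon reads
#'
#' Draws reads from the reference amplicon with independent per-read,
#' per-position edits: the editor's intended conversion (edited base to
#' the primary product, C\eqn{\to}T for a CBE / A\eqn{\to}G for an ABE)
#' at editable window positions with probability \code{intendedProb},
#' bystander conversions at editable flank positions with probability
#' \code{bystanderProb}, indels at the nominal cut site (3 bp from the
#' PAM-proximal protospacer edge) with probability \code{indelProb} and
#' geometric lengths, and uniform per-base sequencing errors with
#' probability \code{errorRate}. Qualities are constant Phred
#' \code{phred}. In paired mode, R1/R2 are the two amplicon ends read
#' inward with an overlap, and merge back losslessly at zero error.
#'
#' @param config An [AnalysisConfig-class] (fixes reference, target and
#'   window geometry).
#' @param n Number of reads (or read pairs).
#' @param seed Integer seed; identical seeds give identical output.
#' @param intendedProb Per-position intended-edit probability.
#' @param bystanderProb Per-position bystander-edit probability at
#'   editable bases in the flanks.
#' @param indelProb Per-read indel probability.
#' @param indelGeomProb Success parameter of the geometric
#'   length distribution (mean extra length \code{(1-p)/p}).
#' @param errorRate Per-base uniform sequencing-error probability.
#' @param paired Emit overlapping R1/R2 instead of full-length reads.
#' @param readLength Read length in paired mode (default 2/3 of the
#'   amplicon, so the mates overlap).
#' @param phred Constant per-base quality score.
#' @return A list: \code{reads} (single mode) or \code{r1}, \code{r2}
#'   (paired mode), each a [Biostrings::QualityScaledDNAStringSet], and
#'   \code{truth}, a per-read data.frame with \code{read_id},
#'   \code{intended}, \code{n_bystander}, \code{indel}
#'   (\code{"none"}/\code{"insertion"}/\code{"deletion"}),
#'   \code{n_errors} and \code{expected_label} (the classification the
#'   analyzer should assign at zero sequencing error).
#' @export
simulateEditedReads <- function(config, n, seed,
                                intendedProb = 0, bystanderProb = 0,
                                indelProb = 0, indelGeomProb = 0.5,
                                errorRate = 0, paired = FALSE,
                                readLength = NULL, phred = 30L) {
  stopifnot(is(config, "AnalysisConfig"), n >= 1L)
  geom <- configGeometry(config)
  refChars <- strsplit(config@reference, "")[[1L]]
  L <- length(refChars)
  # editable positions: reference positions carrying the edited base
  winEditable <- geom$windowRef[refChars[geom$windowRef] == geom$editedRef]
  scopePos <- geom$scopeStart:geom$scopeEnd
  flankPos <- setdiff(scopePos, geom$windowRef)
  flankEditable <- flankPos[refChars[flankPos] == geom$editedRef]
  # primary product on the reference forward strand
  primary <- config@editor@productBases[1L]
  primaryRef <- if (geom$plus) primary else complementChar(primary)
  # nominal cut: 3 bp from the PAM-proximal protospacer edge
  cutAfter <- if (geom$plus == (config@nuclease@pamSide == "three_prime"))
    geom$protoEnd - 3L else geom$protoStart + 2L

  withSeed(seed, {
    bases <- character(n)
    truth <- data.frame(
      read_id = sprintf("sim_%06d", seq_len(n)),
      intended = logical(n), n_bystander = integer(n),
      indel = rep("none", n), n_errors = integer(n),
      expected_label = character(n), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      chars <- refChars
      hitWin <- winEditable[stats::runif(length(winEditable)) < intendedProb]
      chars[hitWin] <- primaryRef
      hitFlank <- flankEditable[
        stats::runif(length(flankEditable)) < bystanderProb]
      chars[hitFlank] <- primaryRef
      indel <- "none"; indelInScope <- FALSE
      if (stats::runif(1L) < indelProb) {
        len <- 1L + stats::rgeom(1L, indelGeomProb)
        if (stats::runif(1L) < 0.5) {
          indel <- "deletion"
          delEnd <- min(cutAfter + len, length(chars))
          indelInScope <- (cutAfter + 1L) <= geom$scopeEnd &&
            delEnd >= geom$scopeStart
          chars <- chars[-((cutAfter + 1L):delEnd)]
        } else {
          indel <- "insertion"
          indelInScope <- cutAfter >= geom$scopeStart &&
            cutAfter + 1L <= geom$scopeEnd
          ins <- sample(ACGT, len, replace = TRUE)
          chars <- append(chars, ins, after = cutAfter)
        }
      }
      nerr <- 0L
      if (errorRate > 0) {
        err <- which(stats::runif(length(chars)) < errorRate)
        for (e in err)
          chars[e] <- sample(setdiff(ACGT, chars[e]), 1L)
        nerr <- length(err)
      }
      bases[i] <- paste(chars, collapse = "")
      # expected_label follows the analyzer's scoping: an indel outside
      # the window +/- flanks does not make the read an indel call
      lab <- if (indel != "none" && indelInScope) indel
        else if (length(hitWin) + length(hitFlank) > 0L) "substitution"
        else "wt"
      truth$intended[i] <- length(hitWin) > 0L && lab == "substitution"
      truth$n_bystander[i] <- length(hitFlank)
      truth$indel[i] <- indel
      truth$n_errors[i] <- nerr
      truth$expected_label[i] <- lab
    }
    if (!paired) {
      reads <- makeQualityReads(
        bases, lapply(nchar(bases), function(k) rep(phred, k)),
        truth$read_id)
      list(reads = reads, truth = truth)
    } else {
      if (is.null(readLength)) readLength <- ceiling(2 * L / 3)
      r1b <- substr(bases, 1L, pmin(readLength, nchar(bases)))
      r2b <- vapply(bases, function(b) {
        k <- nchar(b)
        revcompChar(substr(b, max(1L, k - readLength + 1L), k))
      }, character(1L), USE.NAMES = FALSE)
      r1 <- makeQualityReads(
        r1b, lapply(nchar(r1b), function(k) rep(phred, k)), truth$read_id)
      r2 <- makeQualityReads(
        r2b, lapply(nchar(r2b), function(k) rep(phred, k)), truth$read_id)
      list(r1 = r1, r2 = r2, truth = truth)
    }
  })
}
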