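# Amplicon analyzer: indicator filtering, unique-sequence tallying,
# global alignment, four-way classification, intended-conversion rates,
# per-position substitution profiles, amino-acid frames and control
# overlay.

#' Build an analysis configuration
#'
#' Validates and bundles the analyzer parameters. The target site
#' (spacer + PAM, read 5'\eqn{\to}3' on the targeted strand) must occur
#' exactly once in the reference on the declared strand; the editing
#' window (editor default or override, in nt from the PAM) must map
#' inside the protospacer; and the window plus flanks must lie inside
#' the reference.
#'
#' @param reference Wild-type amplicon, ACGT string.
#' @param targetSite Spacer + PAM string (PAM on the side fixed by the
#'   nuclease profile).
#' @param targetStrand \code{"+"} or \code{"-"}.
#' @param nuclease [NucleaseProfile-class] or registry name.
#' @param editor [EditorPreset-class] or registry name.
#' @param windowOverride Optional \code{c(proximal, distal)}.
#' @param flankLeft,flankRight Analysis flanks in nt (default 5 each).
#' @param minFrequency Minimum absolute read count (default 1).
#' @param frameOffset Reading-frame offset 0/1/2 for translation.
#' @return An [AnalysisConfig-class].
#' @examples
#' ref <- paste0("ATGCTAGCTAGGATCCAGTT", "CAGTACGTACCGTACGTACGTGG",
#'               "TTGACCGGTAGCTTAGCAAT")
#' cfg <- analysisConfig(ref, "CAGTACGTACCGTACGTACGTGG", "+",
#'                       nuclease = "SpCas9", editor = "BE3")
#' cfg
#' @export
analysisConfig <- function(reference, targetSite, targetStrand = "+",
                           nuclease = "SpCas9", editor = "BE3",
                           windowOverride = NULL,
                           flankLeft = 5L, flankRight = 5L,
                           minFrequency = 1L, frameOffset = 0L) {
  if (is.character(nuclease)) nuclease <- nucleaseProfile(nuclease)
  if (is.character(editor)) editor <- editorPreset(editor)
  cfg <- new("AnalysisConfig",
             reference = toupper(reference),
             targetSite = toupper(targetSite),
             targetStrand = targetStrand,
             nuclease = nuclease, editor = editor,
             windowOverride = if (is.null(windowOverride)) integer(0)
                              else as.integer(windowOverride),
             flankLeft = as.integer(flankLeft),
             flankRight = as.integer(flankRight),
             minFrequency = as.integer(minFrequency),
             frameOffset = as.integer(frameOffset))
  geom <- configGeometry(cfg)  # errors if the window does not fit
  if (geom$scopeStart < 1L || geom$scopeEnd > nchar(cfg@reference))
    stop("editing window plus flanks extends outside the reference")
  cfg
}

# Geometry of the target within the reference, all 1-based:
# protospacer interval, window reference positions (sorted), scope
# (window +/- flanks) interval, and strand-adjusted edited/product bases.
configGeometry <- function(config) {
  ref <- config@reference
  site <- config@targetSite
  pamLen <- nchar(config@nuclease@pamPattern)
  sl <- nchar(site) - pamLen
  if (sl < config@nuclease@spacerMin || sl > config@nuclease@spacerMax)
    stop("target site implies a spacer of ", sl,
         " nt, outside the profile's bounds")
  siteFwd <- if (config@targetStrand == "+") site else revcompChar(site)
  pos <- gregexpr(siteFwd, ref, fixed = TRUE)[[1L]]
  if (pos[1L] == -1L) stop("target site not found in reference")
  if (length(pos) > 1L) stop("target site occurs more than once")
  p <- pos[1L]
  threePrime <- config@nuclease@pamSide == "three_prime"
  plus <- config@targetStrand == "+"
  # forward-strand interval of the protospacer
  if ((threePrime && plus) || (!threePrime && !plus)) {
    protoStart <- p; protoEnd <- p + sl - 1L
  } else {
    protoStart <- p + pamLen; protoEnd <- p + nchar(site) - 1L
  }
  window <- effectiveWindow(config@editor, config@windowOverride)
  offs <- windowToSpacerOffsets(window, sl, config@nuclease@pamSide)
  winRef <- if (plus) protoStart + offs else protoEnd - offs
  winRef <- sort(winRef)
  scopeStart <- min(winRef) - config@flankLeft
  scopeEnd <- max(winRef) + config@flankRight
  editedRef <- if (plus) config@editor@editedBase else
    complementChar(config@editor@editedBase)
  productsRef <- if (plus) config@editor@productBases else
    vapply(config@editor@productBases, complementChar, character(1L),
           USE.NAMES = FALSE)
  list(protoStart = protoStart, protoEnd = protoEnd,
       spacerLength = sl, window = window, windowRef = winRef,
       scopeStart = scopeStart, scopeEnd = scopeEnd,
       editedRef = editedRef, productsRef = productsRef,
       plus = plus)
}

#' Extract the 15-nt indicator sequences of a reference
#'
#' The analyzer recognizes valid reads by the first and last 15 nt of
#' the reference amplicon.
#'
#' @param reference ACGT string of length \eqn{\ge} 30, or an
#'   [AnalysisConfig-class].
#' @return \code{c(left =, right =)} 15-nt strings.
#' @export
extractIndicators <- function(reference) {
  if (is(reference, "AnalysisConfig")) reference <- reference@reference
  L <- nchar(reference)
  if (L < 30L)
    stop("reference too short for 15-nt indicators (need >= 30 nt)")
  c(left = substr(reference, 1L, 15L),
    right = substr(reference, L - 14L, L))
}

# best occurrence of a 15-nt indicator in a read: minimal Hamming
# distance; ties resolved to the first (left) or last (right) position
bestIndicatorHit <- function(readChar, indicator, fromPos = 1L,
                             tie = c("first", "last")) {
  tie <- match.arg(tie)
  if (nchar(readChar) - fromPos + 1L < nchar(indicator)) return(NULL)
  mm <- .hamming_scan(substr(readChar, fromPos, nchar(readChar)), indicator)
  best <- min(mm)
  idx <- which(mm == best)
  idx <- if (tie == "first") idx[1L] else idx[length(idx)]
  list(pos = fromPos + idx - 1L, mm = best)
}

# search one orientation of a read; returns NULL or
# list(from, to, mmLeft, mmRight)
indicatorSpan <- function(readChar, left, right, maxMm) {
  hl <- bestIndicatorHit(readChar, left, tie = "first")
  if (is.null(hl) || hl$mm > maxMm) return(NULL)
  hr <- bestIndicatorHit(readChar, right, fromPos = hl$pos + nchar(left),
                         tie = "last")
  if (is.null(hr) || hr$mm > maxMm) return(NULL)
  list(from = hl$pos, to = hr$pos + nchar(right) - 1L,
       mm = hl$mm + hr$mm)
}

#' Filter reads on both indicator sequences
#'
#' Keeps reads in which both 15-nt indicators occur (left before right)
#' with at most \code{maxMm} mismatches each, trying the read and its
#' reverse complement (the orientation with fewer total indicator
#' mismatches wins; ties go to the forward read). Retained reads are
#' trimmed to the span from the left indicator's start through the right
#' indicator's end; all other reads are dropped and counted.
#'
#' @param reads Character vector of read sequences, or a
#'   [Biostrings::DNAStringSet] / QualityScaledDNAStringSet.
#' @param left,right 15-nt indicator strings (see [extractIndicators()]).
#' @param maxMm Maximum mismatches per indicator (default 1).
#' @return A list: \code{queries} (trimmed sequences of retained reads)
#'   and \code{stats} (\code{total}, \code{retained}, \code{dropped}).
#' @export
filterByIndicators <- function(reads, left, right, maxMm = 1L) {
  if (!is.character(reads)) reads <- as.character(reads)
  reads <- toupper(reads)
  stopifnot(nchar(left) == 15L, nchar(right) == 15L)
  uniq <- unique(reads)
  trimmed <- vapply(uniq, function(rd) {
    fwd <- indicatorSpan(rd, left, right, maxMm)
    rc <- revcompChar(rd)
    rev <- indicatorSpan(rc, left, right, maxMm)
    pick <- NULL; src <- rd
    if (!is.null(fwd) && (is.null(rev) || fwd$mm <= rev$mm)) {
      pick <- fwd
    } else if (!is.null(rev)) {
      pick <- rev; src <- rc
    }
    if (is.null(pick)) NA_character_
    else substr(src, pick$from, pick$to)
  }, character(1L), USE.NAMES = TRUE)
  perRead <- trimmed[reads]
  queries <- unname(perRead[!is.na(perRead)])
  list(queries = queries,
       stats = c(total = length(reads), retained = length(queries),
                 dropped = sum(is.na(perRead))))
}

#' Tally unique query sequences
#'
#' Counts recurrent sequences, discards those below the minimum
#' frequency and sorts by descending count (ties broken
#' lexicographically for determinism).
#'
#' @param queries Character vector of query sequences.
#' @param minFrequency Minimum absolute count (default 1).
#' @return \code{data.frame(sequence, count)}.
#' @export
tallyUnique <- function(queries, minFrequency = 1L) {
  stopifnot(minFrequency >= 1L)
  if (length(queries) == 0L)
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(queries)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[df$count >= minFrequency, , drop = FALSE]
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Global affine-gap alignment of a query to the reference
#'
#' Needleman--Wunsch global alignment with affine gap penalties
#' (Gotoh algorithm), scoring match +5, mismatch \eqn{-4}, gap opening
#' 10 and gap extension 0.5 by default; a gap of length L costs
#' \eqn{10 + 0.5L}. End gaps are penalized. The traceback tie-break is
#' fixed (diagonal, then gap-in-query, then gap-in-reference), so the
#' alignment is deterministic.
#'
#' @param reference,query Non-empty ACGT strings.
#' @param match,mismatch,gapOpening,gapExtension Scoring parameters.
#' @return A list: \code{ref_row}, \code{query_row} (equal-length
#'   strings over A/C/G/T/\code{-}) and \code{score}.
#' @examples
#' globalAlign("ACGTACGT", "ACGACGT")
#' @export
globalAlign <- function(reference, query, match = 5, mismatch = -4,
                        gapOpening = 10, gapExtension = 0.5) {
  if (!nzchar(reference) || !nzchar(query))
    stop("both sequences must be non-empty")
  .gotoh_align(reference, query, match, mismatch, gapOpening, gapExtension)
}

# map 1-based reference positions to alignment columns
refColumnMap <- function(refRowChars) {
  which(refRowChars != "-")
}

#' Classify one aligned query
#'
#' Four-way classification of an aligned query against the reference,
#' scoped to the editing window plus flanks: a gap in either row inside
#' the scope makes the read an insertion (excess gaps in the reference
#' row) or deletion (excess gaps in the query row; ties count as
#' deletion); otherwise at least one mismatch inside the scope makes it
#' a substitution, and a read with no in-scope difference is wild type.
#' A substitution read is flagged \code{intended} when at least one
#' window-proper column converts the editor's edited base into one of
#' its product bases (strand-adjusted).
#'
#' @param refRow,queryRow Alignment rows from [globalAlign()].
#' @param config An [AnalysisConfig-class].
#' @return A list: \code{label} (\code{wt}/\code{insertion}/
#'   \code{deletion}/\code{substitution}), \code{intended} (logical) and
#'   \code{products} (product bases, on the spacer strand, observed at
#'   window edited-base positions).
#' @export
classifyAlignment <- function(refRow, queryRow, config) {
  geom <- configGeometry(config)
  rc <- strsplit(refRow, "")[[1L]]
  qc <- strsplit(queryRow, "")[[1L]]
  stopifnot(length(rc) == length(qc))
  colOf <- refColumnMap(rc)
  scopeCols <- colOf[geom$scopeStart]:colOf[geom$scopeEnd]
  hRef <- sum(rc[scopeCols] == "-")
  hQ <- sum(qc[scopeCols] == "-")
  label <- if (hRef + hQ > 0L) {
    if (hRef > hQ) "insertion" else "deletion"
  } else if (any(rc[scopeCols] != qc[scopeCols])) "substitution" else "wt"

  intended <- FALSE
  products <- character(0)
  if (label == "substitution") {
    winCols <- colOf[geom$windowRef]
    hit <- rc[winCols] == geom$editedRef & qc[winCols] %in% geom$productsRef
    if (any(hit)) {
      intended <- TRUE
      obs <- unique(qc[winCols][hit])
      # report products on the spacer strand
      products <- if (geom$plus) obs else
        vapply(obs, complementChar, character(1L), USE.NAMES = FALSE)
    }
  }
  list(label = label, intended = intended, products = products)
}

# align + classify every tallied unique sequence
alignAndClassify <- function(tally, config,
                             match = 5, mismatch = -4,
                             gapOpening = 10, gapExtension = 0.5) {
  n <- nrow(tally)
  refRows <- character(n); queryRows <- character(n)
  labels <- character(n); intended <- logical(n)
  products <- vector("list", n)
  for (i in seq_len(n)) {
    al <- globalAlign(config@reference, tally$sequence[i], match, mismatch,
                      gapOpening, gapExtension)
    cl <- classifyAlignment(al$ref_row, al$query_row, config)
    refRows[i] <- al$ref_row; queryRows[i] <- al$query_row
    labels[i] <- cl$label; intended[i] <- cl$intended
    products[[i]] <- cl$products
  }
  out <- S4Vectors::DataFrame(
    ref_row = refRows, query_row = queryRows, count = tally$count,
    label = labels, intended = intended)
  out$products <- products
  out
}

#' Summarize a classified run
#'
#' Fills the nine-field run summary; the intended substitution rate is
#' the number of reads with intended conversions in the editing window
#' divided by the number of reads above the minimum frequency.
#' Per-product rates (e.g. the C-to-T rate for a CBE) are reported
#' alongside.
#'
#' @param aligned Output of the alignment/classification step (a
#'   DataFrame with \code{count}, \code{label}, \code{intended},
#'   \code{products}).
#' @param totalSequences Total reads in the input FASTQ.
#' @param withBothIndicators Reads retained by the indicator filter.
#' @param editor The [EditorPreset-class] used.
#' @return A [RunSummary-class].
#' @export
summarizeRun <- function(aligned, totalSequences, withBothIndicators,
                         editor) {
  aboveMin <- sum(aligned$count)
  if (aboveMin == 0L) stop("no analyzable reads")
  cnt <- function(lab) sum(aligned$count[aligned$label == lab])
  intendedReads <- sum(aligned$count[aligned$intended])
  perProd <- vapply(editor@productBases, function(p) {
    has <- vapply(seq_len(nrow(aligned)), function(i)
      p %in% aligned$products[[i]], logical(1L))
    sum(aligned$count[has]) / aboveMin
  }, numeric(1L))
  names(perProd) <- paste0(editor@editedBase, ">", editor@productBases)
  new("RunSummary",
      totalSequences = as.integer(totalSequences),
      withBothIndicators = as.integer(withBothIndicators),
      aboveMinFrequency = as.integer(aboveMin),
      wt = cnt("wt"), insertions = cnt("insertion"),
      deletions = cnt("deletion"), withSubstitution = cnt("substitution"),
      intendedInWindow = as.integer(intendedReads),
      intendedRate = intendedReads / aboveMin,
      perProductRate = perProd)
}

#' Per-position substitution profile
#'
#' For every reference position across the editing window plus flanks,
#' tabulates the percentage of each nucleotide among substitution-class
#' reads covering the position gap-free (and, separately, among all
#' classified reads — the heat-map view), and at edited-base positions
#' the per-product transition rate (for a CBE: C\eqn{\to}T, C\eqn{\to}G,
#' C\eqn{\to}A on the spacer strand) as a fraction of covering
#' substitution-class reads. All tallies are weighted by read count.
#'
#' @param aligned Output of the alignment/classification step.
#' @param config An [AnalysisConfig-class].
#' @return A [SubstitutionProfile-class].
#' @export
buildSubstitutionProfile <- function(aligned, config) {
  geom <- configGeometry(config)
  positions <- geom$scopeStart:geom$scopeEnd
  npos <- length(positions)
  refChars <- strsplit(config@reference, "")[[1L]]
  refBases <- refChars[positions]
  prodRef <- geom$productsRef
  prodLabels <- paste0(config@editor@editedBase, ">",
                       config@editor@productBases)

  counts <- matrix(0, 4L, npos, dimnames = list(ACGT, positions))
  countsAll <- counts
  prodCounts <- matrix(0, length(prodRef), npos,
                       dimnames = list(prodLabels, positions))
  coverSub <- numeric(npos)

  isSub <- aligned$label == "substitution"
  for (i in seq_len(nrow(aligned))) {
    rc <- strsplit(aligned$ref_row[i], "")[[1L]]
    qc <- strsplit(aligned$query_row[i], "")[[1L]]
    colOf <- refColumnMap(rc)
    qAt <- qc[colOf[positions]]
    covered <- qAt %in% ACGT
    w <- aligned$count[i]
    for (j in which(covered)) {
      countsAll[qAt[j], j] <- countsAll[qAt[j], j] + w
      if (isSub[i]) {
        counts[qAt[j], j] <- counts[qAt[j], j] + w
        coverSub[j] <- coverSub[j] + w
        if (refBases[j] == geom$editedRef) {
          k <- match(qAt[j], prodRef)
          if (!is.na(k)) prodCounts[k, j] <- prodCounts[k, j] + w
        }
      }
    }
  }
  toPercent <- function(m) {
    tot <- colSums(m)
    out <- sweep(m, 2L, ifelse(tot > 0, tot, NA_real_), "/") * 100
    out
  }
  transition <- sweep(prodCounts, 2L,
                      ifelse(coverSub > 0, coverSub, NA_real_), "/")
  transition[, refBases != geom$editedRef] <- NA_real_

  new("SubstitutionProfile",
      positions = as.integer(positions), refBases = refBases,
      basePercent = toPercent(counts), basePercentAll = toPercent(countsAll),
      transitionRate = transition,
      controlRate = matrix(numeric(0), 0L, 0L),
      background = rep(NA, npos),
      coverage = as.integer(round(coverSub)),
      empty = !any(isSub))
}

#' Translate a region in all three reading frames
#'
#' Standard genetic-code translation of a displayed region for frame
#' offsets 0, 1 and 2; the trailing partial codon is dropped and stop
#' codons render as \code{*}.
#'
#' @param regionSequence ACGT string, length \eqn{\ge} 3.
#' @return Named character vector: amino-acid strings for frames 0/1/2.
#' @examples
#' translateFrames("ATGAAA")[["0"]]  # "MK"
#' @export
translateFrames <- function(regionSequence) {
  if (nchar(regionSequence) < 3L) stop("region must be >= 3 nt")
  out <- vapply(0:2, function(f) {
    sub <- substr(regionSequence, f + 1L, nchar(regionSequence))
    nco <- nchar(sub) %/% 3L
    if (nco == 0L) return("")
    sub <- substr(sub, 1L, nco * 3L)
    as.character(Biostrings::translate(Biostrings::DNAString(sub)))
  }, character(1L))
  names(out) <- as.character(0:2)
  out
}

#' Overlay a control run on a treated substitution profile
#'
#' Attaches the control run's per-position transition rates as
#' negative-signed display values and flags positions where the control
#' rate is positive and at least as large as the treated rate as
#' background. No count subtraction is performed.
#'
#' @param treated,control [SubstitutionProfile-class] objects over the
#'   same positions.
#' @return The treated profile with \code{controlRate} and
#'   \code{background} filled.
#' @export
controlOverlay <- function(treated, control) {
  if (!identical(treated@positions, control@positions))
    stop("treated and control profiles cover different positions")
  ctl <- control@transitionRate
  trt <- treated@transitionRate
  bg <- vapply(seq_along(treated@positions), function(j) {
    cj <- ctl[, j]; tj <- trt[, j]
    ok <- !is.na(cj) & !is.na(tj)
    any(cj[ok] > 0 & cj[ok] >= tj[ok])
  }, logical(1L))
  treated@controlRate <- -ctl
  treated@background <- bg
  treated
}

#' Analyze base-editing outcomes from amplicon sequencing reads
#'
#' The full analyzer pipeline: (optional) paired-end merging, indicator
#' filtering, unique-sequence tallying with a minimum-frequency cut,
#' global alignment of each unique sequence to the reference, four-way
#' classification, run summary, per-position substitution profile,
#' reading-frame translation of the analyzed region and (optional)
#' control overlay.
#'
#' @param fastq1 FASTQ(.gz) path, a
#'   [Biostrings::QualityScaledDNAStringSet], or a character vector of
#'   read sequences.
#' @param config An [AnalysisConfig-class].
#' @param fastq2 Optional mate FASTQ for paired-end input.
#' @param control,control2 Optional control (untreated) FASTQ input,
#'   analyzed with the same configuration and overlaid on the profile.
#' @param minOverlap,maxMismatchFrac Merge parameters (see [mergePair()]).
#' @param match,mismatch,gapOpening,gapExtension Alignment scoring.
#' @return A [BaseEditResult-class].
#' @export
analyzeBaseEdits <- function(fastq1, config, fastq2 = NULL,
                             control = NULL, control2 = NULL,
                             minOverlap = 6L, maxMismatchFrac = 0.08,
                             match = 5, mismatch = -4,
                             gapOpening = 10, gapExtension = 0.5) {
  stopifnot(is(config, "AnalysisConfig"))
  mergeReport <- c(pairs_in = NA_integer_, merged = NA_integer_,
                   rejected_no_overlap = NA_integer_,
                   rejected_mismatch = NA_integer_)
  if (!is.null(fastq2)) {
    if (is.character(fastq1) && length(fastq1) == 1L &&
        file.exists(fastq1)) fastq1 <- readFastqReads(fastq1)
    if (is.character(fastq2) && length(fastq2) == 1L &&
        file.exists(fastq2)) fastq2 <- readFastqReads(fastq2)
    mg <- mergePairs(fastq1, fastq2, minOverlap = minOverlap,
                     maxMismatchFrac = maxMismatchFrac)
    readSeqs <- as.character(mg$reads)
    totalSequences <- mg$report[["pairs_in"]]
    mergeReport <- mg$report
  } else {
    if (is.character(fastq1) && length(fastq1) == 1L &&
        file.exists(fastq1)) fastq1 <- readFastqReads(fastq1)
    readSeqs <- as.character(fastq1)
    totalSequences <- length(readSeqs)
  }

  ind <- extractIndicators(config)
  flt <- filterByIndicators(readSeqs, ind[["left"]], ind[["right"]])
  if (length(flt$queries) == 0L)
    stop("no reads survive the indicator filter (",
         flt$stats[["dropped"]], " of ", flt$stats[["total"]],
         " dropped)")
  tally <- tallyUnique(flt$queries, config@minFrequency)
  if (nrow(tally) == 0L)
    stop("no analyzable reads: every unique sequence falls below ",
         "the minimum frequency (", config@minFrequency, ")")
  aligned <- alignAndClassify(tally, config, match, mismatch,
                              gapOpening, gapExtension)
  summ <- summarizeRun(aligned, totalSequences,
                       flt$stats[["retained"]], config@editor)
  prof <- buildSubstitutionProfile(aligned, config)

  if (!is.null(control)) {
    ctlRes <- analyzeBaseEdits(control, config, fastq2 = control2,
                               minOverlap = minOverlap,
                               maxMismatchFrac = maxMismatchFrac,
                               match = match, mismatch = mismatch,
                               gapOpening = gapOpening,
                               gapExtension = gapExtension)
    prof <- controlOverlay(prof, ctlRes@profile)
  }

  geom <- configGeometry(config)
  region <- substr(config@reference, geom$scopeStart, geom$scopeEnd)
  aa <- translateFrames(region)
  frames <- S4Vectors::DataFrame(frame = 0:2, amino_acids = unname(aa),
                                 selected = 0:2 == config@frameOffset)

  new("BaseEditResult", summary = summ, alignments = aligned,
      profile = prof, frames = frames,
      filterStats = flt$stats, mergeReport = mergeReport,
      config = config)
}
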