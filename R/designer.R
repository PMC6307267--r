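# Guide designer: enumerate base-editor target candidates in a query
# sequence on both strands, with editable-base annotation, 1-based
# relative position of the protospacer 5' end and GC content.

#' Parse raw or FASTA sequence input
#'
#' Accepts either FASTA-formatted text (the first record is used; extra
#' records are reported with a message) or a raw string of IUPAC
#' nucleotide codes. Whitespace and digits are stripped and the sequence
#' is uppercased; any other non-IUPAC character is an error.
#'
#' @param text Character scalar: FASTA text (starting with \code{>}) or a
#'   raw sequence.
#' @return A list with elements \code{sequence} (uppercase IUPAC string)
#'   and \code{originLabel} (FASTA header or \code{"raw"}).
#' @examples
#' parseSequenceInput(">x\nacgT\nACGT")$sequence  # "ACGTACGT"
#' @export
parseSequenceInput <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("input text must be a non-empty string")
  label <- "raw"
  if (startsWith(trimws(text), ">")) {
    lines <- strsplit(text, "\r?\n")[[1L]]
    headers <- grep("^>", lines)
    if (length(headers) == 0L) stop("malformed FASTA input")
    if (length(headers) > 1L)
      message("multi-record FASTA input: using the first record only")
    label <- sub("^>\\s*", "", lines[headers[1L]])
    to <- if (length(headers) > 1L) headers[2L] - 1L else length(lines)
    body <- lines[seq(headers[1L] + 1L, length.out = max(0L, to - headers[1L]))]
    raw <- paste(body, collapse = "")
  } else {
    raw <- text
  }
  cleaned <- toupper(gsub("[[:space:][:digit:]]", "", raw))
  if (!nzchar(cleaned)) stop("no sequence left after cleaning input")
  chars <- strsplit(cleaned, "")[[1L]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad))
    stop("invalid character '", chars[bad[1L]], "' at position ", bad[1L],
         " (IUPAC nucleotide codes only; U is not accepted)")
  list(sequence = cleaned, originLabel = label)
}

editableString <- function(spacer, offs) {
  if (length(offs) == 0L) return("")
  paste(sprintf("%d:%s", offs,
                substring(spacer, offs + 1L, offs + 1L)), collapse = ";")
}

# one-strand candidate scan on a (possibly degenerate) query sequence;
# returns a plain list of candidate records in that strand's coordinates
scanStrandForTargets <- function(seqChar, profile, spacerLength,
                                 editableOffsets, editedBase) {
  pamLen <- nchar(profile@pamPattern)
  L <- nchar(seqChar)
  hits <- Biostrings::matchPattern(profile@pamPattern,
                                   Biostrings::DNAString(seqChar),
                                   fixed = FALSE)
  out <- list()
  skipped <- 0L
  for (k in seq_along(hits)) {
    ps <- BiocGenerics::start(hits)[k]
    pe <- BiocGenerics::end(hits)[k]
    if (profile@pamSide == "three_prime") {
      ss <- ps - spacerLength; se <- ps - 1L
    } else {
      ss <- pe + 1L; se <- pe + spacerLength
    }
    if (ss < 1L || se > L) next
    spacer <- substr(seqChar, ss, se)
    pam <- substr(seqChar, ps, pe)
    if (!grepl("^[ACGT]+$", spacer) || !grepl("^[ACGT]+$", pam)) {
      skipped <- skipped + 1L
      next
    }
    spacerChars <- strsplit(spacer, "")[[1L]]
    edit <- editableOffsets[spacerChars[editableOffsets + 1L] == editedBase]
    out[[length(out) + 1L]] <- list(
      spacer = spacer, pam = pam,
      start1 = ss, end1 = se,
      editable = edit)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Enumerate base-editor target candidates
#'
#' Scans the query region and its reverse complement for PAM matches of
#' the given nuclease profile and emits every position where a
#' full-length spacer fits on the correct side of the PAM. Each candidate
#' is annotated with the editable bases (occurrences of the editor's
#' edited base inside the editing window, as 0-based spacer offsets),
#' the 1-based position of the protospacer 5' end on the input forward
#' strand, and GC content. Candidates without any editable base are
#' returned with \code{has_editable = FALSE} rather than dropped.
#'
#' Degenerate query bases: PAM matching requires the degeneracy sets of
#' pattern and query base to intersect; a spacer containing a non-ACGT
#' code is skipped (counted in \code{metadata(x)$skipped_degenerate}).
#'
#' @param region Output of [parseSequenceInput()], or a raw/FASTA string.
#' @param profile A [NucleaseProfile-class] or registry name.
#' @param editor An [EditorPreset-class] or registry name.
#' @param spacerLength Spacer length in nt; default the profile's.
#' @param windowOverride Optional \code{c(proximal, distal)} window
#'   override, nt from the PAM.
#' @return A [S4Vectors::DataFrame] with columns \code{spacer},
#'   \code{pam}, \code{strand}, \code{start}, \code{end} (0-based
#'   half-open protospacer interval on the forward strand),
#'   \code{relative_position} (1-based 5' end), \code{gc_percent},
#'   \code{editable} (CharacterList of \code{"offset:base"}) and
#'   \code{has_editable}; sorted by \code{start} then strand.
#' @examples
#' cand <- enumerateTargets("CCAGTACGTACGTACGTACGTACCGGTA", "SpCas9", "BE3",
#'                          spacerLength = 20)
#' cand[, c("spacer", "pam", "strand", "start")]
#' @export
enumerateTargets <- function(region, profile, editor,
                             spacerLength = NULL,
                             windowOverride = NULL) {
  if (is.character(region)) region <- parseSequenceInput(region)
  if (is.character(profile)) profile <- nucleaseProfile(profile)
  if (is.character(editor)) editor <- editorPreset(editor)
  if (is.null(spacerLength)) spacerLength <- profile@spacerDefault
  spacerLength <- as.integer(spacerLength)
  if (spacerLength < profile@spacerMin || spacerLength > profile@spacerMax)
    stop("spacerLength must lie in [", profile@spacerMin, ", ",
         profile@spacerMax, "] for ", profile@name)
  window <- effectiveWindow(editor,
                            if (is.null(windowOverride)) integer(0)
                            else as.integer(windowOverride))
  offs <- windowToSpacerOffsets(window, spacerLength, profile@pamSide)

  seqChar <- region$sequence
  L <- nchar(seqChar)
  if (L < spacerLength + nchar(profile@pamPattern))
    stop("query region shorter than spacer + PAM")

  fwd <- scanStrandForTargets(seqChar, profile, spacerLength, offs,
                              editor@editedBase)
  rcChar <- revcompChar(seqChar)
  rev <- scanStrandForTargets(rcChar, profile, spacerLength, offs,
                              editor@editedBase)
  skipped <- attr(fwd, "skipped") + attr(rev, "skipped")
  if (skipped > 0L)
    warning(skipped, " candidate(s) skipped: spacer or PAM contains a ",
            "degenerate base")

  rows <- list()
  for (cnd in fwd) {
    rows[[length(rows) + 1L]] <- data.frame(
      spacer = cnd$spacer, pam = cnd$pam, strand = "+",
      start = cnd$start1 - 1L, end = cnd$end1,
      relative_position = cnd$start1,
      gc_percent = gcPercentChar(cnd$spacer),
      editable = editableString(cnd$spacer, cnd$editable),
      stringsAsFactors = FALSE)
  }
  for (cnd in rev) {
    # map [s,e] on the reverse complement to forward coordinates
    start0 <- L - cnd$end1
    end0 <- L - cnd$start1 + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      spacer = cnd$spacer, pam = cnd$pam, strand = "-",
      start = start0, end = end0,
      relative_position = end0,
      gc_percent = gcPercentChar(cnd$spacer),
      editable = editableString(cnd$spacer, cnd$editable),
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spacer = character(), pam = character(),
               strand = character(), start = integer(), end = integer(),
               relative_position = integer(), gc_percent = numeric(),
               editable = character(), stringsAsFactors = FALSE)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  out <- S4Vectors::DataFrame(df)
  out$has_editable <- nzchar(df$editable)
  S4Vectors::metadata(out) <- list(
    profile = profile@name, editor = editor@name,
    spacer_length = spacerLength, window = window,
    origin = region$originLabel, skipped_degenerate = skipped,
    query_length = L)
  out
}

#' Filter designer candidates by GC content and editability
#'
#' @param candidates Output of [enumerateTargets()].
#' @param gcMin,gcMax GC-content bounds in percent, inclusive.
#' @param requireEditable Keep only candidates with at least one editable
#'   base in the window.
#' @return The filtered [S4Vectors::DataFrame], order preserved.
#' @export
filterCandidates <- function(candidates, gcMin = 0, gcMax = 100,
                             requireEditable = FALSE) {
  stopifnot(gcMin >= 0, gcMax <= 100, gcMin <= gcMax)
  keep <- candidates$gc_percent >= gcMin & candidates$gc_percent <= gcMax
  if (requireEditable) keep <- keep & candidates$has_editable
  candidates[keep, , drop = FALSE]
}

#' Write designer candidates to TSV
#'
#' Columns: spacer, pam, strand, start, end (0-based half-open),
#' relative_position (1-based), gc_percent, editable_bases
#' (semicolon-joined \code{offset:base}), has_editable.
#'
#' @param candidates Output of [enumerateTargets()].
#' @param path Output file.
#' @export
writeCandidates <- function(candidates, path) {
  df <- as.data.frame(candidates)
  names(df)[names(df) == "editable"] <- "editable_bases"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
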