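# Mismatch-bounded off-target scan over a genome FASTA: the PAM must
# match its degenerate pattern exactly; mismatches are counted over the
# spacer only (Cas-OFFinder semantics). Sliding scan, no index: intended
# for desk-scale genomes.

ACGT <- c("A", "C", "G", "T")

# scan one strand of one record; seqChar is the strand's sequence,
# returns data.frame with 1-based spacer start on that strand
scanStrandOffTargets <- function(seqChar, spacerChars, profile,
                                 maxMismatches) {
  sl <- length(spacerChars)
  pamLen <- nchar(profile@pamPattern)
  L <- nchar(seqChar)
  hits <- Biostrings::matchPattern(profile@pamPattern,
                                   Biostrings::DNAString(seqChar),
                                   fixed = FALSE)
  if (length(hits) == 0L)
    return(data.frame(spacerStart = integer(), mismatches = integer(),
                      spacer = character(), pam = character(),
                      stringsAsFactors = FALSE))
  ps <- BiocGenerics::start(hits)
  pe <- BiocGenerics::end(hits)
  if (profile@pamSide == "three_prime") {
    ss <- ps - sl; se <- ps - 1L
  } else {
    ss <- pe + 1L; se <- pe + sl
  }
  ok <- ss >= 1L & se <= L
  ps <- ps[ok]; pe <- pe[ok]; ss <- ss[ok]; se <- se[ok]
  if (length(ss) == 0L)
    return(data.frame(spacerStart = integer(), mismatches = integer(),
                      spacer = character(), pam = character(),
                      stringsAsFactors = FALSE))
  chars <- strsplit(seqChar, "")[[1L]]
  # exclude any site overlapping a non-ACGT base (N runs etc.)
  bad <- cumsum(!chars %in% ACGT)
  siteFrom <- pmin(ss, ps); siteTo <- pmax(se, pe)
  clean <- (bad[siteTo] - ifelse(siteFrom > 1L, bad[siteFrom - 1L], 0L)) == 0L
  ps <- ps[clean]; pe <- pe[clean]; ss <- ss[clean]; se <- se[clean]
  if (length(ss) == 0L)
    return(data.frame(spacerStart = integer(), mismatches = integer(),
                      spacer = character(), pam = character(),
                      stringsAsFactors = FALSE))
  mm <- integer(length(ss))
  for (j in seq_len(sl))
    mm <- mm + (chars[ss + j - 1L] != spacerChars[j])
  keep <- which(mm <= maxMismatches)
  if (length(keep) == 0L)
    return(data.frame(spacerStart = integer(), mismatches = integer(),
                      spacer = character(), pam = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    spacerStart = ss[keep], mismatches = mm[keep],
    spacer = substring(seqChar, ss[keep], se[keep]),
    pam = substring(seqChar, ps[keep], pe[keep]),
    stringsAsFactors = FALSE)
}

#' Scan a genome for off-target sites of a spacer
#'
#' Returns every position, on either strand of every FASTA record, where
#' the nuclease's PAM pattern matches exactly (degenerate IUPAC match,
#' zero PAM tolerance) and the adjacent full-length protospacer differs
#' from the query spacer by at most \code{maxMismatches} (Hamming
#' distance over the spacer only). Sites overlapping a non-ACGT genome
#' base are excluded. DNA/RNA bulges are not modelled.
#'
#' @param genome Path to a FASTA file (plain or gzip), or a
#'   [Biostrings::DNAStringSet].
#' @param spacer Query spacer, ACGT, 5'\eqn{\to}3'.
#' @param profile [NucleaseProfile-class] or registry name; fixes the PAM
#'   pattern and side.
#' @param maxMismatches Spacer mismatch bound (default 2).
#' @param onTarget Optional \code{list(seq_name=, position=, strand=)}
#'   marking the known on-target locus; matching hits get
#'   \code{is_on_target = TRUE}.
#' @return [S4Vectors::DataFrame] with columns \code{seq_name},
#'   \code{position} (0-based protospacer start on the forward strand),
#'   \code{strand}, \code{mismatches}, \code{site_spacer},
#'   \code{site_pam} (and \code{is_on_target} when \code{onTarget} is
#'   given), sorted by seq_name, position, strand.
#'   \code{metadata()} carries the per-mismatch-count summary
#'   \code{n_mm} (hits at 0, 1, ..., maxMismatches mismatches).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr_toy", strrep("AT", 30),
#'              "CCAGTACGTACGTACGTACGTACGG", strrep("TA", 30)), fa)
#' findOffTargets(fa, "CAGTACGTACGTACGTACGT", "SpCas9")
#' @export
findOffTargets <- function(genome, spacer, profile, maxMismatches = 2L,
                           onTarget = NULL) {
  if (is.character(profile)) profile <- nucleaseProfile(profile)
  if (!grepl("^[ACGT]+$", spacer))
    stop("'spacer' must be a non-empty ACGT string")
  maxMismatches <- as.integer(maxMismatches)
  if (maxMismatches < 0L) stop("'maxMismatches' must be >= 0")
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("genome FASTA not readable: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (length(genome) == 0L) stop("genome FASTA contains no records")
  spacerChars <- strsplit(spacer, "")[[1L]]
  sl <- length(spacerChars)
  siteLen <- sl + nchar(profile@pamPattern)

  recNames <- sub("\\s.*$", "", names(genome))
  rows <- list()
  for (r in seq_along(genome)) {
    seqChar <- toupper(as.character(genome[[r]]))
    L <- nchar(seqChar)
    if (L < siteLen) {
      warning("record '", recNames[r], "' shorter than site length; skipped")
      next
    }
    fwd <- scanStrandOffTargets(seqChar, spacerChars, profile, maxMismatches)
    if (nrow(fwd))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_name = recNames[r], position = fwd$spacerStart - 1L,
        strand = "+", mismatches = fwd$mismatches,
        site_spacer = fwd$spacer, site_pam = fwd$pam,
        stringsAsFactors = FALSE)
    rev <- scanStrandOffTargets(revcompChar(seqChar), spacerChars, profile,
                                maxMismatches)
    if (nrow(rev)) {
      se <- rev$spacerStart + sl - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        seq_name = recNames[r], position = L - se,
        strand = "-", mismatches = rev$mismatches,
        site_spacer = rev$spacer, site_pam = rev$pam,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_name = character(), position = integer(),
               strand = character(), mismatches = integer(),
               site_spacer = character(), site_pam = character(),
               stringsAsFactors = FALSE)
  df <- df[order(df$seq_name, df$position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(onTarget))
    df$is_on_target <- df$seq_name == onTarget$seq_name &
      df$position == onTarget$position & df$strand == onTarget$strand
  out <- S4Vectors::DataFrame(df)
  nmm <- vapply(0:maxMismatches, function(k) sum(df$mismatches == k),
                integer(1L))
  names(nmm) <- paste0("n_mm", 0:maxMismatches)
  S4Vectors::metadata(out) <- list(
    spacer = spacer, profile = profile@name,
    max_mismatches = maxMismatches, n_mm = nmm)
  out
}

#' Per-candidate off-target summary
#'
#' @param hits Output of [findOffTargets()].
#' @return Named list: the query spacer plus hit counts at each mismatch
#'   level (\code{n_mm0}, \code{n_mm1}, ...).
#' @export
offTargetSummary <- function(hits) {
  md <- S4Vectors::metadata(hits)
  c(list(candidate = md$spacer, profile = md$profile,
         max_mismatches = md$max_mismatches), as.list(md$n_mm))
}

#' Write off-target hits to TSV
#'
#' @param hits Output of [findOffTargets()].
#' @param path Output file.
#' @export
writeOffTargets <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
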