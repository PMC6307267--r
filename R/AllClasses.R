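#' @import methods
#' @importFrom BiocGenerics start end width
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @useDynLib baseEditR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' NucleaseProfile: a Cas nuclease PAM profile
#'
#' Describes one CRISPR nuclease variant: its PAM pattern in IUPAC
#' degenerate codes, which side of the protospacer the PAM abuts
#' (3' for Cas9-family enzymes, 5' for Cpf1/Cas12a), and the supported
#' spacer-length range.
#'
#' @slot name Short identifier, e.g. \code{"SpCas9"}.
#' @slot pamPattern PAM in IUPAC codes, written 5'\eqn{\to}3',
#'   e.g. \code{"NGG"}.
#' @slot pamSide \code{"three_prime"} or \code{"five_prime"}.
#' @slot spacerDefault,spacerMin,spacerMax Spacer (protospacer) length
#'   default and permitted bounds, in nt.
#'
#' @seealso [builtinProfiles()], [nucleaseProfile()]
#' @export
setClass("NucleaseProfile",
  representation(
    name = "character",
    pamPattern = "character",
    pamSide = "character",
    spacerDefault = "integer",
    spacerMin = "integer",
    spacerMax = "integer"
  )
)

setValidity("NucleaseProfile", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  pat <- object@pamPattern
  if (length(pat) != 1L || !nzchar(pat))
    msg <- c(msg, "'pamPattern' must be a non-empty string")
  else if (!all(strsplit(pat, "")[[1]] %in% names(IUPAC_SETS)))
    msg <- c(msg, "'pamPattern' must use only the 15 IUPAC codes")
  if (!object@pamSide %in% c("three_prime", "five_prime"))
    msg <- c(msg, "'pamSide' must be 'three_prime' or 'five_prime'")
  if (!(object@spacerMin <= object@spacerDefault &&
        object@spacerDefault <= object@spacerMax))
    msg <- c(msg, "spacer lengths must satisfy min <= default <= max")
  if (object@spacerMin < 15L || object@spacerMax > 25L)
    msg <- c(msg, "spacer length bounds must lie in [15, 25]")
  if (length(msg)) msg else TRUE
})

#' EditorPreset: a base-editor deaminase preset
#'
#' Describes a base editor: which base its deaminase edits (C for
#' cytosine base editors, A for adenine base editors), which product
#' bases count as intended conversions (C\eqn{\to}D = A/G/T for CBEs,
#' A\eqn{\to}G for ABEs), and the editing window expressed as nt
#' upstream of the PAM (distal \eqn{\ge} proximal).
#'
#' @slot name Preset identifier, e.g. \code{"BE3"}.
#' @slot editedBase \code{"C"} or \code{"A"}.
#' @slot productBases Bases counted as intended products.
#' @slot windowProximal,windowDistal Editing window bounds in nt upstream
#'   of the PAM (e.g. BE3: 13--17).
#'
#' @seealso [builtinEditors()], [editorPreset()]
#' @export
setClass("EditorPreset",
  representation(
    name = "character",
    editedBase = "character",
    productBases = "character",
    windowProximal = "integer",
    windowDistal = "integer"
  )
)

setValidity("EditorPreset", function(object) {
  msg <- character()
  if (!object@editedBase %in% c("C", "A"))
    msg <- c(msg, "'editedBase' must be 'C' or 'A'")
  if (object@editedBase == "C" &&
      !all(object@productBases %in% c("A", "G", "T")))
    msg <- c(msg, "for a CBE, product bases must be within {A,G,T}")
  if (object@editedBase == "A" &&
      !identical(sort(object@productBases), "G"))
    msg <- c(msg, "for an ABE, product bases must be exactly {G}")
  if (object@windowProximal > object@windowDistal)
    msg <- c(msg, "windowProximal must be <= windowDistal")
  if (object@windowProximal < 1L)
    msg <- c(msg, "window positions are 1-based distances upstream of the PAM")
  if (length(msg)) msg else TRUE
})

#' AnalysisConfig: parameters for one amplicon analysis run
#'
#' Bundles everything the analyzer needs: the wild-type reference
#' amplicon, the target site (spacer + PAM) locating the protospacer
#' within it, the editor preset, an optional editing-window override,
#' flank widths on each side of the window, the minimum read count for a
#' unique sequence to be analyzed, and the reading-frame offset used for
#' amino-acid display.
#'
#' @slot reference Wild-type amplicon sequence (ACGT).
#' @slot targetSite Spacer + PAM as it reads 5'\eqn{\to}3' on the
#'   targeted strand.
#' @slot targetStrand \code{"+"} if the target site reads on the
#'   reference as given, \code{"-"} if on its reverse complement.
#' @slot nuclease [NucleaseProfile-class] (fixes the PAM side and length).
#' @slot editor [EditorPreset-class].
#' @slot windowOverride Optional \code{c(proximal, distal)} nt upstream
#'   of PAM; \code{integer(0)} to use the editor's default window.
#' @slot flankLeft,flankRight Analysis flanks (nt) on each side of the
#'   editing window, in reference orientation.
#' @slot minFrequency Minimum absolute read count per unique sequence.
#' @slot frameOffset Reading-frame offset (0, 1 or 2) for translation.
#'
#' @seealso [analysisConfig()], [analyzeBaseEdits()]
#' @export
setClass("AnalysisConfig",
  representation(
    reference = "character",
    targetSite = "character",
    targetStrand = "character",
    nuclease = "NucleaseProfile",
    editor = "EditorPreset",
    windowOverride = "integer",
    flankLeft = "integer",
    flankRight = "integer",
    minFrequency = "integer",
    frameOffset = "integer"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!grepl("^[ACGT]+$", object@reference))
    msg <- c(msg, "'reference' must be a non-empty ACGT string")
  if (!grepl("^[ACGT]+$", object@targetSite))
    msg <- c(msg, "'targetSite' must be a non-empty ACGT string")
  if (!object@targetStrand %in% c("+", "-"))
    msg <- c(msg, "'targetStrand' must be '+' or '-'")
  if (!length(object@windowOverride) %in% c(0L, 2L))
    msg <- c(msg, "'windowOverride' must be empty or c(proximal, distal)")
  if (length(object@windowOverride) == 2L &&
      object@windowOverride[1L] > object@windowOverride[2L])
    msg <- c(msg, "window override must satisfy proximal <= distal")
  if (object@flankLeft < 0L || object@flankRight < 0L)
    msg <- c(msg, "flanks must be >= 0")
  if (object@minFrequency < 1L)
    msg <- c(msg, "'minFrequency' must be >= 1")
  if (!object@frameOffset %in% 0:2)
    msg <- c(msg, "'frameOffset' must be 0, 1 or 2")
  if (length(msg) == 0L) {
    site <- if (object@targetStrand == "+") object@targetSite else
      revcompChar(object@targetSite)
    n <- length(gregexpr(site, object@reference, fixed = TRUE)[[1L]])
    hit <- gregexpr(site, object@reference, fixed = TRUE)[[1L]][1L] != -1L
    if (!hit)
      msg <- c(msg, "target site not found in reference on declared strand")
    else if (n > 1L)
      msg <- c(msg, "target site occurs more than once in reference")
  }
  if (length(msg)) msg else TRUE
})

#' RunSummary: the analyzer's nine-field statistics record
#'
#' The per-run summary table: total reads, reads carrying both 15-nt
#' indicator sequences, reads above the minimum frequency, and the
#' four-way classification counts (wild type / insertion / deletion /
#' substitution), plus the number of reads with intended conversions in
#' the editing window and the intended substitution rate (intended reads
#' divided by reads above minimum frequency). \code{perProductRate}
#' additionally reports the rate for each specific product (e.g. the
#' C-to-T substitution rate for a CBE).
#'
#' @seealso [summarizeRun()], [analyzeBaseEdits()]
#' @export
setClass("RunSummary",
  representation(
    totalSequences = "integer",
    withBothIndicators = "integer",
    aboveMinFrequency = "integer",
    wt = "integer",
    insertions = "integer",
    deletions = "integer",
    withSubstitution = "integer",
    intendedInWindow = "integer",
    intendedRate = "numeric",
    perProductRate = "numeric"
  )
)

setValidity("RunSummary", function(object) {
  msg <- character()
  if (object@wt + object@insertions + object@deletions +
      object@withSubstitution != object@aboveMinFrequency)
    msg <- c(msg, "class counts must sum to aboveMinFrequency")
  if (object@intendedRate < 0 || object@intendedRate > 1)
    msg <- c(msg, "intendedRate must lie in [0, 1]")
  if (object@intendedInWindow > object@withSubstitution)
    msg <- c(msg, "intendedInWindow cannot exceed withSubstitution")
  if (length(msg)) msg else TRUE
})

#' SubstitutionProfile: per-position substitution table
#'
#' Per reference position across the editing window plus flanks:
#' the percentage of each nucleotide among substitution-class reads
#' covering the position gap-free (\code{basePercent}), the same among
#' all classified reads (\code{basePercentAll}, the heat-map view), and
#' at edited-base positions the per-product transition rate (for a CBE:
#' C\eqn{\to}T, C\eqn{\to}G, C\eqn{\to}A) as a fraction of covering
#' substitution-class reads. After [controlOverlay()], \code{controlRate}
#' holds the control run's transition rates as negative-signed display
#' values and \code{background} flags positions where the control rate
#' reaches the treated rate.
#'
#' @seealso [substitutionProfile()], [controlOverlay()]
#' @export
setClass("SubstitutionProfile",
  representation(
    positions = "integer",       # 1-based reference coordinates
    refBases = "character",
    basePercent = "matrix",      # 4 x npos, rows A/C/G/T, percent
    basePercentAll = "matrix",
    transitionRate = "matrix",   # nproduct x npos, fraction, NA off-site
    controlRate = "matrix",      # negative-signed display values
    background = "logical",
    coverage = "integer",        # substitution-class reads covering gap-free
    empty = "logical"            # no substitution-class reads at all
  )
)

setValidity("SubstitutionProfile", function(object) {
  npos <- length(object@positions)
  msg <- character()
  if (length(object@refBases) != npos)
    msg <- c(msg, "refBases length must match positions")
  if (ncol(object@basePercent) != npos)
    msg <- c(msg, "basePercent must have one column per position")
  tr <- object@transitionRate
  if (length(tr) && any(tr[!is.na(tr)] < 0 | tr[!is.na(tr)] > 1))
    msg <- c(msg, "transition rates must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' BaseEditResult: full output of one analyzer run
#'
#' Container returned by [analyzeBaseEdits()]: the [RunSummary-class],
#' the aligned unique reads with classification labels, the
#' [SubstitutionProfile-class], amino-acid reading frames, and the
#' filtering / merging bookkeeping.
#'
#' @seealso [analyzeBaseEdits()]
#' @export
setClass("BaseEditResult",
  representation(
    summary = "RunSummary",
    alignments = "DataFrame",
    profile = "SubstitutionProfile",
    frames = "DataFrame",
    filterStats = "integer",
    mergeReport = "integer",
    config = "AnalysisConfig"
  )
)
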