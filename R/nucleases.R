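# Built-in nuclease profiles and editor presets, plus IUPAC matching.

newProfile <- function(name, pam, side = "three_prime",
                       default = 20L, min = 15L, max = 25L) {
  new("NucleaseProfile", name = name, pamPattern = pam, pamSide = side,
      spacerDefault = as.integer(default), spacerMin = as.integer(min),
      spacerMax = as.integer(max))
}

newEditor <- function(name, editedBase, productBases, proximal, distal) {
  new("EditorPreset", name = name, editedBase = editedBase,
      productBases = productBases, windowProximal = as.integer(proximal),
      windowDistal = as.integer(distal))
}

#' Built-in nuclease profiles
#'
#' The registry of the 12 supported CRISPR nuclease variants: SpCas9 and
#' its engineered PAM variants, xCas9 3.7 (registered once per PAM, NGR
#' and NG), StCas9, CjCas9, SaCas9 and SaCas9-KKH (all with a 3' PAM),
#' and the two Cpf1/Cas12a orthologs AsCpf1 and LbCpf1 (5' TTTV PAM).
#' Spacer length is configurable from 15 to 25 nt; the default is 20 nt
#' for Cas9-family enzymes, 22 nt for CjCas9 and 23 nt for Cpf1.
#'
#' @return Named list of [NucleaseProfile-class] objects, length 12.
#' @examples
#' names(builtinProfiles())
#' pamPattern(nucleaseProfile("SaCas9-KKH"))  # "NNNRRT"
#' @export
builtinProfiles <- function() {
  profiles <- list(
    newProfile("SpCas9",      "NGG"),
    newProfile("SpCas9-VQR",  "NGAN"),
    newProfile("SpCas9-EQR",  "NGAG"),
    newProfile("SpCas9-VRER", "NGCG"),
    newProfile("xCas9-NGR",   "NGR"),
    newProfile("xCas9-NG",    "NG"),
    newProfile("StCas9",      "NNAGAAW"),
    newProfile("CjCas9",      "NNNVRYAC", default = 22L),
    newProfile("SaCas9",      "NNGRRT"),
    newProfile("SaCas9-KKH",  "NNNRRT"),
    newProfile("AsCpf1",      "TTTV", side = "five_prime", default = 23L),
    newProfile("LbCpf1",      "TTTV", side = "five_prime", default = 23L)
  )
  names(profiles) <- vapply(profiles, function(p) p@name, character(1L))
  profiles
}

#' Built-in editor presets
#'
#' Base-editor presets with their published editing windows, expressed
#' as nt upstream of the PAM: BE3 (C, 13--17), Target-AID (C, 15--19)
#' and ABE (A, products G). ABE's window defaults to 13--17; override it
#' via \code{windowOverride} in [analysisConfig()] when your editor's
#' active window differs. Cytosine presets count any C\eqn{\to}D
#' (D = A, G or T) conversion as intended.
#'
#' @return Named list of [EditorPreset-class] objects.
#' @examples
#' editorWindow(editorPreset("BE3"))        # 13 17
#' editorWindow(editorPreset("Target-AID")) # 15 19
#' @export
builtinEditors <- function() {
  editors <- list(
    newEditor("BE3",        "C", c("T", "G", "A"), 13L, 17L),
    newEditor("Target-AID", "C", c("T", "G", "A"), 15L, 19L),
    newEditor("ABE",        "A", "G",              13L, 17L)
  )
  names(editors) <- vapply(editors, function(e) e@name, character(1L))
  editors
}

#' Look up a built-in nuclease profile or editor preset by name
#'
#' @param name Registry name (see [builtinProfiles()], [builtinEditors()]).
#' @return The matching [NucleaseProfile-class] / [EditorPreset-class].
#' @examples
#' nucleaseProfile("SpCas9")
#' editorPreset("ABE")
#' @export
nucleaseProfile <- function(name) {
  reg <- builtinProfiles()
  if (!name %in% names(reg))
    stop("unknown nuclease '", name, "'; valid names: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' @rdname nucleaseProfile
#' @export
editorPreset <- function(name) {
  reg <- builtinEditors()
  if (!name %in% names(reg))
    stop("unknown editor '", name, "'; valid names: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Match a degenerate IUPAC pattern against a concrete DNA sequence
#'
#' Positionwise degenerate comparison: position i matches when the
#' sequence base belongs to the degeneracy set of the pattern code
#' (N = \{A,C,G,T\}, R = \{A,G\}, V = \{A,C,G\}, ...).
#'
#' @param pattern IUPAC string.
#' @param sequence ACGT string of the same length.
#' @return \code{TRUE} iff every position matches.
#' @examples
#' iupacMatches("NGG", "AGG")       # TRUE
#' iupacMatches("NNGRRT", "AAGAAT") # TRUE
#' iupacMatches("NGCG", "AGCA")     # FALSE
#' @export
iupacMatches <- function(pattern, sequence) {
  if (nchar(pattern) != nchar(sequence))
    stop("pattern and sequence must have equal length")
  pat <- strsplit(pattern, "")[[1L]]
  seq <- strsplit(sequence, "")[[1L]]
  if (!all(pat %in% names(IUPAC_SETS)))
    stop("invalid IUPAC code in pattern: ",
         paste(setdiff(pat, names(IUPAC_SETS)), collapse = ", "))
  if (!all(seq %in% c("A", "C", "G", "T")))
    stop("sequence must contain only A/C/G/T")
  all(mapply(function(p, s) s %in% IUPAC_SETS[[p]], pat, seq))
}

# effective window of an editor with an optional override; returns
# c(proximal, distal) in nt upstream (3' PAM) / downstream (5' PAM) of PAM
effectiveWindow <- function(editor, windowOverride = integer(0)) {
  if (length(windowOverride) == 2L) as.integer(windowOverride)
  else c(editor@windowProximal, editor@windowDistal)
}

# map window (nt from PAM) to 0-based spacer offsets.
# 3' PAM: distance d upstream of the PAM -> offset spacerLength - d.
# 5' PAM (Cpf1): distance d downstream of the PAM -> offset d - 1
# (positions count from the PAM-proximal, i.e. 5', end of the spacer).
windowToSpacerOffsets <- function(window, spacerLength, pamSide) {
  d <- window[1L]:window[2L]
  if (any(d < 1L) || any(d > spacerLength))
    stop("editing window [", window[1L], ", ", window[2L],
         "] does not fit a spacer of length ", spacerLength)
  offs <- if (pamSide == "three_prime") spacerLength - d else d - 1L
  sort(as.integer(offs))
}

#' Export the registry as JSON
#'
#' Serializes the built-in nuclease profiles and editor presets to a
#' JSON document (used by the CLI's \code{list-nucleases} /
#' \code{list-editors} subcommands).
#'
#' @param path Optional file to write; when \code{NULL} the JSON string
#'   is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
registryAsJSON <- function(path = NULL) {
  profs <- lapply(builtinProfiles(), function(p) list(
    name = p@name, pam_pattern = p@pamPattern, pam_side = p@pamSide,
    spacer_length_default = p@spacerDefault,
    spacer_length_min = p@spacerMin, spacer_length_max = p@spacerMax))
  eds <- lapply(builtinEditors(), function(e) list(
    name = e@name, edited_base = e@editedBase,
    product_bases = e@productBases,
    window_proximal = e@windowProximal, window_distal = e@windowDistal))
  js <- jsonlite::toJSON(list(nucleases = unname(profs),
                              editors = unname(eds)),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
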