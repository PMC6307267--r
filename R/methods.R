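# Accessors and show methods.

#' @rdname NucleaseProfile-class
#' @export
setMethod("pamPattern", "NucleaseProfile", function(x) x@pamPattern)

#' @rdname NucleaseProfile-class
#' @export
setMethod("pamSide", "NucleaseProfile", function(x) x@pamSide)

#' @rdname NucleaseProfile-class
#' @export
setMethod("spacerLengths", "NucleaseProfile", function(x)
  c(min = x@spacerMin, default = x@spacerDefault, max = x@spacerMax))

#' @rdname EditorPreset-class
#' @export
setMethod("editedBase", "EditorPreset", function(x) x@editedBase)

#' @rdname EditorPreset-class
#' @export
setMethod("productBases", "EditorPreset", function(x) x@productBases)

#' @rdname EditorPreset-class
#' @export
setMethod("editorWindow", "EditorPreset", function(x)
  c(proximal = x@windowProximal, distal = x@windowDistal))

#' @rdname BaseEditResult-class
#' @export
setMethod("runSummary", "BaseEditResult", function(x) x@summary)

#' @rdname BaseEditResult-class
#' @export
setMethod("alignments", "BaseEditResult", function(x) x@alignments)

#' @rdname BaseEditResult-class
#' @export
setMethod("substitutionProfile", "BaseEditResult", function(x) x@profile)

#' @rdname RunSummary-class
#' @export
setMethod("intendedRate", "RunSummary", function(x) x@intendedRate)

#' @rdname RunSummary-class
#' @export
setMethod("intendedRate", "BaseEditResult", function(x)
  x@summary@intendedRate)

setMethod("show", "NucleaseProfile", function(object) {
  side <- if (object@pamSide == "three_prime") "3'" else "5'"
  cat(sprintf("NucleaseProfile %s: PAM %s (%s), spacer %d nt [%d-%d]\n",
              object@name, object@pamPattern, side, object@spacerDefault,
              object@spacerMin, object@spacerMax))
})

setMethod("show", "EditorPreset", function(object) {
  cat(sprintf(
    "EditorPreset %s: %s -> {%s}, window %d-%d nt upstream of PAM\n",
    object@name, object@editedBase,
    paste(object@productBases, collapse = ","),
    object@windowProximal, object@windowDistal))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat(sprintf("  reference: %d nt amplicon\n", nchar(object@reference)))
  cat(sprintf("  target site: %s (%s strand)\n", object@targetSite,
              object@targetStrand))
  cat(sprintf("  nuclease: %s  editor: %s\n", object@nuclease@name,
              object@editor@name))
  w <- effectiveWindow(object@editor, object@windowOverride)
  cat(sprintf("  window: %d-%d nt from PAM; flanks %d/%d; min freq %d\n",
              w[1L], w[2L], object@flankLeft, object@flankRight,
              object@minFrequency))
})

#' @rdname RunSummary-class
#' @param object A [RunSummary-class].
#' @export
setMethod("show", "RunSummary", function(object) {
  cat("RunSummary\n")
  fields <- c(
    "Total sequences"                = object@totalSequences,
    "With both indicator sequences"  = object@withBothIndicators,
    "More than minimum frequency"    = object@aboveMinFrequency,
    "Wild type"                      = object@wt,
    "Insertions"                     = object@insertions,
    "Deletions"                      = object@deletions,
    "With substitutions"             = object@withSubstitution,
    "Intended conversions in window" = object@intendedInWindow)
  for (i in seq_along(fields))
    cat(sprintf("  %-31s %d\n", names(fields)[i], fields[i]))
  cat(sprintf("  %-31s %.4f\n", "Intended substitution rate",
              object@intendedRate))
  if (length(object@perProductRate))
    for (i in seq_along(object@perProductRate))
      cat(sprintf("  %-31s %.4f\n", names(object@perProductRate)[i],
                  object@perProductRate[i]))
})

setMethod("show", "SubstitutionProfile", function(object) {
  cat(sprintf("SubstitutionProfile over %d positions (%d-%d)%s\n",
              length(object@positions), min(object@positions),
              max(object@positions),
              if (object@empty) " [no substitution-class reads]" else ""))
  if (length(object@controlRate))
    cat(sprintf("  control overlay attached; %d background position(s)\n",
                sum(object@background, na.rm = TRUE)))
})

setMethod("show", "BaseEditResult", function(object) {
  cat("BaseEditResult\n")
  show(object@summary)
  cat(sprintf("  %d aligned unique sequence(s)\n", nrow(object@alignments)))
})

#' Coerce a RunSummary to a one-row data.frame
#'
#' @param x A [RunSummary-class].
#' @param ... Unused.
#' @return A one-row \code{data.frame} with the nine summary columns.
#' @export
as.data.frame.RunSummary <- function(x, ...) {
  data.frame(
    total_sequences = x@totalSequences,
    with_both_indicators = x@withBothIndicators,
    above_min_frequency = x@aboveMinFrequency,
    wt = x@wt,
    insertions = x@insertions,
    deletions = x@deletions,
    with_substitution = x@withSubstitution,
    intended_in_window = x@intendedInWindow,
    intended_rate = x@intendedRate)
}

runSummaryAsList <- function(x) {
  c(as.list(as.data.frame.RunSummary(x)),
    list(per_product_rate = as.list(x@perProductRate)))
}
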