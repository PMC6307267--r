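#' @rdname NucleaseProfile-class
#' @param x A package object.
#' @export
setGeneric("pamPattern", function(x) standardGeneric("pamPattern"))

#' @rdname NucleaseProfile-class
#' @export
setGeneric("pamSide", function(x) standardGeneric("pamSide"))

#' @rdname NucleaseProfile-class
#' @export
setGeneric("spacerLengths", function(x) standardGeneric("spacerLengths"))

#' @rdname EditorPreset-class
#' @param x A package object.
#' @export
setGeneric("editedBase", function(x) standardGeneric("editedBase"))

#' @rdname EditorPreset-class
#' @export
setGeneric("productBases", function(x) standardGeneric("productBases"))

#' @rdname EditorPreset-class
#' @export
setGeneric("editorWindow", function(x) standardGeneric("editorWindow"))

#' @rdname BaseEditResult-class
#' @param x A [BaseEditResult-class].
#' @export
setGeneric("runSummary", function(x) standardGeneric("runSummary"))

#' @rdname BaseEditResult-class
#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))

#' @rdname BaseEditResult-class
#' @export
setGeneric("substitutionProfile",
           function(x) standardGeneric("substitutionProfile"))

#' @rdname RunSummary-class
#' @param x A [RunSummary-class] or [BaseEditResult-class].
#' @export
setGeneric("intendedRate", function(x) standardGeneric("intendedRate"))
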