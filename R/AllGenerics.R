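#' @rdname BaseEditor-class
#' @param object,x a `BaseEditor`, `EditorRegistry` or `ScreeningOutcome`.
#' @export
setGeneric("editorName", function(x) standardGeneric("editorName"))

#' @rdname BaseEditor-class
#' @export
setGeneric("editorClass", function(x) standardGeneric("editorClass"))

#' @rdname BaseEditor-class
#' @export
setGeneric("targetBase", function(x) standardGeneric("targetBase"))

#' @rdname BaseEditor-class
#' @export
setGeneric("convertedBase", function(x) standardGeneric("convertedBase"))

#' @rdname BaseEditor-class
#' @export
setGeneric("pamPattern", function(x) standardGeneric("pamPattern"))

#' @rdname BaseEditor-class
#' @export
setGeneric("activityWindow", function(x) standardGeneric("activityWindow"))

#' @rdname BaseEditor-class
#' @export
setGeneric("spacerLength", function(x) standardGeneric("spacerLength"))

#' @rdname EditorRegistry-class
#' @param x an `EditorRegistry`.
#' @export
setGeneric("editorNames", function(x) standardGeneric("editorNames"))

#' Look up an editor by name
#'
#' Lookup is case-insensitive on the editor name.
#'
#' @param x an [EditorRegistry-class].
#' @param name editor identifier, e.g. `"BE3"` or `"abe7.10"`.
#' @return the matching [BaseEditor-class].
#' @examples
#' getEditor(loadEditors(), "be3")
#' @export
setGeneric("getEditor", function(x, name) standardGeneric("getEditor"))

#' @rdname ScreeningOutcome-class
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname ScreeningOutcome-class
#' @export
setGeneric("siteStatus", function(x) standardGeneric("siteStatus"))

#' @rdname ScreeningOutcome-class
#' @export
setGeneric("failReason", function(x) standardGeneric("failReason"))
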