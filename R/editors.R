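#' Construct a base editor
#'
#' User-level constructor for [BaseEditor-class]. The target and converted
#' bases follow from the editor class (CBE: C to T; ABE: A to G) and need not
#' be supplied; supplying values inconsistent with the class is an error.
#'
#' @param name short identifier.
#' @param editorClass `"CBE"` or `"ABE"`.
#' @param pamPattern IUPAC PAM immediately 3' of the protospacer.
#' @param windowStart,windowEnd activity window, 1-based within the
#'   protospacer from the PAM-distal end, inclusive.
#' @param spacerLength protospacer length in nt.
#' @param targetBase,convertedBase optional; normally derived from
#'   `editorClass`.
#' @return a validated `BaseEditor`.
#' @examples
#' BaseEditor("BE4max", "CBE", "NGG", 4, 8, 20)
#' @export
BaseEditor <- function(name, editorClass, pamPattern, windowStart, windowEnd,
                       spacerLength = 20L, targetBase = NULL,
                       convertedBase = NULL) {
  editorClass <- toupper(as.character(editorClass))
  defaults <- switch(editorClass,
    CBE = c("C", "T"),
    ABE = c("A", "G"),
    stop("configuration error in field 'class': must be CBE or ABE (got ",
         deparse(editorClass), ")", call. = FALSE)
  )
  if (is.null(targetBase)) targetBase <- defaults[1]
  if (is.null(convertedBase)) convertedBase <- defaults[2]
  new("BaseEditor",
    name = as.character(name), editorClass = editorClass,
    targetBase = toupper(targetBase), convertedBase = toupper(convertedBase),
    pamPattern = toupper(as.character(pamPattern)),
    windowStart = as.integer(windowStart), windowEnd = as.integer(windowEnd),
    spacerLength = as.integer(spacerLength)
  )
}

#' @rdname BaseEditor-class
#' @export
setMethod("editorName", "BaseEditor", function(x) x@name)
#' @rdname BaseEditor-class
#' @export
setMethod("editorClass", "BaseEditor", function(x) x@editorClass)
#' @rdname BaseEditor-class
#' @export
setMethod("targetBase", "BaseEditor", function(x) x@targetBase)
#' @rdname BaseEditor-class
#' @export
setMethod("convertedBase", "BaseEditor", function(x) x@convertedBase)
#' @rdname BaseEditor-class
#' @export
setMethod("pamPattern", "BaseEditor", function(x) x@pamPattern)
#' @rdname BaseEditor-class
#' @export
setMethod("activityWindow", "BaseEditor",
          function(x) c(x@windowStart, x@windowEnd))
#' @rdname BaseEditor-class
#' @export
setMethod("spacerLength", "BaseEditor", function(x) x@spacerLength)

setMethod("show", "BaseEditor", function(object) {
  cat(sprintf(
    "BaseEditor %s (%s, %s>%s): PAM %s, window %d-%d, spacer %d nt\n",
    object@name, object@editorClass, object@targetBase, object@convertedBase,
    object@pamPattern, object@windowStart, object@windowEnd,
    object@spacerLength))
  invisible(object)
})

# Shipped defaults. The classic NGG cytosine editor edits efficiently at
# protospacer positions 4-8; the adenine editor ABE7.10 has the narrower 4-7
# window. Both use a 20-nt spacer. All four numbers are config-overridable,
# so a user's registry file, not this code, is authoritative.
.shippedEditors <- function() {
  list(
    BaseEditor("BE3", "CBE", "NGG", 4L, 8L, 20L),
    BaseEditor("ABE7.10", "ABE", "NGG", 4L, 7L, 20L)
  )
}

.ALLOWED_EDITOR_KEYS <- c("name", "class", "pam", "window", "spacer")

.editorFromEntry <- function(entry, index) {
  if (!is.list(entry))
    stop("configuration error: editor entry ", index, " is not a mapping",
         call. = FALSE)
  unknown <- setdiff(names(entry), .ALLOWED_EDITOR_KEYS)
  if (length(unknown))
    stop("configuration error in editor entry ", index,
         ": unknown field(s) ", paste(sQuote(unknown), collapse = ", "),
         call. = FALSE)
  for (key in c("name", "class", "pam", "window", "spacer")) {
    if (is.null(entry[[key]]))
      stop("configuration error in editor entry ", index,
           ": missing field '", key, "'", call. = FALSE)
  }
  win <- suppressWarnings(as.integer(entry$window))
  if (length(win) != 2L || anyNA(win))
    stop("configuration error in field 'window' (entry ", index,
         "): expected two integers [start, end]", call. = FALSE)
  BaseEditor(entry$name, entry$class, entry$pam, win[1], win[2],
             entry$spacer)
}

#' Load a base-editor registry
#'
#' Builds an [EditorRegistry-class] from a YAML document listing editor
#' entries. The shipped defaults (BE3 and ABE7.10) are always present; a
#' config entry with the same name (case-insensitive) overrides the default.
#' An empty or missing config yields just the defaults.
#'
#' The schema is a top-level `editors:` sequence whose entries carry exactly
#' the keys `name`, `class` (CBE/ABE), `pam` (IUPAC string), `window`
#' (two-element `[start, end]`) and `spacer`. Unknown keys are rejected.
#'
#' @param config `NULL` or `""` for defaults only; otherwise a path to a
#'   YAML file or a YAML string.
#' @return an `EditorRegistry`.
#' @examples
#' loadEditors()
#' loadEditors("editors:\n- {name: X, class: CBE, pam: NGG, window: [4, 8], spacer: 20}")
#' @export
loadEditors <- function(config = NULL) {
  editors <- .shippedEditors()
  if (!is.null(config) && !(is.character(config) && !nzchar(config[1]))) {
    doc <- if (length(config) == 1L && file.exists(config)) {
      yaml::read_yaml(config)
    } else {
      yaml::yaml.load(paste(config, collapse = "\n"))
    }
    if (!is.null(doc)) {
      if (!is.list(doc) || length(setdiff(names(doc), "editors")))
        stop("configuration error: expected a single top-level 'editors' list",
             call. = FALSE)
      entries <- doc$editors
      for (i in seq_along(entries)) {
        ed <- .editorFromEntry(entries[[i]], i)
        drop <- vapply(editors, function(e) {
          toupper(e@name) == toupper(ed@name)
        }, logical(1))
        editors <- c(editors[!drop], list(ed))
      }
    }
  }
  names(editors) <- vapply(editors, function(e) e@name, character(1))
  new("EditorRegistry", editors = editors)
}

#' Serialize a registry back to YAML
#'
#' Inverse of [loadEditors()]: reloading the returned text (or file)
#' reproduces the identical registry.
#'
#' @param registry an [EditorRegistry-class].
#' @param path optional file to write; when `NULL` the YAML text is returned.
#' @return the YAML text, invisibly when written to a file.
#' @export
writeEditors <- function(registry, path = NULL) {
  stopifnot(is(registry, "EditorRegistry"))
  entries <- lapply(registry@editors, function(e) {
    list(name = e@name, class = e@editorClass, pam = e@pamPattern,
         window = c(e@windowStart, e@windowEnd), spacer = e@spacerLength)
  })
  txt <- yaml::as.yaml(list(editors = unname(entries)))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname EditorRegistry-class
#' @export
setMethod("editorNames", "EditorRegistry", function(x) {
  vapply(x@editors, function(e) e@name, character(1), USE.NAMES = FALSE)
})

#' @rdname getEditor
#' @export
setMethod("getEditor", "EditorRegistry", function(x, name) {
  nms <- editorNames(x)
  i <- match(toupper(name), toupper(nms))
  if (is.na(i))
    stop("unknown editor ", sQuote(name), "; available: ",
         paste(nms, collapse = ", "), call. = FALSE)
  x@editors[[i]]
})

setMethod("show", "EditorRegistry", function(object) {
  cat("EditorRegistry with", length(object@editors), "editor(s):\n")
  for (e in object@editors) show(e)
  invisible(object)
})
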