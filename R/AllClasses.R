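#' @import methods
#' @importFrom stats pbeta runif rbinom rnorm setNames
#' @importFrom utils read.delim write.table head
NULL

.BASES <- c("A", "C", "G", "T")
.FAIL_LABELS <- c("base_match_error", "no_PAM", "activity_window_error",
                  "continuous_identical_base_error", "GC_ratio_error")

#' BaseEditor: chemistry and geometry of one base editor
#'
#' A `BaseEditor` describes everything the screening model needs to know
#' about an editor: which base it deaminates (`targetBase`) and what that
#' base is read as after repair (`convertedBase`), the PAM it requires
#' immediately 3' of the protospacer (IUPAC pattern), the activity window
#' within the protospacer where deamination is efficient, and the spacer
#' length. Window coordinates are 1-based positions within the protospacer
#' counted from the PAM-distal (5') end, both ends inclusive -- the
#' convention of the base-editing literature.
#'
#' Class constraints are enforced by the validity method: cytosine editors
#' (`editorClass == "CBE"`) convert C to T, adenine editors (`"ABE"`)
#' convert A to G, and the window must lie inside the spacer.
#'
#' @slot name short identifier, e.g. `"BE3"`.
#' @slot editorClass `"CBE"` or `"ABE"`.
#' @slot targetBase single nucleotide the deaminase acts on.
#' @slot convertedBase nucleotide the target is converted to.
#' @slot pamPattern IUPAC string, e.g. `"NGG"`, immediately 3' of the
#'   protospacer.
#' @slot windowStart,windowEnd activity window bounds (1-based, inclusive,
#'   from the 5' end of the protospacer).
#' @slot spacerLength protospacer length in nt.
#'
#' @seealso [BaseEditor()] for the user constructor, [loadEditors()] for the
#'   registry.
#' @export
setClass("BaseEditor",
  representation(
    name = "character",
    editorClass = "character",
    targetBase = "character",
    convertedBase = "character",
    pamPattern = "character",
    windowStart = "integer",
    windowEnd = "integer",
    spacerLength = "integer"
  )
)

setValidity("BaseEditor", function(object) {
  msgs <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a non-empty string")
  if (!object@editorClass %in% c("CBE", "ABE"))
    msgs <- c(msgs, "'editorClass' must be \"CBE\" or \"ABE\"")
  if (!object@targetBase %in% .BASES || !object@convertedBase %in% .BASES)
    msgs <- c(msgs, "targetBase/convertedBase must each be one of A,C,G,T")
  if (object@editorClass == "CBE" &&
      !(identical(object@targetBase, "C") && identical(object@convertedBase, "T")))
    msgs <- c(msgs, "a CBE must convert C to T")
  if (object@editorClass == "ABE" &&
      !(identical(object@targetBase, "A") && identical(object@convertedBase, "G")))
    msgs <- c(msgs, "an ABE must convert A to G")
  if (length(object@pamPattern) != 1L || !nzchar(object@pamPattern) ||
      !all(strsplit(object@pamPattern, "")[[1]] %in%
           names(Biostrings::IUPAC_CODE_MAP)))
    msgs <- c(msgs, "'pamPattern' must be a non-empty IUPAC nucleotide string")
  if (is.na(object@spacerLength) || object@spacerLength < 1L)
    msgs <- c(msgs, "'spacerLength' must be a positive integer")
  if (is.na(object@windowStart) || is.na(object@windowEnd) ||
      object@windowStart < 1L || object@windowStart > object@windowEnd ||
      object@windowEnd > object@spacerLength)
    msgs <- c(msgs,
      "activity window must satisfy 1 <= windowStart <= windowEnd <= spacerLength")
  if (length(msgs)) msgs else TRUE
})

#' EditorRegistry: a validated collection of base editors
#'
#' Holds [BaseEditor-class] objects under case-insensitively unique names.
#' Obtain one with [loadEditors()]; look editors up with [getEditor()].
#'
#' @slot editors named list of `BaseEditor` objects.
#' @export
setClass("EditorRegistry", representation(editors = "list"))

setValidity("EditorRegistry", function(object) {
  if (!all(vapply(object@editors, is, logical(1), "BaseEditor")))
    return("all registry entries must be BaseEditor objects")
  nms <- vapply(object@editors, function(e) e@name, character(1))
  if (anyDuplicated(toupper(nms)))
    return("editor names must be unique (case-insensitive)")
  TRUE
})

#' ScreeningOutcome: editability verdict for one target site
#'
#' Result of running the five sequential screening checks on one site with
#' one editor. Editable sites carry all surviving candidate guides (one row
#' per protospacer placement); failed sites carry the label of the first
#' check that eliminated every placement.
#'
#' @slot siteId site identifier.
#' @slot status `"editable"` or `"failed"`.
#' @slot failReason one of `base_match_error`, `no_PAM`,
#'   `activity_window_error`, `continuous_identical_base_error`,
#'   `GC_ratio_error`, or `""` when editable.
#' @slot candidates data.frame of candidate guides (columns `site_id`,
#'   `strand`, `protospacer`, `pam`, `protospacer_start`, `protospacer_end`,
#'   `target_window_pos`); zero rows iff `status == "failed"`.
#' @export
setClass("ScreeningOutcome",
  representation(
    siteId = "character",
    status = "character",
    failReason = "character",
    candidates = "data.frame"
  )
)

setValidity("ScreeningOutcome", function(object) {
  msgs <- character(0)
  if (!object@status %in% c("editable", "failed"))
    msgs <- c(msgs, "'status' must be \"editable\" or \"failed\"")
  if (object@status == "editable" &&
      (nzchar(object@failReason) || nrow(object@candidates) == 0L))
    msgs <- c(msgs, "editable outcomes must have candidates and no failReason")
  if (object@status == "failed" &&
      (!object@failReason %in% .FAIL_LABELS || nrow(object@candidates) != 0L))
    msgs <- c(msgs,
      "failed outcomes must carry one of the five failure labels and no candidates")
  if (length(msgs)) msgs else TRUE
})

#' CfdTable: multiplicative penalty table for CFD off-target scoring
#'
#' The CFD (cutting frequency determination) score of an off-target locus is
#' the product, over mismatched protospacer positions, of a penalty that
#' depends on the position (1--20, counted from the PAM-distal end), the
#' gRNA base and the genomic base, multiplied by a penalty for the observed
#' PAM variant. A perfect match with a canonical PAM scores 1.
#'
#' Mismatch penalties are keyed as `"<pos>:<query>><genomic>"`, e.g.
#' `"12:A>G"`; PAM penalties by the observed PAM sequence, with the special
#' key `"default"` as fallback. A PAM matching the editor's canonical IUPAC
#' pattern scores 1 unless the table overrides it.
#'
#' @slot mismatchPenalties named numeric vector of multipliers in \[0,1\].
#' @slot pamPenalties named numeric vector of multipliers in \[0,1\].
#' @seealso [uniformCfdTable()], [defaultCfdTable()], [readCfdTable()],
#'   [cfdScore()].
#' @export
setClass("CfdTable",
  representation(
    mismatchPenalties = "numeric",
    pamPenalties = "numeric"
  )
)

setValidity("CfdTable", function(object) {
  msgs <- character(0)
  if (is.null(names(object@mismatchPenalties)) ||
      is.null(names(object@pamPenalties)))
    msgs <- c(msgs, "penalty vectors must be named")
  if (any(object@mismatchPenalties < 0 | object@mismatchPenalties > 1) ||
      any(object@pamPenalties < 0 | object@pamPenalties > 1))
    msgs <- c(msgs, "all multipliers must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
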