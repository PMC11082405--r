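#' Determine the design strand for a target site
#'
#' A base editor can only act on its target base. For a CBE the reference
#' base must be C (design on the plus strand) or G (the edited C lies on the
#' minus strand); for an ABE, A or T respectively. Any other reference base
#' makes the site uneditable with that editor.
#'
#' @param site one-row data.frame or list with at least `ref`.
#' @param editor a [BaseEditor-class].
#' @return `"+"` or `"-"`, or the string `"base_match_error"` when the
#'   reference base matches neither strand.
#' @export
matchTargetBase <- function(site, editor) {
  ref <- toupper(site$ref)
  if (identical(ref, targetBase(editor))) return("+")
  if (identical(ref, .complementBase(targetBase(editor)))) return("-")
  "base_match_error"
}

# All protospacer placements that put the target base at protospacer
# position p (1..spacer, counted from the PAM-distal 5' end) on the design
# strand, with the PAM immediately 3' of the protospacer. Plus strand:
# protospacer spans [t-p+1, t-p+L] with PAM just right of it. Minus strand:
# the protospacer reads off the reverse complement; its plus-strand span is
# [t+p-L, t+p-1] with the PAM just left of it, and both sequences are
# reported 5'->3' on the minus strand.
#' Enumerate candidate protospacer placements for a site
#'
#' Considers every placement of the protospacer that covers the target base,
#' on the design strand returned by [matchTargetBase()]. Placements whose
#' PAM matches the editor's IUPAC pattern form the searchable set; of those,
#' only placements with the target inside the activity window become
#' candidates. Placements running past the chromosome boundary, or touching
#' an N in the protospacer or PAM, are skipped.
#'
#' @param site one-row data.frame with `site_id`, `chrom`, `pos`.
#' @param editor a [BaseEditor-class].
#' @param genome a `DNAStringSet`.
#' @param strand `"+"` or `"-"` from [matchTargetBase()].
#' @return list with `status` (`"ok"`, `"no_PAM"` when no placement in range
#'   has a matching PAM, or `"activity_window_error"` when PAMs exist only at
#'   non-window placements) and `candidates` (data.frame, possibly empty).
#' @export
enumeratePlacements <- function(site, editor, genome, strand) {
  stopifnot(strand %in% c("+", "-"))
  chromSeq <- .chromSeq(genome, site$chrom)
  clen <- length(chromSeq)
  L <- spacerLength(editor)
  P <- nchar(pamPattern(editor))
  win <- activityWindow(editor)
  t <- site$pos
  anyPam <- FALSE
  rows <- vector("list", L)
  for (p in seq_len(L)) {
    if (strand == "+") {
      s <- t - p + 1L
      e <- s + L - 1L
      pamS <- e + 1L
      pamE <- e + P
      if (s < 1L || pamE > clen) next
      proto <- as.character(Biostrings::subseq(chromSeq, s, e))
      pam <- as.character(Biostrings::subseq(chromSeq, pamS, pamE))
    } else {
      e <- t + p - 1L
      s <- e - L + 1L
      pamS <- s - P
      pamE <- s - 1L
      if (pamS < 1L || e > clen) next
      proto <- .revcomp(as.character(Biostrings::subseq(chromSeq, s, e)))
      pam <- .revcomp(as.character(Biostrings::subseq(chromSeq, pamS, pamE)))
    }
    if (grepl("[^ACGT]", proto) || grepl("[^ACGT]", pam)) next
    if (!.iupacMatches(pam, pamPattern(editor))) next
    anyPam <- TRUE
    if (p >= win[1] && p <= win[2]) {
      rows[[p]] <- data.frame(
        site_id = site$site_id, strand = strand, protospacer = proto,
        pam = pam, protospacer_start = s, protospacer_end = e,
        target_window_pos = p, stringsAsFactors = FALSE
      )
    }
  }
  cand <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cand)) cand <- .emptyCandidates()
  status <- if (nrow(cand) > 0L) "ok"
            else if (anyPam) "activity_window_error" else "no_PAM"
  list(status = status, candidates = cand)
}

#' Homopolymer and GC-content filters on candidate guides
#'
#' Stage 1 keeps candidates whose longest run of identical bases in the
#' protospacer is at most 6 (a run of 7 or more impairs gRNA binding); if
#' none survive the site fails with `continuous_identical_base_error`.
#' Stage 2 keeps candidates with GC content between 30% and 75% inclusive,
#' computed over the protospacer only (the spacer is what hybridizes; the
#' PAM is excluded); if none survive the site fails with `GC_ratio_error`.
#' Bounds are compared in integer arithmetic, so a 20-nt spacer with exactly
#' 6 or 15 G/C bases sits exactly on a bound and passes.
#'
#' @param candidates non-empty candidate data.frame from
#'   [enumeratePlacements()].
#' @return list with `kept` (data.frame) and `failReason` (`NA` or one of
#'   the two labels above).
#' @export
applySequenceFilters <- function(candidates) {
  stopifnot(nrow(candidates) > 0L)
  runs <- vapply(candidates$protospacer, .longestRun, numeric(1),
                 USE.NAMES = FALSE)
  stage1 <- candidates[runs <= 6, , drop = FALSE]
  if (nrow(stage1) == 0L)
    return(list(kept = .emptyCandidates(),
                failReason = "continuous_identical_base_error"))
  gc <- vapply(stage1$protospacer, .gcCount, numeric(1), USE.NAMES = FALSE)
  len <- nchar(stage1$protospacer)
  # 0.30 <= gc/len <= 0.75, exactly, without floating-point division
  keep <- (10 * gc >= 3 * len) & (4 * gc <= 3 * len)
  stage2 <- stage1[keep, , drop = FALSE]
  if (nrow(stage2) == 0L)
    return(list(kept = .emptyCandidates(), failReason = "GC_ratio_error"))
  rownames(stage2) <- NULL
  list(kept = stage2, failReason = NA_character_)
}

#' Screen one target site through the five sequential checks
#'
#' Chains [matchTargetBase()], [enumeratePlacements()] and
#' [applySequenceFilters()] in the fixed order target-base match, PAM
#' search, activity window, homopolymer, GC content. The first check at
#' which every placement dies determines the failure label; sites surviving
#' all five are editable and carry all surviving candidates.
#'
#' @param site one-row data.frame with `site_id`, `chrom`, `pos`, `ref`.
#' @param editor a [BaseEditor-class].
#' @param genome a `DNAStringSet`.
#' @return a [ScreeningOutcome-class].
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
#'   strrep("T", 10), "ATACTGACTGAATGTCCAAT", "TGG", strrep("T", 10))))
#' site <- data.frame(site_id = "s1", chrom = "chr1", pos = 14, ref = "C")
#' screenSite(site, getEditor(loadEditors(), "BE3"), genome)
#' @export
screenSite <- function(site, editor, genome) {
  fail <- function(reason) new("ScreeningOutcome",
    siteId = site$site_id, status = "failed", failReason = reason,
    candidates = .emptyCandidates())
  strand <- matchTargetBase(site, editor)
  if (identical(strand, "base_match_error")) return(fail(strand))
  placed <- enumeratePlacements(site, editor, genome, strand)
  if (placed$status != "ok") return(fail(placed$status))
  filtered <- applySequenceFilters(placed$candidates)
  if (!is.na(filtered$failReason)) return(fail(filtered$failReason))
  new("ScreeningOutcome", siteId = site$site_id, status = "editable",
      failReason = "", candidates = filtered$kept)
}

#' Screen a table of target sites
#'
#' @param sites data.frame from [readSites()]; rows with a `load_error` are
#'   skipped (they are reported separately by the pipeline).
#' @param editor a [BaseEditor-class].
#' @param genome a `DNAStringSet`.
#' @return named list of [ScreeningOutcome-class], one per valid site.
#' @export
screenSites <- function(sites, editor, genome) {
  if (!"load_error" %in% names(sites)) sites$load_error <- NA_character_
  valid <- sites[is.na(sites$load_error), , drop = FALSE]
  out <- lapply(seq_len(nrow(valid)), function(i)
    screenSite(valid[i, , drop = FALSE], editor, genome))
  names(out) <- valid$site_id
  out
}

#' @rdname ScreeningOutcome-class
#' @export
setMethod("candidates", "ScreeningOutcome", function(x) x@candidates)
#' @rdname ScreeningOutcome-class
#' @export
setMethod("siteStatus", "ScreeningOutcome", function(x) x@status)
#' @rdname ScreeningOutcome-class
#' @export
setMethod("failReason", "ScreeningOutcome", function(x) x@failReason)

setMethod("show", "ScreeningOutcome", function(object) {
  if (object@status == "editable") {
    cat(sprintf("Site %s: editable, %d candidate gRNA(s)\n",
                object@siteId, nrow(object@candidates)))
  } else {
    cat(sprintf("Site %s: failed (%s)\n", object@siteId, object@failReason))
  }
  invisible(object)
})
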