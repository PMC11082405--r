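# Summary arithmetic over pipeline outputs: how many editable sites have
# k feasible gRNAs, and why non-editable sites failed.

#' Tabulate editable sites by number of feasible gRNAs
#'
#' @param x one of: a list of [ScreeningOutcome-class] objects, an integer
#'   vector of per-site feasible-guide counts, or a named numeric map from
#'   feasible-guide count k to number of sites (names are k).
#' @return data.frame with columns `n_guides`, `n_sites`, `percent`
#'   (half-up, 2 decimals), plus attributes `total_sites` and
#'   `total_guides`.
#' @examples
#' summarizeFeasibleCounts(c(`1` = 378, `2` = 109, `3` = 34, `4` = 3))
#' @export
summarizeFeasibleCounts <- function(x) {
  if (is.list(x) && all(vapply(x, is, logical(1), "ScreeningOutcome"))) {
    perSite <- vapply(x, function(o) nrow(candidates(o)), integer(1))
    perSite <- perSite[perSite > 0L]
    tab <- table(perSite)
    counts <- setNames(as.numeric(tab), names(tab))
  } else if (!is.null(names(x))) {
    counts <- x[x > 0]
  } else {
    x <- x[x > 0]
    tab <- table(x)
    counts <- setNames(as.numeric(tab), names(tab))
  }
  if (length(counts) == 0L || sum(counts) == 0)
    stop("empty table: no editable sites to summarize", call. = FALSE)
  k <- as.integer(names(counts))
  if (anyNA(k) || any(k < 1L))
    stop("feasible-guide counts must be positive integers", call. = FALSE)
  ord <- order(k)
  k <- k[ord]; counts <- as.numeric(counts[ord])
  totalSites <- sum(counts)
  out <- data.frame(
    n_guides = k,
    n_sites = counts,
    percent = .roundHalfUp(100 * counts / totalSites, 2L)
  )
  attr(out, "total_sites") <- totalSites
  attr(out, "total_guides") <- sum(k * counts)
  out
}

#' Tabulate screening failures by cause
#'
#' Counts each of the five failure labels and additionally reports the
#' combined share of the two geometric causes (`no_PAM` plus
#' `activity_window_error`), the dominant reason sites are uneditable.
#'
#' @param failReasons character vector (or named count map) of failure
#'   labels drawn from the five-label vocabulary.
#' @return data.frame with `fail_reason`, `count`, `percent` (half-up,
#'   1 decimal); attributes `total` and `pam_window_percent`.
#' @export
summarizeFailures <- function(failReasons) {
  if (!is.null(names(failReasons)) && is.numeric(failReasons)) {
    counts <- failReasons
  } else {
    tab <- table(failReasons)
    counts <- setNames(as.numeric(tab), names(tab))
  }
  unknown <- setdiff(names(counts), .FAIL_LABELS)
  if (length(unknown))
    stop("unknown failure label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(counts) == 0L || sum(counts) == 0)
    stop("empty table: no failures to summarize", call. = FALSE)
  full <- setNames(numeric(length(.FAIL_LABELS)), .FAIL_LABELS)
  full[names(counts)] <- counts
  full <- full[full > 0]
  total <- sum(full)
  out <- data.frame(
    fail_reason = names(full),
    count = unname(full),
    percent = .roundHalfUp(100 * unname(full) / total, 1L),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  pw <- sum(full[names(full) %in% c("no_PAM", "activity_window_error")])
  attr(out, "pam_window_percent") <- .roundHalfUp(100 * pw / total, 1L)
  out
}
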