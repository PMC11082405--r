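# Five-feature evaluation of screened candidate guides and robust rank
# aggregation (RRA) to pick the best guide per site. Smaller is better for
# every feature: fewer editable bystander bases in the window, lower GC,
# fewer exact genomic repeats, fewer overlapping SNPs, lower mean CFD.

#' Compute the five evaluation features for screened candidates
#'
#' For each candidate: `same_base_in_window` counts bases equal to the
#' editor's target base within the activity window of the protospacer
#' (bystanders plus the target itself, so always >= 1); `gc_fraction` is the
#' GC proportion of the protospacer; `repeat_count` is the number of exact
#' occurrences of the protospacer in the genome on either strand (>= 1,
#' including the on-target copy); `snp_count` is the number of background
#' SNPs overlapping the protospacer's genomic span; `offtarget_score` is the
#' mean CFD over all mismatch hits (see [offtargetFeature()]).
#'
#' @param cands candidate data.frame from [screenSite()] /
#'   [enumeratePlacements()].
#' @param site the screened site (one-row data.frame with `chrom`).
#' @param editor a [BaseEditor-class].
#' @param genome a `DNAStringSet`.
#' @param snpTrack a `GRanges` of SNP positions, or `NULL` (then
#'   `snp_count` is 0 with a warning).
#' @param maxMismatch,cfdTable,pamPolicy off-target scan settings.
#' @return the candidate data.frame with the five feature columns appended.
#' @export
computeFeatures <- function(cands, site, editor, genome, snpTrack = NULL,
                            maxMismatch = 4L, cfdTable = defaultCfdTable(),
                            pamPolicy = "strict") {
  stopifnot(nrow(cands) > 0L)
  win <- activityWindow(editor)
  cands$chrom <- site$chrom
  cands$same_base_in_window <- vapply(cands$protospacer, function(p) {
    sum(strsplit(substr(p, win[1], win[2]), "", fixed = TRUE)[[1]] ==
          targetBase(editor))
  }, integer(1), USE.NAMES = FALSE)
  len <- nchar(cands$protospacer)
  cands$gc_fraction <- vapply(cands$protospacer, .gcCount, numeric(1),
                              USE.NAMES = FALSE) / len
  cands$repeat_count <- vapply(seq_len(nrow(cands)), function(i) {
    g <- cands[i, , drop = FALSE]
    nrow(findOfftargets(g$protospacer, genome, maxMismatch = 0L,
                        pamPattern = pamPattern(editor), pamPolicy = "any",
                        onTarget = g)) + 1L
  }, integer(1))
  if (is.null(snpTrack)) {
    warning("no SNP track supplied; snp_count set to 0 for all candidates",
            call. = FALSE)
    cands$snp_count <- 0L
  } else {
    spans <- GenomicRanges::GRanges(
      seqnames = cands$chrom,
      ranges = IRanges::IRanges(start = cands$protospacer_start,
                                end = cands$protospacer_end))
    cands$snp_count <- GenomicRanges::countOverlaps(spans, snpTrack)
  }
  cands$offtarget_score <- vapply(seq_len(nrow(cands)), function(i) {
    offtargetFeature(cands[i, , drop = FALSE], genome,
                     maxMismatch = maxMismatch, table = cfdTable,
                     pamPattern = pamPattern(editor), pamPolicy = pamPolicy)
  }, numeric(1))
  cands
}

#' Robust rank aggregation score
#'
#' For one candidate with normalized ranks `r` across the feature lists,
#' sort them ascending and take the minimum over k of the Beta(k, n-k+1)
#' CDF evaluated at the k-th smallest rank -- the probability that the k-th
#' order statistic of n independent uniforms would fall at or below the
#' observed value. Smaller scores indicate rank vectors too consistently
#' good to arise by chance; scores are used ordinally (no multiple-testing
#' correction on the minimum), so the candidate ordering is what matters.
#'
#' @param normalizedRanks numeric matrix, one row per candidate, one column
#'   per feature list; entries in (0, 1\].
#' @return numeric vector of RRA scores, one per row.
#' @examples
#' rraAggregate(matrix(c(0.25, 0.25, 0.25, 0.25, 0.25), nrow = 1))
#' @export
rraAggregate <- function(normalizedRanks) {
  if (is.null(dim(normalizedRanks)))
    normalizedRanks <- matrix(normalizedRanks, nrow = 1)
  if (any(!is.finite(normalizedRanks)) || any(normalizedRanks <= 0) ||
      any(normalizedRanks > 1))
    stop("normalized ranks must lie in (0, 1]", call. = FALSE)
  n <- ncol(normalizedRanks)
  apply(normalizedRanks, 1, function(x) {
    r <- sort(x)
    min(pbeta(r, seq_len(n), n - seq_len(n) + 1))
  })
}

#' Rank candidates at one site and flag the best guide
#'
#' Ranks the candidates within the site on each of the five features
#' (ascending, ties averaged), normalizes each rank by the number of
#' candidates at the site, aggregates with [rraAggregate()] and flags the
#' candidate with the smallest RRA score as best. Exact ties are broken
#' deterministically by lower `offtarget_score`, then smaller genomic start,
#' then plus strand.
#'
#' @param features data.frame from [computeFeatures()].
#' @return the data.frame with columns `rank_same_base`, `rank_gc`,
#'   `rank_repeat`, `rank_snp`, `rank_offtarget`, `rra_score`, `is_best`
#'   appended.
#' @export
rankGuides <- function(features) {
  stopifnot(nrow(features) > 0L)
  m <- nrow(features)
  featCols <- c(same_base_in_window = "rank_same_base",
                gc_fraction = "rank_gc",
                repeat_count = "rank_repeat",
                snp_count = "rank_snp",
                offtarget_score = "rank_offtarget")
  for (fc in names(featCols))
    features[[featCols[[fc]]]] <- rank(features[[fc]],
                                       ties.method = "average")
  normalized <- as.matrix(features[, featCols]) / m
  features$rra_score <- rraAggregate(normalized)
  ord <- order(features$rra_score, features$offtarget_score,
               features$protospacer_start,
               match(features$strand, c("+", "-")))
  features$is_best <- FALSE
  features$is_best[ord[1]] <- TRUE
  features
}

#' Best guide at a site
#'
#' @param ranked data.frame from [rankGuides()].
#' @return the single best candidate row.
#' @export
selectBest <- function(ranked) {
  ranked[which(ranked$is_best), , drop = FALSE]
}

#' Screen, evaluate and rank every site: the full design report
#'
#' Runs the screening model on each site, computes the five evaluation
#' features for candidates at editable sites, ranks them with RRA and
#' assembles the per-(site, candidate) report. Failed sites contribute one
#' row with empty candidate fields and their failure label.
#'
#' @param sites data.frame from [readSites()] (rows with `load_error` are
#'   excluded; handle them upstream).
#' @param editor a [BaseEditor-class].
#' @param genome a `DNAStringSet`.
#' @param snpTrack `GRanges` of SNPs or `NULL`.
#' @param maxMismatch,cfdTable,pamPolicy off-target scan settings.
#' @return report data.frame (see [writeReport()] for the column contract).
#' @export
designGuides <- function(sites, editor, genome, snpTrack = NULL,
                         maxMismatch = 4L, cfdTable = defaultCfdTable(),
                         pamPolicy = "strict") {
  if (!"load_error" %in% names(sites)) sites$load_error <- NA_character_
  sites <- sites[is.na(sites$load_error), , drop = FALSE]
  if (is.null(snpTrack)) {
    warning("no SNP track supplied; snp_count set to 0 for all candidates",
            call. = FALSE)
    snpTrack <- GenomicRanges::GRanges()
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    site <- sites[i, , drop = FALSE]
    outcome <- screenSite(site, editor, genome)
    if (siteStatus(outcome) == "failed") {
      return(data.frame(
        site_id = site$site_id, status = "failed",
        fail_reason = failReason(outcome), strand = NA_character_,
        protospacer = NA_character_, pam = NA_character_,
        protospacer_start = NA_integer_, protospacer_end = NA_integer_,
        same_base_in_window = NA_integer_, gc_fraction = NA_real_,
        repeat_count = NA_integer_, snp_count = NA_integer_,
        offtarget_score = NA_real_, rank_same_base = NA_real_,
        rank_gc = NA_real_, rank_repeat = NA_real_, rank_snp = NA_real_,
        rank_offtarget = NA_real_, rra_score = NA_real_, is_best = NA,
        stringsAsFactors = FALSE))
    }
    feats <- computeFeatures(candidates(outcome), site, editor, genome,
                             snpTrack = snpTrack, maxMismatch = maxMismatch,
                             cfdTable = cfdTable, pamPolicy = pamPolicy)
    ranked <- rankGuides(feats)
    ranked$status <- "editable"
    ranked$fail_reason <- ""
    ranked[, .REPORT_COLUMNS, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
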