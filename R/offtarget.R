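# Genome-wide mismatch search for protospacers and CFD-style multiplicative
# off-target scoring. The scan is an internal Biostrings-based equivalent of
# the usual external PAM-constrained mismatch searchers.

#' Uniform CFD test table
#'
#' Every mismatch penalty is `penalty` at every position and for every base
#' pair, and every non-canonical PAM variant scores `pamPenalty`; canonical
#' PAMs score 1. Used to test scoring arithmetic independently of any
#' particular coefficient set.
#'
#' @param penalty mismatch multiplier (default 0.5).
#' @param pamPenalty multiplier for PAMs not matching `pamPattern`.
#' @param pamPattern canonical IUPAC PAM.
#' @param positions protospacer positions covered (default 1:20).
#' @return a [CfdTable-class].
#' @export
uniformCfdTable <- function(penalty = 0.5, pamPenalty = 0.5,
                            pamPattern = "NGG", positions = 1:20) {
  pairs <- expand.grid(q = .BASES, g = .BASES, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$q != pairs$g, ]
  keys <- as.vector(outer(positions, paste0(pairs$q, ">", pairs$g),
                          function(p, s) paste0(p, ":", s)))
  mm <- setNames(rep(penalty, length(keys)), keys)
  pamLen <- nchar(pamPattern)
  variants <- apply(
    do.call(expand.grid, rep(list(.BASES), pamLen)), 1, paste, collapse = "")
  pam <- setNames(
    ifelse(vapply(variants, .iupacMatches, logical(1), pattern = pamPattern),
           1, pamPenalty),
    variants)
  new("CfdTable", mismatchPenalties = mm, pamPenalties = pam)
}

#' Heuristic default CFD table
#'
#' A synthetic, code-generated penalty table standing in for an empirically
#' fitted coefficient set: mismatch tolerance decays linearly towards the
#' PAM-proximal end (`1 - pos/21`, so a seed-region mismatch at position 20
#' is ~20x more penalized than one at position 1), single-offset PAM
#' variants (Hamming distance 1 from the canonical pattern) retain 25%
#' activity and all other PAMs 2%. Use [readCfdTable()] to supply published
#' coefficients instead; ranking arithmetic is identical either way.
#'
#' @param pamPattern canonical IUPAC PAM (default `"NGG"`).
#' @return a [CfdTable-class].
#' @export
defaultCfdTable <- function(pamPattern = "NGG") {
  pairs <- expand.grid(q = .BASES, g = .BASES, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$q != pairs$g, ]
  keys <- character(0); vals <- numeric(0)
  for (p in 1:20) {
    keys <- c(keys, paste0(p, ":", pairs$q, ">", pairs$g))
    vals <- c(vals, rep(1 - p / 21, nrow(pairs)))
  }
  pamLen <- nchar(pamPattern)
  variants <- apply(
    do.call(expand.grid, rep(list(.BASES), pamLen)), 1, paste, collapse = "")
  canonical <- vapply(variants, .iupacMatches, logical(1),
                      pattern = pamPattern)
  near <- vapply(variants, function(v) {
    any(vapply(variants[canonical], .hammingDistance, numeric(1), a = v) == 1)
  }, logical(1))
  pam <- setNames(ifelse(canonical, 1, ifelse(near, 0.25, 0.02)), variants)
  new("CfdTable", mismatchPenalties = setNames(vals, keys),
      pamPenalties = pam)
}

#' Read a CFD penalty table from TSV
#'
#' Expected columns: `position`, `query_base`, `genomic_base`, `multiplier`.
#' Mismatch rows carry a protospacer position (1--20); rows with
#' `position == "PAM"` define PAM-variant penalties, with the variant in
#' `query_base` (the special variant `default` sets the fallback for
#' unlisted PAMs).
#'
#' @param path TSV file.
#' @return a [CfdTable-class].
#' @export
readCfdTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "numeric"))
  need <- c("position", "query_base", "genomic_base", "multiplier")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("format error: CFD table missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  isPam <- toupper(tab$position) == "PAM"
  mm <- setNames(tab$multiplier[!isPam],
                 paste0(tab$position[!isPam], ":",
                        toupper(tab$query_base[!isPam]), ">",
                        toupper(tab$genomic_base[!isPam])))
  pam <- setNames(tab$multiplier[isPam],
                  ifelse(tab$query_base[isPam] == "default", "default",
                         toupper(tab$query_base[isPam])))
  new("CfdTable", mismatchPenalties = mm, pamPenalties = pam)
}

.pamMultiplier <- function(pamSeq, table, pamPattern) {
  pens <- table@pamPenalties
  if (pamSeq %in% names(pens)) return(unname(pens[[pamSeq]]))
  if (.iupacMatches(pamSeq, pamPattern)) return(1)
  if ("default" %in% names(pens)) return(unname(pens[["default"]]))
  stop("configuration error: no CFD penalty for PAM variant ",
       sQuote(pamSeq), call. = FALSE)
}

#' CFD score of one off-target locus
#'
#' Product over mismatched positions of the position- and base-pair-specific
#' penalty, times the PAM-variant penalty. Positions are numbered 1--20 from
#' the PAM-distal end. A perfect match with a canonical PAM scores exactly
#' 1. Protospacers longer than 20 nt are scored over their PAM-proximal
#' 20 nt; shorter protospacers fall back to `0.5^mismatches` with a warning
#' (the table is defined for the standard 20-nt geometry).
#'
#' @param query the on-target protospacer (gRNA spacer sequence).
#' @param siteSequence the genomic protospacer at the off-target locus
#'   (design strand, 5'->3').
#' @param pamSequence the PAM observed at the locus.
#' @param table a [CfdTable-class].
#' @param pamPattern canonical IUPAC PAM of the editor.
#' @return score in \[0, 1\].
#' @export
cfdScore <- function(query, siteSequence, pamSequence,
                     table = defaultCfdTable(), pamPattern = "NGG") {
  query <- toupper(query); siteSequence <- toupper(siteSequence)
  if (nchar(query) != nchar(siteSequence))
    stop("query and site sequence lengths differ", call. = FALSE)
  n <- nchar(query)
  if (n < 20L) {
    nmm <- .hammingDistance(query, siteSequence)
    warning("protospacer shorter than 20 nt; scoring as 0.5^mismatches",
            call. = FALSE)
    return(0.5^nmm * .pamMultiplier(toupper(pamSequence), table, pamPattern))
  }
  if (n > 20L) {
    query <- substr(query, n - 19L, n)
    siteSequence <- substr(siteSequence, n - 19L, n)
  }
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  g <- strsplit(siteSequence, "", fixed = TRUE)[[1]]
  score <- 1
  for (i in which(q != g)) {
    key <- paste0(i, ":", q[i], ">", g[i])
    if (!key %in% names(table@mismatchPenalties))
      stop("configuration error: CFD table has no entry for ", sQuote(key),
           call. = FALSE)
    score <- score * table@mismatchPenalties[[key]]
  }
  score * .pamMultiplier(toupper(pamSequence), table, pamPattern)
}

.pamAccepted <- function(pamSeq, pamPattern, pamPolicy) {
  switch(pamPolicy,
    any = TRUE,
    strict = .iupacMatches(pamSeq, pamPattern),
    relaxed = .iupacMatches(pamSeq, pamPattern) ||
      (identical(pamPattern, "NGG") && .iupacMatches(pamSeq, "NAG")),
    stop("unknown pam policy: ", pamPolicy, call. = FALSE))
}

#' Genome-wide mismatch search for a protospacer
#'
#' Finds every locus, on either strand, whose protospacer-length sequence
#' has at most `maxMismatch` substitutions relative to the query and whose
#' adjacent PAM satisfies the policy; the on-target locus itself is
#' excluded when given. Loci containing N, or whose PAM span would run past
#' the chromosome boundary, are skipped. With `maxMismatch = 0` and
#' `pamPolicy = "any"` this doubles as the exact-repeat counter used by the
#' ranking features.
#'
#' @param protospacer query sequence (design strand, 5'->3').
#' @param genome a `DNAStringSet`.
#' @param maxMismatch mismatch budget (default 4, the usual search depth for
#'   Cas-OFFinder-style scans).
#' @param pamPattern canonical IUPAC PAM of the editor.
#' @param pamPolicy `"strict"` (canonical pattern only), `"relaxed"` (adds
#'   NAG for NGG editors) or `"any"`.
#' @param onTarget optional list/one-row data.frame with `chrom`,
#'   `protospacer_start`, `protospacer_end`, `strand` identifying the
#'   on-target locus to exclude.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `site_sequence`, `pam_sequence`, `n_mismatches` (1-based inclusive
#'   protospacer span on the plus strand; sequences on the hit strand).
#' @export
findOfftargets <- function(protospacer, genome, maxMismatch = 4L,
                           pamPattern = "NGG",
                           pamPolicy = c("strict", "relaxed", "any"),
                           onTarget = NULL) {
  pamPolicy <- match.arg(pamPolicy)
  stopifnot(maxMismatch >= 0L)
  query <- Biostrings::DNAString(toupper(protospacer))
  L <- length(query)
  P <- nchar(pamPattern)
  qChars <- strsplit(as.character(query), "", fixed = TRUE)[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    pattern <- if (strand == "+") query else
      Biostrings::reverseComplement(query)
    m <- Biostrings::vmatchPattern(pattern, genome,
                                   max.mismatch = maxMismatch, fixed = TRUE)
    for (ci in seq_along(genome)) {
      r <- m[[ci]]
      if (length(r) == 0L) next
      chrom <- names(genome)[ci]
      chromSeq <- genome[[ci]]
      clen <- length(chromSeq)
      for (k in seq_along(r)) {
        s <- IRanges::start(r)[k]
        e <- IRanges::end(r)[k]
        if (s < 1L || e > clen) next
        if (strand == "+") {
          pamS <- e + 1L; pamE <- e + P
          if (pamE > clen) next
          siteSeq <- as.character(Biostrings::subseq(chromSeq, s, e))
          pamSeq <- as.character(Biostrings::subseq(chromSeq, pamS, pamE))
        } else {
          pamS <- s - P; pamE <- s - 1L
          if (pamS < 1L) next
          siteSeq <- .revcomp(as.character(Biostrings::subseq(chromSeq, s, e)))
          pamSeq <- .revcomp(as.character(Biostrings::subseq(chromSeq, pamS,
                                                             pamE)))
        }
        if (grepl("[^ACGT]", siteSeq) || grepl("[^ACGT]", pamSeq)) next
        if (!.pamAccepted(pamSeq, pamPattern, pamPolicy)) next
        nmm <- sum(strsplit(siteSeq, "", fixed = TRUE)[[1]] != qChars)
        if (nmm > maxMismatch) next
        if (!is.null(onTarget) &&
            identical(chrom, onTarget$chrom) &&
            s == onTarget$protospacer_start &&
            e == onTarget$protospacer_end &&
            identical(strand, onTarget$strand)) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = s, end = e, strand = strand,
          site_sequence = siteSeq, pam_sequence = pamSeq,
          n_mismatches = nmm, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      site_sequence = character(0),
                      pam_sequence = character(0),
                      n_mismatches = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

#' Mean CFD off-target score of one candidate guide
#'
#' Runs [findOfftargets()] for the candidate and averages the CFD scores of
#' all hits. No hits at all is the best possible outcome and scores 0.
#' The on-target locus is excluded from the average; exact duplicates of the
#' protospacer elsewhere in the genome are included (they are genuine
#' off-targets).
#'
#' @param guide one-row data.frame with `protospacer`, `chrom`,
#'   `protospacer_start`, `protospacer_end`, `strand` (a candidate row plus
#'   its chromosome).
#' @param genome a `DNAStringSet`.
#' @param maxMismatch mismatch budget.
#' @param table a [CfdTable-class].
#' @param pamPattern canonical IUPAC PAM.
#' @param pamPolicy PAM policy for the scan (see [findOfftargets()]).
#' @return mean CFD score (>= 0).
#' @export
offtargetFeature <- function(guide, genome, maxMismatch = 4L,
                             table = defaultCfdTable(), pamPattern = "NGG",
                             pamPolicy = "strict") {
  hits <- findOfftargets(guide$protospacer, genome, maxMismatch = maxMismatch,
                         pamPattern = pamPattern, pamPolicy = pamPolicy,
                         onTarget = guide)
  if (nrow(hits) == 0L) return(0)
  scores <- vapply(seq_len(nrow(hits)), function(i) {
    cfdScore(guide$protospacer, hits$site_sequence[i], hits$pam_sequence[i],
             table = table, pamPattern = pamPattern)
  }, numeric(1))
  mean(scores)
}
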