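# Small sequence and numeric helpers shared across modules.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.complementBase <- function(b) unname(.COMPLEMENT[b])

# Does a concrete nucleotide string match an IUPAC pattern of equal length?
# Ambiguity codes are expanded from Biostrings::IUPAC_CODE_MAP; the observed
# sequence must be concrete (A/C/G/T), so an N in the genome never matches.
.iupacMatches <- function(observed, pattern) {
  if (nchar(observed) != nchar(pattern)) return(FALSE)
  obs <- strsplit(observed, "", fixed = TRUE)[[1]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  for (i in seq_along(obs)) {
    allowed <- map[[pat[i]]]
    if (is.null(allowed) || !grepl(obs[i], allowed, fixed = TRUE)) return(FALSE)
  }
  TRUE
}

# One concrete instance of an IUPAC PAM pattern (used when planting decoys).
.concretePam <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    substr(Biostrings::IUPAC_CODE_MAP[[ch]], 1L, 1L)
  }, character(1)), collapse = "")
}

.longestRun <- function(seq) {
  max(rle(strsplit(seq, "", fixed = TRUE)[[1]])$lengths)
}

.gcCount <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(chars %in% c("G", "C"))
}

.hammingDistance <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Round half away from zero (the printed-table convention), not to even.
.roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

# Shortest decimal representation that parses back to the identical double,
# so written reports round-trip bit-exactly without 17-digit noise.
.formatNumber <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (is.finite(v) && v == trunc(v) && abs(v) < 1e15) {
      return(sprintf("%.0f", v))
    }
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

.emptyCandidates <- function() {
  data.frame(
    site_id = character(0), strand = character(0), protospacer = character(0),
    pam = character(0), protospacer_start = integer(0),
    protospacer_end = integer(0), target_window_pos = integer(0),
    stringsAsFactors = FALSE
  )
}

.chromSeq <- function(genome, chrom) {
  i <- match(chrom, names(genome))
  if (is.na(i)) stop("unknown chromosome: ", chrom, call. = FALSE)
  genome[[i]]
}
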