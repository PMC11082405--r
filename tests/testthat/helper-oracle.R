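# Independent brute-force oracles, written from the constraint definitions
# with plain string operations; they share no code with the package's
# implementation paths.

.orc_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

orc_revcomp <- function(x) {
  paste(rev(unname(.orc_comp[strsplit(x, "", fixed = TRUE)[[1]]])),
        collapse = "")
}

.orc_iupac <- list(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                   S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                   D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

orc_iupac_ok <- function(seq, pat) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(pat, "", fixed = TRUE)[[1]]
  if (length(s) != length(p)) return(FALSE)
  for (i in seq_along(s)) {
    set <- .orc_iupac[[p[i]]]
    if (is.null(set) || !grepl(s[i], set, fixed = TRUE)) return(FALSE)
  }
  TRUE
}

orc_longest_run <- function(x) {
  max(nchar(regmatches(x, gregexpr("(.)\\1*", x))[[1]]))
}

orc_gc_count <- function(x) nchar(gsub("[^GC]", "", x))

# Full screening oracle: slides every (spacer+PAM)-length window over both
# strands, keeps windows whose protospacer covers the target base at a
# window-compatible position with a matching PAM, then applies the
# homopolymer and GC filters; reports the first stage at which all
# placements die.
orc_screen <- function(seqs, chrom, pos, ref, target = "C",
                       pam_pat = "NGG", ws = 4, we = 8, L = 20) {
  fail <- function(reason) list(status = "failed", fail = reason,
                                cands = NULL)
  strand <- if (ref == target) "+"
            else if (ref == .orc_comp[[target]]) "-"
            else return(fail("base_match_error"))
  x <- seqs[[chrom]]
  n <- nchar(x)
  P <- nchar(pam_pat)
  inrange <- list()
  for (a in seq_len(max(0, n - L - P + 1))) {
    if (strand == "+") {
      s <- a; e <- a + L - 1
      if (pos < s || pos > e) next
      proto <- substr(x, s, e)
      pam <- substr(x, e + 1, e + P)
      p <- pos - s + 1
    } else {
      s <- a + P; e <- s + L - 1
      if (pos < s || pos > e) next
      proto <- orc_revcomp(substr(x, s, e))
      pam <- orc_revcomp(substr(x, a, a + P - 1))
      p <- e - pos + 1
    }
    if (grepl("[^ACGT]", proto) || grepl("[^ACGT]", pam)) next
    if (!orc_iupac_ok(pam, pam_pat)) next
    inrange[[length(inrange) + 1]] <- data.frame(
      strand = strand, protospacer = proto, pam = pam,
      protospacer_start = as.integer(s), protospacer_end = as.integer(e),
      target_window_pos = as.integer(p), stringsAsFactors = FALSE)
  }
  if (length(inrange) == 0) return(fail("no_PAM"))
  S <- do.call(rbind, inrange)
  W <- S[S$target_window_pos >= ws & S$target_window_pos <= we, ,
         drop = FALSE]
  if (nrow(W) == 0) return(fail("activity_window_error"))
  runs <- vapply(W$protospacer, orc_longest_run, numeric(1))
  W <- W[runs < 7, , drop = FALSE]
  if (nrow(W) == 0) return(fail("continuous_identical_base_error"))
  gc <- vapply(W$protospacer, orc_gc_count, numeric(1))
  frac <- gc / nchar(W$protospacer)
  W <- W[frac >= 0.3 - 1e-12 & frac <= 0.75 + 1e-12, , drop = FALSE]
  if (nrow(W) == 0) return(fail("GC_ratio_error"))
  rownames(W) <- NULL
  list(status = "editable", fail = "", cands = W)
}

# Literal all-positions off-target scan: per strand, a character-matrix
# mismatch count over every window, then PAM and N filters.
orc_offtargets <- function(query, seqs, max_mm, pam_pat = "NGG",
                           policy = "strict", on_target = NULL) {
  L <- nchar(query)
  P <- nchar(pam_pat)
  qc_plus <- strsplit(query, "", fixed = TRUE)[[1]]
  qc_minus <- strsplit(orc_revcomp(query), "", fixed = TRUE)[[1]]
  pam_ok <- function(pam) {
    switch(policy,
      any = TRUE,
      strict = orc_iupac_ok(pam, pam_pat),
      relaxed = orc_iupac_ok(pam, pam_pat) ||
        (pam_pat == "NGG" && orc_iupac_ok(pam, "NAG")))
  }
  rows <- list()
  for (chrom in names(seqs)) {
    chars <- strsplit(seqs[[chrom]], "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n < L) next
    starts <- seq_len(n - L + 1)
    idx <- outer(0:(L - 1), starts, "+")
    M <- matrix(chars[idx], nrow = L)
    for (strand in c("+", "-")) {
      qc <- if (strand == "+") qc_plus else qc_minus
      mm <- colSums(M != qc)
      for (j in which(mm <= max_mm)) {
        s <- starts[j]; e <- s + L - 1
        if (strand == "+") {
          if (e + P > n) next
          site <- substr(seqs[[chrom]], s, e)
          pam <- substr(seqs[[chrom]], e + 1, e + P)
        } else {
          if (s - P < 1) next
          site <- orc_revcomp(substr(seqs[[chrom]], s, e))
          pam <- orc_revcomp(substr(seqs[[chrom]], s - P, s - 1))
        }
        if (grepl("[^ACGT]", site) || grepl("[^ACGT]", pam)) next
        if (!pam_ok(pam)) next
        if (!is.null(on_target) && chrom == on_target$chrom &&
            s == on_target$protospacer_start &&
            e == on_target$protospacer_end &&
            strand == on_target$strand) next
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = s, end = e, strand = strand,
          site_sequence = site, pam_sequence = pam,
          n_mismatches = unname(mm[j]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      site_sequence = character(0),
                      pam_sequence = character(0),
                      n_mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

hit_keys <- function(df) {
  sort(sprintf("%s:%d-%d%s/%d", df$chrom, df$start, df$end, df$strand,
               df$n_mismatches))
}

# Crafted single-placement context: pad with T so the only NGG placement is
# the planted one (the protospacer must be free of "GG"), target base at
# protospacer position p.
plant_context <- function(proto, p, pam = "TGG", pad_len = 30) {
  stopifnot(!grepl("GG", proto, fixed = TRUE))
  chrom <- paste0(strrep("T", pad_len), proto, pam, strrep("T", pad_len))
  list(seq = chrom, pos = pad_len + p,
       proto_start = pad_len + 1, proto_end = pad_len + nchar(proto))
}

be3 <- function() getEditor(loadEditors(), "BE3")
abe710 <- function() getEditor(loadEditors(), "ABE7.10")

as_genome <- function(seqs) Biostrings::DNAStringSet(unlist(seqs))

site_row <- function(chrom, pos, ref, id = "s1") {
  data.frame(site_id = id, chrom = chrom, pos = pos, ref = ref,
             stringsAsFactors = FALSE)
}
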