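# Deterministic synthetic-data generator: genomes with planted
# editable/uneditable sites and mismatch decoys, SNP tracks, and GWAS
# tables with planted promotion/inhibition effects. Every planted construct
# is verified against an independent sliding-window screen before the
# fixture is emitted, so the accompanying truth tables are guaranteed, not
# assumed.

# Independent brute-force screen: slides every (spacer+PAM)-length window
# over both strands of the region around the site and tests the constraints
# directly. Used only to verify planted constructs; the production path is
# screenSite().
.bruteScreen <- function(genome, site, editor) {
  L <- spacerLength(editor)
  P <- nchar(pamPattern(editor))
  win <- activityWindow(editor)
  chromSeq <- .chromSeq(genome, site$chrom)
  lo <- max(1L, site$pos - (L + P))
  hi <- min(length(chromSeq), site$pos + (L + P))
  chars <- strsplit(as.character(Biostrings::subseq(chromSeq, lo, hi)),
                    "", fixed = TRUE)[[1]]
  t <- site$pos - lo + 1L
  n <- length(chars)
  ref <- chars[t]
  fail <- function(reason) list(status = "failed", fail_reason = reason,
                                candidates = .emptyCandidates())
  strand <- if (ref == targetBase(editor)) "+"
    else if (ref == .complementBase(targetBase(editor))) "-"
    else return(fail("base_match_error"))
  hits <- list()
  for (a in seq_len(max(0L, n - L - P + 1L))) {
    if (strand == "+") {
      s <- a; e <- a + L - 1L
      pamChars <- chars[(e + 1L):(e + P)]
      if (t < s || t > e) next
      p <- t - s + 1L
      proto <- paste(chars[s:e], collapse = "")
      pam <- paste(pamChars, collapse = "")
    } else {
      s <- a + P; e <- a + P + L - 1L
      if (t < s || t > e) next
      p <- e - t + 1L
      proto <- .revcomp(paste(chars[s:e], collapse = ""))
      pam <- .revcomp(paste(chars[a:(a + P - 1L)], collapse = ""))
    }
    if (grepl("[^ACGT]", proto) || grepl("[^ACGT]", pam)) next
    if (!.iupacMatches(pam, pamPattern(editor))) next
    hits[[length(hits) + 1L]] <- data.frame(
      site_id = site$site_id, strand = strand, protospacer = proto,
      pam = pam, protospacer_start = s + lo - 1L,
      protospacer_end = e + lo - 1L, target_window_pos = p,
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(fail("no_PAM"))
  S <- do.call(rbind, hits)
  W <- S[S$target_window_pos >= win[1] & S$target_window_pos <= win[2], ,
         drop = FALSE]
  if (nrow(W) == 0L) return(fail("activity_window_error"))
  runs <- vapply(W$protospacer, .longestRun, numeric(1), USE.NAMES = FALSE)
  W <- W[runs < 7, , drop = FALSE]
  if (nrow(W) == 0L) return(fail("continuous_identical_base_error"))
  gc <- vapply(W$protospacer, .gcCount, numeric(1), USE.NAMES = FALSE)
  len <- nchar(W$protospacer)
  W <- W[10 * gc >= 3 * len & 4 * gc <= 3 * len, , drop = FALSE]
  if (nrow(W) == 0L) return(fail("GC_ratio_error"))
  rownames(W) <- NULL
  list(status = "editable", fail_reason = "", candidates = W)
}

#' Specification for a synthetic fixture
#'
#' Collects everything the generator needs: a single integer seed governing
#' all draws, the genome length, the list of sites to plant (each with its
#' editor, the intended screening outcome and, for editable sites, the
#' candidate multiplicity), mismatch decoys derived from planted sites, the
#' background SNP density, and the GWAS block (number of SNPs and
#' phenotypes, planted per-SNP promotion/inhibition counts, effect
#' magnitude, and the phi/theta ranges).
#'
#' Defaults emulate a compact study: a 10-kb genome carrying one editable
#' site per shipped editor plus one site per failure mode, decoys at 1--3
#' mismatches, one SNP per kb, and 131 GWAS phenotypes with planted
#' profiles spanning weak to strong pleiotropy.
#'
#' @param seed integer seed; identical seed and spec give byte-identical
#'   fixtures.
#' @param genomeLength background genome length in bp.
#' @param plantedSites list of `list(editor=, outcome=, multiplicity=)`;
#'   `outcome` is `"editable"` or one of the five failure labels.
#' @param decoys list of `list(site=<index into plantedSites>,
#'   mismatches=)`.
#' @param snpDensity expected SNPs per bp.
#' @param gwas list with `nSnps`, `nPhenotypes`, `planted` (list of
#'   `c(promote, inhibit)` per SNP, recycled), `effect`, `phiRange`,
#'   `thetaRange`, `alpha`.
#' @return a `PlantSpec` list.
#' @export
plantSpec <- function(seed = 1L,
                      genomeLength = 10000L,
                      plantedSites = list(
                        list(editor = "BE3", outcome = "editable",
                             multiplicity = 1L),
                        list(editor = "BE3", outcome = "editable",
                             multiplicity = 2L),
                        list(editor = "ABE7.10", outcome = "editable",
                             multiplicity = 1L),
                        list(editor = "BE3", outcome = "base_match_error"),
                        list(editor = "BE3", outcome = "no_PAM"),
                        list(editor = "BE3",
                             outcome = "activity_window_error"),
                        list(editor = "BE3",
                             outcome = "continuous_identical_base_error"),
                        list(editor = "BE3", outcome = "GC_ratio_error")
                      ),
                      decoys = list(
                        list(site = 1L, mismatches = 1L),
                        list(site = 1L, mismatches = 3L),
                        list(site = 2L, mismatches = 2L)
                      ),
                      snpDensity = 0.001,
                      gwas = list(
                        nSnps = 8L, nPhenotypes = 131L,
                        planted = list(c(17L, 3L), c(0L, 1L), c(8L, 12L),
                                       c(0L, 0L), c(15L, 12L), c(2L, 0L),
                                       c(0L, 0L), c(5L, 4L)),
                        effect = 0.3,
                        phiRange = c(0.2, 0.5),
                        thetaRange = c(0.2, 0.8),
                        alpha = 0.05
                      )) {
  spec <- list(seed = as.integer(seed), genomeLength = as.integer(genomeLength),
               plantedSites = plantedSites, decoys = decoys,
               snpDensity = snpDensity, gwas = gwas)
  class(spec) <- "PlantSpec"
  spec
}

.randChars <- function(n) sample(.BASES, n, replace = TRUE)

# Force a concrete matching PAM for the placement with the target at
# protospacer position p (plus-strand design; ctx target at index `center`).
# Pattern positions that are N keep whatever base is there.
.forcePam <- function(chars, center, p, editor) {
  L <- spacerLength(editor)
  pat <- strsplit(pamPattern(editor), "", fixed = TRUE)[[1]]
  pamStart <- center - p + L + 1L
  for (j in seq_along(pat)) {
    if (pat[j] != "N")
      chars[pamStart + j - 1L] <- substr(
        Biostrings::IUPAC_CODE_MAP[[pat[j]]], 1L, 1L)
  }
  chars
}

# Rejection-sample a local context (plus-strand design) producing exactly
# the intended screening outcome, then optionally flip it to the minus
# strand. Outcome-specific proposals keep acceptance rates workable; the
# verdict always comes from the independent brute-force screen.
.sampleSiteContext <- function(editor, outcome, multiplicity = 1L,
                               maxTries = 20000L) {
  L <- spacerLength(editor)
  P <- nchar(pamPattern(editor))
  win <- activityWindow(editor)
  half <- L + P + 2L
  ctxLen <- 2L * half + 1L
  center <- half + 1L
  tb <- targetBase(editor)
  minus <- sample(c(FALSE, TRUE), 1L)
  for (try in seq_len(maxTries)) {
    chars <- .randChars(ctxLen)
    if (outcome == "base_match_error") {
      ref <- sample(setdiff(.BASES, c(tb, .complementBase(tb))), 1L)
      chars[center] <- ref
    } else if (outcome == "continuous_identical_base_error") {
      chars[center] <- tb
      runBase <- sample(setdiff(.BASES, tb), 1L)
      chars[(center + 1L):(center + 7L)] <- runBase
      chars <- .forcePam(chars, center, sample(win[1]:win[2], 1L), editor)
    } else if (outcome == "GC_ratio_error") {
      phase <- sample(6L, 1L)
      gcCycle <- rep(c("G", "G", "G", "C", "C", "C"), length.out = ctxLen + 6L)
      chars <- gcCycle[phase:(phase + ctxLen - 1L)]
      nAT <- sample(0:2, 1L)
      if (nAT > 0L)
        chars[sample(ctxLen, nAT)] <- sample(c("A", "T"), nAT, replace = TRUE)
      chars[center] <- tb
      chars <- .forcePam(chars, center, sample(win[1]:win[2], 1L), editor)
    } else {
      chars[center] <- tb
    }
    if (minus) {
      chars <- rev(unname(.COMPLEMENT[chars]))
      ref <- chars[center]
    } else {
      ref <- chars[center]
    }
    mini <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""),
                                              "ctx"))
    site <- list(site_id = "ctx", chrom = "ctx", pos = center, ref = ref)
    verdict <- .bruteScreen(mini, site, editor)
    ok <- if (outcome == "editable") {
      verdict$status == "editable" &&
        nrow(verdict$candidates) == multiplicity
    } else {
      verdict$status == "failed" && verdict$fail_reason == outcome
    }
    if (ok) {
      alt <- if (ref == targetBase(editor)) {
        convertedBase(editor)
      } else if (ref == .complementBase(targetBase(editor))) {
        .complementBase(convertedBase(editor))
      } else {
        sample(setdiff(.BASES, ref), 1L)
      }
      return(list(chars = chars, ref = ref, alt = alt,
                  candidates = verdict$candidates, center = center))
    }
  }
  stop("infeasible plant spec: could not realize outcome ", sQuote(outcome),
       " (multiplicity ", multiplicity, ") within ", maxTries, " draws",
       call. = FALSE)
}

#' Generate a synthetic genome with planted sites and decoys
#'
#' Background bases are drawn uniformly from the seeded generator; each
#' planted construct is embedded in its own well-separated slot and
#' rejection-sampled until the independent brute-force screen confirms
#' exactly the intended outcome (and candidate multiplicity). Decoys copy a
#' planted candidate's protospacer with exactly the requested number of
#' substitutions, followed by a concrete instance of the editor's PAM.
#' After assembly every planted site is re-verified against the full
#' genome.
#'
#' @param spec a [plantSpec()].
#' @param registry an [EditorRegistry-class] resolving the editors named in
#'   the spec.
#' @return list with `genome` (a single-chromosome `DNAStringSet`), `sites`
#'   (truth data.frame: `site_id`, `chrom`, `pos`, `ref`, `alt`, `editor`,
#'   `expected_status`, `expected_fail_reason`, `expected_n_candidates`),
#'   `candidates` (verified candidate placements of the editable sites) and
#'   `decoys` (truth data.frame with the planted mismatch loci).
#' @export
simulateGenome <- function(spec, registry = loadEditors()) {
  stopifnot(inherits(spec, "PlantSpec"))
  set.seed(spec$seed)
  nSites <- length(spec$plantedSites)
  nSlots <- nSites + length(spec$decoys)
  slotWidth <- 120L
  needed <- 60L + nSlots * slotWidth
  if (spec$genomeLength < needed)
    stop("spec error: genomeLength ", spec$genomeLength, " too small for ",
         nSlots, " planted construct(s) (need >= ", needed, ")",
         call. = FALSE)
  bg <- .randChars(spec$genomeLength)
  siteRows <- vector("list", nSites)
  candRows <- vector("list", nSites)
  plantedCtx <- vector("list", nSites)
  for (i in seq_len(nSites)) {
    ps <- spec$plantedSites[[i]]
    editor <- getEditor(registry, ps$editor)
    mult <- if (is.null(ps$multiplicity)) 1L else as.integer(ps$multiplicity)
    ctx <- .sampleSiteContext(editor, ps$outcome, mult)
    half <- (length(ctx$chars) - 1L) %/% 2L
    pos <- 60L + (i - 1L) * slotWidth + half + 1L
    bg[(pos - half):(pos + half)] <- ctx$chars
    offset <- pos - ctx$center
    siteId <- paste0("site", i)
    cand <- ctx$candidates
    if (nrow(cand) > 0L) {
      cand$site_id <- siteId
      cand$protospacer_start <- cand$protospacer_start + offset
      cand$protospacer_end <- cand$protospacer_end + offset
      cand$chrom <- "chr1"
    }
    candRows[[i]] <- cand
    plantedCtx[[i]] <- ctx
    siteRows[[i]] <- data.frame(
      site_id = siteId, chrom = "chr1", pos = pos, ref = ctx$ref,
      alt = ctx$alt, editor = ps$editor,
      expected_status = if (ps$outcome == "editable") "editable" else "failed",
      expected_fail_reason = if (ps$outcome == "editable") "" else ps$outcome,
      expected_n_candidates = if (ps$outcome == "editable") mult else 0L,
      stringsAsFactors = FALSE)
  }
  decoyRows <- vector("list", length(spec$decoys))
  for (j in seq_along(spec$decoys)) {
    dc <- spec$decoys[[j]]
    src <- plantedCtx[[dc$site]]
    if (nrow(src$candidates) == 0L)
      stop("spec error: decoy ", j, " references site ", dc$site,
           " which has no candidate guides", call. = FALSE)
    editor <- getEditor(registry, spec$plantedSites[[dc$site]]$editor)
    query <- src$candidates$protospacer[1]
    qChars <- strsplit(query, "", fixed = TRUE)[[1]]
    mmPos <- sample(length(qChars), dc$mismatches)
    for (mp in mmPos)
      qChars[mp] <- sample(setdiff(.BASES, qChars[mp]), 1L)
    decoySeq <- c(qChars,
                  strsplit(.concretePam(pamPattern(editor)), "",
                           fixed = TRUE)[[1]])
    start <- 60L + (nSites + j - 1L) * slotWidth + 10L
    bg[start:(start + length(decoySeq) - 1L)] <- decoySeq
    decoyRows[[j]] <- data.frame(
      decoy_id = paste0("decoy", j),
      source_site = paste0("site", dc$site),
      query = query, chrom = "chr1", start = start,
      end = start + length(qChars) - 1L, strand = "+",
      n_mismatches = as.integer(dc$mismatches), stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(bg, collapse = ""),
                                              "chr1"))
  sites <- do.call(rbind, siteRows)
  # Re-verify every planted site against the assembled genome: the truth
  # table is only emitted if the independent screen still agrees.
  for (i in seq_len(nSites)) {
    editor <- getEditor(registry, sites$editor[i])
    verdict <- .bruteScreen(genome, sites[i, , drop = FALSE], editor)
    agree <- identical(verdict$status, sites$expected_status[i]) &&
      nrow(verdict$candidates) == sites$expected_n_candidates[i] &&
      (verdict$status == "editable" ||
         identical(verdict$fail_reason, sites$expected_fail_reason[i]))
    if (!agree)
      stop("internal generator error: planted site ", sites$site_id[i],
           " failed post-assembly verification", call. = FALSE)
  }
  candTruth <- do.call(rbind, candRows[vapply(candRows, nrow, integer(1)) > 0])
  list(genome = genome, sites = sites, candidates = candTruth,
       decoys = if (length(decoyRows)) do.call(rbind, decoyRows) else NULL)
}

#' Generate a background SNP track for a synthetic genome
#'
#' SNP positions are independent Bernoulli draws at `spec$snpDensity` per
#' bp; alternate alleles are drawn uniformly among the three non-reference
#' bases. The truth component counts SNPs inside each verified candidate
#' protospacer span.
#'
#' @param spec a [plantSpec()].
#' @param sim output of [simulateGenome()] for the same spec.
#' @return list with `snps` (data.frame `chrom`, `pos`, `snp_id`, `ref`,
#'   `alt`), `vcf` (character vector of VCF 4.2 lines) and `guideSnpCounts`
#'   (truth data.frame: per-candidate SNP counts).
#' @export
simulateSnpVcf <- function(spec, sim) {
  stopifnot(inherits(spec, "PlantSpec"))
  set.seed(spec$seed + 1L)
  chars <- strsplit(as.character(sim$genome[[1]]), "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < spec$snpDensity
  pos <- which(hit & chars %in% .BASES)
  alt <- vapply(chars[pos], function(r) sample(setdiff(.BASES, r), 1L),
                character(1), USE.NAMES = FALSE)
  snps <- data.frame(
    chrom = rep("chr1", length(pos)), pos = pos,
    snp_id = if (length(pos)) paste0("bg", seq_along(pos)) else character(0),
    ref = chars[pos], alt = alt, stringsAsFactors = FALSE)
  vcf <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr1,length=%d>", length(chars)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    if (nrow(snps))
      sprintf("chr1\t%d\t%s\t%s\t%s\t.\tPASS\t.", snps$pos, snps$snp_id,
              snps$ref, snps$alt))
  counts <- NULL
  if (!is.null(sim$candidates) && nrow(sim$candidates)) {
    counts <- sim$candidates[, c("site_id", "protospacer_start",
                                 "protospacer_end")]
    counts$snp_count <- vapply(seq_len(nrow(counts)), function(i) {
      sum(snps$pos >= counts$protospacer_start[i] &
            snps$pos <= counts$protospacer_end[i])
    }, integer(1))
  }
  list(snps = snps, vcf = vcf, guideSnpCounts = counts)
}

#' Generate GWAS summary tables with planted pleiotropy profiles
#'
#' Each synthetic SNP is assigned its planted number of significant
#' promotion and inhibition phenotypes: planted rows carry an observed-scale
#' effect of the requested magnitude with the planted sign and a P value
#' drawn below `alpha/10`; null rows carry a small zero-centered effect and
#' a P value uniform on `(alpha, 1]`, so classification at level `alpha`
#' recovers the planted counts exactly. Case proportions and allele
#' frequencies are drawn per phenotype within their spec ranges (kept away
#' from the extremes so the effect conversion is well-defined and
#' sign-preserving at the planted magnitude).
#'
#' @param spec a [plantSpec()].
#' @return list with `gwas` (long data.frame of records across phenotypes),
#'   `truth` (data.frame `snp_id`, `n_promote`, `n_inhibit`).
#' @export
simulateGwas <- function(spec) {
  stopifnot(inherits(spec, "PlantSpec"))
  g <- spec$gwas
  set.seed(spec$seed + 2L)
  planted <- rep_len(g$planted, g$nSnps)
  maxSig <- max(vapply(planted, sum, numeric(1)))
  if (g$nPhenotypes < maxSig)
    stop("spec error: nPhenotypes must be >= the largest planted profile",
         call. = FALSE)
  phenos <- sprintf("pheno%03d", seq_len(g$nPhenotypes))
  phi <- runif(g$nPhenotypes, g$phiRange[1], g$phiRange[2])
  theta <- runif(g$nPhenotypes, g$thetaRange[1], g$thetaRange[2])
  rows <- vector("list", g$nSnps)
  truth <- vector("list", g$nSnps)
  for (i in seq_len(g$nSnps)) {
    np <- planted[[i]][1]; ni <- planted[[i]][2]
    sig <- sample(g$nPhenotypes, np + ni)
    promote <- sig[seq_len(np)]
    inhibit <- sig[setdiff(seq_len(np + ni), seq_len(np))]
    betaObs <- rnorm(g$nPhenotypes, 0, g$effect / 20)
    pvals <- runif(g$nPhenotypes, g$alpha, 1)
    betaObs[promote] <- g$effect
    betaObs[inhibit] <- -g$effect
    pvals[sig] <- runif(length(sig), 0, g$alpha / 10)
    rows[[i]] <- data.frame(
      snp_id = paste0("rs", i), chrom = "chr1", pos = 1000L + i,
      phenotype_id = phenos, beta_obs = betaObs, p_value = pvals,
      phi = phi, theta = theta, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(snp_id = paste0("rs", i),
                             n_promote = np, n_inhibit = ni,
                             stringsAsFactors = FALSE)
  }
  list(gwas = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Generate a complete fixture on disk
#'
#' Writes `genome.fa`, `sites.tsv` (chrom, pos, ref, alt, id), `snps.vcf`,
#' one GWAS TSV per phenotype under `gwas/`, and the truth tables
#' (`truth_sites.tsv`, `truth_candidates.tsv`, `truth_decoys.tsv`,
#' `truth_snp_counts.tsv`, `truth_gwas.tsv`).
#'
#' @param spec a [plantSpec()].
#' @param dir output directory (created if needed).
#' @param registry editor registry resolving the spec's editor names.
#' @return invisibly, the list of in-memory objects
#'   (`genome`, `sites`, `candidates`, `decoys`, `snps`, `guideSnpCounts`,
#'   `gwas`, `gwasTruth`).
#' @export
simulateFixture <- function(spec, dir, registry = loadEditors()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateGenome(spec, registry)
  snp <- simulateSnpVcf(spec, sim)
  gw <- simulateGwas(spec)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write.table(sim$sites[, c("chrom", "pos", "ref", "alt", "site_id")],
              file.path(dir, "sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(snp$vcf, file.path(dir, "snps.vcf"))
  gdir <- file.path(dir, "gwas")
  dir.create(gdir, showWarnings = FALSE)
  for (ph in unique(gw$gwas$phenotype_id)) {
    sub <- gw$gwas[gw$gwas$phenotype_id == ph,
                   c("snp_id", "chrom", "pos", "beta_obs", "p_value",
                     "phi", "theta")]
    write.table(sub, file.path(gdir, paste0(ph, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(sim$sites, file.path(dir, "truth_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sim$candidates))
    write.table(sim$candidates, file.path(dir, "truth_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$decoys))
    write.table(sim$decoys, file.path(dir, "truth_decoys.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(snp$guideSnpCounts))
    write.table(snp$guideSnpCounts, file.path(dir, "truth_snp_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gw$truth, file.path(dir, "truth_gwas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(genome = sim$genome, sites = sim$sites,
                 candidates = sim$candidates, decoys = sim$decoys,
                 snps = snp$snps, guideSnpCounts = snp$guideSnpCounts,
                 gwas = gw$gwas, gwasTruth = gw$truth))
}
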