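query20 <- "ACATCATCATGCATATACAT"   # GG-free, GC 30%

test_that("an exact duplicate elsewhere is the only zero-mismatch hit", {
  pad <- strrep("T", 25)
  seqstr <- paste0(pad, query20, "AGG", pad, query20, "TGG", pad)
  g <- as_genome(c(chr1 = seqstr))
  on_target <- list(chrom = "chr1", protospacer_start = 26L,
                    protospacer_end = 45L, strand = "+")
  hits <- findOfftargets(query20, g, maxMismatch = 0L, pamPolicy = "strict",
                         onTarget = on_target)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$n_mismatches, 0L)
  expect_identical(hits$start, 26L + 48L)
  expect_identical(hits$pam_sequence, "TGG")
})

test_that("mismatch budgets gate planted decoys exactly", {
  # decoy with exactly 3 substitutions: invisible at budget 2, found at 3
  decoy <- query20
  substr(decoy, 2, 2) <- "G"
  substr(decoy, 9, 9) <- "C"
  substr(decoy, 15, 15) <- "G"
  stopifnot(sum(strsplit(decoy, "")[[1]] != strsplit(query20, "")[[1]]) == 3)
  pad <- strrep("T", 25)
  seqstr <- paste0(pad, query20, "AGG", pad, decoy, "CGG", pad)
  g <- as_genome(c(chr1 = seqstr))
  on_target <- list(chrom = "chr1", protospacer_start = 26L,
                    protospacer_end = 45L, strand = "+")
  h2 <- findOfftargets(query20, g, maxMismatch = 2L, onTarget = on_target)
  h3 <- findOfftargets(query20, g, maxMismatch = 3L, onTarget = on_target)
  expect_identical(nrow(h2), 0L)
  expect_identical(nrow(h3), 1L)
  expect_identical(h3$n_mismatches, 3L)
})

test_that("hit sets equal the literal all-positions scan on random genomes", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 10000
    seqstr <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                    collapse = "")
    query <- substr(seqstr, 501, 520)    # a real 20-mer from the genome
    seqs <- list(chr1 = seqstr)
    g <- as_genome(c(chr1 = seqstr))
    for (mm in c(0L, 2L, 4L)) {
      for (policy in c("strict", "any")) {
        impl <- findOfftargets(query, g, maxMismatch = mm,
                               pamPolicy = policy)
        orc <- orc_offtargets(query, seqs, mm, policy = policy)
        expect_identical(hit_keys(impl), hit_keys(orc))
      }
    }
  }
})

test_that("hit sets are strand-symmetric and monotone in the budget", {
  set.seed(77)
  seqstr <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                  collapse = "")
  query <- substr(seqstr, 101, 120)
  g <- as_genome(c(chr1 = seqstr))
  g_rc <- as_genome(c(chr1 = orc_revcomp(seqstr)))
  n <- 6000
  prev <- NULL
  for (mm in 0:4) {
    hits <- findOfftargets(query, g, maxMismatch = mm, pamPolicy = "any")
    flipped <- findOfftargets(query, g_rc, maxMismatch = mm,
                              pamPolicy = "any")
    # map plus-strand coordinates of the reverse-complemented genome back
    remapped <- sprintf("chr1:%d-%d%s/%d",
                        n - flipped$end + 1, n - flipped$start + 1,
                        ifelse(flipped$strand == "+", "-", "+"),
                        flipped$n_mismatches)
    expect_setequal(hit_keys(hits), sort(remapped))
    if (!is.null(prev)) expect_true(all(prev %in% hit_keys(hits)))
    prev <- hit_keys(hits)
  }
})

test_that("CFD scoring multiplies per-position penalties and the PAM factor", {
  tab <- uniformCfdTable(penalty = 0.5, pamPenalty = 0.25)
  hit1 <- query20
  substr(hit1, 7, 7) <- "G"
  hit2 <- hit1
  substr(hit2, 13, 13) <- "G"

  expect_identical(cfdScore(query20, query20, "AGG", tab), 1)
  expect_equal(cfdScore(query20, hit1, "TGG", tab), 0.5)
  expect_equal(cfdScore(query20, hit2, "CGG", tab), 0.25)
  # non-canonical PAM multiplies in its penalty
  expect_equal(cfdScore(query20, hit2, "CAT", tab), 0.25 * 0.25)
  expect_equal(cfdScore(query20, query20, "CAT", tab), 0.25)

  # a position-specific table: the score is exactly the looked-up product
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tquery_base\tgenomic_base\tmultiplier",
               "7\tT\tG\t0.9",
               "13\tA\tG\t0.3",
               "PAM\tCAT\t\t0.1",
               "PAM\tdefault\t\t0.05"), f)
  custom <- readCfdTable(f)
  stopifnot(substr(query20, 7, 7) == "T", substr(query20, 13, 13) == "A")
  expect_equal(cfdScore(query20, hit2, "AGG", custom), 0.9 * 0.3)
  expect_equal(cfdScore(query20, hit2, "CAT", custom), 0.9 * 0.3 * 0.1)
  expect_equal(cfdScore(query20, hit2, "TTT", custom), 0.9 * 0.3 * 0.05)
  # absent (position, base pair) is a configuration error
  hit3 <- query20
  substr(hit3, 2, 2) <- "A"
  expect_error(cfdScore(query20, hit3, "AGG", custom), "configuration error")
})

test_that("the off-target feature is the mean CFD over hits, 0 when there are none", {
  tab <- uniformCfdTable(penalty = 0.5)
  pad <- strrep("T", 25)
  mm1 <- query20
  substr(mm1, 3, 3) <- "G"
  # genome: on-target + one exact copy (CFD 1.0) + one 1-mismatch copy (0.5)
  seqstr <- paste0(pad, query20, "AGG", pad, query20, "TGG", pad, mm1,
                   "CGG", pad)
  g <- as_genome(c(chr1 = seqstr))
  guide <- data.frame(protospacer = query20, chrom = "chr1",
                      protospacer_start = 26L, protospacer_end = 45L,
                      strand = "+", stringsAsFactors = FALSE)
  expect_equal(
    offtargetFeature(guide, g, maxMismatch = 4L, table = tab), 0.75)

  # isolated guide: no hits anywhere
  g0 <- as_genome(c(chr1 = paste0(pad, query20, "AGG", pad)))
  expect_identical(offtargetFeature(guide, g0, maxMismatch = 2L, table = tab),
                   0)
})

test_that("sub-20-nt protospacers fall back to 0.5^mismatches with a warning", {
  q <- substr(query20, 1, 18)
  h <- q
  substr(h, 4, 4) <- "G"
  expect_warning(s <- cfdScore(q, h, "AGG", uniformCfdTable()),
                 "shorter than 20")
  expect_equal(s, 0.5)
})
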