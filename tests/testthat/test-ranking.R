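# Feature computation and RRA-based guide selection.

make_fixture_site <- function(seed = 5) {
  fx <- simulateGenome(plantSpec(seed = seed))
  pick <- fx$sites[fx$sites$expected_status == "editable" &
                     fx$sites$editor == "BE3", ]
  pick <- pick[order(-pick$expected_n_candidates), ][1, , drop = FALSE]
  out <- screenSite(pick, be3(), fx$genome)
  stopifnot(siteStatus(out) == "editable")
  list(fx = fx, site = pick, outcome = out)
}

test_that("the five features are computed as defined", {
  # bystander count over the window, including the target base itself
  pad <- strrep("T", 30)
  proto <- "ATTCCATCATGCATATACAT"    # window 4-8 content "CCATC": three Cs
  stopifnot(substr(proto, 5, 5) == "C", !grepl("GG", proto, fixed = TRUE))
  seqstr <- paste0(pad, proto, "TGG", pad)
  g <- as_genome(c(chr1 = seqstr))
  site <- site_row("chr1", 35, "C")
  out <- screenSite(site, be3(), g)
  stopifnot(siteStatus(out) == "editable")
  snp <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(33, 44, 80), width = 1))
  feats <- computeFeatures(candidates(out), site, be3(), g, snpTrack = snp,
                           cfdTable = uniformCfdTable())
  expect_identical(feats$same_base_in_window, 3L)
  expect_equal(feats$gc_fraction, orc_gc_count(proto) / 20)
  expect_identical(feats$repeat_count, 1L)       # unique in this genome
  expect_identical(feats$snp_count, 2L)          # two SNPs inside 31..50
  expect_identical(feats$offtarget_score, 0)     # nothing within budget

  # an all-AT protospacer has gc_fraction exactly 0 (checked pre-screening)
  expect_equal(
    computeFeatures(
      data.frame(site_id = "x", strand = "+",
                 protospacer = "ATATATATATATATATATAT", pam = "TGG",
                 protospacer_start = 31L, protospacer_end = 50L,
                 target_window_pos = 5L, stringsAsFactors = FALSE),
      site, be3(), g, snpTrack = snp, cfdTable = uniformCfdTable()
    )$gc_fraction, 0)
})

test_that("a duplicated protospacer is counted as a genomic repeat", {
  pad <- strrep("T", 30)
  proto <- "ACATCATCATGCATATACAT"
  seqstr <- paste0(pad, proto, "TGG", pad, proto, "TAA", pad)
  g <- as_genome(c(chr1 = seqstr))
  site <- site_row("chr1", 35, "C")
  out <- screenSite(site, be3(), g)
  feats <- computeFeatures(candidates(out), site, be3(), g,
                           snpTrack = GenomicRanges::GRanges(),
                           cfdTable = uniformCfdTable())
  expect_identical(feats$repeat_count, 2L)
})

test_that("RRA equals the beta order-statistic minimum and is monotone", {
  # all five lists rank the candidate 1st of 4
  expect_equal(unname(rraAggregate(matrix(rep(0.25, 5), nrow = 1))),
               min(pbeta(0.25, 1:5, 5 - 1:5 + 1)))
  # single-candidate site: all normalized ranks 1, score 1
  expect_equal(unname(rraAggregate(matrix(rep(1, 5), nrow = 1))), 1)
  # componentwise domination can never hurt
  set.seed(9)
  for (i in 1:200) {
    a <- runif(5)
    b <- pmin(1, a + runif(5, 0, 1 - a))   # b >= a componentwise
    expect_lte(rraAggregate(matrix(a, nrow = 1)),
               rraAggregate(matrix(b, nrow = 1)))
  }
  expect_error(rraAggregate(matrix(c(0, .5, .5, .5, .5), nrow = 1)),
               "\\(0, 1\\]")
})

test_that("rankGuides averages ties, flags exactly one winner, and is order-stable", {
  fx <- make_fixture_site(seed = 5)
  feats <- computeFeatures(candidates(fx$outcome), fx$site, be3(),
                           fx$fx$genome, snpTrack = GenomicRanges::GRanges(),
                           cfdTable = uniformCfdTable())
  ranked <- rankGuides(feats)
  expect_identical(sum(ranked$is_best), 1L)
  # normalized ranks never exceed 1 and per-feature ranks sum to m(m+1)/2
  m <- nrow(ranked)
  for (col in c("rank_same_base", "rank_gc", "rank_repeat", "rank_snp",
                "rank_offtarget"))
    expect_equal(sum(ranked[[col]]), m * (m + 1) / 2)

  # permuting candidate order changes neither scores nor the winner
  perm <- sample(seq_len(nrow(feats)))
  ranked_perm <- rankGuides(feats[perm, ])
  key <- function(df) df[order(df$protospacer_start, df$strand),
                         c("rra_score", "is_best")]
  expect_equal(key(ranked_perm), key(ranked), ignore_attr = TRUE)
})

test_that("identical feature vectors tie-break deterministically by position", {
  feats <- data.frame(
    site_id = "s", strand = c("+", "+"),
    protospacer = c("AAA", "CCC"), pam = "TGG",
    protospacer_start = c(50L, 10L), protospacer_end = c(69L, 29L),
    target_window_pos = 5L,
    same_base_in_window = 2L, gc_fraction = 0.4, repeat_count = 1L,
    snp_count = 0L, offtarget_score = 0.1, stringsAsFactors = FALSE)
  ranked <- rankGuides(feats)
  expect_identical(ranked$is_best, c(FALSE, TRUE))  # smaller genomic start
  expect_equal(ranked$rra_score[1], ranked$rra_score[2])
})

test_that("adding a strictly dominated candidate never changes the winner", {
  base <- data.frame(
    site_id = "s", strand = "+",
    protospacer = c("g1", "g2"), pam = "TGG",
    protospacer_start = c(10L, 40L), protospacer_end = c(29L, 59L),
    target_window_pos = 5L,
    same_base_in_window = c(1L, 2L), gc_fraction = c(0.35, 0.5),
    repeat_count = c(1L, 1L), snp_count = c(0L, 1L),
    offtarget_score = c(0.05, 0.2), stringsAsFactors = FALSE)
  winner <- function(df) df$protospacer[df$is_best]
  w0 <- winner(rankGuides(base))
  dominated <- base[2, ]
  dominated$protospacer <- "g3"
  dominated$protospacer_start <- 80L
  dominated$same_base_in_window <- 3L
  dominated$gc_fraction <- 0.7
  dominated$snp_count <- 2L
  dominated$offtarget_score <- 0.5
  expect_identical(winner(rankGuides(rbind(base, dominated))), w0)
})
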