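test_that("the design strand follows the editor's target base chemistry", {
  expect_identical(matchTargetBase(list(ref = "C"), be3()), "+")
  expect_identical(matchTargetBase(list(ref = "G"), be3()), "-")
  expect_identical(matchTargetBase(list(ref = "T"), be3()), "base_match_error")
  expect_identical(matchTargetBase(list(ref = "A"), be3()), "base_match_error")
  expect_identical(matchTargetBase(list(ref = "A"), abe710()), "+")
  expect_identical(matchTargetBase(list(ref = "T"), abe710()), "-")
  expect_identical(matchTargetBase(list(ref = "G"), abe710()),
                   "base_match_error")
})

test_that("a single planted NGG placement yields exactly one candidate at its window position", {
  proto <- "ACATCATCATGCATATACAT"   # GG-free; C at position 5
  stopifnot(substr(proto, 5, 5) == "C")
  ctx <- plant_context(proto, p = 5)
  g <- as_genome(c(chr1 = ctx$seq))
  out <- screenSite(site_row("chr1", ctx$pos, "C"), be3(), g)
  expect_identical(siteStatus(out), "editable")
  cand <- candidates(out)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$target_window_pos, 5L)
  expect_identical(cand$protospacer, proto)
  expect_identical(cand$pam, "TGG")
  expect_identical(cand$protospacer_start, ctx$proto_start)
  expect_identical(cand$protospacer_end, ctx$proto_end)

  # the independent sliding-window oracle agrees placement for placement
  orc <- orc_screen(list(chr1 = ctx$seq), "chr1", ctx$pos, "C")
  expect_identical(orc$status, "editable")
  expect_identical(orc$cands$protospacer, cand$protospacer)
  expect_identical(orc$cands$target_window_pos, cand$target_window_pos)
})

test_that("PAM-free context fails no_PAM; PAM only outside the window fails activity_window_error", {
  # no GG anywhere downstream of the target within the searchable range
  proto <- "ACATCATCATGCATATACAT"
  ctx <- plant_context(proto, p = 5, pam = "TTT")
  g <- as_genome(c(chr1 = ctx$seq))
  out <- screenSite(site_row("chr1", ctx$pos, "C"), be3(), g)
  expect_identical(siteStatus(out), "failed")
  expect_identical(failReason(out), "no_PAM")

  # the only NGG placement puts the target at position 12 (window is 4-8)
  ctx12 <- plant_context(proto, p = 12)
  g12 <- as_genome(c(chr1 = ctx12$seq))
  out12 <- screenSite(site_row("chr1", ctx12$pos, "C"), be3(), g12)
  expect_identical(failReason(out12), "activity_window_error")
})

test_that("minus-strand design reads the reverse complement and maps coordinates back", {
  proto <- "ACATCATCATGCATATACAT"
  ctx <- plant_context(proto, p = 5)
  # reverse-complement the whole chromosome: the site becomes a G on the
  # plus strand and the design must flip to the minus strand
  rc <- orc_revcomp(ctx$seq)
  pos_rc <- nchar(ctx$seq) - ctx$pos + 1
  g <- as_genome(c(chr1 = rc))
  out <- screenSite(site_row("chr1", pos_rc, "G"), be3(), g)
  expect_identical(siteStatus(out), "editable")
  cand <- candidates(out)
  expect_identical(cand$strand, "-")
  expect_identical(cand$protospacer, proto)     # read 5'->3' on its strand
  expect_identical(cand$pam, "TGG")
  expect_identical(cand$target_window_pos, 5L)
  # genomic span still reported in plus-strand coordinates
  expect_identical(cand$protospacer_start,
                   nchar(ctx$seq) - ctx$proto_end + 1L)
  expect_identical(cand$protospacer_end,
                   nchar(ctx$seq) - ctx$proto_start + 1L)
})

test_that("GC bounds are inclusive at 30% and 75% and a 7-run homopolymer fails", {
  make_gc_proto <- function(n_gc) {
    proto <- switch(as.character(n_gc),
      "6"  = "AGATCTAGATCTAGATCTAT",
      "15" = "CTCGCGAGCTCGCGAGCTCG",
      "16" = "CTCGCGAGCTCGCGAGCGCG")
    stopifnot(orc_gc_count(proto) == n_gc,
              substr(proto, 5, 5) == "C",
              !grepl("GG", proto, fixed = TRUE),
              orc_longest_run(proto) < 7)
    proto
  }

  run_case <- function(proto) {
    ctx <- plant_context(proto, p = 5)
    screenSite(site_row("chr1", ctx$pos, "C"), be3(),
               as_genome(c(chr1 = ctx$seq)))
  }

  expect_identical(siteStatus(run_case(make_gc_proto(6))), "editable")   # 30%
  expect_identical(siteStatus(run_case(make_gc_proto(15))), "editable")  # 75%
  out16 <- run_case(make_gc_proto(16))                                   # 80%
  expect_identical(failReason(out16), "GC_ratio_error")

  run_proto <- function(run_len) {
    chars <- c("G", "C", "G", "T", "C",
               rep("A", run_len),
               c("C", "G", "T", "C", "A", "T", "G", "C", "T")[
                 seq_len(15 - run_len)])
    proto <- paste(chars, collapse = "")
    stopifnot(nchar(proto) == 20, orc_longest_run(proto) == run_len,
              !grepl("GG", proto, fixed = TRUE))
    gc <- orc_gc_count(proto)
    stopifnot(gc / 20 >= 0.3, gc / 20 <= 0.75)
    proto
  }
  expect_identical(siteStatus(run_case(run_proto(6))), "editable")
  expect_identical(failReason(run_case(run_proto(7))),
                   "continuous_identical_base_error")
})

test_that("applySequenceFilters keeps survivors and only fails when all candidates die", {
  cands <- data.frame(
    site_id = "s", strand = "+",
    protospacer = c("CCCCCCCATATATATATATA",   # 7-run: dies at stage 1
                    "GCGCGCGCGCGCGCGCGCGC",   # GC 100%: dies at stage 2
                    "ACATCATCATGCATATACAT"),  # passes both
    pam = "TGG", protospacer_start = 1L, protospacer_end = 20L,
    target_window_pos = 5L, stringsAsFactors = FALSE)
  res <- applySequenceFilters(cands)
  expect_true(is.na(res$failReason))
  expect_identical(nrow(res$kept), 1L)
  expect_identical(res$kept$protospacer, "ACATCATCATGCATATACAT")

  res_run <- applySequenceFilters(cands[1, ])
  expect_identical(res_run$failReason, "continuous_identical_base_error")
  res_gc <- applySequenceFilters(cands[2, ])
  expect_identical(res_gc$failReason, "GC_ratio_error")
})

test_that("screening agrees with the brute-force oracle on random genomes", {
  set.seed(42)
  for (rep in 1:30) {
    n <- 400
    seqstr <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                    collapse = "")
    pos <- sample(60:(n - 60), 1)
    ref <- substr(seqstr, pos, pos)
    g <- as_genome(c(chr1 = seqstr))
    out <- screenSite(site_row("chr1", pos, ref), be3(), g)
    orc <- orc_screen(list(chr1 = seqstr), "chr1", pos, ref)
    expect_identical(siteStatus(out), orc$status)
    if (orc$status == "failed") {
      expect_identical(failReason(out), orc$fail)
    } else {
      cand <- candidates(out)
      expect_identical(
        sort(sprintf("%d-%d%s", cand$protospacer_start,
                     cand$protospacer_end, cand$strand)),
        sort(sprintf("%d-%d%s", orc$cands$protospacer_start,
                     orc$cands$protospacer_end, orc$cands$strand)))
    }
    # every emitted failure label is from the five-label vocabulary
    if (siteStatus(out) == "failed")
      expect_true(failReason(out) %in%
                    c("base_match_error", "no_PAM", "activity_window_error",
                      "continuous_identical_base_error", "GC_ratio_error"))
  }
})

test_that("candidate sets do not depend on site list order", {
  fx <- simulateGenome(plantSpec(seed = 3))
  fwd <- screenSites(fx$sites, be3(), fx$genome)
  rev_ <- screenSites(fx$sites[rev(seq_len(nrow(fx$sites))), ], be3(),
                      fx$genome)
  for (id in names(fwd)) {
    expect_identical(siteStatus(fwd[[id]]), siteStatus(rev_[[id]]))
    expect_identical(candidates(fwd[[id]]), candidates(rev_[[id]]))
  }
})
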