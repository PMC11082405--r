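# The generator is first-class code: its truth tables must be recovered by
# the production pipeline, and its output must be byte-stable under a seed.

test_that("identical seeds give byte-identical fixtures; different seeds differ", {
  a <- simulateGenome(plantSpec(seed = 123))
  b <- simulateGenome(plantSpec(seed = 123))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$sites, b$sites)
  expect_identical(a$decoys, b$decoys)
  c_ <- simulateGenome(plantSpec(seed = 124))
  expect_false(identical(as.character(a$genome), as.character(c_$genome)))

  ga <- simulateGwas(plantSpec(seed = 123))
  gb <- simulateGwas(plantSpec(seed = 123))
  expect_identical(ga$gwas, gb$gwas)
})

test_that("planted screening outcomes are recovered exactly by the pipeline", {
  for (seed in c(2, 14, 90)) {
    fx <- simulateGenome(plantSpec(seed = seed))
    reg <- loadEditors()
    for (i in seq_len(nrow(fx$sites))) {
      site <- fx$sites[i, , drop = FALSE]
      out <- screenSite(site, getEditor(reg, site$editor), fx$genome)
      expect_identical(siteStatus(out), site$expected_status)
      expect_identical(nrow(candidates(out)), site$expected_n_candidates)
      if (site$expected_status == "failed")
        expect_identical(failReason(out), site$expected_fail_reason)
    }
  }
})

test_that("planted decoys are found at their mismatch budget and not below", {
  fx <- simulateGenome(plantSpec(seed = 8))
  for (j in seq_len(nrow(fx$decoys))) {
    d <- fx$decoys[j, ]
    src <- fx$candidates[fx$candidates$site_id == d$source_site, ][1, ]
    on_target <- list(chrom = "chr1",
                      protospacer_start = src$protospacer_start,
                      protospacer_end = src$protospacer_end,
                      strand = src$strand)
    key <- sprintf("chr1:%d-%d+", d$start, d$end)
    found_at <- function(mm) {
      h <- findOfftargets(d$query, fx$genome, maxMismatch = mm,
                          onTarget = on_target)
      key %in% sprintf("%s:%d-%d%s", h$chrom, h$start, h$end, h$strand)
    }
    expect_true(found_at(d$n_mismatches))
    if (d$n_mismatches > 0) expect_false(found_at(d$n_mismatches - 1L))
  }
})

test_that("SNP truth counts match the snp_count feature", {
  spec <- plantSpec(seed = 17, snpDensity = 0.02)   # dense enough to land in guides
  fx <- simulateGenome(spec)
  snp <- simulateSnpVcf(spec, fx)
  expect_gt(nrow(snp$snps), 0)
  track <- GenomicRanges::GRanges(
    snp$snps$chrom, IRanges::IRanges(snp$snps$pos, width = 1))
  for (sid in unique(snp$guideSnpCounts$site_id)) {
    site <- fx$sites[fx$sites$site_id == sid, , drop = FALSE]
    ed <- getEditor(loadEditors(), site$editor)
    out <- screenSite(site, ed, fx$genome)
    feats <- computeFeatures(candidates(out), site, ed, fx$genome,
                             snpTrack = track, maxMismatch = 0L,
                             cfdTable = uniformCfdTable())
    truth <- snp$guideSnpCounts[snp$guideSnpCounts$site_id == sid, ]
    m <- merge(feats, truth,
               by = c("site_id", "protospacer_start", "protospacer_end"))
    expect_identical(nrow(m), nrow(truth))
    expect_identical(m$snp_count.x, m$snp_count.y)
  }
})

test_that("zero SNP density yields a header-only VCF that reads back empty", {
  spec <- plantSpec(seed = 4, snpDensity = 0)
  fx <- simulateGenome(spec)
  snp <- simulateSnpVcf(spec, fx)
  expect_identical(nrow(snp$snps), 0L)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(snp$vcf, f)
  expect_identical(length(readSnpTrack(f)), 0L)
})

test_that("GWAS fixtures plant significant rows below alpha/10 and nulls above alpha", {
  spec <- plantSpec(seed = 33)
  gw <- simulateGwas(spec)
  alpha <- spec$gwas$alpha
  planted <- abs(gw$gwas$beta_obs) == spec$gwas$effect
  expect_true(all(gw$gwas$p_value[planted] < alpha / 10))
  expect_true(all(gw$gwas$p_value[!planted] > alpha))
  expect_identical(sum(planted),
                   as.integer(sum(vapply(
                     rep_len(spec$gwas$planted, spec$gwas$nSnps),
                     sum, numeric(1)))))
})

test_that("an infeasible spec is rejected rather than silently mis-planted", {
  expect_error(simulateGenome(plantSpec(seed = 1, genomeLength = 200L)),
               "spec error")
  bad_gwas <- plantSpec(seed = 1,
                        gwas = list(nSnps = 1L, nPhenotypes = 5L,
                                    planted = list(c(10L, 3L)), effect = 0.3,
                                    phiRange = c(0.2, 0.5),
                                    thetaRange = c(0.2, 0.8), alpha = 0.05))
  expect_error(simulateGwas(bad_gwas), "nPhenotypes")
})

test_that("simulateFixture writes a coherent on-disk bundle", {
  dir <- withr::local_tempdir()
  fx <- simulateFixture(plantSpec(seed = 6), dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "sites.tsv", "snps.vcf", "truth_sites.tsv",
    "truth_gwas.tsv")))))
  g <- readGenome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(fx$genome))
  sites <- readSites(file.path(dir, "sites.tsv"), g)
  expect_true(all(is.na(sites$load_error)))
  expect_identical(sites$site_id, fx$sites$site_id)
  gwas <- readGwas(file.path(dir, "gwas"))
  expect_identical(sort(unique(gwas$phenotype_id)),
                   sort(unique(fx$gwas$phenotype_id)))
})
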