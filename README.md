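# BEscreen

In-silico design of base-editing guide RNAs and pleiotropy assessment of
candidate editing loci.

CRISPR base editors correct single bases in place — cytosine editors (CBE,
C→T) and adenine editors (ABE, A→G) — but a target SNP is editable only
when the editor's geometry allows it: a PAM must sit immediately 3′ of a
protospacer that places the target base inside the editor's activity
window, and the resulting guide must be a usable sequence. BEscreen is for
researchers choosing base-editing targets and guides: it decides
editability, explains failures, ranks the feasible guides, and quantifies
the risk that editing a locus perturbs other phenotypes.

The pipeline has three parts:

1. **Site screening** — five sequential checks per site, each with a
   machine-readable failure label: target-base match (`base_match_error`),
   PAM availability (`no_PAM`), activity-window placement
   (`activity_window_error`), homopolymer content
   (`continuous_identical_base_error`, runs ≥ 7 are rejected) and GC
   content (`GC_ratio_error`, 30–75% inclusive). BE3 (NGG, window 4–8) and
   ABE7.10 (NGG, window 4–7) ship as defaults; any editor is definable in
   a small YAML registry.
2. **Guide evaluation** — five features per candidate, smaller is better:
   bystander bases in the window, GC fraction, exact genomic repeats,
   overlapping SNPs, and the mean CFD off-target score from a genome-wide
   mismatch scan. Per-feature ranks are normalized and aggregated with
   robust rank aggregation, ρ = min₍ₖ₎ BetaCDF(r₍ₖ₎; k, 5−k+1); the
   smallest ρ wins, with deterministic tie-breaks.
3. **Pleiotropy profiling** — GWAS observed-scale effects are converted to
   allelic substitution effects via
   β = β_obs · [Φ(1−Φ) + 0.5(1−2Φ)(1−2θ)β_obs −
   (0.084 + 0.9Φ(1−2Φ))θ(1−θ)Φ(1−Φ)β_obs²]⁻¹,
   classified per phenotype (promotion: β > 0, P < 0.05; inhibition:
   β < 0, P < 0.05), counted per SNP, binned by strength (<10, 10–20, >20
   significant phenotypes), and screened for weak-pleiotropy loci.

A deterministic synthetic-data generator (genomes with planted
editable/uneditable sites and mismatch decoys, SNP tracks, GWAS tables
with planted effects) is part of the package and is the ground truth for
the test suite.

## Worked example

```r
library(BEscreen)

dir <- tempfile()
runSimulate(outDir = dir, seed = 1)        # synthetic genome, sites, SNPs, GWAS
res <- runDesign(
  genomePath = file.path(dir, "genome.fa"),
  sitesPath  = file.path(dir, "sites.tsv"),
  editorName = "BE3",
  snpsPath   = file.path(dir, "snps.vcf"),
  outDir     = file.path(dir, "design"))

res$report[res$report$is_best %in% TRUE,
           c("site_id", "strand", "protospacer", "pam",
             "offtarget_score", "rra_score")]
#>  site_id strand          protospacer pam offtarget_score rra_score
#>    site1      + CTAACCCTTTAACCGTATCA CGG       0.4033042 1.0000000
#>    site2      - GCATTCAACGCAGCAGTATG AGG       0.0000000 0.6328125

res$failures
#>                      fail_reason count percent
#>                 base_match_error     2    33.3
#>                           no_PAM     1    16.7
#>            activity_window_error     1    16.7
#>  continuous_identical_base_error     1    16.7
#>                   GC_ratio_error     1    16.7
```

Two of the eight synthetic sites are editable under BE3; each gets exactly
one best guide (`rra_score` is 1 when a site has a single candidate, and
the smallest score among candidates otherwise). The six failed sites are
broken down by the first screening check that eliminated them.

```r
pleio <- runPleiotropy(file.path(dir, "gwas"), outDir = file.path(dir, "pleio"))
pleio$bins
#>  strength_bin count percent
#>           <10     5    62.5
#>         10-20     2    25.0
#>           >20     1    12.5
pleio$weak
#> [1] "rs2" "rs4" "rs7"
```

Five of the eight synthetic SNPs are significantly associated with fewer
than 10 phenotypes; the three reported as weak have at most one
significant association (the default criterion, configurable via
`maxSignificant`) and are the loci safest to edit with respect to
unintended phenotype changes.

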