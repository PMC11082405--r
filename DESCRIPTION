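Package: BEscreen
Title: In Silico Base-Editing gRNA Design and Pleiotropy Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens target loci for editability by configurable CRISPR base
    editors (cytosine and adenine editors; BE3 and ABE7.10 shipped as
    defaults), enumerates candidate guide RNAs under PAM and activity-window
    constraints, filters them by homopolymer and GC-content rules, ranks
    feasible guides by five sequence and genome features aggregated with
    robust rank aggregation, scores off-target loci with a CFD-style
    multiplicative model over a genome-wide mismatch scan, and profiles the
    pleiotropy of candidate editing loci from GWAS summary statistics after
    observed-scale effect conversion. Includes a deterministic synthetic-data
    generator (genomes with planted sites and decoys, SNP tracks, GWAS
    tables) used as the test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
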