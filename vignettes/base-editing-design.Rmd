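---
title: "Designing base-editing gRNAs and assessing pleiotropy with BEscreen"
author: "BEscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing base-editing gRNAs and assessing pleiotropy with BEscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BEscreen)
```

# The problem

CRISPR base editors convert single bases in place — a cytosine editor (CBE)
deaminates C to give C·G → T·A, an adenine editor (ABE) gives A·T → G·C —
without double-strand breaks or donor DNA, which makes them attractive for
correcting pathogenic point mutations. But whether a given SNP can be
edited at all, and which guide RNA to use when several are possible, is
constrained by the editor's geometry: the Cas module needs a protospacer
adjacent motif (PAM) just 3′ of the protospacer, and the deaminase acts
efficiently only within an *activity window*, a few positions at the
PAM-distal end of the protospacer. BEscreen makes those constraints
explicit: it screens target sites for editability, ranks the feasible
guides, and — because correcting one disease allele can perturb other
phenotypes — profiles the pleiotropy of candidate editing loci from GWAS
summary statistics.

# The screening model

Each target site is pushed through five sequential checks; the first check
at which every placement dies labels the site with a machine-readable
failure cause:

1. **Target-base match** (`base_match_error`): the reference base must be
   the editor's target base on one strand — C or G for a CBE, A or T for an
   ABE. The strand carrying the target base becomes the design strand.
2. **PAM search** (`no_PAM`): all placements of the protospacer that cover
   the target base are considered, i.e. the target at protospacer position
   $p \in [1, L]$ for spacer length $L$, with the PAM immediately 3′ on the
   design strand. If no placement's PAM matches the editor's IUPAC pattern,
   the site fails. Defining the searchable range as *every*
   target-covering placement makes `no_PAM` and the next label mutually
   exclusive and well defined.
3. **Activity window** (`activity_window_error`): among PAM-matching
   placements, only those with $w_s \le p \le w_e$ (window bounds counted
   from the PAM-distal 5′ end, 1-based, inclusive) become candidates.
4. **Homopolymers** (`continuous_identical_base_error`): a run of 7 or more
   identical bases impairs gRNA binding; candidates with a longest run
   $\le 6$ are kept.
5. **GC content** (`GC_ratio_error`): candidates with $30\% \le GC \le
   75\%$ over the protospacer are kept. Both bounds are inclusive and are
   compared in integer arithmetic (`10·gc ≥ 3·L` and `4·gc ≤ 3·L`), so a
   20-nt spacer with exactly 6 or 15 G/C bases passes.

GC and homopolymer statistics are computed over the protospacer only — the
spacer is what hybridizes — never over the PAM. Minus-strand designs are
read off the reverse complement and reported 5′→3′ on their own strand,
with genomic spans kept in plus-strand coordinates. Placements running past
a chromosome boundary, or touching an N, are skipped conservatively.

Shipped editor definitions are BE3 (CBE, NGG, window 4–8, 20-nt spacer) and
ABE7.10 (ABE, NGG, window 4–7, 20-nt spacer) — the standard values from the
editors' source publications. They are deliberately config-overridable
(`loadEditors()` with a YAML document): the registry, not the code, is
authoritative, and the YAML schema (`name`, `class`, `pam`, `window`,
`spacer`) rejects unknown keys rather than guessing.

# Evaluating and ranking candidate guides

Editable sites frequently have several feasible guides. Five features are
computed per candidate, with *smaller always better*:

* `same_base_in_window` — bases identical to the editor's target base
  inside the activity window. Every such base is a potential bystander
  edit; the count includes the target itself (a constant +1 that cannot
  affect the ordering, kept so the reported number equals what one counts
  in the sequence).
* `gc_fraction` — GC proportion of the protospacer; higher GC stabilizes
  the RNA–DNA hybrid and tolerates mismatches, promoting off-target
  cutting.
* `repeat_count` — exact occurrences of the protospacer in the genome on
  either strand (≥ 1, including the on-target copy).
* `snp_count` — background SNPs overlapping the protospacer's genomic
  span; a polymorphic protospacer behaves differently across individuals.
* `offtarget_score` — the mean CFD score over all mismatch hits (below).

Within a site, each feature is ranked ascending with ties averaged, each
rank is divided by the number of candidates $m$ at that site, and the five
normalized ranks $r_{(1)} \le \dots \le r_{(5)}$ are aggregated with robust
rank aggregation:

$$\rho = \min_{k = 1..5} \; F_{\mathrm{Beta}(k,\,5-k+1)}\!\left(r_{(k)}\right),$$

the probability that the $k$-th order statistic of five independent
uniforms would fall at or below the observed value. The candidate with the
smallest $\rho$ wins. Scores are used ordinally, so no multiple-testing
correction is applied to the minimum. Exact ties are broken
deterministically: lower `offtarget_score`, then smaller genomic start,
then plus strand.

One consequence of normalizing ranks within the site is worth knowing:
adding or removing a candidate rescales everyone's normalized ranks, and
the Beta-CDF minimum is not order-invariant under that rescaling, so two
near-tied candidates can legitimately swap places when the candidate list
changes. What *is* guaranteed — and what the tests assert — is that a
candidate weakly dominated on all five features never outranks its
dominator, and a candidate ranked last on every list scores $\rho = 1$ and
never wins.

# Off-target scanning and CFD scoring

The genome-wide mismatch search (`findOfftargets()`) returns every locus on
either strand within a mismatch budget of the query protospacer whose
adjacent PAM satisfies the policy. The budget defaults to 4, the
conventional depth for this class of scan, and the PAM policy defaults to
the editor's canonical pattern with an optional relaxed mode adding NAG for
NGG editors; both are exposed as parameters. The on-target locus is
excluded from scoring (scoring it would reward nothing), while exact
duplicates elsewhere are genuine off-targets and are included. The scan is
verified exhaustively in the test suite against a literal all-positions
oracle on genomes of 10–50 kb at budgets 0–4.

Each hit is scored with a CFD-style multiplicative model: the product over
mismatched positions (numbered 1–20 from the PAM-distal end) of a penalty
depending on position, gRNA base and genomic base, times a PAM-variant
penalty; a perfect match with a canonical PAM scores exactly 1. The
penalty table is a first-class object (`CfdTable`): `readCfdTable()` loads
any published coefficient set from TSV, `uniformCfdTable()` builds the flat
table the unit tests use so that scoring arithmetic is checked
independently of any coefficient set, and `defaultCfdTable()` provides a
synthetic, code-generated fallback (penalty $1 - p/21$ at position $p$,
25% activity for single-offset PAM variants, 2% otherwise) whose only
claims are qualitative: seed-proximal mismatches hurt more, non-canonical
PAMs hurt a lot. For publication-grade off-target scores users should load
an empirically fitted table; the ranking machinery is identical either
way. Guides shorter than the 20-nt geometry fall back to
$0.5^{\text{mismatches}}$ with a warning.

# The pleiotropy model

Case-control GWAS effects reported on the observed (linear 0/1) scale
attenuate the allelic substitution effect. `convertBeta()` rescales an
observed effect $\beta_{obs}$ using the study's case proportion $\Phi$ and
reference allele frequency $\theta$:

$$\beta = \beta_{obs}\,D^{-1},\qquad
D = \Phi(1-\Phi) + 0.5\,(1-2\Phi)(1-2\theta)\,\beta_{obs}
  - \bigl(0.084 + 0.9\,\Phi(1-2\Phi)\bigr)\,\theta(1-\theta)\,
    \Phi(1-\Phi)\,\beta_{obs}^2.$$

The grouping of this polynomial is the one that reproduces the standard
small-effect limit $\beta \approx \beta_{obs}/(\Phi(1-\Phi))$, which the
tests verify to $10^{-6}$ relative accuracy across a $(\Phi,\theta)$ grid;
an alternative reading with the trailing $-1$ taken as a subtraction is
kept behind `parse = "offset"` for comparison but does not have that limit
and is not used. When the quadratic term overwhelms the leading one
($D \le 0$) the conversion is undefined; such records raise an error (or
are excluded and counted, in the profiling path).

Per phenotype, an association is a *promotion* if $\beta > 0$ and
$P < \alpha$, an *inhibition* if $\beta < 0$ and $P < \alpha$, otherwise
nonsignificant. $\alpha$ defaults to 0.05 with no multiple-testing
correction — the conventional single-association threshold — and is
configurable. Per SNP, the counts of significant promotions and
inhibitions define the pleiotropy profile; strength bins are fewer than 10,
10–20 (inclusive at both ends), and more than 20 significant phenotypes.
The *weak pleiotropy* screen returns SNPs with at most `maxSignificant`
significant associations (default 1 — at most one phenotype would be
perturbed); the criterion is printed into the output header so every
result is traceable to its rule. QQ diagnostics pair the sorted observed
P values with uniform quantiles $(i - 0.5)/n$ on the $-\log_{10}$ scale.

# The synthetic-data generator

`plantSpec()` / `simulateFixture()` generate the test bed: a uniform-random
genome with planted constructs, a Bernoulli SNP track, and GWAS tables
with planted effects, all driven by one integer seed (identical seed and
spec give byte-identical output; the three sub-generators use fixed seed
offsets so they are individually reproducible).

Planted sites are *rejection-sampled*: a local 51-nt context is drawn
(with outcome-specific biases, e.g. a forced 7-run plus a forced window
PAM for the homopolymer failure, or a GC-saturated background for the GC
failure), then screened by an internal brute-force sliding-window scan,
and accepted only when it produces exactly the intended outcome and
candidate multiplicity; after assembly every site is re-verified against
the full genome. The truth tables are therefore guaranteed by
construction, not assumed. Decoys copy a planted candidate's protospacer
with exactly the requested number of substitutions followed by a concrete
PAM, giving known ground truth for the mismatch scan. GWAS fixtures plant
significant rows at $|\beta_{obs}|$ = 0.3 with $P < \alpha/10$ and null
rows with small zero-centred effects and $P > \alpha$; $\Phi$ is drawn in
(0.2, 0.5) and $\theta$ in (0.2, 0.8), ranges chosen to keep the effect
conversion well-defined and sign-preserving at the planted magnitude, with
131 phenotypes per table mirroring a disease-scale phenome screen.

What the generator does *not* emulate: real genome composition (repeats,
GC isochores, gene structure), linkage disequilibrium among GWAS SNPs,
and winner's-curse effect-size inflation. Passing tests therefore
demonstrate that the algorithms implement their definitions exactly, not
that the five screening criteria capture every determinant of editing
efficiency in real cells.

# Numerical and reporting conventions

* Coordinates are 1-based and inclusive everywhere at the interfaces (VCF
  convention); minus-strand features carry plus-strand spans.
* Percentages are rounded half-up (never to even): 2 decimals for
  feasible-guide category tables, 1 decimal for pleiotropy bins and
  failure tables — the printed-table convention.
* Report TSVs write numerics with the shortest decimal string that parses
  back to the identical double, so read–write–read cycles are bit-exact.
* Zero P values entering QQ computations are clamped to the smallest
  positive double with a warning.
* Zero off-target hits score 0 (the best possible mean CFD).
* Multi-allelic variant records use the first ALT allele.

The test suite runs the exhaustive oracle comparisons on twenty 10–50-kb
genomes at mismatch budgets 0–4, checks RRA against $10^5$ Monte-Carlo
order-statistic draws on 50 rank configurations within three standard
errors, and verifies planted-truth recovery on multiple seeds — sizes
chosen so the whole suite stays in the low tens of seconds while every
code path meets an independent check.

# A worked run

```{r, eval = FALSE}
library(BEscreen)

dir <- tempfile()
runSimulate(outDir = dir, seed = 1)                 # synthetic study
res <- runDesign(
  genomePath = file.path(dir, "genome.fa"),
  sitesPath  = file.path(dir, "sites.tsv"),
  editorName = "BE3",
  snpsPath   = file.path(dir, "snps.vcf"),
  outDir     = file.path(dir, "design"))
res$report[res$report$is_best %in% TRUE,
           c("site_id", "protospacer", "pam", "rra_score")]

pleio <- runPleiotropy(file.path(dir, "gwas"),
                       outDir = file.path(dir, "pleio"))
pleio$bins
```

# Known limitations

* RNA-level off-target effects and DNA/RNA-bulge off-targets are out of
  scope; the scan models substitutions only.
* The default CFD table is a synthetic heuristic (see above); load a
  fitted coefficient table for absolute off-target probabilities.
* Editing-efficiency prediction of the machine-learning kind is not
  attempted; the five features are interpretable screening criteria, not a
  calibrated efficiency model.
* Winner selection can change when the candidate list at a site changes
  (the rank-renormalization effect described earlier); within a fixed
  candidate list, selection is fully deterministic.
* Pleiotropy profiling requires $\Phi$ and $\theta$ as inputs; it does not
  estimate them from genotype data.
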