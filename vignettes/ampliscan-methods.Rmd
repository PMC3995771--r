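---
title: "Designing and evaluating degenerate SSU rRNA primers with ampliscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating degenerate SSU rRNA primers with ampliscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliscan)
```

## The problem

Amplicon surveys of microbial eukaryotes sequence a short stretch of the
18S rRNA gene and assign taxonomy by comparing reads against a reference
database. Two design questions decide how much information such a survey
retains: *where* the primers sit (they must be conserved enough to amplify
most taxa, yet flank enough variable sequence to tell taxa apart) and *how
degenerate* they are (an IUPAC primer is a mixture of concrete oligomers;
more degeneracy buys coverage at the cost of PCR behavior). `ampliscan`
implements the full design-and-evaluation loop: degenerate primer search on
a taxonomically annotated alignment, primer arithmetic, in-silico
amplification and read simulation, and a taxonomic-assignment benchmark —
plus a synthetic reference-database generator so that every stage can be
validated against known ground truth without downloading a curated SSU
database.

## Maximum-coverage degenerate oligomer search

The design primitive is: for a window of `L` alignment columns, find an
IUPAC oligomer of degeneracy at most `D` (the product of per-position code
set sizes) matching as many database sequences as possible. A sequence is
matched when, at every offset, its concrete base lies in the oligomer's
set; sequences with a gap or an ambiguity code inside the window are
excluded outright, since scoring a primer against an ambiguous template
would inflate coverage.

The search exploits a structural fact: for any oligomer, the per-position
union of the variants it covers has degeneracy no larger than the
oligomer's own. An optimal solution is therefore always the union of some
subset of the observed window variants, and enumerating variant subsets is
an exhaustive search. `best_degenerate_oligo()` runs this enumeration as a
depth-first search with degeneracy pruning whenever the window has at most
`exact_max_variants` (default 12) distinct variants — windows in conserved
regions, which are the ones that matter for primer picking, are almost
always in this regime, so the reported oligomer there is the exact
maximizer. Larger (variable-region) tables fall back to a greedy merge:
seed with the most frequent variant, repeatedly merge the variant with the
largest coverage gain that keeps the degeneracy within bound, and re-score
against all variants at the end so that a merged oligomer also absorbs
variants it was never explicitly merged with. Ties are broken by lower
degeneracy, then lexicographic order, which keeps every run reproducible.
The test suite checks the search against an independent flat
subset-enumeration oracle on hundreds of randomized small windows.

Defaults follow standard practice for broad-range SSU primers: window
length 18, maximum degeneracy 12, and alignment trimming to columns with at
least 90% non-gap coverage before scanning (`trim_alignment()` records the
original column indices so window positions remain mappable, and
`build_reference_map()` converts them to the ungapped coordinates of a
named reference such as the *S. cerevisiae* 18S gene).

## Primer arithmetic

`gc_range()` and `tm_range()` report the extremes over all concrete
expansions. The melting temperature uses the basic GC-count formula

$$T_m = 64.9 + 41\,(n_{GC} - 16.4)/N,$$

which is monotone in the GC count, so only the extreme counts need
evaluating; results are rounded to one decimal (GC to integer percent).
This formula is conventionally valid from 14 bases up, and shorter input is
rejected rather than extrapolated. Nearest-neighbor thermodynamics,
dimer/hairpin screening and multiplex design are out of scope.
`reverse_complement()` complements code-wise (R↔Y, K↔M, S and W
self-complementary, B↔V, D↔H), and `trim_terminal_n()` supports the common
post-processing step of dropping a terminal N position that a
maximum-coverage search can legitimately emit.

Two printed rows of the published 18S primer panel are internally
inconsistent with their own sequences (one GC maximum, and one row whose GC
and Tm minima appear swapped); exhaustive expansion cannot reproduce them,
and the package intentionally reports the recomputed values for those rows
rather than forcing agreement.

## Matching, coverage and binding sites

`matches_at()` uses strict set containment: a template base matches only if
its entire IUPAC set is contained in the primer's set at that position, so
a template `N` (an uncalled base) never satisfies a non-`N` primer
position. This is the conservative choice for low-quality database entries;
whether published match counts tolerated template ambiguity is generally
unstated, so the rule is documented rather than asserted as anyone else's.
Coverage (`coverage_by_taxon()`) counts full-length, zero-mismatch,
forward-strand matches only — SSU reference databases are
orientation-normalized, and both-strand search is an explicit flag on
`find_binding_sites()`.

## Read simulation and the unique-amplicon ratio

`simulate_amplicons()` produces error-free reads: the amplicon runs from
the 5' end of the forward primer footprint to the 3'-most template base of
the reverse footprint, inclusive, and reads include the primer-covered
template. For paired layouts, when the amplicon is shorter than twice the
read length the overlapping reads are merged — with no error model the
merge reconstitutes the template amplicon exactly — and otherwise the
forward and reverse reads are concatenated to form the comparison key.
When a record carries several binding sites, the 5'-most forward and
3'-most reverse sites are used (the dominant PCR product) and the
multiplicity is logged. Sequencing error, chimeras and PCR bias are
deliberately not modeled: downstream denoising/OTU clustering suppresses
them in practice, and the quantity of interest is the information ceiling
of a primer pair and layout.

`unique_ratio()` divides the number of distinct fused read sequences by the
number of distinct near-full-length sequences over a reference-coordinate
region among the same records. It is non-decreasing in read length
(extending error-free reads can only separate more sequences), which the
property suite asserts.

## The assignment benchmark

`run_benchmark()` samples query records (fully annotated, matched by both
primers), simulates their reads, and searches them against the whole
database with the query's own record excluded (leave-self-out). The search
engine is internal and self-contained: an 11-mer prefilter proposes
candidate subjects, and candidates are scored by gapped local alignment
with blastn-like constants (match +2, mismatch −3, gap open 5, extend 2),
with e-values from the Karlin–Altschul form `E = m·n·2^(−bitscore)` using
the published gapped constants for this scoring scheme (λ = 0.625,
K = 0.41). These constants are a documented stand-in, not a claim of
bit-compatibility with any external tool; only rankings matter here.
A hit must cover at least 95% of each read's length at the configured
identity (99% by default, 95% as the relaxed variant) with e-value below
10⁻⁵ — each read of a pair must pass individually. Pairs are ranked by the
arithmetic mean of per-read log₁₀ e-values (base 10 is a convention; the
base does not affect ranking). Reads are aligned strand-aware: the strand
is resolved per read, trying the reverse complement when no subject passes
as given, which is exact for orientation-normalized databases and halves
the alignment work.

Agreement is stratified positionally on the root-to-leaf taxonomy path:
`species` (full path equal), `genus` (equal through the second-to-last
rank), `above_genus` (equal through the rank immediately above genus,
whatever that rank is called), else `misassigned`; hits not annotated to at
least family depth (two ranks above species) are excluded from the
accuracy table, mirroring how such benchmarks are reported. Accuracy
fractions are computed among the assessed assignments, with cumulative
values at species → genus → above-genus.

`full_length_distance()` compares the original gapped alignment rows of
query and hit with one-gap conventions: terminal gaps disregarded, both-gap
columns skipped (and transparent to runs), and each maximal run of columns
gapped in exactly one sequence counted as a single difference and a single
compared unit. The measure is symmetric with zero self-distance; the
triangle inequality is *not* guaranteed under run-collapsing and is not
asserted anywhere.

## The synthetic generator

`generate_synthetic_db()` emulates the structure that makes SSU alignments
designable: alternating conserved and variable blocks, a taxonomy tree with
fixed fan-outs, substitutions and indels concentrated in variable blocks,
and optionally planted primer-site motifs. A root sequence is evolved down
the tree; every block carries a quota of reserved columns (15% by default)
that are gaps in the root, insertion events fill a run of reserved columns
for one lineage, and deletions gap out real columns — so all records share
one master gapped coordinate system without re-alignment. Substitutions are
uniform (Jukes–Cantor-style) replacements and indel lengths geometric with
mean 2: the simplest model that exercises gap handling; no claim of
biological realism (no secondary structure, no real V-region boundaries,
no rate heterogeneity within blocks). Planted motifs are overwritten after
evolution with one concrete expansion sampled per record, which makes
degenerate-consensus recovery nontrivial for the scanner — and also means
planted-site variation is independent of phylogeny, unlike real primer-site
alleles; fixtures that need tight within-species identity therefore plant
low-degeneracy motifs.

Branch lengths can be shaped per tree level through `rank_scale`, one
multiplier per rank plus a final one for records within a species. This
knob exists because a single per-branch rate cannot simultaneously give the
deep divergence (between-genus distances above 5%) and shallow tightness
(within-species below 0.5%) that a realistic assignment benchmark needs.
Taxonomy labels are synthetic (`k1;p2;…;s5`-style, using the trailing ranks
for shallow trees) so rank-depth logic is testable without real names.

What passing tests on synthetic data do and do not show: they demonstrate
that the search recovers planted consensus sites exactly, that the
benchmark recovers genus structure when genera are well separated, and that
the pipeline's invariants hold — they do not reproduce database-scale
published figures (coverage percentages in the 82–93% range, unique-read
ratios of 51–78%, ~75–79% genus accuracy), which depend on the full curated
SSU Ref NR database and its very uneven taxon sampling. The package
supports rerunning those numbers on a user-supplied reference alignment in
the same dialect as an optional workflow.

## Problem sizes and numerical choices

The shipped test and acceptance fixtures are sized for quick, deterministic
runs, chosen as representative miniatures: the planted-site recovery
database uses 5 × 4 × 5 taxa with 3 records per species (300 records,
~500 columns); the assignment benchmark uses 3 × 3 × 3 taxa with 3 records
per species (81 records, ~1200 columns) and 30 queries per layout at
2×150, 2×250 and 1×400. Entropy is reported in bits (range [0, 2] over
A/C/G/T), with gaps and ambiguity codes excluded from the frequency counts
and `NA` for columns with no countable base. All coordinates are 1-based
closed intervals; `-` and `.` are interchangeable gap characters; `U` is
normalized to `T` on input. Every stochastic step (generation, query
sampling) is governed by a single integer seed and reruns are
byte-identical.

## Known limitations

* The greedy large-table search path is a heuristic; only the
  small-table regime is provably exact (and is what primer picking uses).
* E-values are internally consistent but not calibrated to any external
  search tool; identity is computed over aligned columns of the local
  alignment, which can differ slightly from other tools' conventions.
* Coverage counting is strict (no mismatch tolerance, template ambiguity
  never matches a narrower primer code), which may undercount relative to
  more permissive conventions.
* The synthetic generator's iid planted-site expansions overstate
  primer-site variability within species; interpret identity-threshold
  effects near planted sites accordingly.
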