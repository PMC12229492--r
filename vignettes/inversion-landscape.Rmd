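---
title: "Classifying inversion-gene intersections across population callsets: methods and design"
author: "inversionscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying inversion-gene intersections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inversionscape)
```

# The analysis in one paragraph

An inversion is a balanced rearrangement delimited by two breakpoint
junctions. Its clinical relevance, when it has any, usually comes from where
those two junctions land relative to protein-coding genes: a junction inside
a gene can truncate or rearrange it, while a gene wholly contained in an
inversion keeps its coding sequence intact (though long-range regulatory
effects remain possible). `inversionscape` harmonizes inversion callsets
from heterogeneous sources into one container, classifies every
inversion-gene intersection by breakpoint placement, stratifies calls by
population allele frequency, walks a recessive-disease candidate cascade,
and quantifies how much two callsets agree about which inversions exist.

# Coordinates

All readers translate their dialect at the boundary: VCF records anchor POS
at the first inverted base by default (`posAnchor = "preceding_base"` covers
producers that anchor one base earlier), with INFO `END` the 1-based
inclusive last base and `SVLEN` the fallback; DGV-style tables are 1-based
inclusive; BED is 0-based half-open. Internally calls live in a `GRanges`,
the Bioconductor convention (1-based, closed). The half-open 0-based view
that SV browsers print is available as `start0()`/`end0()`, and the
identity `width == end0 - start0` means every overlap computation is the
same arithmetic under either convention. Keeping the container native to
GenomicRanges was a deliberate trade: one internal convention, conversions
confined to readers and writers, and full interoperability with the
Bioconductor range machinery instead of a parallel bespoke interval type.

Records on contigs other than chr1-chr22, chrX, chrY are dropped and
counted; exact duplicate (chrom, start, end) records within one callset are
collapsed to one, because downstream redundancy analysis assumes set
semantics. Filter counters always partition the input, which the tests
assert.

# The three-way classification

Breakpoints are operationalized as the **first and last inverted base**, not
the flanking junction positions — junction-anchored definitions differ by
one base, and this choice makes the category definitions coincide exactly
with containment relations. A breakpoint is *within* a gene when it lies on
any base of the gene span, boundaries included (a deterministic edge
policy). For each (inversion, gene) pair with at least one shared base:

- 2 breakpoints in the gene → **intragenic** (inversion ⊆ gene),
- 1 breakpoint in the gene → **gene-disrupting**,
- 0 breakpoints in the gene → **gene-spanning** (gene ⊆ inversion; under
  half-open geometry a positive overlap with both breakpoints outside can
  only mean containment).

The trichotomy is exhaustive and mutually exclusive, so per-dataset category
counts conserve the number of overlapping pairs. Pairs are judged per gene:
an inversion with breakpoints in two different genes yields two
gene-disrupting records, and an inversion intragenic in gene A may be
spanning or disrupting for an overlapping gene B.

For intragenic events the exon/intron context uses the canonical
transcript's blocks: the single-intron flag is true iff the whole inversion
sits inside one intron, and disrupted intron ordinals are reported 5′→3′ in
transcription orientation (strand-aware), matching the "intron 30 of gene X"
style of clinical reporting, while the geometry itself is strand-agnostic.

# Fractional overlap

Cross-dataset matching uses the directional fraction semantics of the
classic intersection tools: inversion *x* in dataset A matches dataset B iff
some *y* in B overlaps at least `f` of *x*'s length (default `f = 0.5`).
Directionality matters — a 1 kb call inside a 100 kb call matches in one
direction only — and is what makes redundancy percentages asymmetric between
a short-read and a long-read callset. The boundary is inclusive (overlap
equal to `f·len` passes) and evaluated as `overlap * den >= num * len` after
replacing `f` by its best rational approximation with denominator ≤ 10^6,
so boundary cases are bit-stable and never at the mercy of floating-point
rounding. A reciprocal mode (`reciprocal = TRUE`) is available behind a
flag; the directional form is the default because it is the semantics of
the `-f` option of the standard tool. Exact matching (identical
chrom/start/end) is always a subset of fractional matching, an invariant the
tests assert.

# Frequency stratification and the candidate cascade

The rare/common boundary is allele frequency 0.05, with AF exactly at the
threshold classed **common** (the "≥ 5%" convention). Calls with missing AF
form an explicit *unknown* stratum and are excluded from the rare/common
denominator rather than silently assumed rare. The candidate cascade is
pair-based — (i) gene-disrupting or intragenic, (ii) OMIM phenotype-linked
gene, (iii) rare — then flags never-homozygous calls (`n_homalt == 0`;
missing counts flag the row unknown and keep it) and finally requires the AR
inheritance mode. The funnel reports distinct-inversion and distinct-gene
counts alongside pair counts at each stage because the quantities of
interest mix granularities ("N inversions affect M genes"); all three are
monotone non-increasing.

Genes carrying several OMIM phenotypes with different inheritance modes get
the **union** of modes; in mode distributions a gene with k modes counts
once per mode, while "AR disease genes" counts each gene once (a gene is an
AR gene iff AR is among its modes). This is a documented choice — the
most permissive one — since gene-level inheritance summaries can reasonably
be defined either way.

# Statistics

- **Quartiles** use linear interpolation between order statistics (type 7,
  the default of most statistical environments); type 6 is available behind
  a flag because quartile values are definition-dependent.
- **Wilcoxon rank-sum** enumerates the exact Mann-Whitney null by dynamic
  programming when `n·m ≤ 10000` and the pooled sample is tie-free;
  otherwise a tie-corrected normal approximation with continuity correction.
  Two-sided p is twice the smaller tail, capped at 1.
- **Binomial** two-sided p uses the small-P method (sum of outcome
  probabilities not exceeding the observed one, with a 1e-7 relative guard
  against floating-point equality); central and one-sided alternatives sit
  behind flags. One- versus two-sidedness of published test labels is
  ambiguous in general, so the common two-sided default was chosen and
  documented.
- **Over-representation** is the hypergeometric upper tail per gene set with
  Benjamini-Hochberg step-up across sets (own implementation; monotone along
  sorted p-values by construction).

The test suite pins each of these to independent oracles: full `combn`
enumeration for the Wilcoxon, closed-form hand computations for binomial and
Fisher, and the stock R implementations as cross-checks.

# The synthetic-data generator

The generator exists so that every pipeline stage can be exercised, with
known truth, on a laptop in seconds. It emulates:

- **Gene architecture**: non-overlapping canonical-transcript genes with
  2-10 exons of 100-300 bp, log-normal intron lengths (median 2 kb),
  intergenic gaps of 10-50 kb — enough structure for every classification
  and intron-context case to arise, at reduced genomic scale.
- **Length structure**: a split (two-piece) log-normal on bp. Real callset
  length distributions are asymmetric *even on the log scale* — for the
  short-read population profile the median/Q1 ratio is ~7.9 while Q3/median
  is ~3.3 — so no single-σ log-normal can reproduce all three quartiles:
  quantile-matching σ to the interquartile spread leaves Q1 and Q3 both off
  by >50%. The split form (scale σ_lo below the median, σ_hi above)
  reproduces median, Q1 and Q3 exactly in expectation, degenerates to the
  ordinary log-normal when the scales are equal, and keeps log-normal
  tails, so means stay far above medians as in real data. The shipped
  `gnomadLikeProfile()` is calibrated to median 7.12 kb, Q1 0.896 kb,
  Q3 23.63 kb.
- **Allele-frequency structure**: a mixture with 98.9% of calls uniform on
  [1e-5, 0.05) and the rest uniform on [0.05, 0.5]; 254/279 of calls are
  never-homozygous by default.
- **Planted truth**: quota-planted inversions are *constructed* to realize
  their category — both breakpoints in a gene's intergenic flanks
  (spanning), one inside and one in the right flank (disrupting), first and
  last exon (intragenic), or inside the widest intron (single-intron) — so
  recovery by the classifier is a sharp 100%-accuracy test, not a
  statistical one. Infeasible quotas fail loudly naming the quota.

What the generator does **not** emulate: breakpoint micro-homology and
repeat context, overlapping genes, clustered or recurrent breakpoints,
population structure in AF, and any sequence-level signal. Passing tests
therefore demonstrate the correctness of the interval logic and bookkeeping
on realistic marginals, not robustness to every property of real callsets.
The OMIM-status mix (30/50/20) and inheritance mix (AR 45%, AD 30%, XLR 5%,
XLD 2%, other 18%) are synthetic defaults chosen to be plausible and fully
configurable; they are not estimates of the real OMIM composition.

Determinism: each generator takes a single seed and identical seeds give
byte-identical outputs end to end, which the tests assert via emitted
tables.

# Numerical and degenerate-input policies

- Empty callsets: readers return a valid empty `InversionCallset`; length
  summaries on empty callsets are hard errors (there is nothing to
  summarize), as are category distributions on zero records.
- Degenerate tests (all values identical, zero variance under ties) return
  p = 1 with a warning rather than NaN.
- Symbol-to-gene ambiguity in annotation joins records a warning and
  resolves first-by-sorted-id, so runs are reproducible.
- Coordinate sanity (end > start, AF in [0,1], non-negative homozygote
  counts, sortedness, id uniqueness) is enforced by S4 validity, not by
  convention.

# Problem sizes

The shipped tests run the oracle-equivalence suites on ~25,000 random
query-subject pairs, classification on synthetic universes of 60-150 genes
and 150-600 calls, and calibration at n = 10,000 generated lengths — sizes
chosen so the whole suite completes in about a minute on one CPU while
leaving the statistical checks well-powered.

# Limitations

The package classifies by positional breakpoint placement only: no splicing
prediction, no regulatory or TAD-level effect modelling, no liftOver between
builds, no SV calling or breakpoint refinement, and no one-to-one event
matching across datasets (matching is existential by design). Inversions
part of complex rearrangements are treated as their reported interval.
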