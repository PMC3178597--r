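---
title: "Methods: barcode-gap evaluation with MycoBarcode"
author: "MycoBarcode authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-gap evaluation with MycoBarcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MycoBarcode)
```

## The analysis in one paragraph

A DNA barcode locus works when conspecific sequences are much closer than
heterospecific ones. MycoBarcode quantifies this for fungal candidate loci
(ITS, COI) without ever relying on a global multiple alignment: sequences
are first clustered into *alignment groups* — sets mutually alignable at
80% or better identity over at least 100 bp — and all distance computation
happens inside groups, where homology assessment is unambiguous. Within
each group the package aligns, computes K2P-corrected pairwise distances,
and summarizes, per species, the maximum intra-specific and minimum
inter-specific divergence. Species whose nearest non-conspecific lies
beyond the clustering cutoff get their inter-specific divergence *capped*
rather than guessed. Loci are then compared by their gap ratios.

## Preprocessing

**ITS trimming.** Complete ITS amplicons are trimmed to begin with the
first occurrence of the conserved motif `CATTA` (3' terminus of the SSU
gene) and end with the last occurrence of `GACCT` (5' terminus of the
LSU), motifs included. Taking the *first* start and *last* end occurrence
makes the operation idempotent and keeps the full ITS region when the
short motifs recur internally by chance. Missing motifs and an end motif
preceding the start motif are distinct errors — truncated amplicons should
fail loudly, not silently shrink.

**5.8S excision.** The ~120 bp 5.8S gene between ITS1 and ITS2 is nearly
invariant across mushrooms; leaving it in place inflates apparent
similarity between otherwise unalignable ITS sequences and drags unrelated
sequences over the clustering threshold. `excise58S()` concatenates
positions `1..its1_end` and `its2_start..length`. Coordinates are supplied
per record (annotation-driven, e.g. from GenBank features); the package
deliberately ships no 5.8S sequence model — a wrong silent model is worse
than an explicit locator table. All coordinates everywhere in the package
are 1-based, fully closed.

**Intron localization.** Fungal COI exons are interrupted by large
(~100-3000 bp) self-splicing introns at unpredictable positions.
`detectIntrons()` compares a query against an intron-free reference exon by
anchor-and-chain: every exact 12-mer shared by query and reference is an
anchor; the maximum-cardinality chain strictly increasing in both
coordinates is selected (ties resolved toward the leftmost reference
coordinate, so calls are deterministic); every inter-anchor stretch of at
least `min_intron_len = 50` extra query bases becomes a call. The call
position is the reference base immediately 5' of the insertion (0 for an
insertion before the first anchored base), matching the convention of
reporting intron sites as points on the exon. The 12-mer default balances
two failure modes: shorter anchors hit by chance in a ~450 bp exon
(expected chance hits scale with `L_ref * L_query / 4^k`), longer ones
break under the ~5% query-reference divergence typical between a specimen
and a database reference. Insertions whose content happens to share an
exact 12-mer with the reference, or whose first bases repeat the
downstream reference, admit several equally valid placements; the package
reports one deterministically, and the test constructions exclude such
coincidences so the expected answer is unique.

**Primers.** `mapPrimer()` matches IUPAC-degenerate primers permissively
(a primer symbol matches a template symbol when their IUPAC classes
intersect), forward primers on the plus strand and reverse primers as
their reverse complement. `primerDegeneracy()` is the product of class
sizes; `predictAmplicon()` includes both primers in the product length.
The packaged COI panel records each primer's 5' start coordinate on a
reference exon; note that published amplicon sizes for such panels rarely
reconcile exactly with any single coordinate convention, so predicted
lengths are reported under the stated convention and not treated as
ground truth.

## Pairwise alignment and identity

The clustering step needs a contig-assembly-style notion of percent
identity. `alignPair()` is a linear-gap Needleman-Wunsch (match +1,
mismatch -1, gap -2) with an *overlap* mode in which terminal gap runs are
free. Identity is the fraction of matching columns within the
doubly-occupied overlap region: terminal overhangs are excluded from the
denominator, internal gaps count against identity, and degenerate symbols
match only when identical. Design choices, all of which are invisible at
the 80%/100 bp resolution the clustering operates at but need fixing for
reproducibility:

- *Linear rather than affine gaps.* Affine penalties would add a parameter
  with no effect on a coarse threshold decision.
- *Gaps count as mismatches in identity.* Whether assembly software counts
  internal gaps is undocumented; this package documents its choice rather
  than guessing another tool's.
- *Deterministic traceback.* Ties prefer diagonal, then a gap in the
  second sequence, then the first; the overlap end-cell prefers the
  corner. Equal-scoring alignments therefore resolve identically on every
  run.

One behavior worth knowing: a contiguous block of substitutions can be
"gapped around" by the optimal alignment, yielding a higher identity than
the nominal substitution fraction. This is correct optimization, not a
defect, but it means synthetic benchmarks should scatter their
substitutions.

`progressiveMSA()` merges profiles along a neighbor-joining guide tree
built from pairwise identity distances (1 - identity). Profile-profile
scoring is the mean pairwise residue score between columns (existing gaps
score 0); inserting a gap column costs the flat per-base penalty. There is
no iterative refinement: within alignment groups (>= 80% identity by
construction) progressive alignment is already near-exact, and for
substitution-only inputs it is provably gapless.

## Alignment groups

`buildGroups()` processes sequences one at a time; each sequence joins the
existing group containing its best-identity member among those meeting
both thresholds (`min_identity = 0.80`, `min_overlap = 100` bases), or
founds a new group. This is single linkage within a greedy pass: joining
by best single member is reproducible and testable, unlike joining against
a proprietary rolling consensus. Exact identity ties go to the
earlier-created group (documented, arbitrary). Greedy assembly is
order-dependent in principle — a sequence 80%-similar to two groups lands
in whichever existed when it arrived — so the default *canonical* order
(descending length, ties by id) makes the result a pure function of the
input set, while `order_policy = "input"` plus
`groupingOrderSensitivity()` exposes the order-dependence for study.

## Distances, capping, trees

`k2pDistance()` counts transitions (A-G, C-T) and transversions over
comparable sites and applies
`d = -0.5 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]`. Under the default *pairwise
deletion*, a site is comparable when both sequences carry an unambiguous
A/C/G/T; *complete deletion* (dropping columns with a gap or ambiguity in
any row) is available where a common site set across all pairs matters
more than per-pair power. When the logarithm's argument is non-positive
(substitution saturation) the distance is **undefined** and stays `NA` in
the matrix — it is never silently replaced. Downstream, undefined
inter-specific distances are capped like any divergence beyond the
threshold.

**The capping rule.** Divergences above `cap_threshold = 0.20` are
recorded as `cap_value = 0.21` — a minimum estimate. The rationale: pairs
beyond the 20% clustering cutoff fall into different alignment groups, so
their divergence was never actually measured; 0.21 says "more than 20%"
without pretending precision. The rule is strictly-greater (0.20 passes
unchanged), idempotent, and monotone. Capped entries enter means and
medians at 0.21 but are excluded from "lowest minimum inter-specific
divergence" extremes, which must come from measured values.

`njTree()` is plain Saitou-Nei neighbor joining with the standard
Q-criterion, chosen over variance-weighted variants because on the
near-additive, low-divergence matrices that arise inside alignment groups
the two are topologically equivalent, and plain NJ recovers additive
matrices exactly (the test suite checks recovery of random additive trees
to RF distance 0 and path distances within 1e-9). Negative estimated
branch lengths are clamped to zero. Q-ties are broken by the
lexicographically smallest joined pair of taxon labels — a deterministic
replacement for random tie-breaking, so identical inputs give identical
trees. `speciesMonophyly()` asks, per species, whether some edge of the
unrooted tree separates exactly that species' leaves.

## Per-species statistics and locus comparison

`speciesStats()` computes, per species: intra-specific max/mean/median
over conspecific pairs co-resident in a group (`NA` when fewer than two
conspecifics share a group), and the minimum distance to any
heterospecific sequence in the same group, capped. The nearest neighbor is
the species attaining that minimum — a distance-based reading of "sister
taxon" that needs no tree reconciliation; the NJ tree is written alongside
for inspection. Conspecific pairs split across groups are simply not
compared: cross-group distances are undefined by construction. A species
alone in its group gets a capped inter-specific divergence and no
neighbor.

`compareLoci()` reports both ratio orientations: intra:inter (smaller is
better; the locus with the strictly smaller ratio "wins", equal ratios
tie) and inter:intra (the barcode-gap criterion, pass when > 1). Both are
reported because the two orientations answer different questions and
published tables have mixed them; the pass criterion used throughout is
inter:intra > 1. Note the least-ratio rule is dominated by zero
intra-specific divergences (ratio 0): with many species showing zero
intra-specific variation at one locus, the mechanical winner count says
little, while the gap criterion remains informative.

## The packaged divergence table

`inst/extdata/published_divergences.tsv` transcribes a published 38-row
comparison of per-species maximum intra-specific and minimum
inter-specific K2P divergences at COI and ITS. Dash cells (inter-specific
divergence beyond the 20% cutoff, never measured) are encoded `CAPPED`;
`N.A.` marks rows whose sequences span different species, so intra-specific
divergence is undefined. A `source_better` column records which locus the
source highlighted per row, and a free-text `flags` column carries its
footnotes; neither affects computation. Loading is validated (proportions
in [0,1], `CAPPED` legal only in inter columns) and exact: summary
extremes computed from the fixture are reproduced to the printed four
decimals by the test suite and the acceptance script.

## What the simulator emulates — and what it does not

`simulateSpeciesDataset()` generates the statistical structure the
analysis assumes: species-level clusters with intra-specific divergence of
order 0-2% separated by inter-specific divergences of order 2-25%. It uses
a star phylogeny at both levels — a uniform-random root, one Jukes-Cantor
branch of `(inter_div - intra_div) / 2` expected substitutions per site to
each species ancestor, one branch of `intra_div / 2` to each sequence —
so that the *expected tip-to-tip path* is exactly `intra_div` within
species and `inter_div` between, which is what K2P estimates. Optional
single-base indels (insertions and deletions equally likely) at
`indel_rate` per site exercise the alignment path. Defaults: 600 bp
(ITS-scale amplicons), `intra_div = 0.01`, `inter_div = 0.10` — mid-range
values for fungal ITS variation.

What it does *not* emulate: coalescent genealogies within species (a star
is the simplest shape exhibiting a barcode gap), rate variation across
sites or lineages, transition/transversion bias (substitutions are JC;
K2P estimation on JC data remains valid), length-variable tandem repeats,
or sequencing error. Passing tests on simulated data therefore show the
pipeline recovers planted structure under its own model assumptions, not
that real ITS data are this well behaved. One relevant measured effect:
the alignment path slightly compresses divergence (gap columns adjacent to
indels exclude divergent sites under pairwise deletion), so pipeline
estimates of `inter_div` run a few percent below the generator's nominal
value — within the tolerance of the calibration checks, but visible.

`perturbSequence()` implements the dummy-sequence experiment: divergence
is metered as edit operations relative to base length (the published
description leaves the metric undefined; operation counts are testable).
`GAPS_EVEN` generalizes "an extra base every 8th position" to spacing
`ceiling(1 / divergence)`, so the whole 1-20% grid is well defined.
`robustnessExperiment()` appends one dummy at a time, re-clusters, and
reports co-clustering. Only the arithmetically forced successes are
asserted (substitution dummies at <= 19% divergence retain >= 81%
identity, above the 80% threshold); failure modes of gap-heavy dummies are
reported, not asserted, because they are properties of the specific greedy
algorithm, not of clustering in general.

## Numerical and scale choices

- Alignment kernels (pairwise DP, profile merge, anchor chaining) are in
  C++; everything else is R.
- Exact-equality traceback is safe because cell values are reproduced by
  the same floating-point additions that created them.
- NJ tie detection uses an absolute 1e-12 window on the Q-criterion.
- The validation suite uses problem sizes chosen to make the checks sharp
  but quick: 500 random 600 bp pairs against the per-site K2P oracle
  (tolerance 1e-12), 100 random additive trees with 4-10 leaves (branch
  lengths to 1e-9), 200 random pairs up to length 8 against exhaustive
  alignment enumeration, 100 constructed intron queries with 1-3
  insertions of 100-2000 bp, a 6-species x 3-sequence recovery experiment
  over 20 seeds (`intra_div = 0.005`, `inter_div = 0.08`,
  `indel_rate = 0.001`), and the full 4-mode x 20-level perturbation grid.
- Degenerate inputs fail explicitly: empty sequences, ragged alignments,
  unlabeled leaves, undefined distances at tree-building, inverted
  excision coordinates, overlapping intron calls.

## Known limitations

- Greedy single-linkage grouping is a reproducible stand-in for
  proprietary contig assembly, not a clone of it; agreement on real data
  is an empirical question the order-sensitivity tool can probe.
- Distance-based nearest neighbors can differ from tree-based sister taxa
  when several species are nearly equidistant.
- The progressive aligner has no refinement pass; outside the >= 80%
  identity regime it is not a general-purpose MSA tool.
- K2P is the field's convention for barcode work and is kept for
  comparability, despite its known downward bias under rate variation.
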