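---
title: "Simulating and phasing Targeted Locus Amplification sequencing"
author: "tlaphaser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and phasing Targeted Locus Amplification sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tlaphaser)
```

## The method in brief

Targeted Locus Amplification (TLA) enriches a whole locus by exploiting
physical proximity: crosslinked chromatin is digested with NlaIII
(recognition sequence CATG), re-ligated at low concentration into
circular chimeric molecules, and amplified by inverse PCR from a primer
pair inside one restriction fragment, the *viewpoint*. Two properties
make the data informative for haplotyping:

1. every amplified circle contains the viewpoint fragment, plus other
   fragments of the locus with a frequency that decays with genomic
   distance from the viewpoint;
2. homologous chromosomes occupy distinct territories, so each circle is
   built from fragments of a *single* haplotype.

Sequencing the amplicons therefore yields chimeric reads whose segments
are scattered over the locus but phase-consistent. The analysis has to
undo the chimerism (split reads at ligation junctions and map the
pieces), call variants from the resulting fragment pileup under a depth
filter, and then turn per-molecule allele co-occurrence into haplotype
blocks. `tlaphaser` implements each of these stages natively, plus a
simulator that generates the data with known truth, so every stage can
be validated end to end.

## The simulator: what it models

**Digestion.** `digest()` cuts immediately *after* each CATG
(`cut_offset = 4`), so every fragment retains CATG at its 3' end,
matching the enzyme's 3' overhang. The orientation of this convention is
a free choice — splitting and simulation only need to share it — and the
mapper mirrors it to "before CATG" for reverse-complemented reads, since
the motif is palindromic. NspI (RCATGY, used in the wet protocol to
promote circularisation) is supported as an IUPAC motif but is otherwise
modelled only through the amplicon length bounds below.

**Contact model.** Fragments join a circle with probability proportional
to $(1+d)^{-\alpha}$, where $d$ is the ordinal fragment distance from
the viewpoint and $\alpha = 1$ by default. The study system motivates
only the qualitative statement that coverage is highest at the viewpoint
and drops quickly; a power law is the standard proximity-ligation
contact model, and $\alpha$ is exposed in `contactModel()`. The number
of non-viewpoint fragments per circle is shifted-geometric with mean 3,
truncated by the amplicon length bounds of 4–10 kb (TLA-PCR amplicons
are typically in this range). Draws violating the bounds are rejected
and resampled; if no admissible circle exists the simulator raises an
error suggesting the bounds be adjusted. Fragment order within a circle
is a uniform random permutation and orientation is kept collinear —
ligation-junction orientation statistics are not characterised for this
protocol, and collinearity keeps the split-mapping oracle exact; an
inversion flag is a natural future extension.

**Amplicons and reads.** Each circle containing the viewpoint yields one
amplicon: the circle rotated so position zero is the forward primer
(default 40 bp into the viewpoint fragment, so that the rotated "head"
piece is itself long enough to map). Short mode draws insert windows of
300–700 bp (amplicons weighted by length, as tagmentation would) and
emits 150 bp mate pairs with substitution errors at $10^{-3}$ per base —
an Illumina-like rate. Long mode draws whole amplicons with weight
$\mathrm{length}^{-\beta}$, $\beta = 1$ (long-read platforms
preferentially sequence shorter molecules), and applies 2% substitution
plus 1% indel errors per base, a deliberately conservative
long-read error profile. Qualities are constant per platform (Q30/Q12);
quality-aware trimming is out of scope, and the mapper's minimum
segment length of 15 bp plays the role that a read-length floor plays
in real pipelines. PCR duplicates are implicit in sampling circles with
replacement; no deduplication stage exists, matching the analysed
protocol. Every read carries base-level provenance (circle, haplotype,
reference intervals per segment), which the test suite uses as ground
truth.

## The split mapper

External aligners are replaced by a native seed-and-extend engine so the
pipeline is self-contained and its behaviour fully testable. A k-mer
index (k = 21) over all references — including any pseudogene decoys —
seeds each segment on both strands; candidates are extended greedily
with match +1, substitution −3, indel −5, an X-drop of 12, and the
argmax as endpoint. In long-read mode the extension may shift diagonals
by up to 2 bp (a band-2 gapped extension), tolerating indel errors; a
shift is accepted only when the 16 bp lookahead matches at 13/16 or
better, which a true indel satisfies and chance-level continuation —
for instance across a ligation junction — essentially never does;
short-read mode is gapless, so a read straddling a heterozygous indel is
split into two abutting segments rather than gapped — a documented
trade-off. Per-segment mismatch budgets are 5% (short) and 15% (long);
the mismatch *penalty* used by the study's aligners does not transplant
across scoring schemes, so tolerance is expressed as a rate.

The TLA loop follows the published description: align the read; if an
alignment is clipped by at least the minimum segment length, split the
remainder at the recognition-site boundary closest to the clipped end of
the mapped portion, re-map the remainders, and iterate until everything
is mapped or no site remains. Splitting operates in read space — the
ligated CATG junctions physically exist in the read — with ties broken
toward the 5' end. Two numerical details matter:

* an extension can gain a few chance-matching bases across a ligation
  junction (and, leftwards, exactly the shared CATG); alignment ends are
  therefore snapped to a junction boundary at most 8 bp away, and the
  spec of recovered segments is compared with truth allowing a 4 bp end
  slop (the cut-convention offset);
* whole-read candidate extensions are cached and reused when aligning
  remainders, which makes the iterative protocol linear rather than
  quadratic in the number of fragments per read.

Unmapped remnants are reported, never silently dropped; segments and
remnants always partition the read. Segments shorter than the seed
length are located by exact search only, so a restriction fragment
shorter than k between two close CATG sites receives *no* direct
alignments even at arbitrary depth — reproducing a structural blind spot
of the technology that deeper sequencing cannot fix.

Ambiguous placements (co-optimal score at more than one location) are
*kept* by default and each placement contributes to the pileup,
mirroring an analysis that does not remove ambiguously mapped reads;
`drop` and `random` policies are available for experiments.

## Calling and phasing

`pileupAlignments()` counts every aligned, non-clipped base; indels are
registered left-normalised (`+SEQ` / `-N`, shifted to their leftmost
equivalent representation, the convention the truth set also uses). Depth counts fragments, not
molecules: two segments of one read over the same position count twice,
as a naive pileup of split alignments would. Calls require the
platform's minimum depth — 25X for short reads, 100X for long reads, the
depth filters the protocol prescribes — and then an allele-fraction
rule: ALT fraction within [0.25, 0.75] with at least 5 supporting
fragments gives 0/1; at least 0.85 gives 1/1. The fraction band and
floor are this package's assumptions (the study delegated calling to
external tools that publish no equivalent thresholds) and are fully
configurable in `callerConfig()`. Raw position depth is used for the
depth filter, as the plainer reading of "detected with a depth of N".

Phasing uses molecule identity: all segments sharing a read id, and both
mates of a pair, derive from one circle and hence one haplotype. For
each molecule the allele at every covered heterozygous call is extracted
(indel observations require the full allele plus one anchor base per
side); each molecule covering two sites adds one unit of cis or trans
evidence. Connected components of the link graph become blocks; a
maximum-weight spanning tree (weight $|n_{cis}-n_{trans}|$) fixes
relative orientations by majority sign from the highest-degree node, and
greedy single-variant flips then remove locally improvable
disagreements. The proprietary phasing algorithm used in the original
analyses is not public; this solver is the package's own definition of
link-based phasing, anchored by `bruteForcePhase()`, an exhaustive
$2^{n-1}$ oracle that the greedy solver provably never exceeds and
matches exactly on tree-shaped link graphs. All tie-breaks (root choice,
block orientation, assignment enumeration) are deterministic.

Benchmarking counts, per variant class, covered / called / concordant /
discordant / missing variants against the planted truth, with covered
defined by the caller's depth floor; phasing concordance picks the best
global orientation per block and additionally reports switch errors
(adjacent agreement-state changes along position-sorted variants), since
"phased correctly" is otherwise ambiguous between per-variant and
junction-based counting.

## Scenario design

`makeScenarios()` encodes the contrasts the study turns on, at sizes a
laptop handles in minutes (stated problem sizes are the package's own
choices):

* `noise_free_long` / `noise_free_short` — one viewpoint in a
  het-containing fragment of an 8-fragment, ~9.6 kb locus with 10
  heterozygous variants; 250 circles; 700 long reads or 2500 read
  pairs. The long-read run recovers genotypes and phase perfectly; the
  short-read run calls as well but phases fewer variants, because a
  150 bp pair rarely spans two het sites.
* `homolog_short` / `homolog_long` — the locus plus an *enriched*
  decoy paralog at ~94% overall identity. The decoy is built
  block-wise: per restriction fragment, the leading 30% is diverged to
  80% identity and the remainder kept identical, emulating the
  interleaved conserved/diverged tracts of real pseudogene pairs —
  a uniform 6% divergence would never confuse a 150 bp read, whereas
  block structure does, which is precisely the phenomenon of interest.
  Homozygous-alt variants planted in the conserved zones are diluted to
  ~50% allele fraction by co-mapping decoy reads under the `keep`
  policy and miscalled heterozygous by short reads; long-read segments
  span the diverged tracts, map uniquely, and avoid the error.
* `viewpoint_with_het` / `viewpoint_no_het` — short-read runs in which
  the single viewpoint either contains a heterozygous variant or not.
  The viewpoint primer is placed on the far side of its het, so the het
  flanks one of the two viewpoint ligation junctions present in every
  amplicon; read pairs crossing that junction link it to variants of
  whichever fragment was ligated there. A viewpoint without a het
  offers no such hub and phases fewer variants — the qualitative
  argument for designing viewpoints near known heterozygous positions.
* `four_viewpoints` — a 16-fragment locus with four evenly spaced
  viewpoints whose reads are merged before pileup, as real
  multi-viewpoint libraries are, covering essentially the entire locus.

All scenarios share one run seed; stages derive named subseeds via
`stageSeed()`, so matched platform pairs see identical loci and circles
and every output (and the md5 manifest) is byte-reproducible.

## What passing tests do and do not show

The simulator emulates the *geometry* of TLA — digestion, haplotype-pure
circular ligation, distance decay, viewpoint anchoring, platform read
lengths and error magnitudes — and therefore supports testing of the
splitting, filtering, linking and benchmarking logic against exact
truth. It does not emulate: structural variants or paralog hybrid
alleles (diploid SNV/small-indel loci only); incomplete digestion or
re-ligation of adjacent fragments beyond what random circle composition
produces; sequence-context error profiles (homopolymer indels),
base-quality variation, or basecalling artifacts; barcode demultiplexing
and pooling effects; and real pseudogene evolutionary structure beyond
the two-tract block model. Results on real libraries will differ in
degree — particularly calling accuracy under context-dependent error —
even where the qualitative contrasts reproduced here are expected to
hold.

## Degenerate inputs and numerical conventions

Coordinates are 0-based half-open internally; VCF and BED output are
1-based (standard). Variants must be non-overlapping and may not create
or destroy a CATG site (the generator rejects such draws), keeping
digestion identical across haplotypes and coordinate maps invertible.
A motif-free sequence digests to a single fragment; an empty variant
list yields identity coordinate maps; zero simulated circles yield
valid empty outputs. Contradictory phase components (all link weights
zero) are left unphased with a warning rather than arbitrarily
resolved. The package refuses: reference mismatches in variant tables
(naming the position), viewpoints outside the reference, k above every
reference length, and pipeline configurations with unknown keys.
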