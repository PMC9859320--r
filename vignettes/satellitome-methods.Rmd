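---
title: "Satellitome discovery and comparison: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellitome discovery and comparison: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satellitome)
```

# The problem

Satellite DNAs (satDNAs) are noncoding sequences organized as long tandem
arrays of a repeated monomer, concentrated in heterochromatin. The complete
catalog of satDNA families in a genome — its *satellitome* — is routinely
characterized not from assemblies (satellite arrays assemble poorly) but
from low-coverage, unassembled short reads: tandem repeats are heavily
over-represented relative to single-copy sequence even at well below 1×
coverage, which makes them detectable long before the genome itself is
assemblable. This package implements that workflow end to end:

1. **discovery** of consensus monomers from reads, iterated with read
   subtraction until nothing new appears;
2. **quantification** of each family's genome proportion (*abundance*) and
   mean mismatch to its consensus (*divergence*) by mapping a read sample
   against the catalog;
3. **homology**: rotation- and strand-invariant similarity between
   monomers, the conventional same-variant / variant / superfamily
   classification, and cross-species comparison tables;
4. a **synthetic-data generator** that plants ground-truthed satellite
   arrays in artificial genomes, so every stage is testable without any
   sequencing data.

# Discovery

## Tandem repeats as k-mer graph cycles

A perfect tandem array of an $m$-bp monomer contains exactly $m$ distinct
k-mers, and under $(k{-}1)$-overlap they form a directed cycle — the
"circular" cluster structure that graph-based satellite detectors exploit.
`detectLongMonomers()` counts canonical (strand-summed) k-mers
($k = 21$ by default), retains those with frequency at or above
`minKmerFreq`, and walks the overlap graph greedily from each retained
k-mer, always taking the highest-frequency successor. A walk that revisits
itself spells out a circular consensus; the fraction of its component's
k-mer mass lying on the cycle is the **circularity score**, and candidates
below `circularityThreshold` (default 0.5) are dropped. Background
sequence at low coverage produces path-shaped components whose walks
dead-end, so cycle closure is itself the false-positive filter.

Low coverage over diverged copies means some consensus k-mers are simply
never sequenced intact: a 600-bp monomer at 0.5× coverage and 5% copy
divergence almost surely has such positions. Walk extension therefore
falls back, at zero-evidence steps, to majority vote over the
hamming-1 neighborhood of the four possible successors (one erroneous base
shifts out of the window within $k$ steps, so the walk re-joins the exact
consensus), and finally to an 11-mer evidence table. Consecutive fallback
steps are capped at $k$, so walks through genuinely unsupported sequence
still terminate. Each candidate is then *polished*: reads sharing an exact
12-mer with the dimerized candidate are aligned to it and every monomer
position takes the column-majority base, iterated to a fixed point.

Defaults and what they mean:

| parameter | default | meaning |
|---|---|---|
| `k` | 21 | odd k-mer size of the overlap graph |
| `minKmerFreq` | 5 | canonical k-mer retention threshold, calibrated to ~0.5× coverage; scale proportionally with coverage |
| `circularityThreshold` | 0.5 | minimum cycle mass / component mass |
| `filterIdentity`, `filterCoverage` | 90, 0.5 | read-subtraction thresholds between rounds |
| `readsPerIteration` | 500,000 | reads fed to each detection round |
| `maxIterations` | 10 | hard cap on rounds |

## Short monomers

Monomers shorter than the k-mer size are recovered directly from reads:
`detectShortMonomers()` finds, per read, the smallest period
$p \in [3, 20]$ whose self-shift identity reaches `minSelfIdentity`,
estimates the read's monomer by majority vote over residue classes mod
$p$, and clusters reads by period and rotation/strand-canonical monomer
into column-majority consensuses. The self-shift compares one array copy
against the *next*, so copy divergence counts twice: copies at $d$%
divergence from their consensus agree at roughly $100 - 2d(1 - d/100)$%.
The default `minSelfIdentity` is therefore 75 — tight enough that random
sequence (~25% self-identity) is nowhere near it, loose enough that
arrays at 10% copy divergence (~81% expected self-identity) are caught.
Periods 1–2 (homopolymers, dinucleotide repeats) are excluded, as
satellite catalogs conventionally omit them.

## The iterative loop

`runDiscoveryLoop()` alternates detection and subtraction: each round
samples `readsPerIteration` reads (fresh deterministic sub-seed per
round), runs both detectors, keeps candidates with rotational similarity
≤ 95% to everything already found, removes matching reads from the pool,
and stops when a round adds nothing. Redundant candidates are merged by
single linkage above 95% similarity, each group represented by its
highest-supporting-mass member. The run log records per-round read counts
and the termination reason.

# Quantification

`mapReads()` aligns every read, on both strands, against each family's
consensus multimerized past the read length (so monomer junctions and any
array phase are fully alignable), and keeps the single best-scoring hit
with identity ≥ `minIdentity` (default 80%) over at least `minCoverage`
(default 0.5) of the read. The aligned-fraction requirement exists because
an unconstrained local alignment always finds short spurious perfect
matches on random reads. Score ties go to the lower (more abundant)
family rank, deterministically — a small, documented bias toward abundant
families. Scoring constants: match +1, mismatch −1, gap open −2, gap
extend −1; identity is matches over alignment columns including internal
gaps.

Before alignment, reads are prefiltered by exact 12-mer seeds shared with
the dimerized consensus (either strand), the standard seed-and-extend
economy: a read genuinely below the identity threshold essentially never
carries such a seed by chance, and unit tests verify that prefiltered
decisions equal brute-force full alignment on complete samples.

`estimateAbundance()` divides summed aligned nucleotides by total analyzed
nucleotides — the genome proportion — and reports divergence as the
aligned-length-weighted mean of $100 - \text{identity}$ (raw mismatch
percent; no substitution-model correction is applied).
`repeatLandscape()` splits each family's abundance mass into divergence
bins; row sums reproduce the abundance column exactly.

Abundance precision is pure counting statistics: a family expecting $r$
mapped reads carries a relative standard error of about $1/\sqrt{r}$.
Estimates within ±20% of truth therefore require on the order of 100
mapped reads per family; the quantification step consequently maps its own
fixed-size random sample, sized so that the rarest family of interest
expects well over 100 reads (the characterization protocol this package
follows does the same, mapping a fixed sample of ~5 million reads rather
than whatever discovery consumed). Discovery coverage and quantification
sample size are independent knobs.

# Homology and classification

Monomers are circular sequences with arbitrary start and strand.
`rotationalSimilarity()` aligns one monomer semi-globally (free end gaps
on the subject side) against the head-to-tail self-concatenation
("dimer") of the other, on both strands, takes the identity of the
best-scoring alignment, and symmetrizes by trying both orientations.
Homology scoring is gap-stringent (match +1, mismatch −1, gap open −5,
gap extend −3), unlike read mapping: monomer homology is substitution
divergence, and at permissive gap costs an optimal aligner stitches
enough random matches that *unrelated* monomers approach 50% identity —
which would hollow out the common-origin threshold entirely. Under the
stringent costs, random monomer pairs of ordinary length (≥ ~100 bp)
score around 40–45%, so the 50% cut discriminates; monomers of a few
dozen bp retain an elevated chance ceiling, which is one reason short
conserved repeats deserve cautious interpretation.
Monomers under 20 bp are concatenated four times instead of two so the
aligner has usable target length. Unaligned overhang of the longer
sequence does not penalize — a deliberate convention matching the
local-hit behaviour of repeat-annotation tools, under which a short
monomer embedded in a longer one scores by its best placement. For
monomers ≤ 30 bp this equals a brute-force maximum over all explicit
rotations and strands with a plain global aligner (verified in tests; the
equivalence is provable when optimal alignments are gap-free, e.g. for
single-substitution differences, and can deviate by a point or two in
degenerate gapped ties).

`classifyPair()` applies the conventional thresholds: similarity above
95% — same variant; 80–95% — variant; 50–80% — superfamily; below 50% —
no common-origin call. The literature states the tiers with overlapping
boundaries; here exactly 95 and exactly 80 classify as variant and
exactly 50 as superfamily ("greater than 95%" being strict), and no
published value in the bundled tables sits on a boundary.
`compareCatalogs()` reports all cross-catalog pairs at ≥ 50%,
`groupSuperfamilies()` single-links within-catalog pairs in [50, 95], and
`multiCatalogConservation()` single-links cross-catalog pairs at ≥ 80%
into a one-row-per-group, one-column-per-species conservation matrix.

# The synthetic-data generator

`generateSpeciesPair()` embodies the **library hypothesis**: an ancestral
set of satDNA families is inherited by two descendant species, each
species' consensus diverging independently by `crossSpeciesDivergence`
percent substitutions, plus optional species-private families. Arrays are
generated copy-by-copy from the species consensus (a star phylogeny of
copies), emulating the homogenized structure concerted evolution
produces; substitutions are uniform over the three alternative bases, and
optional single-base indels are supported. Background is i.i.d. sequence
at a configurable GC content. The truth manifest records every planted
consensus, exact genome fraction (total array length over genome length)
and array coordinates, plus the realized cross-species consensus
similarity of every shared family — with per-base rate $d$ applied
independently to both descendants, expected pairwise identity is
$(1-d)^2 + d^2/3$, i.e. ≈ 90.7% at $d = 0.05$, squarely in the "variant"
band.

`simulateReads()` draws a deterministic $\lfloor cG/L \rfloor$ reads
(coverage $c$, genome $G$, read length $L$; not per-base Poisson — simpler
accounting at desk scale) at uniform positions, each from either strand
with probability 0.5, with i.i.d. substitution errors and constant
placeholder qualities. Defaults mirror the study conditions the package
is validated under: 101-bp reads, ~0.5× coverage, 1% error. Paired-end
structure is not modeled — the pipeline never uses pairing information —
and neither are quality-score profiles, GC-coverage bias, higher-order
repeat structure, nor transposable elements. Passing tests on this
generator therefore demonstrate correctness of the *computations*, not
robustness to every artifact of real libraries.

The validation scenario used throughout the tests plants eight families
spanning genome fractions 0.01 down to 0.0005 and monomer lengths 21 to
600 bp at 5% intra-array divergence in a 2 Mb genome sequenced at 0.5×;
discovery recovers the planted monomers at ≥ 95% consensus identity with
zero false candidates, and abundance estimates from a protocol-sized
mapping sample land within ±20% of truth. These problem sizes were chosen
to be the smallest at which all eight families are physically
discoverable (the rarest family spans only ~33 copies).

# Numerical conventions and edge cases

* Summary statistics are rounded to one decimal with round-half-even;
  published satellitome tables are reproduced at that precision. Note that
  published "median" repeat-unit lengths and A+T values for the two
  bundled catalogs actually equal the arithmetic *means* of the table
  columns (e.g. 286.4 vs a true median of 87.5 for the 30-family
  catalog); `summarizeCatalog()` computes and labels both.
* The bundled catalog tables are transcribed exactly as printed, including
  their internal inconsistencies (two rows whose RUL column disagrees with
  the name-implied length); `summarizeCatalog(useNameRul = TRUE)`
  summarizes name-implied lengths where that is the meaningful column,
  and name/length consistency is enforced only when consensus sequences
  are actually present.
* Consensus orientation and rotation are canonicalized to the
  lexicographically smallest rotation of the lexicographically smaller
  strand, making catalogs diffable across runs.
* Abundance ties in naming break by larger repeat unit first, then
  lexicographic consensus; alignment-score ties break forward-strand
  first, then smaller offset; all tie-breaks are deterministic.
* Empty inputs are contracts, not crashes: an empty family list yields an
  empty catalog, an empty catalog passes reads through the filter
  untouched, and an empty report renders as a valid (empty) document.
  Reads may contain N (excluded from k-mer evidence and alignment);
  consensus monomers may not.
* Every stochastic step takes an explicit seed; per-round and per-stage
  sub-seeds are derived deterministically from the master seed, and all
  pipeline outputs embed the seed and a config hash in their headers.

# Known limitations

* Very rare, long-monomer families are physically undiscoverable at low
  coverage (too few sequenced copies to support any k-mer evidence); the
  detector degrades by omission, not by fabrication.
* Divergence above ~15% between array copies erodes the k-mer graph
  faster than the fallback bridging can compensate; such families are
  better sought with the short-period detector (if short) or more
  coverage.
* Best-hit mapping assigns each read wholly to one family; families above
  95% similarity should be merged before quantification or their
  abundances read jointly.
* The multimerization convention makes similarity asymmetric in length by
  design (overhang-free); monomer pairs of wildly different lengths score
  by embedded placement, which is intended but worth remembering when
  interpreting superfamily calls between a 6-bp and a 600-bp monomer.
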