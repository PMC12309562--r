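---
title: "Telomere contact mapping from SPRITE data: models and methods"
author: "spritetel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telomere contact mapping from SPRITE data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spritetel)
```

# The problem

SPRITE (split-pool recognition of interactions by tag extension) tags
crosslinked chromatin fragments with iteratively built barcodes, so that
fragments sharing a barcode — a *cluster* — were spatially proximal in the
nucleus. Standard 3D-genomics pipelines discard repetitive reads, which
makes telomeres invisible. `spritetel` makes them visible by a small set
of changes to the computational workflow: telomere-repeat reads are
recognized by sequence alone, pulled out before alignment, and assigned to
an artificial single-bp locus called **chrT**. When the contact matrix is
built, chrT is one extra bin, so the genome-wide telomere contact profile
is simply the chrT row. This is of particular interest in ALT
(Alternative Lengthening of Telomeres) cancer cells, whose telomeres are
long, heterogeneous, rich in variant repeats, and prone to seeding
*ectopic* telomere repeats at internal loci.

The package implements, end to end:

1. **Repeat filtering** — classify reads as telomeric by counting
   canonical (TTAGGG/CCCTAA) and variant repeat hexamers.
2. **Clusters and contact matrix** — barcode grouping, repeat masking
   (chrT exempt), and the 2/N-downweighted contact matrix.
3. **Telomere-track analysis** — distance-to-telomere decay, distance
   normalization, annotation group tests, peak proximity profiles,
   compartment correlation.
4. **A/B compartments** — observed-over-expected normalization, Pearson
   correlation matrices, PCA with gene-density component selection.
5. **Ectopic telomere calling** — soft-clip window scan over long-read
   alignments with a mapping-quality/end-distance/support filter chain.
6. **FISH proximity testing** — Multi-Otsu segmentation of nuclei and
   foci, adjacency scoring, randomization percentile test.
7. **Synthetic data** — seeded generators with machine-readable ground
   truth for all of the above, so the whole pipeline is testable without
   any external data.

# Repeat classification

A read sequence is scanned greedily, left to right, per strand: at each
position the canonical hexamer of that strand is tried first, then any
variant hexamer; a match advances by 6 bp, otherwise by 1 bp. The two
strands are never mixed — a genuine telomere fragment derives from one
strand — and the strand with the larger total is reported, ties going to
the G strand. Because all motifs have length 6, leftmost-greedy attains
the maximum possible number of non-overlapping matches (equal-length
intervals make earliest-start equivalent to earliest-finish), which the
test suite verifies against an exhaustive dynamic-programming tiling
oracle. One caveat is documented in `count_repeats`: when a mixed-strand
sequence ties in total between strands, the G-on-tie rule decides which
tiling's canonical count is reported.

A read is **telomeric** when it has at least `min_total` repeats
(canonical + variant) *and* at least `min_canonical` canonical repeats.
The presets are low = (4, 2), medium = (7, 4) and high = (14, 7); a SPRITE
read yields roughly 85–90 bp of genomic sequence, so ~14 repeats is the
ceiling. Medium is the default used throughout.

The shipped variant list (TCAGGG, TGAGGG, TTGGGG, TTCGGG, TTTGGG, TAAGGG,
GTAGGG, CTAGGG and reverse complements) covers the commonly reported
human variant repeats; it is an explicit stand-in, and every result can
be recomputed under a user-supplied list (`read_motif_file()`).

# Clusters and the 2/N contact matrix

Telomeric reads keep their barcode and become chrT reads on the fixed
interval [0, 1). Repeat masking removes genomic reads overlapping mask
intervals by ≥ 1 bp (BED half-open semantics) and never touches chrT.
Within a barcode, reads with identical (chromosome, start) are collapsed
as presumed PCR duplicates; this is switchable (`dedup = FALSE`). One
consequence of the chrT design is that all of a cluster's telomere reads
share (chrT, 0), so after deduplication a cluster carries at most one
chrT member and the chrT–chrT diagonal of the default pipeline is zero;
the telomere *track* (chrT vs genome) is unaffected.

Every unordered pair of members in a cluster of size *n* adds weight
2/*n* to its bin pair, so a cluster contributes C(n, 2) · 2/n = *n* − 1
in total: single interactions matter less in big clusters. Same-bin pairs
are recorded on the diagonal — this makes the total mass identity exact
(the suite checks Σ(n − 1) conservation to 1e-12 relative) — and the
telomere track excludes the chrT self-entry, reporting it separately.
Default size bounds are [2, ∞); display-oriented caps (≤ 100 for cluster
plots at 25 kb, ≤ 1000 at 50 kb) are arguments, not defaults. The matrix
is stored as a sparse symmetric `Matrix`, built with one sparse
cross-product rather than pair enumeration, which keeps 50,000-cluster
builds at a few seconds.

# Telomere track analysis

**Distance classes.** Each genomic bin's class is its bin distance from
the nearest end of its reference chromosome; the terminal bin has class 1,
so at 1 Mb resolution class *d* reads as "*d* Mb from the nearest
telomere". Bins with exactly zero contact are assumed to lack mappable
DNA and are excluded everywhere.

**Decay curve.** Per class, the mean track value over contributing bins,
expressed as a ratio to the class-1 mean.

**Distance normalization** divides each bin by its class mean, removing
the dominant linear-distance effect so that centromere, heterochromatin
and ectopic-repeat effects become visible; by construction every class
mean of the normalized track is exactly 1, and the operation is
idempotent. Group comparisons (e.g. centromere-overlapping bins vs the
rest) use a Welch two-sample t-test on the normalized values, because
group sizes and variances differ drastically.

**Peak proximity.** For H3K9me3-style analyses the package compares,
per signed distance bin around the nearest peak center, read counts in
telomere-containing clusters versus clusters without telomeres, then
normalizes the curve so its minimum is 1. Defaults: ±50 kb window, 1 kb
step, read midpoint to peak center; all are arguments since the choice is
a display convention. A distance bin whose telomere count is zero makes
the literal minimum zero; the curve then falls back to the smallest
positive ratio with a warning.

# A/B compartments

Per chromosome: (1) each intrachromosomal contact is divided by the
genome-wide mean contact at the same bin distance (observed/expected);
(2) bins whose fraction of zero-or-missing O/E entries exceeds 0.5 —
"mostly zero" made concrete; the 0.5 is an exposed knob — are excluded
and the remaining rows are correlated pairwise (Pearson); (3) the
correlation matrix undergoes PCA (mean-centered, unscaled). For each of
the first five components, bins split by eigenvector sign form two
candidate compartments whose gene densities are the mean count of gene
intervals per bin; the first component whose denser side is at least 1.5×
denser is selected, otherwise the component with the largest density
discrepancy (ties to the lowest index). The sign is flipped if needed so
the gene-dense (A) side is positive, which also removes solver sign
ambiguity. The correlation of the telomere track with this eigenvector
uses the distance-normalized track by default (a flag exposes the raw
track), with excluded bins dropped pairwise.

# Ectopic telomere repeat calling

Long reads are screened for a 300-bp window that starts at a canonical
repeat and contains ≥ 45 total repeats (a pure 300-bp tract holds 50
hexamers, so 45 demands a nearly pure repeat). Windows are counted with
the same per-strand greedy scanner as read filtering. Evidence is kept
only when a passing window lies wholly inside a soft-clipped segment —
telomere sequence inside the aligned portion is reference sequence, not a
variant. The insertion position is the alignment start (left clip) or end
(right clip); orientation is *standard* when the G-strand repeat points
away from the aligned segment (TTAGGG on a right clip, CCCTAA on a left
clip), *inverted* otherwise — reported, never filtered on.

The filter chain then drops evidence with MAPQ < 30 or insertion
positions within 100 kb of a chromosome end; merges remaining positions
per chromosome by single linkage with gap ≤ 100 bp (the simplest closure
of the pairwise "within 100 bp" rule); takes the median member position
as the representative (deterministic and robust; even-sized groups round
down); discards loci where ≥ 40% of overlapping reads in the *unfiltered*
alignment set have MAPQ < 10 (inclusive reading of "at least 40%"; zero
coverage also fails); and requires ≥ 2 distinct read ids. Output is
deterministic and invariant to input read order.

# FISH proximity analysis

Nuclei are segmented from the DNA channel by 3-class Multi-Otsu
(exhaustive search over a 128-bin histogram), foreground above the first
threshold, components ≥ 500 px. Foci are segmented within each nucleus
by Multi-Otsu of the masked channel, top class, components ≥ 9 px,
centroid = mean pixel coordinate. Two numerical guards: when fewer than
three intensity levels are occupied the threshold falls back to 2-class
Otsu, and focus pixels must additionally clear 3× the in-mask mean so
that a channel with no genuine foci does not segment its own noise.

A telomere focus is centromere-adjacent when its centroid lies within 5
px (Euclidean, inclusive) of a centromere centroid; the nucleus score is
the mean adjacent-telomere count per centromere focus. The null is built
by relocating every telomere centroid to an independent uniform draw over
the nucleus-mask pixels, 1000 times (centromeres fixed), and the observed
score gets a mid-rank percentile (ties counted half), which is unbiased
under the discreteness of the score. Centroid distance (rather than
boundary distance) is the self-consistent choice because the
randomization relocates point positions.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; real SPRITE sequencing data at this scale is not bundled, so
every acceptance-style check runs on data with planted, machine-readable
ground truth.

**Toy genome.** Six chromosomes of 40–60 Mb (300 Mb total), each with a
100-kb telomeric tract at both natural ends, thirteen 50-kb interstitial
tracts, and one centromere interval. Three choices matter and are
deliberate: arms are long enough that the first ten 1-Mb distance classes
sit far from chromosome midpoints (near the midpoint the two-end decay
flattens by construction); twelve chromosome ends contribute to every
distance class, so per-class means average out single-cluster shot
noise; and interstitial tracts sit at distance classes ≥ 18, because a
tract's contact spillover inherits the heavy tail of the displacement
law and decays only slowly with distance — parked eight classes beyond
the first ten, the spill that reaches class 10 is a small fraction of a
tract bin's own signal. Several tracts lie adjacent to centromeres,
emulating the observed tendency of ectopic repeats to occur near
centromeric sequence.

**SPRITE clusters.** Cluster sizes are log-uniform on [2, 200] (SPRITE
libraries span small and large clusters). Each cluster draws a uniform
genomic anchor; members displace from it by a two-sided Pareto-like law
with scale 500 kb and tail exponent 0.65, reflected at chromosome
boundaries, reproducing a precipitous but heavy-tailed distance decay.
Members landing in a planted tract are emitted as chrT reads with
probability 0.8, multiplied by 3 for clusters anchored in a centromere.
The displacement scale is the one genuinely tuned constant: much smaller
scales concentrate each cluster in one bin, so the rare deep-interior
cluster that catches a telomeric tract deposits a single heavy "lump" of
pair weight and the deep distance classes become noisy; 500 kb spreads
each cluster over several bins, which both shrinks and smooths those
contributions while leaving the near-end decay steep. The defaults were
fixed by a seed-swept design study and then frozen; with them the
generator robustly exhibits the two qualitative features it exists to
emulate — strictly decreasing decay over the first ten classes and
strong distance-normalized enrichment at planted tracts — across seeds,
which is what the acceptance checks assert.

**What the generator does not emulate.** Linear displacement stands in
for 3D proximity, so *trans* contacts, compartment plaids and true
spatial centromere–telomere clustering are absent unless planted;
sequencing error is not modeled (telomeric reads are clean repeat
mosaics); cluster sizes are independent of genomic position. Passing
tests therefore demonstrate correctness of the computational method
under controlled conditions, not biological discovery on real data.

**Long reads.** Planted insertion loci get supporting reads with tandem
soft clips (default 400 bp, MAPQ 60, > 1 Mb from ends, ≤ 30 bp position
jitter so supports merge) plus decoy classes that each violate exactly
one calling rule: single support, MAPQ 29, 99 kb from an end, tract
inside the aligned portion, 200-bp clip, and a locus whose unfiltered
coverage is half MAPQ < 10. The caller must recover exactly the planted
loci.

**FISH images.** Disk nuclei with Gaussian foci (σ = 2.2 px, wide enough
that even a rim-truncated spot keeps ≥ 9 bright pixels) and bright
chromocenter-like DNA speckles, so the DAPI histogram is honestly
trimodal the way real fields are (with a bimodal histogram, 3-class
Otsu may split the background instead and the mask leaks). Centromere
spots stay 8 px from the rim (their 5-px neighborhoods remain inside
the mask) and keep a 7-px spacing for clean detection — they are fixed
under randomization, so this cannot bias the test. Telomere spots are
deliberately iid uniform over the full nuclear disk: the randomization
null *is* iid uniformity over the mask, and any spacing, margin or
position-dependent detection on the telomere channel shifts or
underdisperses the observed scores relative to it. Adjacency-planted
telomere spots are placed within 3.5 px of a random centromere and may
pile up, as genuinely colocalized foci do.

# Problem sizes and numerical choices

The validation suite runs the filter oracle on 10,000 sequences, matrix
conservation on 10,000 clusters, the end-to-end study on the generator
default of 50,000 clusters, the ectopic study on 20 planted loci plus
decoys, compartment recovery on 100-bin two-block matrices over 20 seeds,
and FISH calibration on 200 null nuclei with 1000 randomizations each —
sizes chosen so each stage completes in seconds to a few minutes on one
CPU while leaving the statistical margins comfortable.

Numerical conventions: coordinates are 0-based half-open internally, with
1-based formats converted at the boundary; all cluster, locus and export
orderings use radix (C-locale) sorts so outputs are byte-reproducible;
matrix mass identities hold to 1e-12 relative (floating accumulation
only); PCA sign ambiguity is removed by the gene-density rule; mid-rank
percentiles handle score ties; merge chains and medians make locus calls
order-invariant.

# Known limitations

- The chrT design collapses telomere multiplicity per cluster under
  deduplication (above); relative contact patterns are unaffected.
- The greedy scanner's canonical count under a strand tie is a defined
  convention, not a biological statement.
- `peak_proximity_profile` distance conventions (window, step, center)
  are display choices; defaults are explicit arguments.
- Multi-Otsu segmentation assumes reasonably bimodal/trimodal intensity
  histograms; extremely dim or saturated channels need the exposed
  area/threshold knobs.
- The mappability filter needs the unfiltered alignment set; calling from
  a pre-filtered BAM silently weakens it.
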