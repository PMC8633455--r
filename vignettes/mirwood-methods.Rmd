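---
title: "Methods: small-RNA discovery, differential expression and target integration in developing stems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA discovery, differential expression and target integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`mirwood` implements a complete desk-scale analysis chain for stem
small-RNA libraries sampled across three developmental stages (primary
stem, transitional stem, secondary stem; abbreviated PS/TS/SS), with
three biological replicates per stage:

1. read cleaning,
2. collapsing to sequence tags and annotation into structural-RNA
   classes,
3. identification of existing and conserved miRNAs against a
   miRBase-style catalogue and prediction of novel miRNA hairpins,
4. TPM/FPKM normalisation and negative-binomial exact-test differential
   expression between stages,
5. weighted-mismatch target prediction with a duplex-energy filter,
6. Pearson-correlation integration of DE-miRNA/target pairs, and
7. hypergeometric term enrichment.

Every stage can be exercised without external data through a
synthetic-data generator that plants known ground truth. This vignette
records the model choices, parameter meanings and defaults, the
numerical decisions, and what the synthetic data can and cannot show.

# Read cleaning

Small-RNA reads are filtered in a fixed order so each read lands in
exactly one removal category and the report always sums to the raw
total: (1) malformed records; (2) low-quality reads — more than one base
at Phred ≤ 20, or any uncalled base (N); (3) adapter classification —
the 3' adapter is located by an exact 8-nt seed of its 5' end, extended
over the remaining adapter bases with at most one mismatch, scanning
left to right; reads carrying the 5' adapter, adapter dimers without an
insert, and reads with no detectable 3' adapter are removed; (4) inserts
that are ≥ 90% A (poly(A)); (5) inserts shorter than 18 nt. Inserts
longer than 30 nt are retained; the length histogram is reported over
18–30 nt.

Two of these cut-offs deserve comment. "More than one low-quality base"
is read strictly: two bases at Phred ≤ 20 fail, one passes, and Phred 21
is not low quality. The poly(A) definition (≥ 90% A over the insert) is
a tolerance for single miscalls; the boundary only matters for synthetic
reads, which are generated as pure poly(A).

A read with no recognisable 3' adapter has no defined insert boundary,
so it is dropped (and logged in its own sub-count). This makes the
adapter step deliberately non-idempotent: already-trimmed reads would
all be discarded on a second pass. `clean_srna_reads(...,
require_adapter = FALSE)` is provided for re-filtering trimmed reads;
the remaining filters are idempotent.

mRNA read pairs are adapter-trimmed and dropped as a pair when either
mate is shorter than 50 nt after trimming, has more than 10% N, or has
more than 50% of bases at Phred ≤ 20.

Adapter sequences are parameters, not constants; the generator's
defaults are the common Illumina small-RNA adapters.

# Tag annotation

Clean reads are collapsed to distinct sequences ("tags") carrying one
abundance count per library. Tags are then classified by the first
matching class in a fixed precedence order:

rRNA → snRNA → snoRNA → tRNA → repeat → miRNA catalogue → exon (sense) →
exon (antisense) → intron (sense) → intron (antisense) → unannotated.

Matching is exact full-length substring matching — sense-only against
the structural-RNA reference sets, both strands against the genome —
standing in for zero-mismatch short-read alignment, which keeps every
assignment deterministic and independently checkable. scRNA, which has
no reference set of its own here, is folded into the snRNA class. The
miRNA class precedes the degradation classes so that catalogue miRNAs
whose loci fall inside genes are not claimed by exon/intron categories;
the order is configurable. Multi-locus hits use the first locus in
(sequence name, coordinate) order; only the category matters
downstream.

Category and length distributions are abundance-weighted (not
unique-tag-weighted), because only then do the per-library category
totals equal the clean-read totals — the arithmetic constraint a
category table must satisfy.

# miRNA identification

A tag identical to a focal-species catalogue mature is an **existing**
miRNA and keeps its catalogue name with a `-5p`/`-3p` arm suffix; a tag
matching only another species' catalogue is a **conserved** miRNA,
renamed to the family name with `-x` (5' arm) or `-y` (3' arm). The arm
is determined by folding the catalogue precursor; when the precursor
does not fold into a clean stem-loop, a midpoint rule is the fallback.
When a tag matches several catalogue entries, the focal species wins,
then the alphabetically first name; all matches are logged in the
returned table.

Novel miRNAs are predicted from the unannotated pool under the
MIREAP-style criteria, all of which are recorded per candidate:

| criterion | default |
|---|---|
| mature length | 18–25 nt |
| star (reference) length | 20–23 nt |
| genome copies of the mature | ≤ 20 |
| precursor MFE | ≤ −18 kcal/mol |
| mature/star spacing | 16–300 nt |
| largest duplex bulge | ≤ 4 nt |
| duplex asymmetry | ≤ 4 nt |
| precursor flanks | 20 nt |
| structure | single stem-loop, mature on one arm |

Two published ambiguities are resolved as follows and are configurable.
The "18 kcal/mol" free-energy bound is sign-ambiguous in the field's
usage; it is interpreted as MFE ≤ −18 kcal/mol (a hairpin must be at
least that stable). The "reference sequence length" bounds (20–23 nt)
are interpreted as bounds on the star sequence.

The star is the Dicer partner of the mature with 2-nt 3' overhangs. It
is derived from the folded precursor: the pairing partners of the
mature's outermost paired bases, extrapolated over unpaired terminal
bases, shifted by the overhang. The duplex bulge is the largest unpaired
run between consecutive paired mature positions on either strand;
asymmetry is the absolute difference of total unpaired counts between
the two sides of the duplex.

For each genome hit of a tag, both arm hypotheses are examined. Instead
of folding every possible window, the star is first located by a
complementarity scan: every placement of a candidate star within the
allowed spacing (up to 300 nt on either side) is scored by how many
mature positions find a Watson–Crick or G:U partner, and placements
pairing at least 60% of the mature are folded and checked. This is a
pure efficiency device: the planted and any genuinely qualifying star
pairs most of the mature by definition, and every emitted candidate is
validated through the folded structure. The first passing window per
locus is kept. Candidates sharing a mature collapse into one record
named `novel-mNNNN-<arm>`, ordered by descending total count.

# RNA folding model

Thermodynamic structure prediction uses an internal Zuker-style dynamic
programme over a deliberately small nearest-neighbour model: stacking
energies for adjacent base pairs over the six pair types (AU, UA, GC,
CG, GU, UG), additive loop penalties for hairpin loops (≥ 3 nt), bulges
and interior loops (log-extrapolated beyond tabulated sizes,
Jacobson–Stockmayer style), and an affine multibranch-loop cost. The
tables ship as TSV files and can be overridden. Interior loops are
capped at 30 unpaired nucleotides as part of the model definition.

Energies are handled internally as integers in decikcal/mol, so
minimisation is exact and platform-independent, and the dynamic
programme can be compared *exactly* against an oracle that enumerates
every legal structure of a short sequence and scores it by explicit
loop decomposition. The test suite does this for random sequences up to
20 nt; the intermolecular duplex routine is checked the same way
against exhaustive enumeration of monotone pairings.

Absolute energies from such a reduced parameter set are not comparable
to a full Turner-parameter folder, and are not meant to be: the only
places energies cross a threshold are the precursor stability bound
(configurable, and satisfied with a wide margin by planted hairpins)
and the target-duplex rule, which is a *ratio* of two energies computed
under the same model.

Tie-breaking among equal-energy structures is by a fixed deterministic
traceback order (pairing preferred over leaving a base unpaired,
leftmost pair first; stacking/interior decompositions before
multibranch before hairpin closure). This approximates a lexicographic
minimum on the dot-bracket string while keeping the traceback a single
deterministic pass; identical inputs give identical structures on every
platform. Lonely pairs are permitted.

# Differential expression

miRNA abundances are normalised as TPM = count / total clean reads of
the library × 10⁶ — the totals are *all* clean reads, not miRNA-mapping
reads. Gene abundances are FPKM. Stage changes are reported as log2 of
the later stage over the earlier (TS/PS, SS/PS, SS/TS).

The test is an exact conditional negative-binomial test written for
this package: conditional on a feature's total count over both groups,
the group-A sum follows a distribution that is binomial at dispersion
zero and the NB convolution ratio otherwise (a sum of n iid NB(μ, 1/φ)
replicates is NB with size n/φ). With equal per-replicate means and
sizes under the null, this conditional law does not depend on the
unknown mean, so the test is exactly valid; unequal library sizes are
first adjusted by scaling counts to the geometric-mean size. The
two-sided p doubles the smaller tail, capped at 1. The installed edgeR
package, which the field would normally reach for, serves as an
independent cross-check in the test suite, never as the implementation.

The common dispersion is estimated by method of moments pooled across
features (floored at 10⁻⁶); with three replicates per group, tagwise
estimates are not stable enough to support shrinkage, so none is
attempted. Fold changes use a pseudocount of 0.5 TPM (or FPKM) on both
means to bound ratios involving zeros; the threshold asymmetry of the
study design is preserved exactly — miRNAs are called at |log2FC| ≥ 1
with raw p ≤ 0.05, genes at |log2FC| ≥ 1 with Benjamini–Hochberg
FDR ≤ 0.05.

The qPCR helper implements 2^−ΔΔCt with per-sample mean ΔCt against a
reference assay (5.8S rRNA for miRNAs, β-actin for genes) and a
calibrator sample whose relative expression is exactly 1; the standard
error is taken over per-replicate relative values.

# Target prediction

Candidate sites are every sense-strand transcript window of miRNA
length, aligned antiparallel and ungapped, scored per position from the
miRNA 5' end: 0 for Watson–Crick, 0.5 for G:U, 1 otherwise. A site
passes when all of the following hold:

1. total weighted mismatches ≤ 4;
2. no more than two adjacent mismatch positions;
3. no adjacent mismatches in positions 2–12;
4. no mismatch at positions 10–11;
5. at most 2.5 weighted mismatches in positions 1–12;
6. duplex MFE ≥ 74% of the MFE of the miRNA bound to its perfect
   complement (ratio of magnitudes, computed once per miRNA).

Adjacency under G:U wobbles is undefined in the published rule set, so
it is a documented toggle with strict defaults: for rule 2 a G:U counts
as a mismatch event (but 0.5 toward totals); for rule 3 only runs of
two *full* mismatches reject; for rule 4 a G:U at the cleavage
positions rejects. Scanning is sense-strand only over spliced cDNA, the
alignment admits no gaps, and hits are deduplicated per
(miRNA, transcript) keeping the lowest weighted total, then the highest
energy ratio, then the smallest coordinate.

# Pair integration

For each comparison, pairs are the DE-miRNAs crossed with their
predicted targets that are themselves DE genes in the same comparison.
Each pair's expression profiles are correlated across the six replicate
libraries of the two compared stages; three stage means would leave one
degree of freedom and degenerate p-values, so the per-library reading
is the default (a three-point stage-mean mode can be had by passing
stage means directly). Profiles are log2(x + 1)-transformed before
correlation — a variance-stabilising choice, exposed as a toggle. The
two-sided p uses the t transform with n − 2 degrees of freedom.

Classes follow the strict published boundary: **negative** iff
−1 < r < −0.8 and p ≤ 0.05 (r = −1 itself is excluded by the open
interval; in practice it occurs only for degenerate profiles),
**positive** (mirrored convention) iff r > 0.8 and p ≤ 0.05, otherwise
**none**. The published account of positive pairs prints no threshold;
mirroring the negative one is the only symmetric choice. Unique
DE-miRNA and CTG cardinalities are set sizes over the negative class.

# Enrichment

Term enrichment is the hypergeometric upper tail P[X ≥ k] for k study
genes among K annotated population genes, with the population defaulting
to all genes in the expression matrix — the same universe the targets
were drawn from. FDR is Benjamini–Hochberg within each annotation
namespace (BP/MF/CC tested separately); terms with fewer than two
annotated population genes are untestable and skipped with a message.
No parent-term propagation is applied: annotation maps are taken as
given. The rich factor k/K is emitted for dot plots.

# The synthetic study

The generator emulates the study design end to end: a 100-kb genome
carrying 120 two-exon genes, 3 repeat regions and 8 planted hairpin
loci; a 30-entry catalogue (half focal species, half other species,
each with a constructed precursor); structural-RNA reference sets; nine
gzipped FASTQ libraries of 200,000 reads (3' adapter appended to every
insert, Phred 40 everywhere except planted artifacts); a gene count
matrix; and a gene→term annotation map. Planted ground truth covers
hairpins, DE miRNAs, target sites and negatively correlated pairs.

Hairpins are constructed with a perfect 19-bp stem and 2-nt 3'
overhangs, flanks and loop drawn from an A/C alphabet so they cannot
pair with each other, and are accepted only after the package's own
validator confirms all structural criteria, the mature occurs exactly
once in the genome, and the discovery routine recovers the locus.
Recovery tests on synthetic data therefore measure the pipeline's
plumbing — QC, collapsing, annotation precedence, excision, criteria
evaluation — not folding luck; this is stated here deliberately.

Counts are negative-binomial with mean = depth × relative abundance and
the configured dispersion (default 0.05), matching the assumptions of
the DE test so parameter recovery is a fair check. Twelve miRNAs
(drawn from the lower-abundance half, alternating direction so the
compositional shift between stages stays small) receive an 8-fold
(log2FC = 3) effect in one stage. Each DE miRNA gets two planted target
genes; with probability 0.8 a target is anti-regulated (the mirrored
multiplier), producing the planted negative pairs. Planted sites carry
0.5–1.5 weighted mismatches, never zero: an exact-complement site would
make the mature map antisense to the exon, and the annotation cascade
would (correctly) claim it before discovery. Each planted site is also
checked against the duplex energy-ratio rule at planting time, falling
back to lighter mismatch loads until it passes, so the scanner recovers
every planted site by construction. Star strands are sequenced
at ~4% of the mature abundance, which realistically produces additional
novel records at planted loci; these are re-validated rather than
counted as errors.

Planted QC artifacts (fractions of each library) exercise every removal
branch deterministically: 0.4% 5'-adapter contamination, 0.25% adapter
dimers, 0.2% reads with two Phred-19 bases, 0.1% reads with an N. They
are drawn class-independently, so clean-read class proportions still
track the configured mix.

What the generator does **not** emulate: sequencing error models and
instrument quality-score distributions; isomiR heterogeneity;
multi-mapping repeat families; intron-spanning degradation fragments;
compositional library effects beyond the small planted shifts; any form
of genome annotation error. Passing tests on synthetic data show the
procedures are implemented as specified and recover what they plant —
not that the thresholds are optimal for real tissue.

All randomness flows through one seed; the same configuration produces
byte-identical output files. The problem sizes used in the shipped
checks — 200k reads × 9 libraries for recovery runs, 10,000 features
for test calibration, 30 replicate simulations for power — were chosen
as the smallest sizes at which the binomial error of the measured rates
is well inside the margins being asserted.

# Known limitations

* The folding model is intentionally reduced; absolute MFE values are
  model-internal and the −18 kcal/mol precursor bound should be
  re-examined before applying the package to sequences folded with a
  full parameter set.
* Exact-match annotation has no mismatch tolerance; real catalogues
  with sequence variants need upstream normalisation.
* The exact NB test assumes a common dispersion; strongly tagwise
  dispersion will make it anticonservative for the noisiest features.
* The correlation step treats replicate libraries as independent
  samples; batch structure between replicates is not modelled.
* The toy genome is a single chromosome without Ns or overlapping
  genes; coordinate handling for multi-chromosome genomes is supported
  but exercised only lightly.
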