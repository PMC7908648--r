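---
title: "Methods: integrating read-depth and read-pair evidence for structural variants"
author: "svintegrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating read-depth and read-pair evidence for structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svintegrate)
```

## Overview

Short-read WGS exposes structural variation through three complementary
signals: the depth of coverage (DOC) changes that gains and losses leave on
the read pileup, the discordant read pairs (DP) whose mapping distance or
orientation is inconsistent with the reference, and the split reads (SR)
whose alignment crosses a breakpoint. DOC-driven callers detect dosage
changes robustly but with boundary uncertainty on the order of their window
size; SR/DP-driven callers place breakpoints at base-pair precision but
fail where breakpoints land in repeats. `svintegrate` implements the layer
that consumes candidate calls from one caller of each family, plus the raw
DP/SR/coverage evidence, and produces a single annotated, genotyped,
quality-classified, frequency-annotated call set.

This vignette documents the model, the tunable parameters, the synthetic
data generator the test-bed runs on, and the design decisions taken where
the procedure was genuinely open.

## Evidence extraction

Discordant-pair extraction needs per-sample insert-size cutoffs. The
mapping distances of normally oriented pairs in a sampling region (default
4 Mb, mirroring a standard early-chromosome window, configurable) are
sorted; walking the sorted list from the top and accumulating the count,
the upper cutoff is the distance at which the running count reaches an
average of 100 pairs per Mb of the region; the lower cutoff is obtained
symmetrically from the bottom. Operationally this is the k-th largest
(smallest) distance with k = 100 x region-Mb; ties resolve toward the more
permissive cutoff. A pair is discordant when it is inter-chromosomal,
mis-oriented (anything but FR), or outside `[lower, upper]`. Duplicates and
pairs in excluded regions (maximal intervals above 300x coverage) are
dropped; a mapping-quality floor is exposed (`mq_floor`, default 0) because
the evidence-level filtering rules do not prescribe one.

Split reads are filtered for exactly the pathologies that make a junction
record untrustworthy: reads on decoy contigs (default `NC_007605`,
`hs37d5`), reads with more than one clipped part, reads whose primary and
clipped alignments overlap on the same contig, and reads whose clipped part
has more than one supplementary alignment. Surviving reads are normalized
to junction records carrying the two breakpoint-proximal coordinates.

All coordinates in this package, internal and user-facing, are 1-based
inclusive — the Bioconductor/IRanges convention. Interval length is
`end - start + 1`, and reciprocal-overlap arithmetic is carried out in the
same convention throughout, so all thresholds are convention-consistent.

## Depth of coverage: DRA, DRF, genotype

Coverage lives in fixed-width bins (default 100 bp) alongside a per-bin
average mapping quality. DOC over an interval is the overlap-weighted mean
of bins whose MQ is at least 50; when less than one third of the variant
length qualifies, the restriction is dropped (and recorded), since in
low-mappability regions a hard MQ cut would leave no signal at all.

The autosomal baseline is the median across autosomes of the mean depth in
one fixed 10-Mb window per autosome (positions 20,000,001-30,000,000 on
human-scale contigs; toy contigs fall back to the whole contig). The
median makes the estimate robust to a whole-chromosome aneuploidy in any
single autosome. X uses the entire chromosome, Y its two large unique
intervals, and both are expressed as ratios to the autosomal baseline
rounded to the nearest 0.5 — so an XY male gets X and Y baselines of half
the autosomal depth and a haploid deletion on X still produces DRA near 1
for normal coverage. DRA divides the variant's DOC by this
chromosome-appropriate baseline; DRF divides it by the mean of the two
flanking regions of the same length as the variant (a single flank at
contig edges; undefined when neither exists, in which case the CNV flag
falls back to DRA alone).

The CNV flag is `DRA or DRF < 0.8 or > 1.2`. Genotypes come from DRA
alone: `[0.2, 0.8)` and `(1.2, 1.75]` are heterozygous, `< 0.2` and
`> 1.75` homozygous, the rest copy-neutral. The bins partition the DRA
axis with no gaps (property-tested on a dense grid). A copy-number point
estimate `round(DRA x ploidy)` is reported alongside, using the rounded
sex-chromosome ratios as chromosomal ploidy, which is what aneuploidy
reporting needs.

The population coverage dispersion track is the per-1-kb-interval standard
deviation of DRA across the control cohort. It is the population SD
(divide by N): the cohort is the full reference set and the track is
descriptive, not an inferential estimate of a larger population.
The 1-kb grid is anchored at position 1, i.e. intervals `[1,1000]`,
`[1001,2000]`, ...; a variant is attributed to every interval it overlaps
by at least one base.

## Integration

DOC-caller calls first have any reference-masked (N) spans excised,
splitting the call and discarding zero-length parts; splitting precedes
cross-sample merging (the opposite order is defensible, but split-first
guarantees no output call ever overlaps the mask). Each DOC call is then
annotated with the DP/SR records whose two ends fall inside the breakpoint
evidence windows — the outer limit is 1% of the CNV length clamped to
[1 kb, 5 kb]; the inner limit is half the CNV length capped at 5 kb — and
whose orientation matches the event (deletions: inward FR; tandem
duplications: everted RF; inversions: same-strand FF/RR).

Two calls are mergeable when they share an event class (loss with loss,
gain with gain, inversion with inversion) and either overlap reciprocally
by at least 70% of each call's length or leave at most 200 bases of
non-overlapping residue per call. Cross-sample merging collapses
single-linkage connected components to one call with the average start and
end, retaining per-sample evidence and taking the per-sample maximum of
read counts (members of a component can share reads, so summing would
double-count). DOC calls then merge into SR/DP calls under the same rule,
keeping the SR/DP coordinates because they are breakpoint-precise. When
one call could fuse with several partners, the pair with the highest
reciprocal overlap wins and the rest pass through unmatched; ties break
deterministically toward the smaller start coordinate. Translocation
breakends pass through integration unmerged.

In joint batches, a deletion or duplication supported by depth in some
samples but only by DP/SR in others is emitted twice: one CNV call
restricted to the depth-supported samples and one copy-neutral call for
the rest, so dosage-bearing and dosage-neutral carriers are never
conflated.

## Confidence tranches and quality attributes

The tranche rules are threshold rules on size, evidence and mapping
quality, exposed in `tranche_rules()` for recalibration:

| class | HIGH | PASS |
|---|---|---|
| CNV | > 100 kb; or > 10 kb and avg MQ > 55 | > 10 kb; or <= 10 kb and SU >= 2 |
| copy-neutral SV | SU >= 10 with >= 1 SR and >= 1 DP | SU >= 6 |

Everything else is LOW. "Spanning read" support for copy-neutral SVs is
read as the discordant-pair source, SR and DP being the two read-evidence
channels. The rules are monotone in read support (property-tested): more
evidence never demotes a call. Pass CNVs at or below 10 kb are gated on
evidence counts only, not on an additional depth criterion — the quoted
rule is count-only, and the depth requirement is already embedded in the
CNV flag itself.

Quality attributes: average MQ across the variant and in +/- 500 bp windows
around each breakpoint (the window size is this package's choice; the
breakpoint neighborhood is what read evidence actually samples); GC
percent over unambiguous bases; the sequence compression ratio, i.e.
compressed byte length over sequence length, with the compressor pinned to
DEFLATE (gzip container, default level) so the ratio is bit-reproducible —
tandem-repeat sequence compresses markedly below complex sequence; and the
best-matching segmental duplication, scored as overlap (% of variant
length) plus sequence similarity (%), the argmax over overlapping records.

## Population allele frequencies

Five estimates, three from the control cohort database and two from
external sets:

- **PAFSU = SUC / SU / NCS.** SUC sums control DP/SR counts within 1000
  bases of either breakpoint with event-consistent orientation; SU is the
  variant's own support; NCS the cohort size. With SU = 10, SUC = 200 and
  NCS = 500, PAFSU is 4%. The two breakpoint windows are summed without
  deduplication (for variants longer than 2 kb the windows are disjoint
  anyway). PAFSU is an abundance ratio, not a proportion: it can exceed 1
  and is documented as unbounded above.
- **PAFDRA**: the fraction of control samples showing the same direction
  of depth change (loss < 0.8, gain > 1.2) over at least 90% of the CNV's
  overlapped 1-kb intervals; sub-kilobase CNVs use their single interval.
- **PAFV**: carrier fraction of the best-matching called Pass/High control
  variant. Matching requires the SV type and CNV state to agree; then
  copy-neutral SVs match within 1000 bases per breakpoint, and CNVs match
  when the overlap covers at least 20% of the reference variant and at
  least 90% of the query. Query CNVs under 1 kb substitute a 70%-of-query
  clause for the 90% clause while the 20%-of-reference clause is retained —
  the sub-kilobase rule is stated only for the query side, and keeping the
  reference-side floor prevents a 500-bp call from matching a megabase
  reference record.
- **PAF1KG / PAFG**: allele frequency of the best-matching record in an
  external reference set, by the same matching rules. PAFG is
  annotation-only.

A variant is common when any of PAFV, PAFSU, PAFDRA or PAF1KG is strictly
greater than 0.01; otherwise rare. PAFG is excluded from the rule by
design; missing values count as zero.

## Annotation and prioritization

Gene annotation is any overlap with the gene body (pseudogenes excluded at
load time), with configurable padding defaulting to zero; exon-aware
refinement and breakpoint-uncertainty padding are reporting policy, not
pipeline logic. Disease terms join per gene from a prepared mapping table.
With a pedigree, IA/IUA count called carriers among affected/unaffected
individuals (unknown status counts in neither; carriers are genotype-level
calls, not raw evidence). The prioritized subset is rare AND gene-
overlapping AND tranche HIGH or PASS; the filter is idempotent.

## Concordance evaluation

`match_callsets()` implements the benchmarking rule used throughout the
test-bed: a truth variant is recovered when a same-type query call has
both breakpoints within 1000 bases or at least 80% reciprocal overlap, or
— in multipart mode — when several HIGH/PASS query parts jointly cover it,
with the union of parts required to satisfy the reciprocal-overlap
criterion itself (this keeps a scatter of small calls from "covering" a
large variant they jointly misrepresent). Sensitivity is TP / (TP + FN);
unmatched query calls are false positives. Microarray-style comparison
uses 50% reciprocal overlap with the breakpoint clause disabled.
One-to-many matching exists only in multipart mode; otherwise matching is
greedy best-overlap with coordinate tie-breaks. Tightening either
criterion never increases TP (property-tested).

## The synthetic data generator

The generator emulates evidence, not reads: per-bin coverage is drawn as
`rpois(depth x bin/read_length x CN/2) x read_length/bin` (so a 30x
baseline has per-bin noise around 22% CV at 100-bp bins), DP and SR records
cluster at planted breakpoints with Poisson counts of mean
`depth x allele_fraction` (DP) and half that (SR), correct per-type
orientation, and fragment-length-scaled offsets. Low-mappability patches
depress the MQ track and suppress evidence generation, emulating repeats.
Control cohorts draw carriers binomially at the configured carrier
frequency (carriers are heterozygous unless promoted) and summarize each
control's DRA directly on the 1-kb grid with Gaussian noise (sd 0.1,
matching the dispersion observed across most of a real genome) rather than
simulating full per-control coverage tracks — the database only ever sees
the 1-kb summary, and this keeps 500-sample cohorts instant.

Defaults are the study conditions: 30x depth, 150-bp reads, 450 +/- 75 bp
fragments, 100-bp bins, MQ 60 baseline, 5-kb minimum spacing between
planted variants. What the generator does **not** emulate: GC-coverage
bias, error profiles, chimeric artifacts, breakpoint microhomology, or
dosage-independent complex rearrangements. Passing tests therefore
demonstrate the correctness of the integration arithmetic and its
behavior under idealized evidence — not caller performance on real
libraries.

A deliberately naive fixed-bin segmenter (`naive_doc_segmenter`: running
median of the DRA track, threshold at the CNV band, minimum run length 10
bins) exists solely to derive DOC-caller-shaped candidate input from
simulated tracks. It is not a reimplementation of any published caller and
is not part of the analysis surface.

## Numerical choices and degenerate inputs

- Insert cutoffs error below 1000 sampled distances; the threshold index
  is rounded, and a pathological distribution where the k-th smallest
  exceeds the k-th largest collapses to the observed range.
- Division by a zero baseline (genome average or flank) raises an error
  (DRA) or leaves the ratio undefined (DRF) rather than propagating Inf.
- `compute_gc` returns NA (flagged) on all-ambiguous intervals; the
  compression ratio requires at least 50 bases.
- Zero control SD leaves a QC z-score undefined and flags the metric for
  review. A sample passes QC when at most half of its metrics with defined
  z-scores fall outside |z| <= 2 ("most metrics within 2 SD").
- All writers are deterministic given identical input; no timestamps are
  embedded.
- The IGV session references 11 review tracks (control DOC, sample DOC —
  rendered over all reads or MQ >= 20 from the same resource — MQ, DOC SD,
  segmental duplications, integrated calls, DP, SR, control-cohort calls,
  known-variant database, genes); a missing track path errors, naming the
  gap.

## Problem sizes used by the test-bed

The suites run on: a 50-Mb single-contig genome with 200 planted DEL/DUP
of 0.5-500 kb (log-uniform) for the end-to-end sensitivity harness; a
10-Mb genome with 200 deletions and a 200-sample cohort for frequency
recovery; 1000 random interval pairs and 40 random clusters for the merge
oracles; 500 random query/truth sets for the matching oracle; and dense
grids for the threshold partitions. These sizes were chosen so each
property is tested well inside its asymptotic regime while the whole suite
stays interactive.

## Known limitations

- BAM ingestion is delegated to upstream extractors; the package consumes
  normalized alignment-record and evidence tables (the equal first-class
  input path). Breakend (BND) records pass through integration unmerged.
- Copy-neutral SVs are not classified into mobile-element-insertion
  subtypes.
- The control database loads fully into memory; at human scale with
  hundreds of controls a coordinate-indexed on-disk layout would be
  preferable. The directory layout (breakpoint count tables, per-contig
  1-kb DRA matrices, control variants) is designed so such an index can be
  added without interface change.
- DRF-based genotyping is deliberately absent: genotype is defined purely
  on DRA, and DRF serves the CNV flag only.
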