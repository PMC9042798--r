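---
title: "Circle-Seq eccDNA analysis: models, parameters and design choices"
author: "CircleSeqTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circle-Seq eccDNA analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CircleSeqTools)
library(GenomicRanges)
```

# Scope

CircleSeqTools analyses aligned Circle-Seq data: it calls extrachromosomal
circular DNA (eccDNA) from junction evidence, filters the calls, and
computes the population-level statistics used to characterize cell-free
eccDNA — size periodicity, GC contrast against flanks, genomic-element
and repeat enrichment against a random null, junction microhomology, and
cohort contrasts. Because real Circle-Seq cohorts are large and external,
the package ships a first-class simulator whose outputs carry the
statistical structure the analysis assumes; every claim the test suite
makes is validated against that known truth.

# Coordinates

All tabular input/output (Circle-Map-style TSV, BED) is 0-based half-open,
so circle length is `end − start`: a record spanning 7,712,600–7,712,978
is a 378-bp circle. Internally circles are `GRanges` (1-based closed); the
conversion preserves `width(gr) == end − start`. A circle's two junction
coordinates are its 0-based `start` (first base inside) and `end` (first
base outside); junction windows of half-width $w$ are
`[start−w, start+w)` and `[end−w, end+w)` on the plus strand.

# Circle calling

A split read — a primary alignment carrying an `SA` tag whose
supplementary segment maps to the same chromosome — witnesses one
junction: the cluster interval is `[min(segment starts), max(segment
ends))`. Split reads are clustered with a ±5 bp breakpoint tolerance; the
consensus breakpoint is the modal coordinate, ties toward the smaller
value. Discordant pairs (outward orientation: leftmost mate on the
reverse strand) falling inside a candidate support it. Coverage metrics
use primary alignments only (no supplementary/secondary/duplicate/QC-fail
records).

The six-criterion filter retains candidates with

* split reads ≥ 2,
* circle score ≥ 20, where the score is $\sum \min(\mathrm{MAPQ}, 10)$
  over supporting split reads — a deliberate surrogate for realignment
  probability scores of dedicated callers, chosen so that two uniquely
  mapped split reads satisfy the split and score defaults simultaneously,
* coverage increase ≥ 0.33 at both breakpoints, computed as
  $(c_{in}-c_{out})/c_{in}$ over 50-bp windows just inside/outside (0.33
  means inside ≥ 1.5× outside; 0 when $c_{in}=0$),
* coverage continuity (fraction of zero-coverage positions inside)
  ≤ 0.1,
* coverage SD strictly smaller than mean coverage.

All comparisons are inclusive except the SD criterion. Deduplication is
by exact `(chrom, start, end)`, keeping the highest-scoring duplicate;
intervals differing by one base remain distinct.

**Outside-window masking.** The coverage-increase windows measure linear
background. When two true circles overlap or sit within 50 bp of each
other, the naive window reads the neighbour's circular coverage and the
ratio collapses, discarding genuine circles (about 7% of planted circles
at the densities used in the tests). Positions inside *another* candidate
interval are therefore excluded from the outside windows. This is a
design choice of this package's surrogate metrics; it does not claim
equivalence with any external caller's definition.

# EPM and cohort statistics

EPM (eccDNAs per million mapped reads) is
`n_circles / (mapped_reads / 1e6)`, invariant under joint scaling of
circle and read counts. Group EPM is compared with a two-sided Wilcoxon
rank-sum test — exact enumeration when both groups have ≤ 10 samples and
no ties (the exact 3-vs-3 p for fully separated groups is 0.1, which the
test suite checks against a hand-rolled enumeration oracle), otherwise
the normal approximation with tie-corrected variance. Group means carry
normal-theory 95% CIs (mean ± 1.96 SE); a bootstrap CI was considered and
rejected as overkill at cohort sizes of 10–30. Correlations are Pearson
product-moment with the t-transform p on n − 2 degrees of freedom;
degenerate (zero-variance) input is an error, except in the
per-chromosome density table where a constant vector is reported as r = 0
(no detectable association) rather than undefined.

A circle "carries" a miRNA gene only under full containment
(`circle.start ≤ mirna.start` and `mirna.end ≤ circle.end`); recurrence
counts distinct samples with at least one carrying circle (multiple
carriers in one sample count once for recurrence; the total carrier count
is reported alongside and breaks ranking ties, then the miRNA id).

# Element enrichment and the random null

The expectation baseline draws circles chromosome-proportionally
(probability ∝ chromosome length), start uniform, size uniform on
150–850 bp, resampling (not clipping) circles that run off a chromosome
so the size distribution is preserved. "Weighted average of chromosome
length" is read as length-proportional chromosome sampling — the only
interpretation that yields a genome-wide expectation. No assembly-gap
masking is applied (the toy genomes have none; real use can pre-filter
the annotation).

For an element class, `expected_fraction` is the merged class length over
genome length. For `observed_fraction` the default convention counts
junction endpoints in the class over all $2n$ endpoints. This choice is
deliberate: it is calibrated so uniform random circles give ratio 1.0 for
*any* class geometry. The alternative — counting a circle once when
*either* junction falls in the class — inflates the null ratio toward 2
for element classes much shorter than a circle (two nearly independent
chances per circle), which would make "enrichment" partly an artefact of
element length. That circle-level convention remains available
(`mode = "either"`), and is the rule used for the *intragenic* fraction,
where genes are long relative to circles and the circle-level reading is
the natural one (uniform circles over genes covering 40% of a genome give
an intragenic fraction of ≈ 0.40).

The repeat "normalized mapping ratio" divides the fraction of
primary-aligned reads overlapping a repeat class by ≥ 1 bp by the class's
genome fraction; a read overlapping two classes counts once per class.

# Size and GC distributions

Circle lengths are summarized by a Gaussian KDE (default bandwidth 5 bp,
chosen to resolve the ≈ 150–200 bp nucleosomal inter-peak spacing).
Peaks are local maxima with height ≥ 5% of the global maximum, with two
numerical safeguards:

* **Minimum separation** (10× bandwidth): at small bandwidth, sampling
  noise can split one component into two adjacent local maxima; the
  lower of two maxima closer than 50 bp is dropped.
* **Mean-shift localization**: the raw KDE mode of a minor component
  (weight 0.06 at n = 10,000 circles) has a standard error near 4 bp,
  which is too noisy to report peak positions at ±5 bp. Peak *detection*
  stays kernel-based, but each reported position is refined by a local
  mean (window bounded by half the distance to the nearest peak, at most
  8× bandwidth, iterated three times). For a symmetric component this is
  unbiased and has standard error under 1 bp.

GC is (G+C)/(A+C+G+T) with ambiguous bases excluded from the denominator;
an all-N window is flagged as undefined. Each circle is compared against
upstream/downstream flanks of its own length; circles whose flanks do not
fit on the chromosome are flagged and excluded from the flank comparison.
Reported "peak values" are argmaxes of a bandwidth-0.01 KDE over
per-circle GC.

# Junction motifs

Direct repeats are exact-match longest common substrings of the two
junction windows, length in `[4, min(18, 2w)]`, ties broken by the
smaller start-window offset then the smaller end-window offset (offsets
are signed positions relative to the junction). The search window is the
±10 bp extraction by default, so repeats longer than 10 bp are reported
at length 10 unless `w` is raised (set `w = 18` for full-range
detection); no mismatches are allowed. The implementation is a
common-suffix dynamic programme and is tested for exact agreement with a
quadratic brute-force oracle on random windows.

A palindromic unit is a 10-bp decomposition `t1 + spacer(4) + t2` with
`t2 = revcomp(t1)`. By default the unit must straddle the junction (first
base strictly before it, last base at or beyond it), matching the idea of
repeats flanking the breakpoint; `straddle = FALSE` scans whole windows.
Per-base nucleotide frequency matrices (4 × 2w, columns summing to 1 over
A/C/G/T) are computed per junction side, optionally within size bins
whose default edges are the midpoints between the 207/358/553/732 bp
peaks.

# The simulator: what it emulates, and what it does not

`generateReference` builds chromosomes of i.i.d. bases at the background
GC (default 0.41), then plants: non-overlapping protein-coding genes
(exon/intron structure, terminal-exon UTRs, strand-aware 2-kb flanks;
gene placement leaves ≥ 4.2 kb gaps so flanks never reach a neighbouring
gene), CpG islands whose sequence is rewritten at GC 0.65, repeat classes
per the element plan (defaults SINE 10%, LINE 6%, LTR 4%, simple repeats
2% — toy stand-ins at roughly genomic proportions), and 60–100 bp miRNA
genes placed half inside gene bodies, half intergenic.

`sampleTrueCircles` draws sizes from a four-component truncated-normal
mixture, by default at 207/358/553/732 bp with weights
0.06/0.82/0.06/0.06 (the second peak an order of magnitude above the
others, the mono- to tetra-nucleosome ladder of cell-free DNA), sd 20 bp,
truncated to [50, 2000] bp since nearly all observed cell-free circles
are below 1 kb. Origins are drawn with weight
$\propto \exp(\beta \cdot \mathrm{GC}_{200bp})$; $\beta = 2$ by default,
a mild preference consistent with the reported GC-richness of cell-free
eccDNA. Junction motifs are planted by rewriting the genome *before* read
simulation (direct repeat: the start-junction substring is copied to the
end junction, length uniform on 4–18 bp, probability 0.66; palindromic
unit: probability 0.4, written straddling the start junction). Planting
probabilities are fixed once: 0.66 mirrors the reported fraction of
junctions with detectable repeats, and 0.4 is a realistic middle ground
for a motif whose true planting rate the source data only shows
qualitatively. Overlapping rewrites are applied last-wins and logged.

`simulateReads` draws fragments on circular coordinates (positions modulo
circle length — rolling-circle concatemers), emitting a junction-crossing
read as a split alignment (primary + supplementary with `SA` tags), a
junction-straddling fragment without a crossing read as an outward
discordant pair, and genome-wide proper pairs as linear background
(default 150-bp reads, fragment 300 ± 60 bp, MAPQ 60 for planted reads, a
5% MAPQ-0 fraction among background reads to exercise the score
surrogate). Expected junction-spanning coverage equals `circleDepth`.
Circles shorter than a read are wrapped and soft-clipped, never dropped.

Deliberately *not* modelled: sequencing errors and quality strings,
adapters, PCR chimeras and duplicates, multi-fragment circles spanning
chromosomes, mappability structure, and isochore-scale GC heterogeneity.
Two consequences matter when reading test output. First, the toy genome's
between-window GC variance is far smaller than a real genome's, so with
$\beta = 2$ the circle-vs-flank GC peak shift is subtle (fractions of a
percentage point), unlike the multi-point contrast seen in real data; the
simulator tests the *machinery* of the GC profile, not its real-data
effect size. Second, because reads are generated per circle at fixed
junction depth, a sample's mapped-read count scales with its circle load,
so the EPM contrast between a 3× cohort and its control is compressed
relative to the circle-count ratio (the rank-sum test still separates the
groups decisively); in a real experiment sequencing depth is set by the
run, not by circle load.

`simulateCohort` derives per-sample seeds from a master seed, gives the
disease group its own configuration (typically a higher circle rate
and/or size shift) and plants a configurable set of recurrent circles,
each fully containing a chosen miRNA gene, in every disease sample.

# Problem sizes and run times

The test suite validates: breakpoint recovery on 200 planted circles at
12× junction depth over 2 × 500 kb (≥ 90% exact recovery required;
observed ≈ 99%); zero calls from pure linear background; null
calibration of all eleven annotated element classes with 50,000 random
circles on 2 × 1 Mb (ratios within [0.9, 1.1]); the four size peaks from
10,000 simulated circles within ±5 bp; 500-window brute-force agreement
for both junction motif searches; and an 8 + 8 cohort at a 3× disease
circle rate (rank-sum p < 0.05; planted recurrent miRNA circle ranked
first with recurrence 8). These sizes keep the full suite in the
few-minute range on one core while leaving each statistical check a
comfortable margin over its own sampling noise.

# Known limitations

* The circle score, coverage-increase and continuity metrics are
  documented surrogates, not re-implementations of any external caller's
  probabilistic model; thresholds share only their nominal values.
* Deduplication is per sample; pooled cohort totals are reported
  aggregates, not cross-sample deduplicated sets.
* The junction-endpoint enrichment convention makes ratios comparable
  across element classes of different lengths, at the cost of departing
  from a circle-level count; both conventions are exposed.
* Direct-repeat detection is exact-match within the extraction windows;
  mismatch-tolerant microhomology search is out of scope.
* The simulator's genome lacks long-range GC and mappability structure,
  so genome-scale correlations (e.g. density vs gene content) are only as
  strong as the planted structure.
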