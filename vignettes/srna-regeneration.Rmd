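---
title: "Profiling small RNAs in regenerating planarians: methods and design"
author: "srnaregen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling small RNAs in regenerating planarians: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaregen)
```

## The analysis

Planarians such as *Dugesia japonica* regenerate a complete head within
days of decapitation. Small RNA sequencing over a regeneration time course
(0 h, 24 h, 72 h and 120 h post amputation) asks which classes of small
RNAs — microRNAs, tRNA fragments (tRFs) and PIWI-interacting RNAs
(piRNAs) — change in abundance, and which individual species rise early
enough to be candidate regulators of regeneration.

`srnaregen` implements that analysis as a tested pipeline:

1. **QC** (`filter_reads`): five raw-read filter rules with per-rule
   accounting, adapter trimming, and collapsing to unique sequences.
2. **Mapping** (`map_reads`, `besthit_filter`): ungapped genome alignment
   with up to 3 substitutions, then per-read best-hit filtering allowing
   at most one internal mismatch and two non-template 3' nucleotides.
3. **Annotation** (`classify_reads`): a precedence cascade
   miRNA > tRNA > rRNA > mRNA > repeat > none, with tRF typing against the
   mature tRNA termini and repeat sense/antisense accounting.
4. **miRNA discovery** (`find_mirna_loci`, `assign_names`): de novo locus
   calling with hairpin-duplex criteria and homology naming by local
   alignment E-value.
5. **piRNA diagnostics** (`select_candidates`, `u1_fraction`,
   `pingpong_profile`, `pingpong_matrix`, `predict_clusters`,
   `merge_clusters`): 5' uridine bias, the ping-pong signature, and
   cluster prediction.
6. **Expression dynamics** (`build_matrix`, `cluster_rows`,
   `select_upregulated`): per-class RPM matrices, average-linkage/Pearson
   clustering with row Z-scores, and candidate selection.
7. **Downstream** (`scan_targets`, `go_enrichment`,
   `regen_target_comparison`, `classify_phenotype`, `pr_stats`): seed-based
   target scanning on 3' UTRs, chi-square GO enrichment with Bonferroni
   correction, and knockdown phenotype scoring.

Every stage is driven by a synthetic-data generator (`build_genome`,
`simulate_library`) that plants the features and statistical structure the
analysis assumes, together with per-read truth labels, so the whole
pipeline is verifiable without any external downloads.

## The synthetic data generator

The generator is first-class, tested code, not a fixture. `build_genome`
plants non-overlapping features in random contigs:

* **miRNA hairpins**: two 22-nt arms around a 15-nt loop. The 3' arm is
  the reverse complement of the 5' arm with three interior substitutions.
  The imperfection matters twice: perfectly complementary arms would let
  every mature read map to both arms (on opposite strands), destroying
  both best-hit uniqueness and the strand-bias signal that miRNA locus
  discovery relies on; real hairpins are likewise imperfect. The planted
  star read carries the canonical 2-nt 3' overhang of the miRNA/miRNA*
  duplex, and the hairpin truth interval includes that overhang template.
* **tRNAs** (72 nt, alternating strands), **rRNAs** (120 nt), **mRNAs**
  (600 nt with the final 200 nt annotated as 3' UTR).
* **repeat families**: a 200-nt consensus per family, planted as exact
  copies in both orientations; the last family is recorded with unknown
  orientation. Exact copies make repeat reads genuine multi-mappers,
  exercising the 1/placement weighting downstream.
* **piRNA clusters**: intergenic intervals (default 5 kb) from which
  piRNA reads are drawn.

Features are separated by at least 250 nt — more than the 200-nt
read-clustering gap used in locus discovery — so each planted feature
yields an unambiguous locus.

`simulate_library` draws class counts multinomially from `class_mix` and
emits reads with the structure the analysis assumes. Defaults are the
study conditions: a class mix of 13% miRNA, 13% tRF, 4% rRF, 5% mRNA, 21%
repeat and 44% piRNA reads (matching the observed mapped-read fractions),
read-length peaks at 22 nt (miRNA) and 30-34 nt (piRNA/tRF, uniform per
the reported piRNA length window), a 5' uridine fraction of 0.775 among
piRNA reads (the reported 77-78%), a 2.45-fold antisense excess among
repeat reads (reported 2.4-2.5), and a ping-pong pair fraction of 0.25
(the strength of the reported signature is not quantified as a fraction;
0.25 produces a clearly significant 10-nt overlap enrichment without
dominating the pool, and the detection tests also probe the boundary
value 0.2 and the null 0).

Two design points deserve emphasis:

* **1U is positional, not mutational.** A piRNA read "starts with T" by
  choosing a genomic 5' position whose base is T (on the proper strand),
  never by editing the read. Genuine reads are therefore exact genome
  substrings and mapping statistics stay clean.
* **Ping-pong pairs are geometric.** A pair is a plus-strand 5' end at
  position *p* and a minus-strand 5' end at *p* + 9 (a 10-nt 5' overlap).
  Because position 10 of the secondary read pairs position 1 of the
  primary, a 10A bias on secondaries arises automatically whenever the
  primary carries 1U; there is no separate 10A switch.

Artifact reads violate exactly one QC rule each: clean reads are emitted
as insert + 3' adapter at Q30 throughout, so each of the five filter rules
is independently triggerable (5 bases at Q9; 7 bases at Q12; a poly-A
insert; a prepended 5' adapter; a missing 3' adapter; an adapter-only
read; a 17-nt insert). Inserts that would trip a rule by chance — e.g.
containing the 8-nt adapter match k-mer, roughly a 5e-4 event per read —
are re-drawn, so planted artifact counts are exact. The generator does
not model sequencing errors, ligation bias or PCR duplicates; tests
passing on it show the pipeline's logic and calibration, not robustness
to those noise sources.

## QC rules and their order

A read is rejected by its first failing rule, in the order q10 (more than
4 bases below Q10), q13 (more than 6 bases below Q13), homopolymer (one
nucleotide at least 90% of the insert), 5' adapter contamination, missing
3' adapter, empty insert, insert shorter than 18 nt. The source protocol
does not state an order; this one puts sequencing-quality failures before
structural ones, which only affects attribution, never the kept set.
Quality rules are evaluated on the full read because whether the original
pipeline trimmed before or after quality filtering is not documented; the
3' adapter is located by an exact match of its first 8 bases (leftmost
match wins) and trimmed before the length check.

## Mapping and best-hit filtering

The mapper is a seed-and-verify k-mer index written in C++: a read of
length L mapped with at most m substitutions is split into m+1 chunks, at
least one of which must match exactly (pigeonhole), and candidate
placements are verified by Hamming count. `N` never matches and counts as
a mismatch at its position. Mismatches in the last two read positions (3'
end, read orientation) are counted separately as putative non-template
additions. Best-hit filtering keeps, per read, only placements at the
read's minimal total mismatch count, then discards placements with more
than one internal mismatch or more than two 3'-terminal ones. All
surviving placements of a multi-mapper are retained; downstream
statistics decide the weighting (class labels use any hit; cluster mass
uses count/placements). The test suite proves the mapper identical to an
exhaustive sliding-window Hamming scan on small instances.

## Annotation cascade

A mapped read is assigned the highest-precedence class among
miRNA > tRNA > rRNA > mRNA > repeat overlapped by any retained hit,
requiring at least 50% of the read inside the feature (both the
precedence order and the overlap quantum are conventions of cascade-style
small RNA annotators; the source does not state them). tRFs are typed
5'/3'/other by whether the read's 5' (3') end lies within 1 nt of the
mature tRNA's terminus on the same strand. Class fractions are
read-count-weighted by default; unique-sequence weighting is available by
passing unit counts.

## miRNA locus discovery

Reads pooled over libraries (mapped at up to 2 mismatches for this stage)
are clustered into loci separated by more than 200 nt; a locus is accepted
iff (a) at least 80% of its read mass lies on one strand, (b) the dominant
read length is 20-24 nt, (c) a read-supported star interval forms a duplex
with the mature arm in the register implied by 2-nt 3' overhangs, (d) the
duplex pairing fraction (Watson-Crick plus G:U) is at least 0.6, and (e)
mature plus star reads carry at least half the locus mass. Criterion (e)
is a precision requirement analogous to ShortStack's: without it, any
dense pile of fragments containing a chance-complementary interval pair
would be called a miRNA gene. The pairing check is a heuristic
complementarity count, not thermodynamic folding — deliberately desk-scale
and testable.

Homology naming aligns each locus sequence against known hairpins
(match +2, mismatch -3, blastn-like gap penalties) and computes an
ungapped Karlin-Altschul E-value (lambda solved numerically for the score
scheme, K = 0.41, search space = query length times database length); the
best hit names the locus if E < 1e-6, otherwise the locus is novel. With
locus and hairpin sequences of ~60 nt, a perfect match scores E below
1e-25 while the best chance alignment of unrelated sequences sits many
orders of magnitude above the cutoff, so the naming decision is robust to
the approximation.

## piRNA diagnostics

Candidates are mapped reads of 24-35 nt labelled `none` or `repeat`. The
lower bound is 24 nt rather than 30 so that the cluster criterion's size
window (reads within 24 to `pimax` = 35 nt) is meaningful; the source
variously reports a 30-35 nt prose window and 30-34 nt length peaks, so
the window is configurable.

The ping-pong profile accumulates, for each 5' overlap o in 1..30, the
mass n(o) = sum over opposite-strand 5'-position pairs of the product of
read counts at the two positions. Z(o) is computed against the mean and
sample standard deviation of all other overlaps; with fewer than two
overlaps carrying mass the background is undefined and all Z are reported
as 0 with a flag. Pair mass uses full read counts (the convention for the
headline statistic); the ping-pong length matrix accumulates mass of
exactly-10-nt-overlap pairs symmetrically at (len_a, len_b) and
(len_b, len_a).

Cluster prediction slides 1-kb windows (step 100 nt) of normalized mass
(count/placements per read); a window qualifies at mass >= 10 if its 1U
fraction is >= 0.5 or at least 75% of its mass falls in the 24-`pimax`
size window. Qualifying windows are merged, merged intervals are trimmed
to the span of their supporting reads (raw window unions overhang a
planted locus by up to a window length per side, which would misstate
cluster boundaries), and clusters shorter than 1 kb are dropped. Merging
cluster sets across libraries is a plain interval union. Pipeline-level
1U and ping-pong statistics are computed on the unannotated (`none`)
candidate fraction — the population the original 1U figure refers to —
while cluster prediction uses all candidates including repeat-derived
reads.

## Expression dynamics

Counts are normalized to reads per million within their own class per
library (so each matrix column totals 1e6 before filtering), entities
must reach 100 RPM in at least one timepoint, and rows/columns are
clustered by average linkage on the Pearson distance d = 1 - r. The two
clusters under the final row merge define group-a/group-b, oriented so
group-a has the higher mean row Z-score at 24 h (the early regeneration
response). Agglomeration is performed on raw RPM rows and Z-scores are
used for display and group orientation, matching the common heatmap
convention when the scaling step is not documented. Candidate selection
takes entities whose maximum post-amputation RPM is at least twice the
0 h value (entities silent at 0 h but expressed later count as
upregulated) with mean RPM >= 100. Note that RPM is compositional: a
planted k-fold rise in counts appears as less than k-fold in RPM when the
rising entities carry appreciable mass, which is why the acceptance
script plants 4-fold count risers to demonstrate 2-fold RPM selection.

## Downstream statistics

Target sites require a perfect antiparallel seed match of miRNA positions
2-8 on the 3' UTR (up to one G:U tolerated, no mismatch) plus a duplex
score over the full-length ungapped extension: Watson-Crick +5, G:U +2,
mismatch -3 per position with seed positions weighted twice, reported at
score >= 140 by default (a perfect 22-nt duplex scores 145). The doubled
seed weight plays the role of the 5'-region weighting in energy-based
target scanners; this scanner is a documented seed+score approximation,
not a reimplementation of an alignment/energy model, so absolute site
counts are not comparable with energy-based tools.

GO enrichment tests each term's 2x2 table (target genes vs non-target
background, with vs without the term) by an uncorrected Pearson
chi-square; terms with any expected cell below 5 are excluded from
testing (the usual validity rule, unstated in the source), and
significance uses the strict Bonferroni level alpha divided by the number
of tested terms.

Phenotype scoring classifies each animal as lesion/lysed (dominant flag),
no-PR, cyclopia, or — for paired photoreceptors — irregular iff the two
surface areas differ by more than 33% of the smaller one, the
photoreceptor distance relative to head diameter deviates more than 33%
from the control mean, or the surrounding white region is absent. The
smaller-area denominator makes 100 vs 140 area units a 40% difference and
hence irregular. Size comparisons use the pooled-variance (Student)
two-sample t-test, two-tailed, per the "two independent means" phrasing;
Welch is available behind a flag. For photoreceptor distances only the
variance ratio is reported, descriptively, because no test is named for
that observation.

## Numerical choices and degenerate inputs

* Determinism: both generator entry points take explicit seeds and
  restore the caller's RNG state; identical spec + seed gives
  byte-identical FASTQ and truth tables.
* Ties in agglomeration resolve to the lowest-index pair; cluster and
  locus calling are invariant to read input order.
* Constant expression rows get Z = 0 and a flag; correlation with a
  constant row is treated as distance 2 (the maximum), identical constant
  rows as distance 0.
* Empty inputs return empty, well-typed results (empty FASTQ, zero QC
  counters, empty locus/cluster lists); an undefined ping-pong background
  is flagged rather than producing NaN Z-scores.
* Reads shorter than 4 x (max_mismatch + 1) nt are rejected by the mapper
  (the seed index needs chunks of at least 4 nt); QC guarantees >= 18 nt.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
a 2 x 50 kb genome with 8 hairpins, 6 tRNAs, 2 rRNAs, 6 mRNAs, 3 repeat
families x 5 copies and 2 x 5 kb piRNA clusters; libraries of 50,000
reads for recovery checks, 100 x 2,000 reads for ping-pong calibration,
and 2-kb genomes with 200 reads for exhaustive mapper verification. These
sizes give 3-sigma binomial resolution of about +/- 1% on class shares
and sub-percent resolution on the 1U fraction while keeping the full
suite under a minute of compute.

## Known limitations

* The mapper is ungapped; indels and spliced alignments are out of scope.
* Hairpin evaluation is complementarity counting, not folding; loci with
  long bulged stems that a thermodynamic model would accept may be missed.
* The E-value uses ungapped Karlin-Altschul constants with a gapped local
  alignment score — adequate for the decision at hand (E thresholds
  separated by >20 orders of magnitude), not for reporting calibrated
  E-values near the cutoff.
* proTRAC-style cluster prediction is simplified (one window geometry,
  two piRNA-likeness criteria); concordance with proTRAC's exact output
  is not claimed.
* The target scanner approximates, and deliberately does not reproduce,
  miranda's alignment/energy model.
* Real-data headline figures (cluster counts, locus counts, class
  percentages of the published libraries) require the original libraries
  and genome; this package reproduces the methods and verifies them on
  synthetic data at desk scale.
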