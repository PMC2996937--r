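---
title: "Discovering putative miRNA from small RNA-seq and testing their target-site conservation"
author: "smallmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering putative miRNA from small RNA-seq and testing their target-site conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep small RNA sequencing of a tissue captures mature microRNA (miRNA)
together with degradation products, fragments of other non-coding RNA
(ncRNA), and assorted background transcription. Two questions drive this
package: which of the sequenced ~22-nt RNAs are processed from genuine
precursor hairpins that are not yet annotated, and which of those putative
miRNA are *functional* — that is, under evolutionary selection, visible as
conservation of the miRNA sequence itself and of the reverse-complement
target sites its seed addresses in 3'UTRs? The same machinery also detects
the opposite signal, *target avoidance*: a significant deficit of conserved
seed-match sites, the expected footprint of a small RNA whose targeting is
harmful (seen among miRNA-like fragments of snoRNA, tRNA and other ncRNA).

`smallmir` implements the full chain as testable components: read
preprocessing and exact mapping, annotation by majority overlap, local
hairpin folding and candidate filters, two independent precursor
classifiers, conservation classification against a composition-matched
genomic background, and the seed-family target-site conservation test.
Because the real inputs (a mammalian genome, tens of millions of reads, a
multi-species conservation track) are far beyond desk scale, the package
ships a synthetic-study generator with planted ground truth, and all
claims about the pipeline are made — and tested — against that truth.

## Pipeline stages and their parameters

### Reads

Raw reads are fixed-length (36 nt) and carry a 3' adapter. Trimming scans
adapter start positions left to right and accepts the leftmost position
whose adapter/read overlap (at least 6 nt) shows at most 3 mismatches;
reads with no acceptable position, or containing non-ACGT characters, are
discarded with counted reasons. Low-complexity inserts are removed with a
DUST-style triplet score (window 64 nt, threshold 2.0). Identical inserts
are collapsed; only sequences of 18–28 nt supported by at least 2 raw
reads proceed. Every raw read is accounted for across the stage
(conservation-of-reads is asserted in the tests).

Mapping is exact (no mismatches) on both strands, delegated to
`Biostrings` pattern matching behind the package's `build_index()` /
`map_reads()` surface; a read maps to the minus strand where its reverse
complement occurs on the forward genome. Multi-mapping reads keep all
placements, each carrying the full read count (`n_hits` records the
placement count so the policy can be revisited downstream).

### Annotation

A read belongs to a category (miRNA, ncRNA, repeat, exon, intron) when at
least half of its length falls inside a category interval — the boundary
is inclusive — with miRNA > ncRNA > repeat > exon > intron precedence and
intergenic as the fallback. Strand must agree for miRNA and ncRNA, whose
biogenesis is strand-specific; repeat/exon/intron overlap is
strand-blind. Star products of annotated precursors are called from reads
inside the precursor that overlap the annotated mature by less than half
and sit mostly on the arm across the loop, grouped by identical 5' ends;
stars out-expressing their mature, or exceeding 3,000 copies, are flagged.

### Folding engine

Local structure comes from a dynamic-programming *maximum weighted base
pairing* model: G-C = 3, A-U = 2, G-U = 1, minimum hairpin loop 3 nt,
deterministic traceback (ties resolved by leaving the 3' base unpaired,
else the leftmost partner). This is deliberately not a nearest-neighbour
thermodynamic model: it is dependency-free, exactly reproducible, and
small instances can be checked against exhaustive enumeration — the test
suite verifies DP optimality for every sequence up to length 8 and for
hundreds of longer random sequences. The score is a proxy for stability,
not kcal/mol; the folding contract is narrow enough that a thermodynamic
backend could replace the engine without touching any caller.

Two regularizations compensate for what the score model lacks. Because no
penalty discourages lone pairs, optimal structures are decorated with
spurious one-to-three-pair helices; helices shorter than 4 stacked pairs
are therefore pruned before stem-loop extraction (`min_stack = 4`).
Without the prune, junk helices masquerade as terminal loops or as
multiloop branches and corrupt the stem-loop topology. Second, during
extraction the outward walk stops at bulges/internal-loop sides longer
than 8 nt in the discovery pipeline (`max_bulge = 8`); otherwise stems
grow indefinitely through sparsely paired flanking sequence.

### Hairpin discovery

110-nt windows slide (stride 10 by default; 1 for small test genomes)
over the regions ±100 nt around mapped reads, merged per chromosome and
strand. Unbranched stem-loops with ≥ 20 base pairs are extracted, mapped
back to genome coordinates, and deduplicated per overlapping cluster
(highest pair count wins). Each surviving locus is then *refined*: a
window centred on the locus is refolded and re-extracted, because
off-centre windows systematically clip stems at their edge or extend them
into flank pairings. Reads within a stem-loop are grouped by identical 5'
end; the highest-expressed sequence of the strongest group becomes the
candidate mature, required to keep at least 16 nt inside the stem and not
to span the terminal loop. Candidates whose mature is exonic by the
majority rule are excluded; candidates inside annotated ncRNA are kept
but tagged `ncrna_derived` and analyzed separately.

### Two classifiers

**Structure approach.** A random forest over hairpin features:
length-normalized pairing score, the z-score and empirical p of the score
against 1,000 dinucleotide-preserving shuffles (Eulerian-path shuffle,
exactly preserving dinucleotide counts and terminal bases — a property
asserted on every test run), the 32 local triplet structure-composition
frequencies (computed on the pruned structure, consistent with the
extraction semantics that define candidates), stem length, loop size and
GC. Training fixtures are synthesized: positives are precursor-grade
hairpins passed through the same embed → fold → extract path as real
candidates; negatives are the best extractable stem-loops of random
(exon-like) sequence windows — what background transcription actually
offers the discovery stage (a relaxed 10-pair floor is used for the
negative pool, since 20-pair stems are vanishingly rare in random
sequence). Because random-forest vote fractions are poorly calibrated in
the mid-range, the reported score is a logistic recalibration of the
votes fitted on the out-of-bag predictions, making it an honest class
probability — which is what a fixed cut-off presumes. The pass rule is a
calibrated score of at least 0.70 (boundary inclusive). Training is
seeded and deterministic.

**Read-signature approach.** Biogenesis leaves a footprint in the reads:
5' ends pile up at the mature 5' end, a star product sits on the opposite
arm with 2-nt 3'-overhang duplex geometry, and the loop is read-poor. The
score `2·f5 + 1·star − 2·floop + 0.5·min(max(z,0),5)` is compared against
100 permutations of read positions within the precursor; candidates pass
at an add-one empirical p ≤ 0.01 (the smallest value 1/101 attainable at
100 permutations, i.e. the observed configuration must beat every
permutation). The weights are package constants, config-exposed.

Candidates passing *either* approach form the putative novel set; the
overlap of the two approaches is reported with an exact hypergeometric
upper-tail probability.

### Conservation

A candidate mature is conserved when the mean of its per-base
conservation scores (missing positions excluded) is at least 0.8,
boundary inclusive; an interval with no scored positions is never
conserved. The background expectation comes from 1,000 simulations that
re-place every candidate interval into intron/intergenic space, matching
each drawn interval's GC to the candidate set's aggregate GC within ±5%
(rejection sampling, with stepwise relaxation and a warning if matching
is infeasible). Matching in aggregate rather than per candidate keeps the
sampler feasible for short intervals while still controlling the main
compositional driver of conservation-score bias.

### Target-site conservation

Conserved matures are grouped into seed families (identical positions
2–8); the family's UTR-sense target motif is the seed's reverse
complement. Each 3'UTR is scanned with a 7-nt window at 1-nt steps,
skipping the first 15 nt after the stop codon; a window counts as
conserved when at least 3 of its positions are scored and their mean is
≥ 0.8. From the genome-wide table of per-motif totals `t` and conserved
counts `c`, the control conservation `p0` for a family pools `c` and `t`
over up to 100 distinct permutations of the target motif's letters whose
total frequency lies within ±10% of the target's (the identity
permutation is excluded; seeds with no qualifying control are flagged
untestable, e.g. homopolymeric seeds). Pooling stabilizes `p0` for rare
motifs compared with averaging per-control fractions. The observed `c` is
then tested against `Binomial(t, p0)` by exact summation, one tail per
direction at α = 0.05 — excess (functional targeting) and deficit
(avoidance) are distinct findings and are reported separately, without a
multiple-testing correction across families (a documented limitation of
the reporting convention this mirrors).

Motifs are also ranked by `t` and by `c` (descending, ties broken
lexicographically); the rank score `(R_t − R_c)/M` over the `M` motifs
with `t > 0` is positive when a motif stands higher in the conserved
ranking than its abundance predicts.

The family-level summary compares the observed fraction of testable
families significant for excess (and, symmetrically, deficit) against
1,000 simulations drawing the same number of random motifs uniformly from
those with `t > 0` and running the identical test; the 2.5/97.5
percentiles give the background interval and an add-one empirical p.

## The synthetic study

The generator defines the conditions every claim is tested under:

* genome 500 kb (single chromosome), with non-overlapping annotation
  blocks for ncRNA, exon, intron and repeat; the complement is intergenic;
* 30 novel precursors (intergenic), 10 annotated precursors (with
  annotated mature, loop coordinates and star-arm reads), 5 ncRNA-hosted
  precursors, and 10 decoys that each violate one candidate filter
  (short stem, exonic origin, or no read support — recorded in the truth);
* 50,000 raw 36-nt reads; per-feature expression is log-uniform over 6
  orders of magnitude with a minimum of 8 reads per expressed feature
  (the deep-coverage regime: every true feature present in the library is
  represented by at least two reads); 20% of reads come from a pool of
  800 background degradation loci; mature 5'/3' ends jitter by 1 nt with
  probabilities 0.05 and 0.2 (end-heterogeneity knobs, not literature
  values); star reads at ~12% of feature reads;
* a conservation track with Beta-distributed background (mean 0.3), 10%
  missing positions, and planted conserved matures re-drawn until their
  interval mean is ≥ 0.8;
* 1,600 UTRs of 1–3 kb with a background window-conservation rate of 0.15
  (sized so the per-motif window total t is ~190, ample for both test
  directions at the planted effect sizes);
  the seeds of 10 novel matures are planted as *enriched* (target-site
  conservation at 3× background) and the 5 ncRNA-hosted seeds as
  *avoided* (0.3× background), implemented per occurrence of the target
  motif on top of random conserved blocks.

Precursors are built as exact reverse-complement arms around a loop. Two
constructional choices matter. The loop uses only A and C, which cannot
pair with each other, so the terminal loop cannot fold in on itself under
the pairing engine. And the planted imperfections of the mature/star
duplex are G·U *wobbles* (complement C→T under a mature G, A→G under a
mature U) rather than mismatches: the helix stays fully paired — so the
engine recovers one clean stem — while sequence identity is broken, which
both mimics real duplex imperfection and guarantees that the mature
sequence occurs exactly once in the genome (a perfect palindrome would
carry the mature's exact reverse complement on its other arm). Planted
matures and their seeds are verified unique, and every non-decoy
precursor is verified, at planting time, to refold from its actual
genomic context (a centred 110-nt window) into an unbranched stem-loop of
≥ 20 pairs covering the mature; failures are redrawn, with a bounded
retry budget that turns an overfull configuration into an error.

What the generator does *not* emulate: sequencing errors and quality
scores, amplification bias, multi-species orthology/alignment artifacts,
isomiR complexity beyond 1-nt end jitter, overlapping or nested gene
structure, and chromosome-scale heterogeneity. Passing tests therefore
demonstrate that the algorithms recover the signals they define, under an
idealized error model — not that the pipeline's operating point is
optimal for any particular real library.

## Numerical conventions

* Coordinates are 0-based half-open internally; conversion to 1-based
  happens only at the GFF3/GRanges boundary.
* All empirical p-values are add-one corrected, `(1 + k)/(n + 1)`, hence
  confined to `[1/(n+1), 1]`.
* Exact binomial and hypergeometric tails are computed by direct
  summation of log-space terms (both tails include the point mass, so
  they sum to at least 1); the tests require agreement with R's
  reference distributions to 1e-12.
* Ties: same-5'-end read groups prefer the higher count, then the longer,
  then the lexicographically smaller sequence; motif rank ties break
  lexicographically; the folding traceback is deterministic as described.
* Degenerate inputs are explicit: zero shuffle controls is an error, a
  candidate with no reads is an error, an all-missing interval is "not
  conserved", an untestable seed is excluded from family proportions but
  counted in reports.

## Study sizes used in tests

The end-to-end test and the acceptance script run the default study above
(≈3 minutes on one core). Component tests use a 60-kb study with 11
planted precursors and 5,000 reads. The type-I calibration uses one
400-UTR null table for the 200-seed excess-rate check, and 100
independently generated 100-UTR null tables (200 simulations each) for
the coverage of the family-proportion interval. These sizes are the
package's chosen operating points: large enough that planted effects are
detected with the margins the tests assert, small enough to be re-run
routinely as part of the suite.

## Known limitations

* The pairing-score engine ignores stacking energies, loop penalties and
  temperature; absolute stability values are not comparable to
  thermodynamic MFE, and the `min_stack`/`max_bulge` regularizations are
  engine artifacts, not biology.
* The structure classifier is trained on synthetic fixtures; its absolute
  scores are meaningful only relative to this study design.
* One-tailed α = 0.05 per direction without multiple-testing correction
  matches the reporting convention the pipeline mirrors; family-level
  discoveries on real data would warrant FDR control.
* The binomial target test conditions on `p0` as if known; control
  sampling variance is not propagated (pooling over up to 100 controls
  keeps it small).
* Single-chromosome genomes only in the generator (the analysis code
  itself is multi-chromosome capable).
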