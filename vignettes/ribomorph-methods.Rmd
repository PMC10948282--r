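---
title: "Assembling rDNA morphs from long reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling rDNA morphs from long reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ribosomal DNA (rDNA) arrays are tandem repeats of a large unit — roughly
45 kb and a few hundred copies in human — whose copies are so similar that
whole-genome assemblers collapse them. The distinct full-length unit
sequences that actually occur in an array are called *morphs*; a morph may
be present once or in dozens of copies. `ribomorph` assembles and phases
morphs from two complementary read sets: accurate long reads (HiFi-like,
sub-percent error) that capture every variant but rarely span a whole unit,
and ultralong noisy reads (ONT-like, several percent error) that span one
to several complete units and therefore carry the phasing information.

## The method

The workflow is a reference-based pipeline:

1. **Recruitment.** A related reference repeat sequence is indexed by
   canonical k-mers (k = 21) and accurate reads sharing at least a fraction
   (default 0.2) of their k-mers are recruited. The reference only needs to
   share most k-mers with the target locus, not to be complete or accurate
   at base level.
2. **Allele graph.** Recruited reads are homopolymer-compressed and a de
   Bruijn graph over canonical k-mers with multiplicity at least
   `solid_min` is compacted into unitigs. Run lengths for every compressed
   position are accumulated from all supporting read observations (a
   histogram per position, summarised by the median) so node sequences can
   be expanded back to base space. This graph — the allele graph — contains
   every variant the accurate reads support at `solid_min` copies or more.
   Low-coverage nodes and short dead-end tips are removed and the graph is
   re-compacted.
3. **Graph alignment.** Ultralong reads are recruited against the graph's
   k-mers, then threaded through the graph: exact 17-mer anchors against
   expanded node sequences are collapsed into colinear diagonal segments,
   segments are chained by a gap-consistency score, and the unanchored gaps
   between chained segments are filled by comparing the read substring
   against candidate graph paths (shortest-first enumeration for simple
   gaps; a base-level read-to-graph edit-distance search, bounded by the
   enumeration's score, where several variant sites or collapsed repeat
   cycles fall inside one gap).
4. **Loops.** The anchor node — the highest coverage-times-length node that
   is not a collapsed repeat — defines the repeat-unit origin. One *loop*
   is the expanded path sequence between two consecutive same-orientation
   anchor visits in a read's path: a complete repeat-unit traversal
   observed in a single molecule. Loops outside 0.5-2 times the approximate
   unit size are discarded.
5. **Clustering.** Pairwise loop edit distances are computed up to a
   threshold (`max_rough_diff`); union-find over pairs within the threshold
   yields *rough clusters*; the DBSCAN radius ε is estimated as the mean
   finite within-rough-cluster distance (floored at `min_epsilon`), and
   DBSCAN over the precomputed distances produces the morph clusters.
   A small ε means the morphs were well separated; a large ε means similar
   morphs will be merged — exactly the behaviour expected when several
   diverged repeat families are pooled in one graph.
6. **Consensus.** Each cluster is polished from its medoid by iterative
   pileup majority over the member loops, then polished once more against
   the loops' raw read-space sequences (see below). A *genome-wide
   consensus* is also produced by greedily walking the highest-coverage
   edges from the anchor; because each variant site is decided
   independently, this walk readily pairs alleles that never co-occur in a
   single unit — a mosaic existing in no genomic copy — which is precisely
   why per-morph consensus is preferable.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `approx_morph_size` | 45 000 bp | approximate unit size; bounds loop length and the consensus walk |
| `k_recruit` | 21 | recruitment k-mer size |
| `k_graph` | 101 (compressed) | de Bruijn k; 31 is used at few-kb unit scale |
| `solid_min` | 5 | minimum k-mer multiplicity entering the graph |
| `anchor_k` | 17 | seed length for graph alignment; at 5% read error roughly 42% of 17-mers survive intact |
| `max_rough_diff` | 4% of unit size | union-find join threshold; must exceed the within-morph loop divergence of the aligner |
| `min_epsilon` | 1 edit | DBSCAN radius floor |
| `min_pts` | 5 (2 HiFi-only) | DBSCAN core threshold; kept below reporting thresholds so low-copy morphs survive |
| `report_min_coverage` | 30 | reporting flag only, never a clustering filter |

The HiFi-only mode (units shorter than accurate reads) reuses the pipeline
with the accurate reads in both roles and the tight overrides
`max_rough_diff = 10`, `min_epsilon = 1`, `min_pts = 2`: accurate loops from
the same morph are typically identical, so the estimated within-morph
distance is 0 and ε lands on its floor.

## Design choices made where the design was open

* **Rough threshold at 4% of the unit size.** The threshold's purpose is to
  exceed any plausible ε so that union-find never splits what DBSCAN would
  join. The seed-and-chain aligner used here leaves a within-morph loop
  divergence of a few percent (a full sequence-to-graph aligner would leave
  less), so a 1% threshold fragments true clusters; 4% comfortably covers
  the observed within-morph spread while staying below typical between-morph
  divergence.
* **Anchor selection.** The coverage-times-length argmax is restricted to
  nodes whose coverage is consistent with one traversal per repeat copy
  (at most 3 times the length-weighted 95th percentile). Collapsed tandem
  repeats concentrate enormous coverage on short cycle nodes, and anchoring
  loops inside a repeat cycle makes loop extraction meaningless.
* **Repeat-aware seeding.** Anchor segments lying on collapsed-repeat nodes,
  or made of k-mers hitting many homologous locations, are dropped before
  chaining. Inside a collapsed repeat the read's position is genuinely
  ambiguous; the traversal count is instead chosen by aligning the read
  substring across the cycle.
* **Two-stage consensus polish.** All loops threaded through the graph
  share the graph's pooled run-length estimates, so homopolymer and
  microsatellite variation *between* morphs that is invisible in compressed
  space is collapsed to the pooled median — a systematic bias that majority
  voting over loops cannot remove. The final polish therefore re-aligns the
  same loops in read coordinates: individually noisy but unbiased, their
  majority restores morph-specific run lengths. Residual consensus error is
  dominated by homopolymer and microsatellite indels, which is also the
  error class this method family is known to leave behind.
* **Gap threading by branch and bound.** Candidate graph paths for a gap
  are enumerated shortest-first and ranked by edit distance to the read
  substring; only when no candidate explains the gap is the exact
  read-to-graph Dijkstra search run, bounded by the best candidate's score.
  This keeps the common case cheap and the hard case exact.
* **Rotation-aware matching.** Two morphs are compared by locating exact
  21-mer probes of one in the doubled sequence of the other, aligning
  globally at the best rotation (both strands), trimming terminal gaps, and
  requiring 99% identity over 99% of both sequences. Assembled loops and
  ground-truth units have arbitrary origins, so linear alignment would
  systematically fail.

## The simulator

The synthetic-data generator emulates the published simulation design: a
panel of source units with a chosen average pairwise divergence, morphs
built as mosaics of the sources (Poisson(3) breakpoints, uniform positions,
source switch at each breakpoint) plus 0.2% random mutations (80%
substitutions, 20% single-base indels), geometric copy counts truncated to
[1, 15], tandem arrays in shuffled copy order, and reads drawn with
lognormal lengths and per-base errors with a homopolymer indel bias, from
both strands, with origins recorded in the read descriptions.

Two modelling choices deserve emphasis. First, divergence is concentrated
outside a conserved block covering 20% of the unit, and that block wraps
the unit boundary — mirroring real rDNA, where the core promoter and
external transcribed spacers flank the tandem junction while the variable
intergenic spacer lies mid-unit. Second, each source carries an embedded
tandem motif region (a microsatellite), so the graph's known collapse of
tandem repeats is exercised rather than avoided.

What the simulation does *not* model: systematic platform error profiles
(errors are i.i.d. with a homopolymer weight), the coverage bias real HiFi
sequencing shows in rDNA, chimeric reads, and adapter artifacts. Passing
the simulated study therefore demonstrates the algorithmic pipeline under
idealised noise, not robustness to instrument-specific artifacts.

## Numerical choices

Edit distances use bit-parallel dynamic programming with a block band
around the main diagonal when a threshold is given (exact for distances
within the threshold; pairs beyond it are reported as "exceeds").
All-vs-all loop distances additionally skip pairs whose greedily chosen
representatives are provably too far apart by the triangle inequality —
an exact pruning. Alignment tracebacks use banded global DP with the band
sized from a previously computed distance. Ties in pileup majority keep
the current consensus base; ties in the consensus walk prefer the
higher-coverage edge, then the lower node id; DBSCAN border points joining
several clusters take the lowest cluster id. Degenerate inputs (empty
recruitment, empty graph, zero loops) abort with stage-named errors.

## Validation scale

The packaged validation re-runs the simulation study at reduced scale:
5 kb units, nine morphs at 4.4% average divergence, about 25-40 copies in
total, HiFi-like coverage 35x and ONT-like coverage 60x with 25 kb mean
read length, two seeded replicates both in the test suite and in
`scripts/acceptance.R`. One replicate takes a few minutes on one CPU. At
this scale the pipeline recovers nearly all morphs with consensus errors
of a few edits per 5 kb unit and a coverage/copy-count correlation around
0.93-0.96.

## Known limitations

* Copy counts are not estimated; morph coverages are loop counts, which
  scale with copy number but depend on read length distribution.
* Morph order along the array is not resolved.
* Homopolymer and microsatellite variation between morphs that is invisible
  in compressed space and not rescued by read-space polish remains
  collapsed; morphs differing by fewer than ε edits are merged.
* The seed-and-chain graph aligner is a simplification; its loop error is
  higher than a full sequence-to-graph aligner would leave, which is why
  the rough-cluster threshold defaults to a larger fraction of the unit
  size than the ideal-aligner setting would need.
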