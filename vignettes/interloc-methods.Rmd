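---
title: "Hybrid detection of interchromosomal rearrangements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid detection of interchromosomal rearrangements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the signal model

An interchromosomal rearrangement fuses material from two non-homologous
chromosomes. In paired-end short-read data it leaves two complementary
footprints:

* **chimeric read pairs** — sequenced fragments that straddle the fusion, so
  the two mates align to different chromosomes. These localise a junction
  only to within the fragment-size scale.
* **soft-clipped reads** — reads that cross the junction itself. An aligner
  anchors the longer portion on one chromosome and soft-clips the remainder,
  which derives from the partner chromosome. The clip boundary sits exactly
  on the junction, giving base-pair precision — but few reads cross any one
  junction, so clips alone lose sensitivity at low coverage.

`interloc` combines the two: pair clusters *nominate* loci with high
sensitivity; clipped reads, realigned across the fusion, *resolve* the
breakpoints precisely. A locus is promoted to a call only if at least one
clipped subread realigns into the partner search window, which keeps the
false-positive rate low because a ~20 bp subsequence almost never matches a
~640 bp window by chance (the package's null test measures < 1% over 1,000
random trials; on i.i.d. random sequence the expected rate is orders of
magnitude lower still).

## Clustering

Let `mean` and `stdev` be the mean and standard deviation of the outer
distance of concordant pairs, estimated from the data (up to 10,000 pairs by
default), and

```
L = mean + k * stdev,    k = 3 by default.
```

All reads supporting one junction must map within `L` of it, hence within
`L` of each other, on a common strand per side. Chimeric pairs are therefore
stratified by (canonical chromosome pair, strand pair) and grouped by
single-linkage on the junction-facing coordinate (a read's 3' end on `+`,
5' start on `-`) with link distance `L`, first on one side, then verified
and split on the other; any component whose span still exceeds `L` is cut at
its largest internal gap. `k = 3` bounds the straddle geometry for ~99.7% of
a Gaussian insert distribution; `min_pairs = 2` discards loci supported by a
single stray fragment. Both are user-settable. For up to a few hundred pairs
the suite checks this grouping against a brute-force transitive-closure
oracle.

The strand pair doubles as the fusion-orientation signature: reads point
into the junction, so the breakpoint lies right of a `+` read set and left
of a `-` one. With a centromere BED the signature is translated into
arm-to-arm nomenclature (p-p, p-q, q-p, q-q); this mapping is a
reconstruction from the geometry, and the strand/side signature remains the
primitive representation used downstream.

## Breakpoint resolution

For each cluster side a search window of length `L` extends from the
outermost read **toward** the junction. We anchor the window at the
outermost read's far edge (leftmost aligned base of a `+` side), so it
covers the read set's own territory up to and including the junction. The
design alternative — starting the window one base past the junction-side
read end — fails on exactly the reads that matter: a soft-clipped chimeric
pair member abuts the junction, so a window disjoint from the cluster span
contains neither clip boundaries nor realignment targets. Every cluster
read starts within `L` of the breakpoint, so the anchored window reaches
the junction except in a vanishing tail of the insert distribution.

Within the windows `W` (side *i*) and `X` (side *j*), junction-facing soft
clips of at least `min_clip = 20` bp are harvested, at most `max_clips = 5`
per window (an efficiency cap; one spanning read already fixes the
boundary). The 20 bp floor reflects the realignment minimum for confident
placement of short subsequences; it is configurable downward for short-read
libraries at a documented sensitivity/specificity cost — with very short
reads, clipped portions rarely reach the threshold and resolution cannot
trigger, a stated limitation of the approach.

Each harvested clip is realigned **only against the partner window** — not
the whole genome — by end-free (fit) alignment under unit edit costs
(match 0, mismatch/gap −1), accepting placements with edit distance at most
`ceiling(0.1 * clip_len)`. The promotion rule only asks whether the clip
remaps into `W` or `X`, so a genome-wide search would change nothing but
cost. When the cluster's two strands are equal the fusion joins opposite
reference orientations and the clip is reverse-complemented first.
Realignments landing in the window are accepted regardless of placement
strand beyond this rule; the suite's inverted-fusion fixture checks the
orientation logic both ways.

The breakpoint on side *i* is the mode of the junction-adjacent coordinates
of `Align(i)` (boundaries of clips harvested in `W`) together with
`Clipped(i)` (termini of side-*j* clips realigned into `W`); ties break to
the smallest coordinate (deterministic; the data give no reason to prefer
either). One-sided evidence is allowed — the call criterion is *at least
one* successful realignment into `W` or `X` — and per-side support counts
(`n_clips`, `mode_support`, `n_realign`) are reported so users can filter.
A small geometric fact makes the mode well-defined on both sides whenever
the criterion holds: a successful realignment implies clips existed on the
opposite side, so neither coordinate set is empty.

## Event classification

Calls on one chromosome pair are partnered greedily, closest first (summed
per-chromosome separation, deterministic content-based tie order), each call
joining at most one event. For a candidate pair with opposite strand
signatures on both chromosomes:

* **insertion** — one chromosome's two breakpoints co-locate within
  `insertion_site_tol` (default `L`: the recipient site is one physical
  locus, so its two breakpoints should agree to paired-end uncertainty)
  while the other chromosome's breakpoints bracket a segment of at least
  `min_donor_span`; **inverted** when each call's two strands are equal
  (an inversion flips one side's read orientation across the junction),
  else **direct**;
* **balanced translocation** — both separations within `recip_tol`
  (default 1 Mb), reciprocal exchanges being allowed to overlap or gap by
  up to that much through duplications/deletions at the exchange point;
* anything unpartnered is an **unbalanced translocation**.

This rule set is a reconstruction: in reference coordinates alone, a
reciprocal translocation with a kilobase-scale breakpoint duplication is
*structurally identical* to a direct insertion of the duplicated segment —
both produce one chromosome with co-located, outward-facing breakpoints and
one with bracketing, inward-facing breakpoints. Without a read-depth signal
(out of scope here) only scale separates them, which is what
`min_donor_span` (default 10 kb) encodes: breakpoint duplications sit at
the ~1 kb scale, transferred segments at hundreds of kilobases. Whether
partnering should be globally optimal rather than greedy, and whether a
reciprocal pair must also show consistent arm fusions, is left open;
greedy matching with a deterministic order is what ships. Events touching
an annotated centromere are flagged low-confidence rather than dropped.

## The simulator

The bundled simulator forges a rearranged genome from a truth table and
emits reads with their *true* alignments, so caller experiments need no
external aligner. Derived chromosomes are ordered runs of reference slices
(forward or reverse-complemented) and novel bases; every coordinate
operation — splicing variants, planting indels, mapping reads back —
happens on that segment structure, keeping derived-to-reference bookkeeping
exact. Unbalanced fusions keep their unused chromosome parts as remainder
chromosomes, so every reference base remains covered exactly once and
sequence content is conserved (up to planted duplications).

Truth-table convention: one row per junction; each side records the
junction-adjacent *retained* base (1-based) and the orientation of that
side's segment in the derived genome. Under this self-consistent reading
the bundled design-1 balanced exchange carries a 1,001 bp duplication and
the caller's coordinates agree with the truth exactly; the alternative
off-by-one convention (partner side starting one past the recorded
coordinate) was rejected because it makes the recorded coordinate a
*non-retained* base on one side and would bias every second breakpoint by
1 bp.

Reads follow the wgsim model: fragments drawn uniformly, lengths
`Normal(insert_mean, insert_stdev)` (defaults 400 ± 80, redrawn when not
longer than the read length); haplotype mutations planted first at
`mut_rate` (default 0.001; `indel_frac = 0.15` of them indels, lengths
1 + Geometric(0.7), insertions and deletions equally likely); per-base
sequencing errors applied to the reads last (`base_error = 0.02`, the
wgsim convention; substitutions only). Base qualities are written as a
constant placeholder — the error process is explicit, not encoded in
qualities. A read crossing a junction aligns its longest block (ties to
the left), with small same-chromosome gaps rendered as I/D CIGAR
operations (up to `max_del_gap = 50` bp) and everything else soft-clipped
— mirroring how a real aligner renders exactly these cases. Everything is
a deterministic function of the seed; the suite asserts byte-identical
reruns.

### Desk-scale study designs

Two bundled designs mirror the published simulated datasets at reduced
scale, fixed once as the package's study conditions:

* **design 1** — 12 junction rows over 18 chromosomes (~4.4 Mb): six
  unbalanced fusions, one balanced pair with a ~1 kb duplication, one
  direct and one inverted insertion; coordinates scaled 1/200.
* **design 2** — 9 rows over 16 chromosomes (~2.6 Mb, 75 bp reads):
  seven unbalanced fusions and one exactly reciprocal balanced pair;
  coordinates scaled 1/400.

Every chromosome keeps 50 kb beyond its outermost breakpoint. Donor
segments are scaled only 1/10 (20 kb and 60 kb) so they stay far above
both `L` and `min_donor_span`, preserving the original scale separation
between breakpoint duplications and transferred segments; the duplication
keeps its absolute ~1 kb size for the same reason. Full coverage is 40X
with 100 bp (design 1) or 75 bp (design 2) reads; the coverage titration
re-uses one simulation through nested down-sampling (pairs kept with a
shared-seed uniform draw, so the 10% sample is a subset of the 25%
sample), which gives clean trend tests even though independent sampling
would match the original protocol more literally.

### What the simulation does and does not show

The toy references are i.i.d. random sequence: no repeats, no segmental
homology, no polymorphism between non-homologous chromosomes. Those are
precisely the features that generate false chimeric clusters on real
genomes, so specificity measured here is an upper bound — on real data the
mapping-quality filter (`min_mapq = 20` by default; the original method
description is silent on this, so published figures may differ) and the
centromere flag carry that burden. Truth alignments also remove
aligner-specific artefacts: mapping errors, multi-mapping, unmarked
duplicates (duplicate-flagged records are skipped on input; marking is
assumed done upstream). Within those limits the simulations reproduce the
expected headline behaviour: all 12 design-1 junctions and all 9 design-2
junctions detected at full coverage with no false calls and ~0–1 bp mean
breakpoint error, correct classification of every partnered event, and a
detection count that falls away on the 10% down-sample.

## Numerical and edge-case choices

* Coordinates are 1-based inclusive everywhere (SAM convention); BED input
  is converted on read. Breakpoints are the junction-adjacent retained base
  on each side.
* Windows are truncated at chromosome ends; window length is
  `ceiling(L)` so all window arithmetic stays integral.
* Hard clips are ignored as breakpoint evidence — the clipped bases are
  absent from the record, and realignment needs the bases.
* Insert statistics require ≥ 100 concordant pairs; below that the caller
  stops and asks for explicit `insert_stats()` values.
* Mode ties break to the smallest coordinate; greedy matchers (event
  partnering, evaluation) use content-based deterministic orders, so all
  outputs are invariant to input row order.
* Evaluation matching tolerance defaults to `L` — the method description
  never states how predictions were counted against truth, and the
  paired-end uncertainty length is the least arbitrary choice; it is a
  flag, not a constant. "Specificity" is reported call-denominated
  (matched calls / all calls), i.e. precision, matching the conventional
  table layout this field uses.
* A balanced pair counts as two junction rows in both truth and scoring,
  matching the 12/12 and 9/9 denominators of the reproduced tables; one
  could defensibly count physical events instead, which would change
  denominators, not behaviour.

## Problem sizes

The packaged experiments run at the scale a laptop handles comfortably:
design 1 simulates ~0.9 M pairs, design 2 ~0.7 M; the full
simulate–call–evaluate round trip for both designs plus the coverage
titration completes in minutes on one core. All fixtures are generated
programmatically from seeds; nothing binary ships with the package.
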