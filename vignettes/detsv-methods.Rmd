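---
title: "Deterministic SV detection from overlapping read pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic SV detection from overlapping read pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the approach

Paired-end SV callers usually decide whether a read pair is discordant by
comparing its mapping distance against the library's fragment-size
distribution. That makes the discordance call probabilistic: events smaller
than a few standard deviations of the fragment size are invisible, and
breakpoints are only localized to within the fragment-size spread.

detsv implements a deterministic alternative built on *overlapping*
paired-end reads: reads long enough (150 bp) relative to the fragment
(at most 287 bp) that the two mates share the fragment's central sequence.
The workflow is:

1. **Fragment reconstruction.** For each pair, read 2 is
   reverse-complemented and slid along read 1; at overlap offset $i$ the
   score is the fraction of matching bases in the overlap of length $L-i$.
   Only pairs reaching score exactly 1 — a perfect overlap of at least
   $m_{\min}=13$ bases — are merged. The merged sequence is the exact
   fragment, with exact length $l_f = i + L$. The probability that a random
   offset produces a false perfect overlap is $4^{-m_{\min}}$ per offset,
   about $1.5\cdot10^{-8}$ at the default.
2. **Seed placement.** Full reads crossing an SV junction fail to align, so
   only the high-confidence 5' prefix of each read (the *seed*, 30 bp) is
   placed on the reference, allowing one mismatch, on both strands. Both
   seeds must place uniquely, otherwise the pair is unusable. Seed length 30
   sits where the unique alignability of genomic k-mers saturates
   (`unique_alignability()` reproduces that analysis).
3. **Exact classification.** With read 1 forward at 5' position $p_1$ and
   read 2 reverse with 5' base at $p_2$, the outer mapping distance is
   $D = p_2 - p_1 + 1$. A pair is concordant iff the seeds are on one
   chromosome, in inward forward/reverse orientation, and $D = l_f$
   *exactly*; everything else is discordant. No distributional threshold
   exists anywhere in this rule — this is what makes the caller independent
   of the fragment-size distribution, and single-base-precise.
4. **Breakpoint localization.** For each discordant pair a *minimal
   reference* is built: from each seed placement, a window of length $l_f$
   grown in the read's 3' direction (reverse-complemented where needed so
   the joined sequence is collinear with the fragment). The fragment is
   aligned to the joined $2\,l_f$ construct by Needleman-Wunsch with affine
   gap penalties (opening 10, extension 0.5/base); the gap's start and end
   columns, mapped back through the window coordinates, are the breakpoints,
   and the gap content is the inserted/deleted sequence.
5. **The discordant graph.** Breakpoints become vertices; each fragment
   contributes a directed edge from its read-1 breakpoint to its read-2
   breakpoint, typed by the pair of sides from which the fragment approaches
   them: `a` = (left,left), `b` = (left,right), `c` = (right,left),
   `d` = (right,right). Because sequencing orientation is arbitrary,
   $a(u,v)\equiv a(v,u)$, $d(u,v)\equiv d(v,u)$ and $b(u,v)\equiv c(v,u)$;
   edges are stored canonically and parallel evidence accumulates as the
   edge weight. Connected components are candidate SVs.
6. **Prototype matching.** Each component is tested for isomorphism — a
   vertex bijection preserving canonical edge types — against a catalog of
   16 prototype graphs: insertion (one vertex, self-loop), deletion
   ($b(u,v)$, $u<v$), tandem duplication ($b$ with reversed coordinate
   order), inversion ($a$ and $d$ on one vertex pair), and
   {insertional duplication, cut-and-paste translocation} $\times$
   {intrachromosomal upstream, intrachromosomal downstream,
   interchromosomal} $\times$ {inverted, non-inverted}. A non-inverted
   insertion junction contributes $b$-edges between the site and the donor
   boundaries; an inverted one contributes $a$ and $d$ edges; a
   translocation additionally carries the donor-excision $b$-edge, which is
   what distinguishes it from an insertional duplication. Prototypes are
   tried in specificity order (richer signatures first) and matched
   components become typed calls, filtered by the minimum required weight
   (MRW); unmatched components are reported as residuals.
7. **Zygosity.** The wildtype allele contributes concordant pairs spanning
   the breakpoints, the variant allele contributes the discordant weight.
   The wildtype fraction $r = C/(C+W)$ (with $C$ the mean concordant
   coverage at the breakpoint columns — positions the variant allele no
   longer covers concordantly) is near 0 for homozygous events and near 0.5
   for heterozygous ones; calls whose weight is small relative to the
   flanking coverage are flagged low-confidence instead, as such isolated
   discordant evidence is typical of library artifacts.

## Equivalent placements and representative selection

Within repeats, several breakpoint placements describe the same sample
sequence — inserting an `A` into the run `AAA` is identical for all four
placements — and independent fragments may localize the "same" breakpoint at
different but equivalent coordinates. detsv makes the equivalence explicit:
every junction carries a *shift range*, the maximal interval of placements
preserving the sample sequence (computed by sliding the junction while the
entering and leaving bases agree, with complementation across inverted
junctions). Evidence is merged in two stages:

* instances of the same edge type whose shift ranges intersect are one edge;
* endpoints of *different* edges that can realize a common coordinate are
  constrained to coincide. Constraint propagation (an affine union-find over
  per-edge shifts) maximizes vertex merging, i.e. prefers the highest-order
  graph consistent with the evidence — this is what keeps a translocation's
  three junctions in a single component even when each junction's repeat
  context slides differently.

Within the remaining freedom the central placement (lower median of the
feasible interval) is selected, so all fragments of an event report one
deterministic representative. `enumerate_optimal_placements()` exposes the
equivalence class; for an insertion into a homopolymer of length $n$ it has
exactly $n+1$ members.

The same convention applies to evaluation: planted truth coordinates are
moved to the central placement of their equivalence class before comparing
with calls, so the evaluation tolerance measures genuine localization error
rather than arbitrary choices among indistinguishable placements.

## Numerical and design choices

**Substitution scores.** The gap costs (open 10, extend 0.5) are fixed by
the method; substitution scores are a free choice and interact strongly with
them. With a large match reward (e.g. +5/-4), any random exact run of three
or more bases pays for a gap opening, and the optimal alignment of a
fragment against the doubled minimal reference degenerates into a mosaic of
short placements — the single SV gap disappears. detsv defaults to match +1,
mismatch -3 (the megablast regime), under which a gap opening outweighs any
random run shorter than eleven bases; a true indel still beats a gapless
placement easily because the frame shift it avoids would mismatch about
three quarters of the downstream flank. Both scores are configurable.

**Anchored global alignment.** The fragment's first base coincides with the
start of window 1 and its last base with the end of window 2 — the windows
are grown from the seed placements. The alignment is therefore anchored at
both ends (terminal reference gaps are charged), and every alignment pays
exactly one junction gap; a fitting mode with free reference ends exists as
an option. Unanchored ends would let the optimizer soft-clip a short flank
as a spurious insertion at the cost of one lucky match.

**Gap-run budget.** A fragment carries at most one SV (nested events are out
of scope by design), which corresponds to at most two gap runs against the
minimal reference: the SV's own gap plus the window-junction gap. The DP
enforces this budget; it is what makes the cheap published gap extension
safe against mosaic alignments. The budget, and the unlimited mode, are
exposed as `max_gap_runs`.

**Insertions.** For a pure insertion the two windows overlap and the
insert's edge bases often coincide with reference bases at the junction, so
the score-optimal gap placement may split the event into a shorter insertion
plus a tiny back-junction, or absorb a mismatching column into a flank.
Since the insert length is known exactly ($l_f - D$) and both fragment ends
are anchored, detsv recovers the canonical insertion directly by longest
common prefix/suffix against the windows whenever the flanks match exactly,
and falls back to the alignment-derived events otherwise (e.g. flank
sequencing errors).

**Identity filter.** Fragments whose alignment matches fewer than 95% of
aligned columns outside gaps are discarded as chimeric artifacts.

**Vertex merging.** Vertices merge only when their equivalence ranges allow
the *same* coordinate; there is no fuzzy clustering window. Single-base
resolution is the point of the method, and planted-indel tests assert exact
breakpoint recovery at tolerance 0 on non-repetitive flanks.

**Zygosity thresholds.** $r \le 0.1$ is homozygous, $0.3 \le r \le 0.7$
heterozygous, weight below 15% of the flanking coverage low-confidence.
The ratio compares the two alleles at the same locus, so local coverage
fluctuations cancel; the thresholds are symmetric bands around the 0 and 0.5
expectations and are configurable. Depletion-based zygosity is informative
for deletions, insertions and inversions; duplicative events retain
wildtype-like concordant coverage at their breakpoints (the duplicated
sequence still matches the reference there), so their ratio sits near 0.5
regardless of zygosity — copy-number evidence would be needed instead and
is out of scope. Insertions whose site lies in a repeat share their
equivalent placements with variant-allele-covered columns, which can blur
the ratio toward the low-confidence band.

**Translocation ambiguity.** Moving donor $[Y,Z)$ downstream to $X$ produces
exactly the same sample sequence as moving $[Z,X)$ upstream to $Y$; both
readings match translocation prototypes. The caller reports the reading with
the shorter donor, which is deterministic and, under the simulator's
geometry (donors up to 900 bp, sites at least 2 kb away), always the planted
one.

**Prototype arity.** The translocation prototypes use three vertices: with
exact breakpoints the excision edge lands on the same two donor coordinates
that the insertion junctions pin. The donor-adjacency `e` edge can only be
pinned by a single fragment spanning the whole donor, which cannot happen
for donors longer than the maximal fragment (287 bp); it is therefore an
*optional* member of the duplicative prototypes, accepted when present but
not required.

## The simulator

`generate_reference()` draws i.i.d. uniform sequence (GC configurable;
optional planted repeat cassettes for alignability stress tests).
`plant_svs()` applies any mix of the 16 types to one or two haplotypes and
records exact truth coordinates. Default size ranges follow the
experimentally validated ranges for this method: insertions 22-133 bp,
deletions 22-245 bp, tandem duplications 293-889 bp; inversions and
duplication/translocation donors use the same 300-900 bp scale, with
insertion sites 2-3 kb from the donor. Events are spaced by at least 700 bp
plus their footprint so that no two signatures interact (nested/overlapping
SVs are excluded by design, matching the caller's scope).
`simulate_reads()` draws fragment starts uniformly; in the default
overlap-guaranteed mode fragment sizes are uniform on [200, 287]
(mean about 250 bp, matching the sequenced libraries), and an untruncated
normal mode reproduces the bimodal overlap-score distribution of real data.
Substitution errors are optional and default to 0.

What the simulator does *not* emulate: genomic repeat structure beyond
optional cassettes (real genomes have repeat families, which reduce seed
uniqueness), indel sequencing errors, quality-score profiles, PCR
duplicates, and chimeric fragments. Passing tests on this generator
therefore demonstrate the correctness of the algorithmic machinery — exact
classification, breakpoint arithmetic, graph assembly, typing — not the
recall to expect on a repeat-rich genome with real error profiles.

## Problem sizes and measured behavior

The bundled benchmark plants 200 events per scenario in a 2 Mb
two-chromosome reference at coverage 20 with error-free reads (the published
experiment used 1000 events per type on the fly genome; the desk-scale
version keeps the per-event coverage identical and completes in minutes).
Under these idealized conditions the pipeline recovers essentially every
planted deletion (tolerance 0) and intrachromosomal translocation
(tolerance 10): measured recall is 1.00 for both, which brackets the
published 0.96 from above but exceeds the published 0.88 for translocations
— on a random reference with error-free reads, none of the failure modes
(repeat-induced seed ambiguity, sequencing errors) that limit recall on a
real genome are present. The acceptance suite asserts the published bands
two-sided, so the translocation check documents this difference rather than
hiding it.

Zygosity recovery on a diploid simulation (50 homozygous + 50 heterozygous
deletions, coverage 20) is about 98% correct with the allele-ratio
estimator.

## Known limitations

* Nested or overlapping SVs within one fragment are out of scope; fragments
  yielding more than two gap events are discarded.
* Insertional duplications whose donor is shorter than the fragment span are
  reported as plain insertions: their junction fragments carry the complete
  donor copy, which is sequence-identical to a novel insertion at the site.
* Events closer together than a seed length impede seed placement and are
  likely missed, a lower bound inherited from the seed-based alignment.
* The built-in exhaustive seed aligner targets genomes up to roughly 10 Mb;
  for larger genomes, run an external seed aligner (report up to 11
  placements, one mismatch, 30 bp seeds) and ingest the SAM/BAM.
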