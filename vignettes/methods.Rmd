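---
title: "Methods: comparing fragmented mitochondrial karyotypes and counting fragmentation origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing fragmented mitochondrial karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitokaryo)
```

## The data model

A mitochondrial *karyotype* is a species' mt genome described as a set of
circular chromosomes, each an ordered sequence of oriented genes and
non-coding regions (NCRs) over the canonical 37-gene bilaterian complement.
Three modelling commitments shape everything downstream:

- **Circularity.** A written gene order is one arbitrary linearization of
  a circle. Chromosome identity is therefore defined on a canonical form:
  the lexicographically least signed sequence over all rotations of the
  order and all rotations of its full reversal. Rotating or reversing a
  chromosome never changes any result.
- **No absolute strand.** Full reversal flips every orientation, so only
  *relative* orientation within a chromosome is meaningful. All
  orientation-sensitive comparisons are frame-relative (below).
- **Single-copy genes.** No gene may occur twice in a karyotype. Every
  karyotype described for this system is single-copy, and the constraint
  makes gene positions unambiguous anchors for homology. Duplications
  would need a different (and much harder) matching model; they are out of
  scope.

NCRs are retained in the model — they carry length metadata and matter for
describing minichromosomes — but all comparison operations drop them
first. The conserved clusters in these genomes are defined purely on gene
order, and published clusters span NCRs (e.g. a cluster whose cox1–atp6
adjacency contains a non-coding region in both species), so an NCR must
not break a run.

## Pairwise comparison

`compare_karyotypes()` composes five operations.

**Chromosome homology** is an exact maximum-weight one-to-one matching
between the chromosome sets, with weight = number of shared genes
(zero-weight pairings excluded). Chromosome counts here are tiny (2–6 per
species, a few tens at worst in simulations), so the matching is solved
exactly by dynamic programming over subsets; ties between optimal
matchings break deterministically toward lexicographically smallest label
pairs, making reports reproducible.

**Split/merger detection** attributes each unmatched chromosome to the
matched pair whose opposite-side partner shares the most genes with it
(ties by label). Each resulting one-vs-many group is one homologous
*unit* — e.g. one species' M2 corresponding to the other's M2+M3. A
chromosome sharing no gene with any partner is an orphan and is excluded
from gene-level calls rather than force-grouped.

**Shared clusters** are maximal runs (length at least 2; singleton sharing
is vacuous) of oriented genes contiguous in the circular gene-only order
of a chromosome of each karyotype, where a run and its full reversal are
the same cluster. Runs are found by marking, for every adjacency of the
first karyotype, whether it occurs in the second in the written or the
flipped frame, then chaining frame-consistent adjacencies; maximality
holds per frame, and a run strictly contained in a longer run found in the
other frame is dropped. Clusters spanning a whole chromosome on both
sides are flagged: shared whole minichromosomes are the strongest derived
characters. `derived_clusters()` screens clusters against an explicit
reference arrangement; a cluster absent from the reference is a candidate
synapomorphy. The reference is an argument, not an assumption: the
packaged analysis uses the single-chromosome arrangement of
*Laemobothrion* sp. 1 as a proxy for the unfragmented ancestral
organization, a deliberate, documented choice.

**Translocation** is assignment change across homologous units for a gene
present in both karyotypes. Moves *within* a unit are a different
phenomenon (positional shuffles) and are reported separately as
*repositioned* genes: same-unit, orientation-concordant genes lying in no
shared run. This separation reproduces the distinction the source
descriptions make between "translocation between minichromosomes" and "a
different location of seven genes" within a single chromosome.

**Inversion** needs a reading frame. For every chromosome of the second
karyotype the frame (as written vs fully reversed) is chosen to maximize
orientation concordance of the genes shared with its anchor chromosome in
the first karyotype; ties resolve to the written frame. A shared gene
discordant in that frame is inverted; a translocated gene is assessed in
its destination unit, so a gene can be both translocated and inverted.
Whether such a gene inverted before or after moving is not identifiable
from two endpoints; the destination-unit convention is one consistent
choice and is applied uniformly.

Two deliberate non-goals: no minimal-event edit distance (DCJ/HP-style
optimization) — the analyses this package supports report gene sets and
split/merger structure, not distances — and no simultaneous multi-way
comparison; many-way questions are answered pairwise plus
`derived_clusters()` against a reference.

## The fragmentation character on trees

`fitch_origins()` counts state changes of the binary character
(0 = single chromosome, 1 = fragmented) by unit-cost Sankoff dynamic
programming (polytomies handled natively) and reports the range of gains
(0→1 edges) across all most-parsimonious reconstructions. The root is
constrained to 0 by default because the single-chromosome organization is
ancestral to animals; an unconstrained mode exists. Because a fragmented
genome reassembling into a single circle is biologically implausible,
`irreversible = TRUE` forbids 1→0 edges (Camin–Sokal counting); that is
the reading under which statements like "two origins on this topology,
three on that one" are made, and the packaged pipeline reports both.

`mk_loglik()` implements Felsenstein pruning for the 2-state Markov chain
with the closed-form transition matrix; partial likelihoods are rescaled
per node, so long trees cannot underflow. `fit_mk()` maximizes the
likelihood on the log-rate scale — bounded scalar optimization for Mk1,
L-BFGS-B for AsymmMk started from the Mk1 optimum so the nested model's
likelihood can never be exceeded downward. Rates are bounded to
[1e-9, 1e3] with convergence tolerance 1e-8; all-constant data drive the
rate to the lower bound, which is reported as such rather than as an
interior optimum. The root prior is uniform (0.5, 0.5) by default — the
conventional default of likelihood ancestral-state reconstruction tools
for this character — with a stationary-prior option for AsymmMk.
`marginal_asr()` computes per-node marginals by the standard
inside–outside construction, equivalent to re-rooting at every node;
probabilities sum to 1 within 1e-9 by construction and the whole surface
is verified against brute-force enumeration over internal states on small
trees.

Branch lengths for the packaged topologies are unit lengths: the source
figures do not state which lengths their reconstruction consumed, so the
package asserts only what survives that uncertainty (direction of the
root-state inference, parsimony counts, which are length-free).

## The simulator

`evolve_on_tree()` is the synthetic-data backbone: per branch the event
count is Poisson(total rate × branch length); the class is drawn
proportionally to the configured rates; fission cuts a chromosome at two
uniform inter-gene positions (each product receives a 1-bp NCR
placeholder at its new junction, for realism of the written format only);
fusion joins two chromosomes at uniform rotations with uniform relative
orientation; translocation excises a block of length uniform on
[1, `max_block`] and reinserts it at a uniform position and orientation on
another chromosome; inversion reverses a block in place. Impossible draws
(fusion on a single-chromosome genome, fission when every chromosome has
one gene) are resampled and logged as skipped, keeping Poisson counts
interpretable. Gene content conservation is asserted after every event,
and the event log carries full parameters so `replay_events()` reproduces
every node karyotype exactly.

The rate values, block-length and position distributions are simulator
conventions: the observed karyotype differences fix the event
*vocabulary*, not a parameterized process. Defaults (fission 0.2, fusion
0.1, translocation 0.3, inversion 0.3 events per unit length,
`max_block = 3`) produce tip karyotypes in the observed range (one to
about six chromosomes on trees of a few units' depth). NCR lengths do not
evolve and nothing sequence-level is simulated.

What passing simulator-based tests shows — and what it does not: recovery
tests use one event per branch with non-overlapping blocks, where the
comparison operations are provably well-posed; the event-recovery harness
uses a four-chromosome root (sizes 10/10/9/8 over the 37-gene complement)
and blocks of at most 3 genes, so an inverted or moved block is always the
minority of its chromosome and the majority-concordance frame is anchored
by the unmoved genes. Real histories superimpose events; after multiple
overlapping events the report describes net differences, not the event
path, and that limitation is intrinsic to two-endpoint comparison, not to
the implementation.

`make_paper_like_dataset()` mirrors the study design that motivated the
package: 23 tips (a 19-tip ingroup in clades of 3, 2, 2, 2 and 10, plus a
4-tip outgroup), three irreversible gains of the fragmented state, and
evolved karyotypes — the end-to-end integration fixture.

## Fixtures and transcription auditing

The ten packaged karyotypes reproduce every published statement about the
system: chromosome counts, per-chromosome gene counts, censuses (23/37
with 14 tRNAs unidentified in one *Myrsidea*; 35/37 with trnP and trnR
missing in both *Actornithophilus*), NCR positions and sizes, all shared
and derived cluster strings, the translocated/inverted sets, the
seven relocated *Laemobothrion* genes, and the 1/4/32 *L. tinnunculi*
partition. Where those constraints do not pin the full circular order,
the order is a synthetic reconstruction and the fixture header says so.
`transcription_lint()` re-derives the pinned counts from the loaded
fixtures and reports findings without failing, so a transcription error is
auditable; one finding is permanently waived and reported as such: the six
cluster strings shared by the two *Austromenopon* species contain 18
genes, while the accompanying prose total says 20 — the package follows
the listed strings and surfaces the discrepancy rather than resolving it.
Two cross-study karyotypes (*Myrsidea* sp. 2, *L. tinnunculi*) are
packaged only at the cluster/partition granularity restated in this
system's description. Chromosome sizes in bp are metadata; raw-sequence
quantities (assembly coverage, percent identity) are not computable at
this level and are not represented.

## Problem sizes and numerical checks

The validation suite sizes were chosen to make each check exhaustive or
statistically meaningful: pruning vs enumeration on 500 random trees of
3–6 tips (enumeration over all internal assignments is exact there), with
agreement required within 1e-10; marginal normalization within 1e-9; Mk1
rate recovery as the median over 200 replicates of 64-tip simulated trees
(tolerance 25% of the generating rate, reflecting ML estimator dispersion
at that size); rearrangement recovery over 1000 single-event replicates
with class and exact gene block required in at least 99%. Deterministic
tie-breaks (lexicographic labels, written-frame preference, sorted
reported sets) make every report byte-reproducible.

## Known limitations

- Duplicated genes are rejected, by design.
- The comparison describes net differences; it does not infer event order
  or count superimposed events.
- "Derived" status is always relative to an explicit reference
  arrangement; no reference, no polarity.
- The Mk machinery is strictly 2-state; multi-state karyotype characters
  (e.g. chromosome number itself) are not modelled in likelihood.
- Packaged topologies carry unit branch lengths; conclusions that depend
  on branch-length magnitudes should be re-run with user-supplied trees.
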