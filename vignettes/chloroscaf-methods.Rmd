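---
title: "Scaffolding chloroplast genomes as exact optimisation over genomic regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding chloroplast genomes as exact optimisation over genomic regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chloroplast genomes are small, circular, and structurally stereotyped: a
long and a short single-copy region (LSC, SSC) separated by a pair of
repeats, most often an inverted repeat (IR) — two subsequences where one is
the reverse complement of the other — and occasionally a direct repeat
(DR) — two near-identical subsequences in the same orientation.  The same
cell hosts several *forms* of the genome: flip-flop inversion during
replication can reverse the region enclosed by the two IR copies, so the
SSC coexists in both orientations (structural heteroplasmy).

`chloroscaf` scaffolds contigs of such a genome **without distance
information**.  Its inputs are deliberately minimal:

* a set of contigs, each an opaque identifier with a *multiplicity*
  `mult(c)` (an upper bound on how many times the contig may occur in the
  genome) and a non-negative *existence weight* `wex(c)` (how strongly the
  contig looks chloroplastic, e.g. from alignments to related genomes);
* a set of *links*, ordered pairs of oriented contigs, closed under the
  reverse-complement symmetry of double-stranded DNA: if `(c, d)` is a
  link then so is `(rev(d), rev(c))`;
* a *starter* contig with `mult = 1` that anchors every solution.

The output is a circular sequence of oriented genomic **regions** —
single copies (SC), direct repeats and inverted repeats — together with
every genome form that the region structure admits.

## The multiplied doubled contig graph

Orientation and multiplicity are made explicit in one directed graph.
Every contig `c` contributes `2 * mult(c)` vertices — one per
(orientation, occurrence) pair — and every link `(c, d)` contributes
`mult(c) * mult(d)` edges over all occurrence combinations.  A genome
candidate is a *valid circuit*: it starts and ends at the starter's
forward occurrence 0, never visits a vertex together with its reverse
partner, and follows edges.

Repeats are built from *repeated fragments*: pairs of occurrences
`(2k, 2k+1)` of a multiplicity-`>1` contig, in the same orientation for
direct fragments, or forward paired with reverse for inverted fragments.
Two fragments extend the same repeat when a *canonical adjacent edge* and
its partner edge (the same adjacency seen from the repeat's other region)
are both traversed: for a DR the partner shifts both endpoint occurrences
to the fragment mates; for an IR it is the reversed edge between the
mates.  The canonical-edge sets follow the displayed set-builder
conditions of the source formalism literally and are validated in the
tests against the worked adjacency examples.

## The ILP formulations

All three scaffolding problems share a flow-based circuit block: binary
edge variables `x_e`, flows `f_e` with `x_e <= f_e <= M x_e`
(`M = sum(mult)`), unit flow out of the starter, and a unit flow *gain* at
every used vertex.  The flow monotonicity makes subcircuits infeasible
without Miller–Tucker–Zemlin orderings, and the vertex indicators `i_v`
may be declared continuous in `[0, 1]`: they are provably integral at any
optimum (the tests assert this on every solved instance).

The repeat problems (DRP for direct, IRP for inverted repeats) maximise

```
sum over fragments m_p  +  sum over canonical adjacencies isadj_e
```

which equals the cumulative repeat length minus the number of repeats —
the model prefers one long repeat over two short ones of the same total
length, which matters when repeats have degenerated.  Order constraints
encode the biology: the two occurrence intervals of two direct repeats
may interleave but never nest; those of two inverted repeats may nest but
never cross.  Forbidden orders are detected through position comparisons
`alpha[u, v]` ("u precedes v", linearised against the flow-defined
position `pos(v)` = flow leaving `v`) and quartet detectors `forbid`.
A design point worth recording: a circuit is free to traverse *either*
side of a fragment first (the toy example's own optimum traverses its two
inverted fragments in opposite within-fragment orders), so the two
forbidden patterns per fragment pair are instantiated for both
within-fragment assignments of each side — eight quartets per pair.  With
only the two literal patterns, a genuinely crossing configuration could
be co-selected.  The brute-force equivalence suite (below) confirms this
reading.

The single-copy problem (SCP) maximises the total existence weight of the
used vertices, starter excluded.

Two symmetry-breaking families — occurrence-monotone usage and
fragment-monotone selection — only prune permutations of occurrences;
the tests check they leave the optimum unchanged.

## Hierarchical succession and selection

Repeats are scaffolded before single copies, in both orders
h1 = DRP–IRP–SCP and h2 = IRP–DRP–SCP.  Each stage *fixes* the regions of
its predecessors (vertices forced in, adjacency edges and their partners
forced in); SCP re-optimises the full circuit subject to those pins.  The
succession(s) whose objective vector attains the componentwise maximum
are retained.  The componentwise rule can leave the set empty — e.g. on
the toy instance, Z vectors (0, 3, w) and (3, 0, w) are incomparable
because the comparison is by stage position, not by problem.  In that
case both successions are retained and the result is flagged ambiguous;
in practice the retained decompositions frequently coincide, and
reporting all of them mirrors how benchmark summaries list several
optimal successions per instance.

## From a circuit to regions and genome forms

The solution circuit is cut into regions at every type change and at
every contiguity break between repeat fragments (an edge that is neither
a selected canonical adjacency nor the partner of one).  Repeat regions
are paired with a FIFO queue for DRs and a LIFO queue for IRs — exactly
the interleaving-vs-nesting disciplines that the ILP's order constraints
guarantee, so a queue mismatch can only signal an internal decoding bug
and is raised as one.  The result is `COR` (each region stored once,
forward) and `SOR` (the circular sequence of oriented region references,
anchored at the starter's region, which is always a single copy).

The *region graph* has both orientations of every region as vertices and,
per circular adjacency of `SOR`, an edge plus its reverse.  Genome forms
are Eulerian circuits from the starter region's forward vertex that use
exactly one member of each reverse pair; they are enumerated by
backtracking with a deterministic edge order (sorted by target region and
orientation), duplicates suppressed.  The count is bounded by `2^m'` with
`m'` the number of IRs.  Forms that violate the repeat-order definitions
are still reported — they correspond to real molecules produced by
flip-flop inversion; the `check_sor` validator can be used to annotate
them.

## Certificate validators

`check_sor` and `check_soc` are linear-time verifiers of a proposed
solution: IR pairs must be disjoint or nested (LIFO pass), the cumulative
IR length and IR count are certified against a threshold pair `(k, m')`,
and the flattened oriented-contig sequence must respect the link set and
the multiplicities.  DR pairs get the symmetric FIFO check behind a flag,
for completeness beyond the IR-only decision problem.  Every
solver-produced decomposition must pass both checks; this end-to-end
self-consistency is part of the test suite.

## The synthetic benchmark generator

`generate_perfect(sc_len, ir_len)` emits the smallest instance whose
architecture is `SC1 – IR – SC2 – rev(IR)`: chains of multiplicity-1
contigs for the single copies, multiplicity-2 contigs for the IR, four
junction links closing the circle, all weights 1.  Defaults follow the
benchmark conditions: single copies of 20 contigs, IR lengths growing in
steps of 20.  Closed forms the generator satisfies (and the tests pin):
one-direction link count `2(sc_len−1) + (ir_len−1) + 4`, graph sizes
`|V| = 2 sum(mult)`, and IRP optimum `2 ir_len − 1`.
`generate_noisy` degrades a perfect instance the way read-derived input
is degraded: each non-starter contig's multiplicity is overestimated by
one with probability 0.25, and each contig gains one link to another
uniformly chosen contig with probability 0.25 (orientations uniform,
duplicates dropped, reverse closure maintained).  Because noise only adds
vertices and edges, the perfect optimum stays feasible and the noisy
optimum can only be at least as large — a property the tests check over
20 seeds.

What the generator does *not* emulate: nucleotide content, coverage-based
multiplicity estimation errors other than +1, chimeric links correlated
with genomic position, or repeat degeneration.  Green tests on this data
therefore certify the combinatorial machinery — graph construction, ILP
correctness, extraction, enumeration — not robustness to every artefact
of real assemblies.

## Numerical choices

* MILP backend: the models are solver-agnostic; the default backend is
  HiGHS (through `scipy.optimize.milp` in a Python subprocess), an exact
  branch-and-bound solver.  Any solver implementing the narrow
  list-of-models contract can be plugged in via the `backend` argument.
* A relative MIP gap of `1e-9` is requested so printed optima (all
  integral) are met exactly; decoded values `>= 0.5` count as 1.
* Big-M is `sum(mult)`, the tightest uniform bound on any flow value.
* Ties in the strict total order on contigs never arise (ids are unique);
  the order itself is byte-wise lexicographic, fixed across platforms.
* Degenerate inputs: a single-contig, zero-link instance is valid; an
  instance whose cycles all avoid the starter is reported infeasible, not
  an error; self-links are accepted (the circuit constraints exclude
  self-loop edges on their own).

## Problem sizes used by the test suite

Unit tests run on the 4-contig toy instance and perfect/noisy instances
with single copies of 1–3 contigs.  The acceptance checks solve the
perfect instances with `ir_len` 20, 40 and 100 (optima 39, 79, 199) and
verify the zero LP-relaxation gap at `ir_len = 20`; the property suite
compares the ILP against exhaustive circuit enumeration on 50 randomized
instances with at most 14 vertices, for all three problems.  These sizes
were chosen so the whole suite completes in minutes on one CPU while
still covering a full order of magnitude of instance growth.

## Known limitations

* Weights live on contigs, not on links; SCP can be indifferent between
  alternative single-copy paths of equal weight.
* The starter must truly lie in a single-copy region; a starter inside a
  repeat contradicts the model's anchoring assumption.
* Multiplicities are trusted as upper bounds; underestimated
  multiplicities make the true architecture infeasible.
* Solve time grows quickly with the number of fragment pairs (the
  order-constraint blocks are quadratic in the number of inverted
  fragments); exact solving is practical because chloroplast instances
  are small.
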