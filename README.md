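# chloroscaf

Distance-free scaffolding of chloroplast genome assemblies by exact
integer linear programming, with enumeration of all coexisting genome
forms (structural haplotypes).

## What it does, and for whom

Chloroplast genomes are small circular molecules with a stereotyped
architecture: two single-copy regions (LSC, SSC) separated by a repeat
pair — usually an inverted repeat (IR), sometimes a direct repeat (DR).
Assembly pipelines leave them as a handful of contigs whose order,
orientation and copy number remain to be resolved.  `chloroscaf` is for
researchers assembling organelle genomes who have contigs, linking
evidence between contig extremities, and no reliable distance
information: it scaffolds by **modelling the region structure itself**
rather than insert sizes.

Inputs are a contig table (id, multiplicity `mult`, existence weight
`wex`), a link table of ordered pairs of oriented contigs (closed under
reverse-complement symmetry `(c,d) -> (rev(d), rev(c))`), and a starter
contig with `mult = 1`.

## The model

Contigs are expanded into the *multiplied doubled contig graph*: one
vertex per (contig, orientation, occurrence) with `|V| = 2 Σ mult(c)`,
one edge per multiplied link with `|E| = Σ_(c,d) mult(c)·mult(d)`.  A
genome candidate is a circuit through the starter that never uses a
vertex together with its reverse complement.  Three ILPs are solved in
hierarchical succession (repeats first, both orders DRP–IRP–SCP and
IRP–DRP–SCP), each stage preserving the regions of its predecessors:

* **DRP / IRP** — maximise `Σ_p m_p + Σ_e isadj_e` (selected repeated
  fragments plus selected adjacencies), which equals the cumulative
  repeat length minus the number of repeats.  A flow formulation
  (`x_e ≤ f_e ≤ M x_e`, unit flow gain at every used vertex) eliminates
  subcircuits; order constraints forbid nesting DRs and crossing IRs via
  position comparisons `alpha_uv` and quartet detectors.
* **SCP** — maximise `Σ_v wex_v i_v` over the used non-starter vertices.

The solution circuit is decomposed into regions (`COR`, the forward
regions; `SOR`, the circular sequence of oriented region references), and
all genome forms are enumerated as Eulerian circuits of a *region graph*
(one edge pair per region adjacency; at most `2^{#IR}` forms, the
flip-flop haplotypes).  Linear-time validators certify any proposed
solution against the link set, the multiplicities and the repeat-order
rules.

Models are solver-agnostic; the default exact MILP backend is HiGHS
(via `scipy.optimize.milp` in a Python subprocess).

## Worked example

The bundled 4-contig toy instance (contigs `a`, `b`, `c`, `d` with
multiplicities 1, 2, 2, 1; five links listed in one direction):

```r
library(chloroscaf)
contigs <- data.frame(id   = c("a", "b", "c", "d"),
                      mult = c(1, 2, 2, 1),
                      wex  = c(0.70, 0.83, 0.17, 0.43))
links <- data.frame(c1 = c("a", "a", "b", "b", "b"),
                    o1 = c("f", "r", "r", "f", "f"),
                    c2 = c("c", "c", "c", "d", "d"),
                    o2 = c("r", "r", "f", "f", "r"))
inp <- scaffold_input(contigs, links, starter = "a")
#> link set completed with 5 reverse link(s) (10 total)
fit <- scaffold(inp)
summary(fit)
```

prints

```
Chloroplast scaffolding of 4 contigs (|V| = 12 , |E| = 24 )
  h1 (ir-sc): Z = (0, 3, 2.43)  [selected]
  h2 (ir-sc): Z = (3, 0, 2.43)  [selected]
  successions incomparable: both retained
  ...
Region decomposition: 3 regions ( 2 SC, 0 DR, 1 IR )
SOR: 0_f -> 1_f -> 2_f -> 1_r
  region 0 [SC]: a_f
  region 1 [IR]: c_r,b_f
  region 2 [SC]: d_f
  form 1: 0_f -> 1_f -> 2_f -> 1_r
  form 2: 0_f -> 1_f -> 2_r -> 1_r
```

Read: the repeat stage finds one inverted repeat worth objective 3 (two
fragments, `b` and `c`, glued by one adjacency — cumulative repeat
length 4 minus 1 repeat); the single-copy stage collects weight 2.43.
The genome is `SC(a) – IR(c̄,b) – SC(d) – rev(IR)`, and the two genome
forms differ by the orientation of region 2 (`d`) — the flip-flop
haplotype pair expected between two IR copies.

A shell front end with `scaffold`, `validate` and `generate` subcommands
is installed at `system.file("scripts", "chloroscaf", package = "chloroscaf")`.

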