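---
title: "Deciding and constructing time-consistent species trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding and constructing time-consistent species trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtctree)
```

## The problem

A gene family's history is a rooted gene tree $T$ whose internal vertices
can be annotated with the event that created them: a *speciation*
($\mathfrak{s}$), a *duplication* ($\mathfrak{d}$) or the origin of a
*horizontal gene transfer* ($\mathfrak{t}$), with the transferred copy
hanging off a flagged *transfer edge*.  Each sampled gene belongs to a
species through a surjective map $\sigma$.  Such event-labeled gene trees
can be estimated from sequence data via orthology/paralogy/xenology
relations, without knowing either tree's topology beforehand.

An annotated gene tree is *biologically feasible* only if some species
tree $S$ exists into which it can be embedded by a reconciliation map
$\mu$ that (i) respects the events — leaves map to their species,
speciations to species-tree vertices, duplications and transfer origins
to species-tree edges — and (ii) is *time-consistent*: there are strictly
increasing time maps $\tau_T, \tau_S$ under which no gene lineage jumps
backwards in time.  Transfers are the crux: a transferred gene must land
in a lineage that *coexists* with the donor, which couples the embedding
to the (unknown) relative timing of the species tree.  With the species
tree given, time-consistency is a known polynomial check; this package
solves the harder problem where $S$ is unknown (or only partially
resolved), in overall cubic time in the number of genes.

## The two certificates

Everything the gene tree says about $S$ is condensed into two objects.

**Informative triplets** $\mathcal{R}(T;t,\sigma)$.  Deleting the
transfer edges from $T$ leaves a forest whose components evolve
vertically.  A species triplet $AB|C$ is forced whenever (1) some
component displays a gene triplet $ab|c$ over three distinct species
whose component-lca is a speciation, or (2) two genes of species $A,B$
sit below one endpoint of a transfer edge and a gene of species $C$ below
the other — donor and recipient lineages must be separated in $S$.  A
reconciliation (time-consistent or not) exists iff $\mathcal{R}$ is
compatible, and any $S$ displaying $\mathcal{R}$ admits one
(`informativeTriplets`, `speciationTriplets`, `transferTriplets`).

**The auxiliary timing digraph** $A(T,S)$ (`buildAuxGraph`).  Its
vertices are the gene-tree and species-tree vertices; its edges encode
"must predate" constraints of four kinds: every gene-tree edge with
leaves/speciations replaced by their lca-image in $S$ (A1), every
species-tree edge (A2), an edge from each duplication/transfer vertex
down to its lca-image (A3), and, for each transfer edge, an edge from the
lca of the two endpoint images down to the transfer origin (A4) — the
donor must predate the divergence point of donor and recipient lineages.
$T$ admits a time-consistent reconciliation with $S$ **iff** $S$
displays $\mathcal{R}$ and $A(T,S)$ is acyclic (`verifySolution`).

## The solver

`solveGtc` starts from the star tree over the observed species (or any
user-supplied almost binary tree whose only multifurcations are
cherries) and resolves one cherry per iteration through *good split
refinements*.  For a cherry $x$, an Aho-style constraint graph on the
leaves below $x$ (`goodSplitGraph`) joins two species whenever splitting
them apart would either contradict a triplet of $\mathcal{R}$ (C1) or
create an edge into $x$ of the refined $A(T,S)$ from a vertex that is not
yet in the *maximal topological sort* of the current graph, or a
self-loop at $x$ (C2–C4).  The maximal topological sort
(`maximalTopologicalSort`) is the inclusion-maximal set of vertices
peelable at in-degree zero; its membership set is unique regardless of
tie-breaking, and it equals the whole vertex set exactly when the graph
is acyclic.  If some cherry whose strict ancestors are all already
sorted has a disconnected constraint graph, any disconnected bipartition
yields a refinement that keeps triplet agreement and strictly extends
the sort; if no cherry qualifies while the tree is still non-binary, no
solution exists at all, and the solver reports so.  At most
$|\Sigma|-2$ iterations are possible, each costing low-order polynomial
work on top of the (worst-case cubic) triplet set, which is computed
once.

The package re-verifies the final tree with the two-part
characterization before reporting success; the trace of applied splits
is returned for reproducibility.

## Reconciliation and time maps

For a verified pair, `constructReconciliation` produces an explicit
embedding and `constructTimeAssignment` explicit times; both are checked
by literal, independent re-implementations of the constraints
(`checkReconciliation`: leaf anchoring, event constraints including
incomparability of transfer endpoints and of speciation children,
ancestor constraints along transfer-free paths; `checkTimeAssignment`:
strict monotonicity along *all* gene-tree edges, shared times for
leaves/speciations, strict interior times for edge-mapped vertices).

Two design points deserve a note:

* **Edge placement of duplications and transfers.**  Mapping every
  $\mathfrak{d}/\mathfrak{t}$ vertex to the species edge directly above
  the lca of its species set is the textbook construction for *plain*
  reconciliation, but it can be temporally impossible even when a
  time-consistent map exists: a transfer chain can force such a vertex
  to predate that lca's parent.  The package therefore derives times
  first — integer topological ranks of $A(T,S)$, species vertices and
  $\mathfrak{d}/\mathfrak{t}$ vertices each carrying their own rank —
  and then places each $\mathfrak{d}/\mathfrak{t}$ vertex on the unique
  edge of its lca's root path whose rank interval contains the vertex's
  rank.  When $A(T,S)$ is cyclic (no time-consistent map exists) the
  lca-edge placement is used instead, so that a valid plain
  reconciliation is still produced for any displaying tree.  The
  constructed objects are always passed through the checkers; a checker
  failure would be an internal error, not a silent result.
* **Exact arithmetic.**  Only the order of times matters, so all times
  are integers (ranks); strictness checks use exact comparisons with no
  tolerances.

A vertex mapped above the species root (possible for crafted instances
with pre-speciation histories) is encoded on the conceptual *planted
edge* with an absent parent end; the simulator never produces such
instances because gene histories start at the first speciation.

## Determinism and tie-breaking

All outputs are reproducible: children of every tree vertex are kept in
canonical order (by smallest descendant label), internal vertex ids are
assigned in depth-first reading order, Kahn peeling breaks ties by
species-before-gene then lexicographic id (harmless, since the sorted
*set* is tie-break invariant — a property the tests exercise with random
priority orders), cherries are scanned by smallest descendant species,
and the bipartition applied is always the component holding the
lexicographically smallest species versus the rest.  Splits at binary
cherries are skipped: they are the identity refinement and cannot make
progress.

## The simulator

`simulateInstance` emulates gene-family evolution inside a known timed
species tree, so that ground truth exists by construction:

* an ultrametric binary species tree on `nSpecies` leaves with distinct
  speciation times (uniform on the unit tree height, merged
  coalescent-style);
* a gene lineage entering at the first speciation and, along each
  branch, experiencing duplications, transfers and losses at exponential
  waiting times with rates `dupRate`, `transferRate`, `lossRate` per
  lineage per unit height (defaults 0.3/0.3/0.2, a mid-range regime that
  yields a few transfers on typical trees without exploding the family);
* transfer recipients drawn uniformly among the species branches alive
  at the transfer time — this is what guarantees a time-consistent
  embedding exists;
* an observability projection: extinct subtrees are removed,
  pass-through vertices suppressed, and a transfer event is kept only
  when both its vertical and horizontal lines retain sampled
  descendants.  A horizontal copy whose donor line died out is treated
  as unsampled, because the event-labeled model cannot attach a transfer
  edge to a non-transfer vertex; this mirrors the axiom that observable
  transfers leave traces on both sides.

The resulting instances always satisfy the observability axioms (every
internal vertex has two surviving lines; transfer vertices keep one
edge of each kind; speciation children and transfer-edge endpoints have
disjoint species sets in the transfer-free forest), and the true species
tree restricted to the observed species verifies as a solution.

What the simulator does *not* emulate: event-annotation errors (labels
are exact by construction), non-binary gene trees (multifurcations enter
the test suite only as crafted fixtures), rate heterogeneity across
branches, replacing transfers, and incomplete lineage sorting.  Passing
tests on simulated data therefore certify the algorithmic contracts, not
robustness to noisy annotations of real data.

## Worked fixture

`exampleGtcInstance` ships a small instance over species A–D with three
nested transfers whose informative triplets are exactly
$\{AB|D, AC|D\}$.  It reproduces, end to end, the canonical behavior of
the theory: the least resolved displaying tree `((A,B,C),D);` admits a
reconciliation but no time-consistent one (the auxiliary graph has a
cycle through the transfer chain), while the refinement
`(((A,B),C),D);` is time-consistent and is found by the solver from the
star in two split refinements, the first separating D after a
four-vertex, two-edge constraint graph, the second resolving the
remaining cherry.  The fixture is a synthetic construction, checked by
the test suite against all of these properties.

## Problem sizes used by the checks

The test suite and the acceptance script work at desk scale, chosen to
exercise every code path while keeping a full run in minutes: verdict
cross-validation against brute force over all 3/15/105 binary species
trees on 3–5 species (about 300 instances, including event-perturbed
copies and crafted incompatible cases); 200 simulated instances on 4–20
species for solver completeness and reconciliation/time-map round trips;
100 transfer-free instances against an independent BUILD implementation
(`ahoBuild`); 200 instances of at most 12 leaves against a literal
brute-force triplet extractor.

## Limitations

The solver returns one binary solution (there may be exponentially many,
and non-binary least-resolved solutions are out of scope); event labels
and transfer flags are trusted as given, with no error correction;
cost-based (parsimony) reconciliation is a different, NP-hard problem
that this package deliberately does not touch.
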