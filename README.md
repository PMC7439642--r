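# gtctree

Deciding whether an event-labeled gene tree is biologically feasible —
and building a species tree that proves it.

## The problem

Gene families evolve inside species trees through **speciations** (𝔰),
**duplications** (𝔡) and **horizontal gene transfers** (𝔱).  Methods
based on pairwise orthology/paralogy/xenology relations can annotate a
gene tree `(T; t, σ)` with these events (plus flagged transfer edges and
a gene→species map σ) without knowing the species tree.  Such an
annotated tree is only *biologically feasible* if some species tree `S`
admits a **time-consistent reconciliation**: an embedding `μ` of the gene
tree into `S` with strictly increasing time maps `τ_T, τ_S`, so that no
transferred gene lands in a lineage it could never have coexisted with.

`gtctree` answers the question *"does a time-consistent species tree for
this gene tree exist, and what does one look like?"* in polynomial
(cubic) time.  It is aimed at phylogenomics researchers who infer
event-labeled gene trees and want to test their feasibility, recover the
species tree signal they carry, or generate calibrated test instances.

The decision rests on two certificates:

* the **informative triplets** `R(T;t,σ)` — species triplets `AB|C`
  forced either by a speciation vertex of the transfer-free forest or by
  the two sides of a transfer edge; a species tree must display all of
  them (necessary and sufficient for a plain reconciliation);
* the **auxiliary timing digraph** `A(T,S)` on gene and species vertices,
  with four edge classes encoding "must predate" constraints; `S` is
  time-consistent for the gene tree **iff** it displays `R` and `A(T,S)`
  is acyclic.

The solver starts from the star tree over the observed species (or any
almost binary starting tree) and resolves one cherry per iteration with
**good split refinements**, read off the connected components of an
Aho-style constraint graph, until the tree is binary or provably no
solution exists.

## Worked example

The bundled fixture is a seven-gene family over species A–D with three
nested transfers:

```r
library(gtctree)
ex <- exampleGtcInstance()
ex$geneTree
#> GeneTree: 7 genes over 4 species; 3 speciations, 0 duplications, 3 transfer vertices, 3 transfer edges

formatTriplets(informativeTriplets(ex$geneTree))
#> [1] "A,B|D" "A,C|D"
```

Two species trees display these triplets, but displaying is not enough:

```r
verifySolution(ex$geneTree, ex$leastResolvedTree)   # ((A,B,C),D);
#> [1] FALSE      -- reconcilable, but A(T,S) has a cycle: not time-consistent
```

The solver refines the star tree and finds the (here unique) binary
solution:

```r
res <- solveGtc(ex$geneTree)
res$status
#> [1] "solved"
writeNewick(res$speciesTree)
#> [1] "(((A,B),C),D);"
res$trace
#>   cherry sideA sideB
#> 1     v0 A,B,C     D
#> 2     x1   A,B     C
```

The trace records each applied split: first D is separated from
{A,B,C} (the star-phase constraint graph on four species has exactly two
edges, A–B and A–C, leaving D isolated), then the {A,B,C} cherry is
resolved.  An explicit embedding with exact integer times comes from the
topological order of `A(T,S)`:

```r
mu  <- constructReconciliation(ex$geneTree, res$speciesTree)
tau <- constructTimeAssignment(ex$geneTree, res$speciesTree, mu)
head(cbind(mu, tau = unname(tau$tauT[mu$vertex])), 5)
#>   vertex event   type head tail tau
#> 1     v0     S vertex   v0 <NA>   1
#> 2     v9     S vertex   x2 <NA>  16
#> 3     v7     T   edge   v4   v0  14
#> 4     v5     T   edge   x2   x1  12
#> 5     v3     T   edge   v3   x1   9
```

Speciations sit on species vertices, transfer origins on species edges
(`head`/`tail` are the edge endpoints), and every constraint — leaf
anchoring, event constraints, ancestor constraints, strict timing — is
re-verified by independent checkers
(`checkReconciliation`, `checkTimeAssignment`), which report zero
violations here.

Other entry points: `readGeneTree` (NHX input with `ev=S|D|T`, `xfer=1`
and `S=<species>` tags, or a TSV species map), `validateObservability`
(the three observability axioms), `simulateInstance`
(duplication–transfer–loss simulation along a known timed species tree),
`allBinarySpeciesTrees` and `ahoBuild` (brute-force and BUILD oracles).
A command-line wrapper with `solve`, `validate`, `triplets`, `check` and
`simulate` subcommands lives in `inst/scripts/gtc-tool.R`.

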