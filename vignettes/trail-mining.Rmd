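---
title: "Mining maximum-span supported trails across metabolism and gene order"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining maximum-span supported trails across metabolism and gene order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailspan)
```

## The model

Bacterial genomes tend to keep functionally coupled genes close together:
operons and conserved gene clusters often encode consecutive steps of a
metabolic route. `trailspan` looks for exactly this signal. It couples three
objects for one species:

* a **directed reaction graph** `D`, one per metabolic pathway, whose
  vertices are reactions and whose arc $(r_i, r_j)$ states that $r_i$
  produces a metabolite consumed by $r_j$;
* an **undirected gene-neighborhood graph** `G'` over the species' genome,
  linking two protein-coding genes when they lie on the same strand of the
  same chromosome with at most $\delta_G$ genes between them;
* a **correspondence** mapping each reaction to the genes whose products
  catalyze it.

From these a derived undirected graph `G` on the vertex set of `D` links
two reactions when some gene of one is adjacent in `G'` to a gene of the
other. Two reactions catalyzed by the *same* gene are also linked: a gene
is trivially in its own neighborhood, and without this rule a two-reaction
chain carried by one bifunctional enzyme could never be supported.

Metabolic pathways contain cycles (reversible reactions among others), so
solutions are **trails** — walks that may repeat vertices but never an arc
— rather than paths. The **span** of a trail is its number of distinct
reactions:

```{r}
trail_span(trail(c("r2", "r3", "r7", "r8", "r3", "r4")))
```

The core problem solved here: given `D`, `G` and an arc $(u, v)$, find a
trail of maximum span through $(u, v)$ whose distinct vertices induce a
connected subgraph of `G`. Running the solver once per arc yields several
trails per pathway instead of a single global optimum. The problem is
NP-hard in general, which shapes the algorithm and the timeout machinery
below.

## The exact solver

`max_span_trail()` is exact but not exhaustive: among several maximum-span
trails through an arc it reports one (ties resolved toward the
lexicographically smallest reaction sequence, purely for determinism). It
works in the line graph `L(D)`, whose vertices are the arcs of `D`; a trail
in `D` is precisely a simple path in `L(D)`, so arc-distinctness is
guaranteed by construction. The steps:

1. **Reduction.** `graph_reduction()` prunes, to a fixpoint, vertices that
   cannot belong to any supported trail through $(u,v)$: a surviving vertex
   must be connected to $u$ in the underlying undirected restriction of `D`
   and connected to $u$ or $v$ in the restriction of `G`. Both conditions
   are necessary for membership in a solution, so pruning preserves the
   optimum — a property the test suite asserts arc-by-arc on random
   instances rather than takes on faith.
2. **Condensation.** Strongly connected components of `L(D)` are
   contracted (via igraph) into an acyclic quotient `C`. SCC labels follow
   a topological order with deterministic tie-breaks.
3. **Access points and partial paths.** For every SCC, entry points from
   each predecessor SCC and exit points toward each successor are recorded.
   Simple paths are then enumerated inside each SCC between the pairs a
   translation can need. Because any SCC can open or close a translated
   path, sources and destinations degenerate to all members; the
   entry-to-exit restriction only bites for internal segments.
4. **Concatenation.** Every path of `C` through the SCC containing $(u,v)$
   is translated into candidate paths of `L(D)` by concatenating stored
   partial paths across the actual connector arcs between consecutive
   SCCs. Each candidate containing the query arc is mapped back to its
   trail, checked for support in `G`, and the best supported trail is kept.

### Why the store keeps more than one "best" partial path

Within one SCC, two source-to-destination paths can touch the same
reactions through different arcs, and per-SCC optima need not compose to a
global optimum because different segments may revisit the same reaction of
`D`. The store therefore keeps, for every (source, destination) pair, one
representative per distinct *set of traversed line-graph vertices*, ranked
by the span of the corresponding trail. Deduplicating on the coarser set of
touched reactions is tempting but wrong: it can discard the only
representative that actually traverses the query arc. With the finer key,
any optimal solution has, segment by segment, an interchangeable stored
representative, which is what makes the assembled optimum exact; the
oracle-equivalence tests (below) pin this property down empirically.

### Worked example

The bundled ten-reaction instance exercises every part of the machinery:
a central cycle, a detour creating a repeated vertex, a source and a sink
branch. Its companion graph is complete, so support never constrains and
the printed maxima are pure trail structure:

```{r}
fx <- fig1_instance()
max_span_trail(fx$D, fx$G, c("r1", "r2"))
max_span_trail(fx$D, fx$G, c("r2", "r7"))
```

### Gene-level consistency

Support in `G` is a lifted, lossy summary of gene adjacency, so accepted
trails are re-checked against `G'` itself: `genomic_consistency()` asks
whether *some* selection of one or more catalyzing genes per trail reaction
induces a connected subgraph of `G'`. The "some selection" reading (rather
than all catalyzing genes at once) matches how isoenzymes scattered around
a genome should not veto a tight cluster that suffices on its own. Despite
the combinatorial flavor the check is polynomial: a qualifying selection
exists exactly when one connected component of the subgraph induced by all
candidate genes covers every trail reaction.

## Gap parameters

Strict adjacency is often too rigid: a single intervening gene (*ftsW*
inside the *E. coli mur* cluster is the textbook case) or one reaction
absent from an organism would break otherwise perfect chains. Two
preprocessing knobs relax the model, both defaulting to 0 and documented
for the range 0–3 — larger values rapidly lose biological meaning:

* $\delta_D$ (`expand_gaps_directed()`): adds an arc $(a, c)$ whenever a
  directed path with at most $\delta_D$ intermediate reactions leads from
  $a$ to $c$. The relation is directed on purpose; skipping must follow
  metabolite flow, not undirected proximity.
* $\delta_G$ (`build_gene_graph()`): links genes separated by at most
  $\delta_G$ others on the same strand. Non-enzyme genes occupy positions
  and count toward the separation. Genome tables carry a per-chromosome
  `circular` flag (default linear, since downloaded gene lists are linear)
  and neighborhoods wrap across the origin when it is set.

## Timeouts and the blacklist

Path enumeration is exponential in the worst case — that is intrinsic, not
an implementation artifact. Each pathway run gets a wall-clock budget
(default 300 s). A pathway that exhausts it without yielding a single
record is appended to a plain-text blacklist keyed by species, pathway and
the gap pair; a blacklisted entry also covers every componentwise larger
gap pair, because adding arcs and edges only enlarges the search space.

## Grouping across species

Trails are compared across species as **reaction sets** (order and
repetition dropped): reversed or partially re-ordered routes and repeated
vertices are the same biological pattern. Two genes count as *neighboring*
at this stage when at most three genes separate them — a fixed, slightly
laxer rule than the solver's $\delta_G$, applied uniformly so grouping does
not depend on which gap setting produced a trail. From the pooled sets of a
reference species `S`, two tables are built against an ordered species
panel (the order is supplied by the user; the package deliberately does not
infer a phylogeny):

* **By reactions** (`group_by_reactions()`): one row per (reaction set,
  reaction). For each other species, a maximum subset of the row's set
  whose reactions are carried by neighboring genes of that species gets
  crosses (`x`); reactions the species performs outside that neighborhood
  get dots (`.`); reactions it does not perform at all stay blank. The
  subset search runs over maximal runs of candidate genes: including more
  genes of a run never breaks the chain condition, so maximal runs are
  exactly the candidates and the search is linear rather than a subset
  enumeration.
* **By genes** (`group_by_genes()`): rows are the reference genes involved
  in reaction sets shared — as identical sets — with at least one other
  species, ordered by chromosome, strand and position, and partitioned
  into maximal neighboring groups. Per group and species, the neighboring
  set of that species' functionally similar genes maximizing the number of
  matched reference genes is chosen; matched genes get `x`, the rest `.`.
  A dot here is deliberately ambiguous between "reaction absent" and
  "genes not clustered"; the by-reactions table is the one that separates
  those cases.

Row order inside a reaction-set block follows the position of the
reference genes catalyzing each reaction, which keeps the table aligned
with the genome browser view a curator would check it against. All
orderings are byte-wise (`method = "radix"`), so reruns are byte-identical
across locales.

```{r}
fx <- table1_instance()
pooled <- list(
  S  = species_data(fx$genomes$S,  fx$correspondences$S,  fx$records$S),
  S1 = species_data(fx$genomes$S1, fx$correspondences$S1, fx$records$S1))
tbl <- group_by_reactions(panel_config("S", "S1"), pooled)
cbind(tbl$rows, tbl$cells)
```

The bundled two-genome instance attributes the same reaction set to both
species, including a reaction the second species cannot perform. That is a
didactic device, not a solver output: the strict shared-set rule would
otherwise leave the by-genes table without rows, and the instance exists
precisely to pin down the symbol semantics of both tables on a case where
they differ.

## The synthetic-data generator and what passing tests show

`random_instance()` draws Erdős–Rényi-style reaction graphs (default 6
reactions, arc density 0.3), a one-chromosome genome with genes split
randomly across both strands, and a Bernoulli reaction–gene incidence
(default 8 genes, rate 0.3). These sizes keep instances inside the reach
of `brute_force_max_span()`, the independent exhaustive oracle (guarded at
16 arcs), while arc spans of 4–14 still produce nontrivial SCC structure,
unsupported arcs and disconnected components. The generator emulates graph
shape, not biochemistry: it has no bias toward long linear chains, no
reversible-reaction pairing, no operon-like clustering of the
correspondence. Passing the oracle-equivalence corpus therefore certifies
the combinatorial core exactly on small dense instances; it says nothing
about runtime behavior on large sparse KEGG maps, which the timeout
machinery, not the tests, is responsible for.

Test problem sizes were chosen to keep the full suite comfortably within a
desk-scale run: 100 seeded oracle instances (every arc, solver vs. oracle
and reduced vs. unreduced) in the acceptance corpus and smaller sweeps in
the property tests.

## Numerical and degenerate-input choices

* Empty pathway, arcless graph, or arc with no supported trail: the solver
  returns an explicit empty solution (span 0) so per-arc iteration can
  proceed; `solve_pathway()` simply drops it.
* Duplicate KGML arcs collapse and self-loops are dropped; the reaction
  graph is a simple digraph throughout.
* Reversible KGML reactions contribute arcs in both directions — cycles in
  pathways largely come from reversibility, and the trail formulation
  exists to handle them.
* When one KGML `<reaction>` element names several reaction numbers, each
  becomes a vertex sharing that element's substrates and products.
* Ties anywhere (solver solutions, neighborhood candidates) resolve by
  byte-order lexicographic comparison; no result depends on hash order or
  locale.

## Known limitations

* The per-arc loop re-solves arcs already covered by earlier trails;
  results are deduplicated afterwards (exact duplicates and contiguous
  sub-trails dropped) rather than skipped up front.
* Functional similarity across species is purely "involved in the same
  reaction"; there is no orthology inference, operon prediction or EC
  hierarchy reasoning.
* The optional KEGG REST retrieval of the original workflow is out of
  scope; local KGML/TSV files are the contract.
* Reference genes belonging to two overlapping neighboring groups cannot
  occur under the maximal-run partition; this is a modeling choice, and
  other group definitions would need a tie rule.
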