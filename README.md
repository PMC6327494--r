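# trailspan

Exact mining of **maximum-span supported trails**: chains of metabolic
reactions whose enzymes are encoded by neighboring genes, and the
conservation of such chains across species.

## The problem

Bacteria keep functionally coupled genes clustered — operons encoding
consecutive steps of a metabolic route are the classic example. To detect
this signal systematically, a species is modeled as

* a directed reaction graph *D* per metabolic pathway (an arc
  (*r_i*, *r_j*) means *r_i* produces a metabolite consumed by *r_j*),
* an undirected gene-neighborhood graph *G′* over its genome (same strand,
  same chromosome, at most δ_G genes between), and
* a correspondence mapping each reaction to the genes catalyzing it,

from which a derived graph *G* on the reactions links *r_i* and *r_j* when
their genes are neighbors (or identical). Because pathways contain cycles,
solutions are **trails** — walks that may repeat vertices but never an
arc. The **span** of a trail is its number of distinct reactions. For each
arc (*u*, *v*) of *D* the solver returns a trail of maximum span through
(*u*, *v*) whose distinct vertices induce a connected subgraph of *G*. The
problem is NP-hard; the solver is exact regardless, working in the line
graph *L(D)* with SCC condensation, per-component path enumeration and
partial-path concatenation, plus a solution-preserving graph reduction and
a per-pathway timeout with a persistent blacklist for the hard cases.

Per-species trails are then pooled as reaction sets and compared across a
species panel, producing two CSV tables per reference species: by
reactions (symbols `x` / `.` / blank: clustered / performed elsewhere /
absent) and by genes (`x` / `.`).

## Worked example

The bundled ten-reaction instance (`fig1_instance()`) has a central cycle,
a detour, a source and a sink branch; its companion graph is complete so
connectivity never constrains:

```r
library(trailspan)
fx <- fig1_instance()
fx$D
#> <pathway_graph> 10 reactions, 12 arcs
max_span_trail(fx$D, fx$G, c("r1", "r2"))
#> <masst_solution> through r1->r2: (r1, r2, r3, r4, r5, r6, r2, r7, r8), span 8
max_span_trail(fx$D, fx$G, c("r2", "r7"))
#> <masst_solution> through r2->r7: (r4, r5, r6, r2, r7, r8, r3, r4, r9, r10), span 9
```

Through (r1, r2) no trail can reach more than 8 distinct reactions; any
arc inside the central cycle admits a span of 9 (note the repeated vertex
r4 — a trail, not a path). `brute_force_max_span()` is an independent
exhaustive oracle that confirms both values.

Grouping on the bundled two-genome instance (`table1_instance()`;
reference species S against S1):

```r
fx2 <- table1_instance()
pooled <- list(
  S  = species_data(fx2$genomes$S,  fx2$correspondences$S,  fx2$records$S),
  S1 = species_data(fx2$genomes$S1, fx2$correspondences$S1, fx2$records$S1))
tbl <- group_by_reactions(panel_config("S", "S1"), pooled)
cbind(tbl$rows, tbl$cells)
#>              set reaction S1
#> 1 r2;r3;r6;r7;r8       r2  .
#> 2 r2;r3;r6;r7;r8       r8  x
#> 3 r2;r3;r6;r7;r8       r3   
#> 4 r2;r3;r6;r7;r8       r7  x
#> 5 r2;r3;r6;r7;r8       r6  x
```

Reactions r6, r7, r8 are carried in S1 by the neighboring genes T1, W1,
X1 (one non-enzyme gene is skipped), r2 is performed by a distant gene
(dot), and r3 is absent from S1 (blank).

## Command line

Thin wrappers over the package functions live in `inst/cli/`:

```sh
Rscript inst/cli/trailfind.R --species eco --pathways kgml/ --genome eco.tsv \
        --dD 1 --dG 1 --timeout 300 --blacklist blacklist.txt -o eco_trails.tsv
Rscript inst/cli/group.R --panel panel.yaml --results results/ --genomes genomes/ -o tables/
```

Pathways are KGML files (or `from`/`to` TSV edge lists); genome tables are
TSV with columns `species, gene_id, chromosome, strand, position,
reactions`. Formats are documented in the function reference
(`?read_genome_table`, `?parse_kgml`).

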