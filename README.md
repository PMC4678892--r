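# filamentcover

Networks extracted from images of filamentous structures — actin
cytoskeletons, microtubule arrays, neuronal arbors, galaxy filaments —
represent filament *segments* as weighted edges. Classical network analysis
therefore loses the identity of the individual filaments: a single filament
is scattered over many edges, crossings conflate unrelated filaments, and
overlapping filaments share edges. `filamentcover` recovers the individual
filaments from any weighted geometric graph, and quantifies how well two
filament assignments agree.

## The filament cover problem

A filamentous network is a weighted geometric graph *G* with *N* positioned
nodes and *E* undirected edges whose weights *w<sub>e</sub>* > 0 encode
segment intensity or thickness. A filament is an edge-path
*p* = (*e*<sub>p,1</sub>, …, *e*<sub>p,P</sub>), an ordered sequence of
adjacent edges (a closed path models a loop filament). Path quality is
measured by roughness functionals:

- **pairwise**: r<sub>pair</sub>(p) = (1/(P−1)) Σ |w<sub>p,i+1</sub> −
  w<sub>p,i</sub>| — mean absolute weight change between adjacent edges;
- **all-to-all**: r<sub>all</sub>(p) = (1/P) Σ<sub>i</sub> max<sub>j</sub>
  |w<sub>p,i</sub> − w<sub>p,j</sub>| — mean per-edge maximal weight
  difference;
- a single-edge path scores its own weight, which penalises fragmentation;
- **angular**: the maximal deflection angle between consecutive oriented
  segments (0° = straight).

The **filament cover problem (FCP)** asks for a set of edge-paths of
minimal total (or average) roughness such that every edge is covered at
least once (overlapping filaments allowed) or exactly once (an exact
cover). The FCP is intractable in general, so candidate paths are sampled
first — by an angle-constrained breadth-first search (all paths whose
deflections stay below 60°, including closed loops) or from 100 random
minimal spanning trees — and the binary set-cover program

min Σ<sub>p</sub> r<sub>p</sub> x<sub>p</sub> / (Σ x<sub>p</sub>)<sup>A</sup>  s.t. Σ<sub>p ∋ e</sub> x<sub>p</sub> ≥ 1 (or = 1) for every edge *e*,  x<sub>p</sub> ∈ {0, 1}

is solved exactly over the sample by branch-and-bound (the average
objective, A = 1, via Dinkelbach's iteration). All four choices —
sampling, cover type, roughness measure, objective — are categorical, so
all 2⁴ = 16 combinations can be checked without parameter tuning.

Covers are compared with the variation of information VI, the Rand index
RI and the Jaccard index JI, plus their **structure-aware** variants
RI<sup>d</sup>/JI<sup>d</sup> that count only edge pairs separated by at
most *d* nodes in the graph: d = 1 restricts to adjacent edge pairs (local
agreement), d = ∞ recovers the classical indices. Filament identities
between two covers are aligned by a Hungarian assignment maximising shared
edges.

## Worked example

The built-in benchmark scene plants seven filaments — four crossing open
filaments, a pair sharing a three-edge run, and a closed loop — with
per-filament intensities and 2% Gaussian weight noise:

```r
library(filamentcover)

sc  <- contrived_scene(seed = 1)             # graph + planted ground truth
sc$graph
#> <filament_graph> 72 nodes, 71 edges (2D)
#>   edge weights in [0.6989, 1.012]

sol <- solve_fcp(sc$graph, cover_options("bfs", "over", "pair", "total"))
sol
#> <filament_cover> 7 filaments, 75 edge slots (R = 0.270487)

compare_covers(sol, sc$cover, sc$graph, d_list = c(1, Inf))
#>     d        RI       JI
#> 1   1 1.0000000 1.000000
#> 2 Inf 0.9983903 0.990099
```

All seven filaments are recovered: the structure-aware agreement with the
planted cover is perfect (RI¹ = JI¹ = 1; 75 edge slots > 71 edges because
the two overlapping filaments both cover the shared run). The classical
JI at d = ∞ is 0.99 because the solver returned the cost-equivalent
routing of the two overlapping filaments through the shared run, which is
indistinguishable locally. Per-filament measures
(`filament_metrics(sol, sc$graph)`) include edge counts, geometric length,
mean weight, both roughness values, maximal angle, median orientation and
convolutedness; the loop shows up with convolutedness 3.11, the straight
filaments near 1.

`write_cover_gml()` stores filament identities as edge attributes,
`write_filament_csv()` the per-filament table. The same pipeline is
scriptable from the shell:

```sh
exec/filamentcover simulate --contrived --seed 1 --out scene.gml --out-truth truth.gml
exec/filamentcover decompose scene.gml --sampling bfs --cover over \
    --roughness pair --objective total --out-gml cover.gml --out-csv cover.csv
exec/filamentcover compare cover.gml truth.gml --d-list 1,inf
```

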