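---
title: "Decomposing filamentous networks: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing filamentous networks: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filamentcover)
```

## The model

A filamentous structure is represented as a weighted geometric graph:
nodes carry 2D (or 3D) positions, edges carry positive weights encoding
the local intensity or thickness of the filament segment they represent.
An individual filament is an edge-path — an ordered sequence of adjacent,
pairwise-distinct edges; a closed edge-path models a loop filament. The
package deliberately does not touch image processing: it starts from the
graph (GML input) and ends at filaments (GML/CSV output).

Path quality is scored by roughness functionals over the traversal-ordered
edge weights $w_{p,1}, \dots, w_{p,P}$:

* **pairwise roughness** $r_{pair}(p) = \frac{1}{P-1}\sum_{i=1}^{P-1}
  |w_{p,i+1}-w_{p,i}|$ — small when thickness varies smoothly along the
  filament, as expected for physical filaments;
* **all-to-all roughness** $r_{all}(p) = \frac{1}{P}\sum_i \max_j
  |w_{p,i}-w_{p,j}|$ — a single abrupt jump (e.g. where two filaments
  superpose and the apparent thickness doubles) dominates every edge's
  maximum, so this measure penalises globally bimodal filaments that the
  pairwise measure tolerates;
* a **single-edge path scores its own weight**. This convention is load-
  bearing: it makes fragmenting a network into singleton filaments
  expensive and thereby drives the optimisation toward long coherent
  filaments;
* the **maximal deflection angle**: edges are oriented along the traversal
  direction (never by stored node order — deflection is direction-
  dependent) and the maximum angle between consecutive segment vectors is
  taken; dot products are clipped to $[-1,1]$ before `acos`.

The **filament cover problem** selects, from a candidate path set, a
subset of minimal total (or average) roughness covering every edge at
least once (`over`) or exactly once (`exact`). Overlapping covers model
physically superposed filaments; exact covers force edge-disjointness.

### Reading of "average maximal difference"

The all-to-all measure is described verbally as the *average maximal
difference between any two edge weights*. Two parses are defensible: the
mean over edges of each edge's maximal absolute difference to any other
edge (the literal parse of "average maximal"), or the plain range
$\max w - \min w$. The per-edge-max mean is the default; the range is
available as `all_variant = "range"` in `cover_options()`. For a path with
weights $(0.2, 0.5, 0.3)$ the two give $0.8/3 \approx 0.267$ and $0.3$.

## Candidate path sampling

Enumerating all edge-paths is hopeless, so the program is built over a
sampled candidate set, always augmented with all single-edge paths so that
the covering program is feasible by construction.

**Angle-constrained BFS** (`sampling = "bfs"`) extends partial paths
breadth-wise from every starting edge and prunes any extension whose
newest deflection reaches the straightness threshold (default 60°,
strict, a tolerant estimate of real filament bending). A partial path may
close into a loop only at its own start node, and on closure the
deflection across the seam is checked too — without the seam check, loop
candidates could bend arbitrarily at the junction. Enumerated paths are
canonicalised (lexicographically smaller of path and reversal; loops
rotated to their minimal node id first) and deduplicated. A safety cap
(default $10^6$ paths) raises an explicit resource error rather than
silently truncating: real filament graphs keep the enumeration small
because node degrees are low and crossings meet at wide angles, and inputs
violating that assumption should fail loudly.

**Random minimal spanning trees** (`sampling = "rmst"`, default $T = 100$
trees) draw i.i.d. uniform auxiliary edge weights, compute the MST per
connected component, and add the unique tree path between every node pair.
Trees are loopless, so no candidate ever contains a full cycle — loop
filaments are necessarily over-segmented under this sampler, which is the
documented contrast with BFS sampling. One seeded generator drives all
repetitions, so a fixed seed reproduces the candidate set exactly.

## Solving the covering program exactly

No mixed-integer programming backend is assumed: the binary covering
program is solved by an exact branch-and-bound written for the block
structure of this problem.

* **Decomposition.** Two edges interact only if some candidate path
  contains both. On filamentous graphs with wide-angle crossings, BFS
  candidates rarely bridge filaments, so the program splits into small
  independent blocks whose optima add up. (Tree-path candidates do bridge
  filaments; those instances form one large block and take tens of seconds
  instead of fractions of a second.)
* **Bounds.** Each block search is pruned with the maximum of (a) a
  cost-share bound, $\sum_{e\,\mathrm{uncovered}} \min_{p \ni e} c_p/|p|$,
  and (b) dual-ascent price bounds: prices $y_e \ge 0$ with
  $\sum_{e \in p} y_e \le c_p$ for every path are raised along four
  deterministic edge orders, and $\sum_{e \in U} y_e$ bounds the cost of
  covering any uncovered subset $U$. Both bounds are maintained
  incrementally during the search.
* **Reduced-cost fixing.** With dual-feasible prices and a greedy
  incumbent of value $UB$, any solution containing path $p$ costs at least
  $\sum_e y_e + (c_p - \sum_{e\in p} y_e)$; paths for which this exceeds
  $UB$ are dropped before branching. This is what keeps the large
  tree-path instances tractable.
* **Branching** follows the uncovered edge with the fewest covering
  candidates, with inclusion/exclusion over its cost-sorted candidates.
* **Correctness guard rails.** The price bounds are only used in blocks
  whose costs are all non-negative (a non-negative price vector cannot be
  dual-feasible against a negative-cost path), and the early loop break on
  cost-sorted candidates is likewise disabled when negative costs are
  present. Both situations arise only inside the ratio iteration below.
  Returned covers are re-validated against their constraints independently
  of the solver, and the test suite checks both objectives against
  exhaustive enumeration over all $2^{|\mathcal P|}$ subsets on hundreds
  of random tiny programs.

**Average objective.** Minimising $\sum r_p x_p / \sum x_p$ is a
fractional 0–1 program. It is solved by Dinkelbach iteration: repeatedly
minimise $\sum (r_p - \lambda) x_p$ under the covering constraints and
update $\lambda$ to the incumbent ratio, stopping when the parametric
optimum reaches $-10^{-9}$ (iteration cap 100; the $\lambda$ sequence is
checked to be non-increasing). Dinkelbach is exact and finite for ratio
objectives with a positive denominator, so this is an
equivalent-by-optimality route rather than a monolithic binary
reformulation. $\lambda$ is initialised at the ratio of the all-singletons
cover, which is always feasible and cheap. In overlapping mode, paths
whose shifted cost is negative are always part of a parametric optimum
and are fixed upfront.

Tie-breaking among multiple optimal covers accepts the solver's incumbent;
tests therefore compare objective values, never path identities, except
where the optimum is provably unique.

## Comparing filament covers

Two covers of the same graph are compared on their edge labellings.

* **Distance convention.** The distance between edges is the minimum over
  endpoint pairs of shortest-path length in edges; edges are "separated by
  at most $d$ nodes" iff that distance is $\le d-1$. Hence $d = 1$ selects
  exactly the adjacent edge pairs (local agreement) and $d = \infty$ all
  pairs, recovering the classical indices — the convention is stated
  explicitly because shifting it by one silently changes every
  $RI^d/JI^d$ value.
* **Overlap rule.** For overlapping covers, an edge pair counts as "same"
  when their membership sets intersect — the minimal consistent extension
  of the partition case.
* $RI = (h_{==} + h_{\ne\ne})/h_{tot}$,
  $JI = h_{==}/(h_{==} + h_{=\ne} + h_{\ne=})$ over the admissible pairs;
  the variation of information uses natural logarithms and raises a domain
  error for overlapping covers, where it is not well-defined.
* **Identity matching** between covers solves a rectangular linear
  assignment (Hungarian algorithm, via `clue`) maximising total shared
  edges; surplus filaments stay unmatched.

Why a structure-aware index at all? Classical RI/JI count all
$\binom{E}{2}$ edge pairs, most of which are far apart in the graph and
carry no information about local filament assignment — RI is then
dominated by distant "different/different" agreements and JI by distant
disagreements. $JI^1$ asks the operative question: do adjacent segments
that belong together get assigned together?

## The planted-scene generator

`generate_scene()` draws open polylines with turning angles bounded by
`turn_max_deg`, closes a filament into a loop with probability `p_loop`
(a regular polygon with enough vertices that all deflections, seam
included, stay below the bound), and with probability `p_overlap` routes a
filament along an existing filament's edge run, sharing those edges.
Crossings between polylines become shared nodes that split both edges.
Edge weights follow an additive intensity model: each filament draws a
base intensity $b_f$ uniformly from `base_intensity_range` (default
$[0.65, 0.95]$, the bright-but-unsaturated regime of fluorescence
recordings after normalisation); an edge covered by filaments $F$ gets
$\min(1, \sum_{f \in F} b_f)$ — overlaps saturate, mirroring the abrupt
apparent-thickness increase where physical filaments superpose — plus
centred Gaussian noise (default sd 0.02, clipped at $10^{-6}$ to keep the
roughness domain).

`contrived_scene()` is the benchmark instance used throughout the tests:
a fixed hand-designed layout (four long crossing filaments, one
two-filament shared run entered through single-edge connectors at 30°,
one 12-gon loop; 71 edges), with only the intensities and the noise
drawn from the seed. Fixing the geometry mirrors how such methods are
validated against one drawn test image, and guarantees that crossings,
overlap and loop are present for every seed. Design choices that matter:

* all planted turning angles stay below 45°, so the full planted cover is
  contained in every BFS candidate set at the 60° threshold;
* all crossings meet at 60–120°, so no BFS-admissible path can switch
  filaments at a crossing — recovery of crossing filaments is therefore
  angle-driven and robust to weight noise;
* the overlapping pair has single-edge connectors around the shared run,
  so breaking it apart would create singleton filaments whose roughness
  equals their (large) edge weight — the single-edge convention is what
  makes the planted overlap optimal;
* the two cost-equivalent routings of the overlap pair through the shared
  run are indistinguishable at $d = 1$ (both cover the run), so perfect
  local agreement $JI^1 = 1$ is a well-posed target while the global $JI$
  may legitimately fall just short of 1.

What passing on such scenes does **not** show: real image-derived networks
have spatially varying background, crossing angles near the straightness
threshold, and intensity profiles that are not piecewise-constant plus
noise. The planted scenes are structural analogues for validating the
optimisation and bookkeeping, not emulations of a microscope.

## Robustness protocols

Two protocols probe stability of the decomposition, both scored by mean
$JI^1$ against the planted reference:

* **edge removal**: for $k = 1..50$, delete $k$ random edges, re-solve,
  and compare against the reference restricted to the surviving edges
  (deleted-edge protocols necessarily compare covers of different
  graphs); 3 random subsets per $k$;
* **weight noise**: perturb each weight by centred Gaussian noise with sd
  a given fraction of the weight, re-solve, average over 25 instances per
  level (levels 0–100%). Noise leaves the topology untouched, so the
  candidate set is sampled once and only path costs are recomputed.

On the benchmark scene the decline is well under 0.001 per removed edge
and per 1% noise, and mean $JI^1$ plateaus high at strong noise — the
scene's angle-driven disambiguation means most of the planted structure is
recoverable from topology and geometry alone, which is the designed regime
(and the stated reason the high-noise plateau sits above zero).

## Problem sizes and numerical choices

The suite and the acceptance script use: the 71-edge benchmark scene; 50
random tiny graphs (≤ 8 edges, ≤ 15 candidate paths) × {over, exact} ×
{total, average} for the enumeration oracle; 100 random labelled graphs
for the similarity identities; 50 removal steps × 3 samples and 5 noise
levels × 25 instances for the robustness curves. These sizes keep a full
run in minutes on one CPU while exercising every code path; they are
choices of this package, and all of them scale up by passing larger
parameters.

Other numerical conventions: GML/CSV output at 6 significant digits (for
reproducible text diffs); weights are never rescaled on load (the
single-edge convention makes results scale-dependent, so normalisation —
e.g. `--normalize` in the CLI — is the user's explicit decision);
zero-extent bounding boxes give convolutedness 1; solver tolerance
$10^{-12}$ on cost comparisons and $10^{-9}$ on the Dinkelbach ratio.

## Known limitations

* Optimality is relative to the sampled candidate set; no gap against the
  unrestricted FCP is claimed (the unrestricted problem is intractable).
* Branch-and-bound worst-case time is exponential; tree-path candidate
  sets on larger graphs can become slow even with reduced-cost fixing.
* Convolutedness inherits the orientation bias of axis-aligned bounding
  boxes; the maximal deflection angle is the orientation-free alternative.
* `median_orientation()` folds angles to $[0°, 90°]$; signed orientations
  in $[-90°, 90°]$ are not distinguished.
* The BFS sampler allows node revisits (self-crossing filaments) but a
  path may close only at its own start node; exotic edge-paths that pass
  through their start node and continue are not enumerated.
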