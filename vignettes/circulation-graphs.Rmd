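---
title: "Modeling congenital heart disease as a labeled directed graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling congenital heart disease as a labeled directed graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdgraph)
```

## The model

`chdgraph` represents a circulation as a simple labeled digraph
$G(V, E)$: each vertex is a space through which blood flows (a chamber, a
vessel segment, a lung, or the aggregate of all systemic target organs),
and each edge is a directed blood flow between two spaces.  The canonical
normal heart has 24 vertices in a fixed order — superior vena cava
($v_1$) through the systemic circulation target organs, SCTO ($v_{24}$) —
and 32 directed flows.  SCTO deliberately aggregates brain, viscera and
soft tissue into one vertex so that systemic arteries drain somewhere and
blood returns to both venae cavae: the model is a closed circuit, and
every vertex lies on a directed cycle.

The equivalent algebraic object is the binary adjacency matrix
$A = [a_{ij}]$ with $a_{ij} = 1$ exactly when blood flows from $v_i$ to
$v_j$.  Rows are sources, columns destinations, the diagonal is zero, and
at most one edge joins any ordered pair — a deliberate modeling
restriction, since a 0/1 matrix cannot hold two parallel flows with the
same origin and destination.  Conversions `to_binary_matrix()` /
`from_binary_matrix()` are exact inverses.

Two points in the design were genuinely open and were fixed as follows.

* **The normal edge set.**  The vertex list is published exactly; the
  arrow-by-arrow edge list of the normal heart is shown only pictorially.
  The 32-edge set used by `build_normal_heart()` is the unique
  physiological reading consistent with every published matrix element:
  caval return to the RA, RA→RV→PT, branch pulmonary arteries to the
  lungs, four pulmonary veins to the LA, LA→LV→AAo, the arch giving the
  innominate, left carotid, left subclavian and descending aorta, the
  innominate splitting into right carotid and right subclavian, all five
  systemic arteries draining into SCTO, and SCTO returning to SVC and
  IVC.  The closing edges SCTO→SVC and SCTO→IVC are an interpretation
  (the target-organ vertex exists precisely "to complete the circuit"),
  and the aortic isthmus is not given a vertex of its own.
* **Indexing.**  The public contract is 1-based throughout, matching the
  $v_1 \dots v_{24}$ assignment and element subscripts like $b_{23,25}$.

## Disease and procedure transformations

A condition is an *edit script* over the graph: ordered steps drawn from
`add_vertex`, `add_edge`, `remove_edge`, `isolate_vertex`,
`relabel_vertex` and `interchange_columns`.  The shipped catalog
(`inst/extdata/catalog.yaml`, a user-extensible schema) covers fourteen
CHD manifestations in the five structural categories and six procedures:

```{r catalog}
disease_names()
procedure_names()
```

Choices worth recording:

* **Septal defects** are parameterized by `direction`
  (`left_to_right`, `right_to_left`, `bidirectional`), defaulting to
  bidirectional — the worked tetralogy example shows both VSD
  directions.
* **d-TGA** is encoded as a single interchange of the PT column (5) and
  the AAo column (16): each ventricle keeps its outflow but the great
  arteries swap their origins.  On the normal heart this reproduces the
  four published edge changes exactly; the row's atrioventricular
  concordance values are carried as *assertions* checked after
  application, not as edits.  l-TGA composes two interchanges
  (4↔15, then 5↔16).  The interchange is an involution, which is
  precisely why the arterial switch — the same interchange — undoes
  transposition.
* **"Decreased vertices"** (absent pulmonary artery) keeps the matrix
  dimension and removes the vertex's incident edges: an isolated vertex
  is operationally equivalent to an absent one, and keeping the
  dimension keeps matrices comparable.
* **Truncus arteriosus** relabels vertex 16 rather than adding a vertex;
  the common trunk occupies the ascending aorta's slot and additionally
  feeds the pulmonary trunk (edge 16→5).
* **Extreme tetralogy of Fallot** is the composite
  VSD (bidirectional) + pulmonary atresia + reversal of the PT→RPA edge.
  The reversal is placed in the composite, not the shunt script: the
  right mBT shunt's published manifestation is exactly two elements
  ($b_{23,25}, b_{25,6}$), while the retrograde filling of the trunk is
  part of the shunted-TOF physiology.
* New vertices always take index $n+1$; strict application refuses
  edits that do not apply (removing an absent edge, duplicating an
  edge), with a lenient mode that downgrades these to warnings.

## Viability: the two-path survival rule

A circulation is compatible with life when *there exists a lung with a
path from the systemic venous return into it and a path from it to the
systemic arterial supply*.  `check_survival()` checks exactly this
connectivity condition (defaults: sources SVC/IVC, lungs RL/LL, target
AAo) and returns witness paths for audit:

```{r survival}
check_survival(build_condition(c("d-TGA", "VSD")))
```

Transposition without a septal defect fails the rule — venous blood is
pumped straight back to the aorta without gas exchange — and a VSD
restores both paths.  The rule is connectivity-only by design: adequacy
of mixing, pressures and saturations are out of scope, and other unknown
factors may still decide survival.  An optional stricter flag
(`require_full_circuit`) additionally demands that the arterial target
reach a venous source, closing the systemic loop; the classical rule
states only the two paths, so the flag is off by default.

## Five-category structural classification

`classify_diff()` compares two matrices element-wise and assigns the
differences to five categories: increased vertices, decreased vertices,
increased edges, decreased edges, abnormal connections.  The
interesting case is the last one: a removed edge paired with an added
edge sharing its source (or sharing its destination with changed
source) is reported as one *rewiring* rather than as an independent
loss plus gain.  This heuristic reproduces the accepted assignments —
transposition, DORV and truncus classify as abnormal connections while
a VSD stays a pure edge increase — because discordance literally
redirects an existing flow.  Edges incident to an added vertex are
attributed to the vertex addition (a PDA is an increased-vertex
anomaly, not also an increased-edge one), and edges lost by an isolated
vertex to the isolation.  Pairing is greedy in row-major order;
deterministic, and exercised against every catalog script in the tests.

## Diagnosis by matrix matching

`diagnose()` ranks catalog conditions by element-wise Hamming distance
to the input matrix, zero-padding the smaller matrix (vertex identity is
positional, so padding never relabels).  Distance 0 is an exact
diagnosis.  The default catalog expands parameterized conditions into
their discrete variants, so a lone RA→LA edge matches
"ASD (right_to_left)" exactly rather than sitting one element from the
bidirectional default.

## Weighted adjacency matrices

Clinically one inspects a few spaces at a time, so weighting starts from
`select_submatrix()` over the vertices of interest (e.g. RV, PT, RPA,
LPA after tetralogy repair; SVC, RPA, IVC, LPA in a Fontan circulation).
`build_weighted_matrix()` then places measured values — peak velocity in
cm/s by default — on the connectivity submatrix.  The binary mask
travels with the weights, and a connected-but-unmeasured edge is listed
explicitly, so a zero is never ambiguous between "no edge" and "no
data".  One metric per matrix; multi-metric data are multiple matrices.

The synthetic generator stands in for flow-imaging measurements (the
published figures' numeric velocities are not printed in text, so no
attempt is made to reproduce them).  It draws a baseline per edge from a
uniform range keyed on the source compartment — ventricular outflow
80–120 cm/s, pulmonary/great arteries 60–100, caval flow 20–60, other
30–90 — and multiplies stenotic edges by a factor (default 2.5, the
order of a tight stenosis jet relative to baseline).  These defaults
were fixed once, from textbook normal ranges, and are configuration, not
fitted values.  What the generator emulates is the *magnitude structure*
of peak-velocity data: it does not model flow conservation at
branch points, cardiac-cycle dynamics, regurgitant jets or measurement
noise correlated along a vessel, so tests passing on synthetic data show
the bookkeeping is right, not that the package validates imaging
pipelines.  Determinism: the seed is applied internally and the caller's
RNG state is restored.

## Enumerating candidate anatomies

With 24 labeled vertices there are $2^{24 \times 23} = 2^{552} \approx
1.47 \times 10^{166}$ simple digraphs — vastly more than the known
CHDs, which motivates the discovery partition:

(all digraphs on the given vertices) − (known anatomies) − (anatomies
lethal under known rules) = (viable but unreported) + (lethal under
rules not yet known).

`count_graphs()` computes the count exactly (schoolbook digit doubling,
with a half-even 3-significant-figure scientific rendering), and
`enumerate_graphs()` materializes the space on a *restricted subset*:
full 24-vertex enumeration is infeasible and is refused by a cap
(default 20 free edge positions, i.e. $2^{20}$ graphs).  Fixed and
forbidden edges shrink the free space.  `partition_candidates()` then
assigns every enumerated graph to exactly one bucket: `known` (exact
matrix equality with a catalog projection — vertices are labeled, so no
isomorphism search), `lethal_known_rules` (fails the survival rule under
roles mapped onto the subset), or `viable_unreported`.  The last bucket
necessarily conflates genuinely unreported anatomies with ones excluded
by rules connectivity cannot see; the report says so.  How a known
24-vertex condition projects onto a subset is itself a choice: the
package restricts rows and columns to the subset's canonical indices and
compares exactly.

## Numerical and degenerate-input choices

* Matrices are validated on construction: square, 0/1, zero diagonal,
  abbreviations unique, indices gap-free; errors name the offending cell.
* A column interchange that would move an edge onto the diagonal (the
  two columns are joined by an edge) is refused rather than silently
  producing a self-loop.
* `reachable(v, v)` is `TRUE` (the empty path); reachability is
  delegated to igraph, and the test suite cross-checks it against an
  independent Boolean power-sum transitive closure on random digraphs.
* Ties in diagnosis are broken alphabetically by condition name.
* The exact power of two is rendered with round-half-even at the third
  significant digit.

## Problem sizes

The test suite runs enumeration cross-checks at $n \le 4$ (4096 graphs),
reachability property tests on 200 random digraphs of up to 8 vertices,
and generator statistics over 100 seeds — sizes chosen so the whole
suite completes in well under a minute while still exercising every
branch of the partition and closure logic.

## Limitations

* No spatial anatomy: situs inversus, L-loop, overriding aorta, right
  aortic arch, aberrant subclavians and coronary courses are not
  representable in a pure connectivity model.
* No parallel edges: two distinct flows with identical origin and
  destination collapse to one.
* The survival rule is connectivity-only; hemodynamic adequacy is not
  modeled.
* Weighted matrices store point measurements, not time-resolved flow.
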