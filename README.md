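# chdgraph

Congenital heart diseases (CHDs) are, at their core, connectivity
disorders: chambers, vessels and organs joined or separated in ways the
normal circulation is not.  `chdgraph` models a circulation as a simple
labeled directed graph — vertices are the spaces blood flows through,
edges are the directed flows — together with its binary adjacency matrix
`A = [a_ij]`, where `a_ij = 1` exactly when blood flows from space `v_i`
to space `v_j`.  The canonical normal heart spans 24 vertices
(`v_1` = SVC … `v_24` = SCTO, the aggregate systemic target organs that
close the circuit) and 32 directed flows.

On top of that representation the package provides, for clinicians,
imaging researchers and modelers:

- a **declarative catalog** of CHD manifestations (PDA, MAPCA, PLSVC,
  septal defects, atresias, anomalous venous return, d-/l-TGA, DORV,
  truncus) and procedures (mBT shunts, Norwood, Glenn, Fontan, arterial
  switch) as graph edit scripts, applied and composed by an engine
  (transposition is literally an interchange of the PT and AAo columns;
  the arterial switch is the same interchange, hence its own inverse);
- the **two-path survival rule**: a heart is viable iff some lung is
  reachable from the systemic venous return and itself reaches the
  systemic arterial supply — with witness paths for audit;
- a **five-category structural classifier** of the difference between two
  hearts (increased/decreased vertices, increased/decreased edges,
  abnormal connections) and **diagnosis** by Hamming-distance matching
  against the catalog;
- **weighted adjacency matrices** attaching hemodynamic measurements
  (peak velocity, cm/s) to a connectivity submatrix over vertices of
  interest, with a seeded synthetic-measurement generator;
- a **desk-scale enumerator** of all simple labeled digraphs on a
  restricted vertex subset, partitioned into known / lethal-by-rule /
  candidate-unreported anatomies (there are `2^(24*23) ≈ 1.47 × 10^166`
  such graphs on the full vertex set, so discovery must be constrained).

## Worked example

```r
library(chdgraph)

build_normal_heart()
#> Circulation graph: normal heart
#>   24 vertices, 32 directed edges
#>   flows: SVC->RA, IVC->RA, RA->RV, RV->PT, PT->RPA, PT->LPA, RPA->RL, LPA->LL ...

# extreme tetralogy of Fallot (VSD + pulmonary atresia + reversed PT-RPA
# flow), palliated with a right modified Blalock-Taussig shunt
tof <- build_condition(c("extreme_TOF", "right_mBT_shunt"))
B <- to_binary_matrix(tof)
dim(B)            # 25 x 25 -- the shunt is a new vertex, v25
B[23, 25]; B[25, 6]   # 1, 1: RSCA -> shunt -> RPA
B[4, 5]; B[6, 5]      # 0, 1: pulmonary atresia; retrograde RPA -> PT flow

check_survival(build_condition("extreme_TOF"))
#> Survival-rule check: normal heart + extreme TOF
#>   viable: FALSE
check_survival(tof)
#> Survival-rule check: normal heart + extreme TOF + right_mBT_shunt
#>   viable: TRUE
#>   qualifying lungs: RL, LL
#>   RL: venous path 1->3->4->15->16->17->19->23->25->6->8; arterial path 8->10->14->15->16
#>   LL: venous path 1->3->4->15->16->17->19->23->25->6->5->7->9; arterial path 9->12->14->15->16
```

Unpalliated extreme TOF fails the survival rule (no lung is reachable);
the shunt restores a path from the right subclavian artery into the
pulmonary circulation, and both lungs qualify, each with an explicit
venous and arterial witness path.  The same matrix diagnoses itself
against the catalog:

```r
head(as.data.frame(diagnose(B)), 3)
#>                          condition distance
#> 1 extreme TOF with right mBT shunt        0
#> 2                      extreme TOF        2
#> 3              VSD (bidirectional)        5

classify_diff(to_binary_matrix(build_normal_heart()),
              to_binary_matrix(build_condition("d-TGA")))
#> Structural diff
#>   categories: abnormal_connections
#>   added edges: RV -> AAo, LV -> PT
#>   removed edges: RV -> PT, LV -> AAo
#>   rewiring at RV: RV->PT replaced by RV->AAo
#>   rewiring at LV: LV->AAo replaced by LV->PT

count_graphs(24)
#> 2^(24×23) = 2^552 = 1.47 × 10^166
```

The distance-0 diagnosis is an exact catalog match; the d-TGA diff pairs
each lost ventricular outflow with the discordant one that replaced it,
which is what places transposition in the "abnormal connections"
category.

## Command line

A thin CLI over the same functions is installed at
`system.file("exec", "chdgraph", package = "chdgraph")`:

```sh
chdgraph build --condition d-TGA,VSD --out dtga.json
chdgraph check-survival dtga.json
chdgraph diff normal.csv variant.csv
chdgraph diagnose matrix.csv
chdgraph count --n 24
chdgraph enumerate --vertices RA,RV,PT,AAo --sources RA --lungs PT --target AAo
```

Results go to stdout (or `--out` files) as JSON/CSV/DOT/GraphML; logs go
to stderr; validation errors exit with code 2 and a JSON error payload.

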