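---
title: "Models and methods in colonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in colonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

colonet models the spread of a generic aquatic invertebrate with a
terrestrial life stage across a landscape, twice over: a deterministic
discrete-time *dispersal simulation* on a habitat network, and a
*quickest-flow mixed integer program* (MIP) on a time-expanded copy of
the same network whose optimum is a provable lower bound on the number
of time steps needed to colonise designated destination habitats. This
vignette records the models, the defaults, and the design decisions a
maintainer would want to know about.

## The landscape

The cost raster has four land-cover classes with per-cell dispersal
costs: agriculture 50, forest 75, urban 100, aquatic 25 cost units, on
100 m cells. The species' budget is the cost of 2500 m of travel
through open agricultural land, `C_max = 50 * 25 = 1250` cost units;
two habitat patches are connected in the network exactly when the
least-cost path between them costs strictly less than `C_max`.

Two synthetic generators emulate the landscape inputs:

* **Land cover** comes from a modified random-cluster neutral
  landscape model: a percolation map at occupation probability 0.5
  (subcritical for the 4-connected lattice, threshold 0.593, so
  clusters stay finite), cluster-wise class assignment with
  probabilities equal to the target class proportions, and
  majority-of-neighbours infill. Class fractions therefore concentrate
  on their targets as the grid grows (the tests check ±3 points at
  500 × 500) while the map stays spatially autocorrelated. The default
  proportions 2/3, 1/9, 2/9 are the 66.6/11.1/22.2 mix normalised to
  sum exactly to one.
* **The stream network** is a drainage surrogate grown headward from a
  boundary outlet. A direction-persistent walker carves the main
  channel; tributaries are then extended by drawing a uniform random
  target cell and growing a channel from the *nearest* stream cell
  toward it, so empty regions attract growth and the network spans the
  landscape at any density (7.8% of cells by default, the density of
  the reference extent: 19,490 aquatic cells per 500 × 500 grid).
  Every added cell must touch exactly one existing stream cell, which
  makes the aquatic set a tree on the grid — connected, acyclic,
  branching — by construction. Two earlier candidate generators were
  rejected for cause: uniform tree-Eden growth produces a compact blob
  around the outlet rather than a spanning network, and taking union
  of root-paths in a random spanning tree of the full lattice produces
  channels that run side by side without joining, breaking the
  on-grid tree property.

What the generators do *not* emulate: real hydrographic geometry
(meanders, flow accumulation, valley confinement), elevation, and any
correlation between land cover and the river corridor. Results on
these synthetic landscapes show that the two models behave and compare
as described; they do not calibrate either model to a real region.

## Habitat network

Patches are a uniform 10% sample of aquatic cells. Habitat quality is
drawn `Uniform(0.5, 1)` and the carrying capacity is
`K(v) = quality * K_max` (default `K_max` = 100 biomass units). The
lower quality bound keeps `K` away from zero; fill times scale with
`1/K`, so unboundedly poor patches would produce arbitrarily long,
uninformative colonisation times. Least-cost distances use the
standard GIS convention — 8-connected moves costing the mean of the
two cell costs, `sqrt(2)`-weighted on diagonals — so a straight run of
`n` uniform cells costs `n` times the cell cost, reproducing the
50 × 25 = 1250 budget arithmetic exactly. One truncated Dijkstra sweep
per patch (capped at `C_max`) finds all sub-budget pairs.

## The dispersal simulation

Time advances in synchronous steps. A patch holding at least the
colonisation threshold `T_SH` (the minimum viable population, default
10 biomass units) is a source habitat from the next step on. Each
source `v` emits a pool `S_DIS * K(v)` per step (default
`S_DIS` = 0.1), split among **all** its neighbours with shares
proportional to the survival factor `1 − C(e)/C_max`; the share is
further multiplied by that same factor in transit (cost-proportional
mortality). Arrivals at patches that are already sources are
discarded; everyone else accumulates. This "split among many
neighbours" rule is what makes dense neighbourhoods slow to colonise
any *particular* destination — the mechanism behind the large
simulation-to-optimisation speed factors.

Two switches bracket behaviours the published record leaves open:

* `allocation = "inverse_cost"` replaces the survival-factor weights
  by `1/C(e)`.
* `growth = "logistic"` replaces the default instant jump to `K` upon
  crossing `T_SH` by a logistic ramp at rate `growth_rate`. The
  default mirrors the optimisation model's simplification and was
  fixed before any comparison experiment was run; a slower ramp can
  only delay downstream colonisation, so the reported speed factors
  are conservative with respect to richer demography.

`T_SH = 10`, `S_DIS = 0.1`, `K_max = 100` were chosen so that a
one-hop colonisation over a mid-cost edge (survival 0.5) takes two
steps — placing typical network-scale colonisation times in the tens
of steps. All are configurable.

## The optimisation model

The habitat network is expanded in time: `T + 1` copies of every
patch, two directed move arcs per habitat edge between consecutive
layers, zero-cost holdover arcs, and a super source `Q` injecting
`T_SH` into the layer-0 copy of every initial source habitat. Flows
`f(e) ≥ 0`, copy binaries `x(v_t)` and layer binaries `x(t)` satisfy:
a copy is a source only if its inflow reaches `T_SH` (1); the holdover
arc carries a patch's whole previous inflow forward (2); emissions,
inflated by `1/(1 − C/C_max)` to account for mortality, are capped by
`u(v) = S_DIS K(v)` plus the carried biomass (3); source injections
are fixed (4); a layer counts only when every destination is colonised
in it (5); and some layer must count (6). The objective
`min Σ t·x(t)` is the quickest-flow objective; `t*` is read as the
smallest layer with `x(t) = 1`, which is robust to the zero objective
coefficient of `x(0)`.

Because every admissible dispersal behaviour — including the
simulation — respects the same emission cap and mortality, any
feasible flow dominates it: `t*` is a lower bound on the simulation's
first-colonisation time. This dominance is tested on randomized
instances.

### Time horizon

`TH1` is the serial fill time along the cost-shortest path from the
nearest source (sum over edges of
`ceil(T_SH / (K(tail) S_DIS (1 − C/C_max)))`; the sum runs over the
path's `k − 1` edges, the reading consistent with successively
colonising the patches along the path). `TH2` repeats this for the
second-nearest source — integer rounding can make it the smaller one.
A third bound `TH_coop` comes from a feasible *sequential cooperative*
schedule: colonise one patch at a time, all already-colonised
neighbours feeding it jointly at full capacity (no emission budget is
shared because nothing else is pending), choosing the next patch by
fill time plus hop distance to the destination. On a single-source
path network it equals `TH1`; in dense neighbourhoods it is far
tighter. The horizon is `min(TH1, TH2, TH_coop, 30)`; if the MIP is
infeasible the cap escalates to 60, 90, … until feasible, which must
happen by `min(TH1, TH2, TH_coop)` since that schedule is itself
feasible. For several destinations the horizon is the maximum of the
per-destination horizons.

### Making the instances tractable

Three optimum-preserving reductions keep the time-expanded MIPs small:

* **Patch pruning**: a patch with hop distance `hs` from the sources
  and `hd` to the nearest destination is dropped when `hs + hd > T`
  (every move arc advances one layer, holdovers none).
* **Layer windows**: copies of `v` after layer `T − hd(v)` cannot lie
  on any flow path that reaches a destination within the horizon;
  their arcs are omitted and biomass at the window edge is simply
  discarded. Constraint (2) is imposed only where the holdover arc
  exists.
* **Variable fixing and monotonicity cuts**: `x(v_t) = 0` for
  `t < hs(v)`, and `x(v_t) ≤ x(v_{t+1})` within the windows (source
  status can always be carried forward on the holdover arc, so these
  cuts only remove symmetric duplicates).

Solutions are always re-audited in R against the plain constraint
system (1)–(6) at tolerance `1e-6`, independent of both the solver and
the matrix assembly.

### Solver

The MIP is solved by HiGHS through a bundled Python helper (scipy's
`milp` interface), with MIP gap 0 — the objective is integer-valued,
so the gap certifies optimality. A per-solve time limit can be set;
a timeout is reported as such, never as a silent wrong answer.
Instances can also be exported as LP/MPS text for any external solver.
No R MILP interface is part of the package's dependencies; the
constraint matrices, the audit and the route decomposition are all
native R.

## The comparison experiment

One habitat network; random source sets (10% of patches each) and
random destinations; one simulation per source set (dispersal is
undirected and deterministic, so a single run yields every patch's
colonisation time) and one optimisation per (source set, destination)
pair. Reported statistics: Pearson correlations of `t*` with the
nearest-source and mean-source dispersal costs, and the *speed factor*
— the mean over pairs of the per-run ratio `t_sim/t*`, over pairs with
a colonised destination and `t* ≥ 1` (the ratio is undefined at
`t* = 0`, which arises here because destinations may coincide with
sources; such pairs are counted and excluded). Simulation-censored
pairs (not colonised within 250 steps) are excluded from the factor
and summarised by their `t*` distribution. Pairs whose optimisation
exceeds its time budget are recorded as timeouts, never dropped
silently.

The scaled-down study conditions used by the acceptance script and the
replication test are a 150 × 150-cell landscape (~175 patches) with 10
source sets × 10 destinations. At this extent the network is denser
relative to the dispersal budget than at the reference 500 × 500
extent, so optimal times are smaller and correlations somewhat
attenuated; the qualitative pattern — strong nearest-source
correlation exceeding the mean-source correlation, and a speed factor
well above one — is the reproduction target.

## Numerical choices and degenerate inputs

* Edge costs live strictly below `C_max`; an arc at `C_max` would zero
  the survival denominator and is rejected at network build.
* Ties between equal-cost least-cost paths are broken arbitrarily;
  only the cost enters either model.
* Route decomposition backtracks greedily along the largest remaining
  incoming flow (deterministic); the layered network is acyclic, so
  residual positive-flow cycles cannot arise, and any untraceable
  remainder is reported in a `residual` field rather than raised.
* A destination that is also a source short-circuits to `t* = 0`
  without a solve; an unreachable destination is reported as
  `unreachable` (the MIP would be infeasible at every horizon).
* Binary solutions are accepted only within `1e-5` of integrality and
  re-audited at `1e-6`.

## Known limitations

* The synthetic landscape generators are morphological surrogates,
  not hydrological models.
* The simulation's demography is deliberately minimal (threshold +
  instant or logistic growth); with slow real demography the lower
  bound can be far below observed colonisation times.
* Costs are isotropic and undirected; downstream drift is not
  modelled.
* Very hard MIP instances (long horizons on dense networks) can hit
  the per-solve time budget and are then reported as timeouts.
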