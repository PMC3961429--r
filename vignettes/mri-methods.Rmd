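---
title: "Minimum Reaction Insertion: model, encodings and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum Reaction Insertion: model, encodings and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolgap)
```

## The Boolean producibility model

A metabolic network here is a bipartite directed graph: compound nodes
and reaction nodes, edges only between the two types. Reactions behave
as AND gates over their substrate compounds; compounds behave as OR
gates over their producing reactions; source (seed) compounds are fixed
to 1 and must have no incoming edges. This is a qualitative model: there
are no stoichiometric coefficients, flux bounds or compartments, and a
reaction fires as soon as *all* its substrates are producible. Compared
with flux-based gap filling, the Boolean model does not require
downstream consumption of by-products, so its insertion sets tend to be
smaller; compared with shortest-path methods, it does require *every*
substrate of a used reaction to be producible, not just one neighbour.

With directed cycles the validity conditions alone are ambiguous: a
cycle can sit at all-1 with no support from any source. The model
resolves this with the **minimal valid assignment** — the unique valid
assignment with inclusion-minimal 1-set. It is computed as the least
fixpoint of the monotone Boolean update starting from "sources only"
(`minimal_valid_assignment()`): synchronous Kleene iteration, converging
in at most one sweep per node. Any chaotic/worklist update order yields
the same fixpoint because the operator is monotone; the test suite
checks a randomized worklist evaluator against the synchronous one.
Uniqueness also has a direct structural proof, which the tests replay as
a property: zeroing every node of a valid assignment that is not
*source-connected* (reachable from a source through 1-valued nodes)
always lands on the least fixpoint.

**Minimum Reaction Insertion (MRI)**: given host ⊂ reference, sources
and a target, find a minimum-cardinality set of non-host reactions whose
insertion makes the target 1 in the minimal valid assignment. The
assignment's domain is the subgraph induced by the host nodes, the
inserted reactions and their adjacent compounds; reference compounds
outside that set count as 0.

## Integer-program encodings

All three encodings minimize the number of insertion decisions `TER<id>`
(one binary per candidate reaction, or one per reversible pair under the
default pair costing) and use exact two-sided linearizations,

* AND: `y ≤ x_i` for all i, `y ≥ Σx_i − (k−1)`,
* OR: `y ≥ x_i` for all i, `y ≤ Σx_i`,

so that for any fixed insertion choice the state variables are *forced*,
not merely bounded — the minimality argument needs a unique trajectory.
Complementary false-variables are eliminated by the `1 − T`
substitution. An insertion decision enters its reaction's AND like a
virtual substrate, keeping non-inserted reactions at 0.

**IP-MRI-A** unrolls the synchronous update over `t = 0..T` with
`T = #nodes`, a safe upper bound on fixpoint convergence (each
pre-fixpoint sweep switches at least one node to 1). Sources are 1 at
every step, everything else 0 at `t = 0`, the target must be 1 at
`t = T`. Exact, with `#nodes·(T+1)` state variables.

**IP-MRI-B** drops time entirely: one variable per node and the same
AND/OR equalities. On acyclic induced graphs the equalities have a
unique solution and the encoding is exact; on cyclic graphs it admits
self-supporting cycles and can undercut the true optimum (`CYCTRAP`:
timeless optimum 2 versus true optimum 3). It is deliberately exposed
only behind `allow_unsafe = TRUE` as a diagnostic.

**IP-MRI-C** splits a set S of reaction nodes into an in-half (all
former in-edges) and an out-half (all former out-edges): a greedy
reaction-only feedback vertex set, plus the *border* reactions
(insertable reactions with at least one host substrate). The split
graph is acyclic, so within one time step everything is encoded
timelessly; time advances only through the split nodes via copy
constraints `TSR<id>(t+1) = TR<id>(t)`, with out-halves 0 at `t = 0` and
an in-half = out-half equality at the final step that pins the last step
to a fixpoint — i.e. to the minimal valid assignment. Zero-initializing
the out-halves is what excludes the unsupported-cycle pathology; given
it, the final-step equality is usually redundant, but it is still
emitted because it is part of the method's specification of the
encoding.

### Horizon choice

The method's published step count is `|FVS| + 1` (a single-cycle network
encodes in exactly 2 time steps, which `build_ip_mri_c()` reproduces and
the acceptance script measures). That count is exact when only feedback
vertices are split. Splitting border reactions — needed so host-computed
values and downstream values live in different steps — delays
propagation by one copy per split border, and a chain of split borders
can exceed `|FVS| + 1`: the `BORDER` fixture has an empty FVS, and its
1-step encoding is infeasible although the instance is solvable.
`build_ip_mri_c()` therefore keeps the published default `|FVS| + 1`,
while `solve_mri()` passes the always-sufficient `|S| + 1` steps: values
are monotone across steps and each step before the fixpoint switches at
least one of the |S| out-halves to 1. This costs at most |borders| extra
steps and never changes the optimum, only guarantees it.

### Solving

No MILP solver ships with the environments this package targets, so it
includes an exact depth-first branch-and-bound for pure-binary programs
(`solve_ip()`, C++ core): bounds-consistency propagation at every node,
branching on the insertion decisions first with 0 tried before 1, and
incumbent pruning (objective coefficients are non-negative, so the
committed objective is a valid lower bound). The search is deterministic
and returns status `limit` rather than an unproven answer if the node
budget is hit. `solve_mri()` never trusts solver output alone: trivial
and infeasible cases are decided beforehand by one fixpoint evaluation
(host only, respectively all candidates inserted), and every optimal
insertion set is re-verified against `minimal_valid_assignment()`.
Alternate optima are enumerated by re-solving under no-good cuts
`Σ_{r∈V} x_r ≤ |V| − 1`.

The exhaustive oracle `brute_force_mri()` scans decision subsets in
increasing cardinality using only the fixpoint semantics; it shares no
code path with the encodings and anchors the equivalence tests.

## Tunable parameters

* `reversible_cost` (`"pair"`, default, or `"direction"`): whether a
  decomposed reversible pair `P#####`/`Q#####` costs one decision for
  both directions or one per direction. Reported solutions list base
  R-numbers with a direction annotation either way.
* `source_policy` (`"strip"`, default, or `"strict"`): real pathway maps
  routinely give seed compounds incoming edges (e.g. the backward half
  of a reversible reaction that consumes a seed); `"strip"` removes such
  edges with a warning, `"strict"` refuses the network.
* `n_steps` in `build_ip_mri_c()`: time-step indices to unroll (see
  horizon discussion).
* `node_limit` in `solve_ip()`/`solve_mri()`: search-node budget
  (default 5·10⁶), the only resource guard.

## What the generator emulates

`random_network()` builds seeded bipartite instances around a guaranteed
source→target reaction path, adds randomly wired side reactions, injects
a requested number of compound→reaction→compound→reaction cycles
attached off the path (the trap topology that makes minimality bind),
and draws host membership per reaction, anchoring the host at the
sources; host compounds are those touching host reactions. It does
*not* emulate genome-scale degree distributions, realistic stoichiometry
or currency metabolites — passing tests on generated instances shows the
algorithms are correct on bipartite AND–OR networks with cycles and
borders of this scale, not that any biological claim holds. The unit and
acceptance suites use instances of roughly 4–9 compounds and 6–10
reactions (at most 12 insertion candidates) so the exhaustive oracles
(2^candidates fixpoints, 2^nodes assignments, 2^vertices covers) stay
exact and the full 200-instance equivalence suites complete in seconds.

## Numerical and degenerate-case choices

* All variables are binary; constraint propagation uses an absolute
  tolerance of 10⁻⁷ on integer data, so no genuine numerical issues
  arise.
* Reactions with no substrates are constant-1 (AND over the empty set);
  non-source compounds with no producers are constant-0. Compounds that
  are neither sources nor producible simply stay 0.
* Greedy FVS tie-breaks: trim nodes of in- or out-degree 0, then remove
  the reaction of maximum total degree, ties by lexicographically
  smallest id — fully deterministic. Which FVS is found does not affect
  the optimum (tested against the exact minimum FVS).
* The degree-bounding gadget rewrites fan-in/fan-out above 2 through
  pass-through nodes (single-input AND / single-producer OR are
  copies). Intermediates are host nodes: inheriting non-host membership
  would enlarge the candidate set and change the objective, whereas host
  pass-throughs fire automatically and leave the insertion decisions on
  the original reactions.
* Serialization sorts all ids, so equal networks produce byte-identical
  JSON.

## Known limitations

* The Boolean model ignores stoichiometry; solutions may be infeasible
  for a flux-based model that requires by-product balancing.
* `minimal_valid_assignment()` evaluates the subgraph induced by
  host + insertions + adjacent compounds. The IP encodings run on the
  full reference with gating. The two views coincide whenever every host
  reaction has all substrates among host compounds — true for every
  network this package constructs — but hand-built networks violating
  that closure can make a host reaction behave differently in the two
  views.
* The built-in solver targets the instance sizes of this package's
  analyses (tens of candidate reactions); genome-scale instances call
  for an external MILP solver via the LP export (`write_lp()`).
* KGML assembly uses the reaction elements only; relation/enzyme
  annotations, glycans and rpair data are ignored, and maps that annotate
  the same reaction with conflicting directions are merged by unioning
  directions (reversible wins).
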