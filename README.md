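# boolgap — Minimum Reaction Insertion in a Boolean metabolic model

`boolgap` fills gaps in metabolic networks: given a **host** network (the
reactions an organism already has) embedded in a larger **reference**
network (reactions available across organisms), a set of **source** (seed)
compounds and a **target** compound, it finds a minimum-cardinality set of
reference reactions whose insertion makes the target producible. It is
aimed at synthetic-biology and metabolic-engineering analyses where the
question is "what is the smallest set of pathway reactions I must add so
that this strain can make compound X?".

## The model

A metabolic network is a bipartite directed graph with compound nodes and
reaction nodes. Producibility follows Boolean AND–OR semantics: a 0/1
assignment σ over the subgraph induced by the host plus an insertion set
V_a is **valid** when

* σ(s) = 1 for every source s,
* a compound is 1 iff at least one producing reaction is 1 (OR),
* a reaction in host ∪ V_a is 1 iff all its substrate compounds are 1
  (AND); reactions outside host ∪ V_a are 0.

On cyclic networks several valid assignments exist — a directed cycle can
sustain itself at 1 with no source support. The model therefore uses the
**minimal valid assignment**: the unique valid assignment whose 1-set is
inclusion-minimal, equal to the least fixpoint of the Boolean update
started from "only sources are 1". **Minimum Reaction Insertion (MRI)**
asks for a minimum set V_a of non-host reactions such that σ(target) = 1
in that minimal valid assignment. The problem is NP-complete (by
reduction from minimum vertex cover, even with all degrees ≤ 2), which is
why the search is encoded as a binary integer linear program:

* **IP-MRI-A** — time-expanded: exact synchronous updates over
  t = 0..(#nodes), zero initial state; exact but large.
* **IP-MRI-B** — timeless: one variable per node; small but *unsound* on
  cycles (it happily sets an unsupported cycle to 1), kept only as a
  diagnostic.
* **IP-MRI-C** — the method of choice: a greedy reaction-node feedback
  vertex set (FVS) plus the border reactions (insertable reactions fed
  directly by the host) are split into in/out halves; the acyclic
  remainder is encoded timelessly within each time step and time advances
  only through the split nodes, so only |FVS|+1 (solver: |split|+1) steps
  are unrolled instead of #nodes.

Reversible reactions are decomposed into forward/backward halves
(`R00001` → `P00001`/`Q00001`); by default a pair costs one insertion
decision covering both directions.

A small exact branch-and-bound solver with constraint propagation is
built in, so no external MILP solver is required.

## A worked example

The classic pitfall is a cycle through the target. Fixture `CYCTRAP` has
a host path `s1 → rh → c1`, an insertable 3-reaction path
`c1 → ra1 → c4 → ra2 → c5 → ra3 → target` and an insertable 2-reaction
cycle `target → rb → c2 → rc → target`:

```r
library(boolgap)
net <- fixture("CYCTRAP")
solve_mri(net, method = "C")
#> <mri_solution> status: optimal   objective: 3
#>   inserted: ra1, ra2, ra3
#>   encoding: IP-MRI-C
```

Inserting the cycle `{rb, rc}` would be cheaper (2 reactions) and
satisfies the timeless encoding — but the cycle is not source-connected,
so the least fixpoint keeps it at 0:

```r
is_producible(net, c("rb", "rc"))
#> [1] FALSE
solve_ip(build_ip_mri_b(net))$objective   # the unsound timeless optimum
#> [1] 2
```

The same interface reads KEGG KGML pathway maps
(`parse_kgml()`, `merge_maps()`), plain JSON networks
(`read_network_json()`), and undirected edge lists for the vertex-cover
reduction (`mvc_to_mri()`). A command-line front end is installed as
`exec/boolgap` with subcommands `solve`, `check`, `fvs`, `encode`,
`reduce-mvc`, `synth` and `oracle`, e.g.

```sh
boolgap synth --name CYCTRAP --out net.json
boolgap solve --network net.json --method C
```

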