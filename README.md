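# pathcausal

Causality analysis for biochemical reaction networks.

Molecular and systems biologists routinely need to reason about *causality*
inside a pathway: what lies downstream of a perturbed protein, how many
reactions separate two proteins, where feedback loops close, and which
reactions are common downstream targets of several inputs. `pathcausal`
answers these questions on a reaction-centric model of a pathway: reactions
are state transitions with input and output participant sets (proteins,
small molecules, and nested complexes), and a **causal relationship**
r₁ → r₂ holds whenever an output participant of reaction r₁ is an input
participant of reaction r₂.

On the resulting causality graph the package computes:

- **downstream closures** with BFS levels (each reaction visited once, so
  loops terminate; the levels double as animation frames),
- **minimum reaction-hop distances** between participants over the
  alternating entity → reaction → entity relation (unreachable entities
  carry no number),
- **common downstream** intersections of two or more seed sets,
- **feedback loops** — elementary directed cycles, enumerated exhaustively
  within strongly connected components with a truncation cap,
- a **cycle-tolerant topological ordering**: Kahn elimination that, when no
  zero-in-degree reaction remains, removes the reaction with the maximum
  number of direct downstream connections; **back arcs** under this order
  flag potential feedback,
- a **greedy crossing-reducing participant ordering** for the five-column
  reaction-centric view (input proteins | input complexes | reactions |
  output complexes | output proteins), with an inversion-based crossing
  count,
- description-text analytics (top-k terms, term co-occurrence, search
  filtering).

Pathways load from BioPAX Level-3 OWL (RDF/XML) or a simple JSON dialect;
graphs export to GraphML and DOT; the five-column view renders to
deterministic SVG with yellow→black gradient causal arcs. A seeded
synthetic generator plants feedback loops and complexes so everything is
testable offline.

## Worked example

The package ships a small synthetic reconstruction of an ERK1-activation
pathway (`inst/extdata/erk1_activation_synthetic.json`): MEK1 binds ERK1,
phosphorylates it within the complex, and the complex dissociates again —
six reactions in all.

```r
library(pathcausal)

p <- parse_simple(system.file("extdata", "erk1_activation_synthetic.json",
                              package = "pathcausal"))
p
#> <pathway 'erk1_activation_synthetic'> 9 entities, 6 reactions, 0 controls
#>   entities: complex=4, protein=5

g <- build_causality_graph(p)
g$edges
#>   source target     channel
#> 1    RX1    RX2 participant
#> 2    RX2    RX3 participant
#> 3    RX3    RX1 participant
#> 4    RX3    RX4 participant
#> 5    RX4    RX5 participant
```

Six reactions, five causal relationships. The dissociation (RX3) feeds the
binding reaction (RX1) again — one branch loops back, the other continues:

```r
seeds <- seed_reactions(p, g, "ERK1")   # reactions consuming ERK1
ds <- downstream_of(g, seeds)
str(ds$levels)
#> List of 5
#>  $ : chr "RX1"
#>  $ : chr "RX2"
#>  $ : chr "RX3"
#>  $ : chr "RX4"
#>  $ : chr "RX5"
```

Five animation levels: RX1 is not revisited despite the loop. Hop distances
from ERK1 show the activated kinase p-S218,222-MEK1 reachable after exactly
3 reactions, while plain MEK1 (produced only by the unconnected RX6) is
absent from the table — not downstream at all:

```r
shortest_hops(p, "ERK1")$distances
#>            ERK1      ERK1_pMEK1     pERK1_pMEK1          p-ERK1 p-S218_222-MEK1
#>               0               1               2               3               3
#>     pERK1_dimer pERK1_dimer_nuc
#>               4               5

find_feedback_loops(g)
#> <feedback loops> 1 cycle(s)
#>   RX1 -> RX2 -> RX3 -> ...

ord <- cyclic_toposort(g)
ord$order
#> [1] "RX6" "RX3" "RX1" "RX2" "RX4" "RX5"
back_arcs(g, ord)
#>   source target     channel
#> 1    RX2    RX3 participant
```

When the cycle blocks ordinary topological sorting, the dissociation RX3 —
the reaction with the most direct downstream connections — is eliminated
first, and the single remaining back arc marks the feedback loop.
`render_static(p)` draws the five-column figure as SVG.

## Command line

A thin wrapper over the same functions installs as `exec/pathcausal`:

```sh
pathcausal synth --reactions 12 --cycles 1x3 --seed 7 -o fixture.json
pathcausal loops fixture.json
pathcausal downstream fixture.json --seed E0001
pathcausal hops fixture.json --from E0001 --format tsv
pathcausal render fixture.json -o figure.svg
```

Exit codes: 0 success, 1 usage error, 2 data/integrity error.

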