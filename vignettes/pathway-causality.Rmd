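---
title: "Reaction-centric causality analysis of biological pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-centric causality analysis of biological pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcausal)
```

## The model

pathcausal treats the biochemical reactions of a pathway as its backbone.
A reaction is a state transition with a set of input participants and a set
of output participants; participants are physical entities — proteins, small
molecules, or complexes with a recursive (acyclic) component list. Control
links attach a regulator entity to a reaction with an activation, inhibition,
or catalysis effect. Stoichiometry is deliberately ignored: the participant
model is set-based, so duplicate participants within one side of a reaction
are collapsed at load time, while an entity may legitimately appear on both
sides.

A *causal relationship* holds from reaction $r_1$ to reaction $r_2$ when an
output participant of $r_1$ is an input participant of $r_2$; $r_2$ is then
*downstream* of $r_1$. The *causality graph* is the directed graph over
reactions induced by this relation, with each edge carrying the witness
entities that realise the overlap. Everything else in the package — downstream
closures, hop distances, feedback loops, orderings — is computed on this
graph or on the underlying bipartite entity/reaction relation.

Two opt-in refinements exist because curated databases model the same
biology in two styles. Where complex assembly and dissociation are explicit
reactions (the Reactome style), exact participant-id matching already chains
causality through complexes, and that is the default. Where a pathway treats
a protein and a complex containing it as interchangeable,
`expand_complexes = TRUE` lets an output entity match an input complex that
transitively contains it (and vice versa). Control-mediated edges
(`control_edges = TRUE`) are carried on a separate `"control"` channel and
are off by default, since the causal relation proper is defined through
shared participants only. Self-loops — a reaction regenerating its own
input — are suppressed by default because a downstream animation would
otherwise revisit the same reaction forever.

## Input formats

`parse_biopax()` reads the BioPAX Level-3 OWL subset this model needs:
`Protein`, `SmallMolecule`, `Complex` (recursive `component`), other
physical-entity classes as kind `"other"`, `BiochemicalReaction`
(`left` → inputs, `right` → outputs, document order preserved), and
`Catalysis`/`Control`. Entity identity is the RDF resource fragment, so
post-translationally modified forms (`MEK1` vs `p-S218,222-MEK1`) are
distinct entities. All other classes are skipped with a reported count; a
`conversionDirection` other than LEFT-TO-RIGHT is reported and the stated
left/right orientation kept. A dangling participant reference is a hard
integrity error naming the id — silently dropping a participant would change
every downstream result.

`parse_simple()`/`write_simple()` implement a small JSON dialect (top-level
`entities`, `reactions`, `controls`) used for fixtures and interchange. The
writer sorts entities by id and keeps reactions in stored order, so
serialisation is byte-deterministic and round-trips. `write_biopax()` emits
exactly the subset the parser reads, giving an isomorphic BioPAX round trip.

Reaction order as stored in the document is meaningful: every tie-break in
the package (BFS level ordering, elimination ties, cycle rotation, greedy
chaining) keys on pathway reaction order and then lexicographic id, so every
result and every rendered figure is reproducible byte for byte.

## The analyses

**Downstream closure** (`downstream_of()`) is breadth-first search over
causal edges; each reaction is visited at most once, so a branch that loops
back onto an already-visited reaction terminates rather than cycling. The
BFS levels double as animation frames (`animation_frames()`): frame $i$
highlights levels $0..i$, and the number of frames equals the number of
levels.

**Hop distances** (`shortest_hops()`) run BFS on the alternating relation
entity → consuming reaction → output entity; the distance of an entity is
the minimum number of reactions on any such path from the source. Entities
with no path are omitted rather than given a sentinel — an unreachable
protein carries no number.

**Common downstream** (`common_downstream()`) intersects two or more
closures, excluding the seeds themselves unless asked otherwise.

**Feedback loops** (`find_feedback_loops()`) are elementary directed cycles.
Enumeration is a Johnson-style blocked search restricted to strongly
connected components (own Tarjan implementation), with nodes explored in
pathway order so each cycle emerges rotated to its smallest-position
reaction. Because the number of elementary cycles can grow exponentially,
enumeration truncates at `max_loops` (default 10,000) with an explicit
`truncated` flag — truncation is a signal, never an error. A cheaper
non-exhaustive alternative (`method = "backarc"`) closes each back arc of
the cycle-tolerant ordering through a shortest return path.

**Cycle-tolerant topological ordering** (`cyclic_toposort()`) is Kahn
elimination with one modification: when no node of residual in-degree zero
exists (the remainder is all cycles), the node with the maximum number of
direct downstream connections is eliminated, breaking as many cycles as
possible at once. "Maximum outputs" is interpreted as *residual* out-degree
in the working graph, since the elimination metaphor operates on what
remains; the original-out-degree variant is available via
`residual = FALSE` for comparison. Where several candidates tie — a case the
ordering rule alone does not determine — the earliest reaction in pathway
order wins; this is a declared convention of this package, chosen for
reproducibility. Under the resulting order, `back_arcs()` (edges pointing
backwards) flag potential feedback loops: every directed cycle must contain
at least one.

## Layout and crossing counting

`order_participants()` produces the five-column arrangement: input proteins,
input complexes, reactions, output complexes, output proteins. Non-complex
entities participating on a side — directly or packaged inside a complex on
that side — populate that side's protein column (small molecules share it;
a separate column would add width without analytical value). Each protein
column is ordered by greedy chaining: repeatedly append the unplaced entity
sharing the greatest number of reactions and/or complexes with the most
recently placed one, jumping to the next unplaced entity in pathway order
when nothing shares. Complexes and reactions are then placed at the
barycenter (mean normalised position) of their already-placed members and
participants — the barycenter step is this package's choice; the chaining
rule only covers proteins.

`count_crossings()` treats every drawn link (protein–complex membership,
participant–reaction) as a straight segment between its endpoint columns
with vertical positions normalised to $[0,1]$ per column. For each unordered
pair of links whose column spans overlap and that share no endpoint, a
crossing is counted when the vertical order inverts between the two ends of
the shared span, i.e. $(a_e - a_f)(b_e - b_f) < 0$. For links confined to
one adjacent column pair this is exactly the classic bipartite inversion
count (and is tested against a brute-force oracle); the span formulation
extends it to protein→reaction links that pass across the complex column,
counting each geometric crossing once. Exact position ties count as no
crossing. Nested-complex links are intra-column and excluded. Optimal
crossing minimisation is NP-hard and out of scope; the greedy ordering is
evaluated statistically instead (below).

## Rendering and export

`render_static()` draws the five columns as SVG with fixed geometry
(column x-positions 100/250/400/550/700, 26-unit row spacing — constants,
since the data carries none). Reactions are circles with radius
$4 + 1.5\,s$ where $s$ is the participant count; complexes are triangles
when they appear on only one side of reactions and diamonds when on both,
with glyph size $6 + 2c$ for $c$ transitive components (linear scaling with
documented constants; the source material specifies only "larger means more
components"). Causal arcs are semicircles in the center column — bowing
right for forward edges and left for back arcs, so left-side arcs flag
potential feedback — filled with a yellow→black gradient oriented from
source to target. Link classes (`reaction_links`, `complex_links`,
`causal_arcs`) can be faded to opacity 0.15. Output is deterministic byte
for byte. `export_graphml()`/`export_dot()` serialise the graph with witness
and channel attributes in fixed order.

## Text analytics

`top_terms()` ranks description tokens — lowercased, split on
non-alphanumeric characters, minimum length 3, minus a bundled ~100-word
stop list shipped as an auditable plain-text file — by total occurrence
(default `k = 20`; per-description counting via `per_document = TRUE`,
since either reading of "most common" is defensible). Ties break
lexicographically. `term_cooccurrence()` counts, for each term pair, the
descriptions containing both; counts are raw, any display threshold is a
rendering decision. `search_filter()` is case-insensitive substring matching
over names and descriptions; the empty phrase matches nothing.

## The synthetic generator

`generate_pathway()` exists so every analysis is testable without any
database download. It emulates the structural features the analyses depend
on: multi-input/multi-output reactions, dedicated linker entities chaining
planted feedback loops of chosen lengths, random *forward* extra causal
edges (acyclic by construction, so planted cycles are the only deliberate
ones — though an extra edge may close a chord cycle with a planted
wrap-around edge, which the recovery tests account for by requiring
exactness only at `extra_edge_probability = 0`), and complexes assembled by
explicit binding reactions in the curated-database style, so default
exact matching propagates causality through them. Defaults (12 core
reactions, extra-edge probability 0.1, complex probability 0.15, complexes
of at most 3 components) give sparse graphs comparable to the
dozen-reaction pathways the analyses target; test and acceptance fixtures
span 7–44 core reactions. Generation is deterministic given the seed, runs
behind a private RNG stream that never disturbs the caller's, and scales to
hundreds of reactions in seconds.

What the generator does *not* emulate: empirical degree distributions,
compartments, stoichiometry, annotation vocabularies richer than templated
verb phrases. Passing tests therefore demonstrate algorithmic correctness
on structurally realistic graphs, not biological fidelity of any particular
database export.

A companion fixture, `inst/extdata/erk1_activation_synthetic.json`, is a
hand-built *synthetic reconstruction* of a small ERK1-activation pathway:
six reactions whose causality graph has five arcs, one branch looping back
to the first reaction, and p-S218,222-MEK1 reachable from ERK1 in exactly
three reaction hops while unphosphorylated MEK1 is unreachable. It is not a
database export; it encodes the canonical MAP-kinase example the analyses
are usually explained with, and the test suite asserts the pipeline
reproduces those structural numbers.

## Numerical and degenerate-input choices

Empty pathways yield empty graphs, empty orderings, and a scaffolding-only
SVG rather than errors. Unknown ids raise classed lookup errors; integrity
violations (dangling references, duplicate ids, cyclic complex composition,
empty complexes) raise integrity errors — the CLI maps usage errors to exit
code 1 and data errors to 2. All set-valued results are reported in pathway
order; all randomness is confined to the generator and to explicitly seeded
baselines. Problem sizes in the shipped tests (50 fixtures of up to ~44
core reactions for the oracle-equivalence properties, 20 fixtures for the
enumeration, hop and layout properties, 100 random layout baselines per
fixture) were chosen so each property exercises non-trivial structure while
the whole suite stays interactive-fast.

## Known limitations

- The BioPAX reader targets the declared subset; generic entity classes
  become kind `"other"`, and stoichiometry, compartments and cellular
  locations are ignored by design.
- No SBML/SBGN/KGML, no kinetics, no probabilistic causal inference;
  "knocking out" a participant is modelled purely as its downstream cone.
- Elementary-cycle enumeration is exponential in the worst case; the cap
  plus truncation flag make that explicit rather than hiding it.
- The greedy ordering is a heuristic: it is evaluated as "at or below the
  random-ordering median on ≥ 90% of fixtures", not as optimal.
- Cross-pathway analysis (loops spanning multiple pathways) is out of
  scope.
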