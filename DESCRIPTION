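Package: pathcausal
Title: Causality Analysis for Biochemical Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses biological pathways from BioPAX Level-3 OWL (RDF/XML) or a
    simple JSON dialect into a reaction-centric model and analyses causal
    structure among biochemical reactions: reaction-to-reaction causality
    graphs with witness entities, downstream closures with animation levels,
    minimum-reaction-hop distances between participants, elementary
    feedback-loop enumeration, common-downstream intersections, a
    cycle-tolerant topological ordering, and a greedy crossing-reducing
    participant layout. Graphs export to GraphML and DOT; static figures of
    the five-column reaction-centric view render to SVG. A seeded synthetic
    pathway generator with planted feedback loops supports testing without
    any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
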