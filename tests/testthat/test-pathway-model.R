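test_that("pathway construction enforces referential integrity", {
  expect_error(
    pathway(entities = list(entity("A"), entity("A"))),
    class = "pc_integrity_error")
  expect_error(
    pathway(entities = list(entity("A")),
            reactions = list(reaction("R1", inputs = "A", outputs = "X"))),
    class = "pc_integrity_error")
  expect_error(
    pathway(entities = list(entity("C", kind = "complex", components = "Z"))),
    class = "pc_integrity_error")
  # complex composition must be acyclic
  expect_error(
    pathway(entities = list(
      entity("C1", kind = "complex", components = "C2"),
      entity("C2", kind = "complex", components = "C1"))),
    class = "pc_integrity_error")
  # a complex cannot be empty, a protein cannot have components
  expect_error(entity("P", components = "X"), class = "pc_integrity_error")
  expect_error(
    pathway(entities = list(entity("C", kind = "complex"))),
    class = "pc_integrity_error")
})

test_that("duplicate participants collapse and reaction_size reflects it", {
  p <- make_pathway(list(R1 = list(c("A", "A"), "A")))
  expect_identical(p$reactions$R1$inputs, "A")
  expect_identical(reaction_size(p, "R1"), 2L)  # overlap across sides allowed
  p2 <- make_pathway(list(R1 = list("A", "B"), R2 = list(c("A", "B"), c("C", "D", "E"))))
  expect_identical(reaction_size(p2, "R1"), 2L)
  expect_identical(reaction_size(p2, "R2"), 5L)
  expect_error(reaction_size(p2, "nope"), class = "pc_lookup_error")
})

test_that("complex roles partition referenced complexes into the four classes", {
  p <- make_pathway(
    list(R1 = list("CIN", "COUT"), R2 = list("CBOTH", "X"), R3 = list("Y", "CBOTH")),
    complexes = list(CIN = "A", COUT = "B", CBOTH = "A", CUNUSED = "B"))
  roles <- complex_roles(p)
  expect_identical(roles[["CIN"]], "input_only")
  expect_identical(roles[["COUT"]], "output_only")
  expect_identical(roles[["CBOTH"]], "both")
  expect_identical(roles[["CUNUSED"]], "unused")
  expect_identical(sort(names(roles)), sort(c("CIN", "COUT", "CBOTH", "CUNUSED")))
})

test_that("complex roles partition holds on generated pathways", {
  for (seed in 1:5) {
    p <- gen_fixture(seed, n_reactions = 15L, cxp = 0.5)$pathway
    kinds <- vapply(p$entities, function(e) e$kind, character(1))
    roles <- complex_roles(p)
    expect_identical(length(roles), sum(kinds == "complex"))
    expect_true(all(roles %in% c("input_only", "output_only", "both", "unused")))
    for (rid in names(p$reactions))
      expect_gte(reaction_size(p, rid), 1L)
  }
})

test_that("simple dialect round-trips and serialises deterministically", {
  expect_identical(length(parse_simple('{"entities":[],"reactions":[]}')$reactions), 0L)
  # one protein as both input and output of the same reaction
  p1 <- parse_simple('{"entities":[{"id":"A","kind":"protein"}],
    "reactions":[{"id":"R1","inputs":["A"],"outputs":["A"]}]}')
  expect_identical(p1$reactions$R1$inputs, "A")
  expect_identical(p1$reactions$R1$outputs, "A")

  for (seed in c(3L, 11L)) {
    p <- gen_fixture(seed, cycle_lengths = 3L, cxp = 0.4)$pathway
    txt <- write_simple(p)
    expect_identical(txt, write_simple(p))  # byte-determinism
    expect_true(pathcausal:::pathways_equal(p, parse_simple(txt)))
  }
  expect_error(
    parse_simple('{"entities":[{"id":"A","kind":"gene"}],"reactions":[]}'),
    class = "pc_format_error")
  expect_error(
    parse_simple('{"entities":[{"id":"A"},{"id":"A"}],"reactions":[]}'),
    class = "pc_integrity_error")
})

test_that("BioPAX parsing handles a minimal hand-written document", {
  doc <- paste(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#">',
    '<bp:Protein rdf:ID="A"><bp:displayName>A</bp:displayName></bp:Protein>',
    '<bp:Protein rdf:ID="B"><bp:displayName>B</bp:displayName></bp:Protein>',
    '<bp:BiochemicalReaction rdf:ID="R1">',
    '<bp:left rdf:resource="#A"/><bp:right rdf:resource="#B"/>',
    '</bp:BiochemicalReaction>',
    '</rdf:RDF>', sep = "\n")
  p <- parse_biopax(doc, quiet = TRUE)
  expect_identical(length(p$entities), 2L)
  expect_identical(length(p$reactions), 1L)
  expect_identical(p$reactions$R1$inputs, "A")
  expect_identical(p$reactions$R1$outputs, "B")
})

test_that("BioPAX parsing reports malformed XML and dangling references", {
  expect_error(parse_biopax("<rdf:RDF><unclosed>"), class = "pc_parse_error")
  doc <- paste(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    ' xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#">',
    '<bp:Protein rdf:ID="A"/>',
    '<bp:BiochemicalReaction rdf:ID="R1">',
    '<bp:left rdf:resource="#A"/><bp:right rdf:resource="#X"/>',
    '</bp:BiochemicalReaction>',
    '</rdf:RDF>', sep = "\n")
  expect_error(parse_biopax(doc, quiet = TRUE), "X", class = "pc_integrity_error")
})

test_that("generated BioPAX documents round-trip isomorphically", {
  for (seed in c(1L, 8L)) {
    gen <- gen_fixture(seed, cycle_lengths = 3L, cxp = 0.4)
    p <- gen$pathway
    p2 <- parse_biopax(write_biopax(p), quiet = TRUE)
    expect_true(pathcausal:::pathways_equal(p, p2))
    expect_identical(names(p2$reactions), names(p$reactions))
  }
  # controls survive the round trip
  p <- make_pathway(list(R1 = list("A", "B"), R2 = list("B", "C")),
                    controls = list(control_link("B", "R2", "catalysis")))
  expect_true(pathcausal:::pathways_equal(p, parse_biopax(write_biopax(p), quiet = TRUE)))
})
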