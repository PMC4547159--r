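# Compact pathway construction for tests: rx is a named list mapping reaction
# id -> list(inputs, outputs); entities are inferred (proteins unless listed
# in `complexes`, a named list complex id -> component ids).
make_pathway <- function(rx, complexes = list(), controls = list(),
                         descriptions = list()) {
  eids <- unique(c(unlist(lapply(rx, unlist), use.names = FALSE),
                   names(complexes),
                   unlist(complexes, use.names = FALSE)))
  ents <- lapply(eids, function(id) {
    if (id %in% names(complexes))
      entity(id, kind = "complex", components = complexes[[id]])
    else entity(id)
  })
  rxns <- lapply(names(rx), function(rid) {
    reaction(rid,
             description = if (rid %in% names(descriptions)) descriptions[[rid]] else "",
             inputs = rx[[rid]][[1]], outputs = rx[[rid]][[2]])
  })
  pathway(entities = ents, reactions = rxns, controls = controls)
}

chain_pathway <- function(n = 3L) {
  ids <- sprintf("X%d", seq_len(n + 1L))
  rx <- lapply(seq_len(n), function(i) list(ids[i], ids[i + 1L]))
  names(rx) <- sprintf("R%d", seq_len(n))
  make_pathway(rx)
}

cycle_pathway <- function(n = 3L) {
  ids <- sprintf("X%d", seq_len(n))
  rx <- lapply(seq_len(n), function(i) list(ids[i], ids[if (i == n) 1L else i + 1L]))
  names(rx) <- sprintf("R%d", seq_len(n))
  make_pathway(rx)
}

# The 4-node cycle-breaking fixture: R1->R2->R3->R1 plus R1->R4.
handtrace_pathway <- function() {
  make_pathway(list(
    R1 = list("A", c("B", "W")),
    R2 = list("B", "C"),
    R3 = list("C", "A"),
    R4 = list("W", "Z")))
}

gen_fixture <- function(seed, n_reactions = 12L, cycle_lengths = integer(),
                        extra = 0.1, cxp = 0.15) {
  generate_pathway(pathway_params(
    n_reactions = n_reactions, cycle_lengths = cycle_lengths,
    extra_edge_probability = extra, complex_probability = cxp, seed = seed))
}

reaction_descriptions <- function(p)
  unname(vapply(p$reactions, function(r) r$description, character(1)))
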