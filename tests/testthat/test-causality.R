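test_that("single-overlap and disjoint reaction pairs produce the expected edges", {
  p <- make_pathway(list(R1 = list("A", "B"), R2 = list("B", "C")))
  g <- build_causality_graph(p)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$source, "R1")
  expect_identical(g$edges$target, "R2")
  expect_identical(g$witness[[1]], "B")

  p2 <- make_pathway(list(R1 = list("A", "B"), R2 = list("C", "D")))
  expect_identical(nrow(build_causality_graph(p2)$edges), 0L)
})

test_that("edge set matches the brute-force all-ordered-pairs oracle", {
  for (seed in c(7L, 21L, 33L)) {
    p <- gen_fixture(seed, n_reactions = 12L, cycle_lengths = c(3L, 4L),
                     extra = 0.2, cxp = 0.3)$pathway
    g <- build_causality_graph(p)
    oracle <- oracle_participant_edges(p)
    expect_identical(edge_key(g$edges$source, g$edges$target),
                     edge_key(oracle$source, oracle$target))
    # every witness is genuinely shared between source outputs and target inputs
    for (i in seq_len(nrow(g$edges))) {
      w <- g$witness[[i]]
      expect_true(all(w %in% intersect(
        p$reactions[[g$edges$source[i]]]$outputs,
        p$reactions[[g$edges$target[i]]]$inputs)))
    }
  }
})

test_that("self-loops are suppressed by default and kept on request", {
  p <- make_pathway(list(R1 = list("A", "A")))
  expect_identical(nrow(build_causality_graph(p)$edges), 0L)
  g <- build_causality_graph(p, self_loops = TRUE)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$source, g$edges$target)
})

test_that("complex expansion adds component-mediated edges monotonically", {
  # R1 outputs protein P; R2 consumes complex CX containing P
  p <- make_pathway(list(R1 = list("A", "P"), R2 = list("CX", "B")),
                    complexes = list(CX = c("P", "Q")))
  g_exact <- build_causality_graph(p)
  g_exp <- build_causality_graph(p, expand_complexes = TRUE)
  expect_identical(nrow(g_exact$edges), 0L)
  expect_identical(nrow(g_exp$edges), 1L)
  expect_setequal(g_exp$witness[[1]], c("P", "CX"))

  # expansion never removes an edge on generated pathways
  for (seed in 1:5) {
    p <- gen_fixture(seed, cycle_lengths = 3L, cxp = 0.5)$pathway
    e1 <- build_causality_graph(p)$edges
    e2 <- build_causality_graph(p, expand_complexes = TRUE)$edges
    k1 <- paste(e1$source, e1$target)
    k2 <- paste(e2$source, e2$target)
    expect_true(all(k1 %in% k2))
  }
})

test_that("control links yield opt-in edges on a separate channel", {
  p <- make_pathway(list(R1 = list("A", "K"), R2 = list("B", "C")),
                    controls = list(control_link("K", "R2", "catalysis")))
  expect_identical(nrow(build_causality_graph(p)$edges), 0L)
  g <- build_causality_graph(p, control_edges = TRUE)
  expect_identical(g$edges$channel, "control")
  expect_identical(g$edges$source, "R1")
  expect_identical(g$edges$target, "R2")
  expect_identical(g$witness[[1]], "K")
})

test_that("seed_reactions finds reactions consuming the seed entities", {
  p <- make_pathway(list(R1 = list("A", "B"), R2 = list("B", "C")))
  g <- build_causality_graph(p)
  expect_identical(seed_reactions(p, g, "B"), "R2")
  expect_identical(seed_reactions(p, g, "C"), character())
  expect_error(seed_reactions(p, g, "nope"), class = "pc_lookup_error")

  # a protein packaged in an input complex seeds the consuming reaction
  # only under expansion
  p2 <- make_pathway(list(R3 = list("CX", "B")), complexes = list(CX = c("P", "Q")))
  g_exact <- build_causality_graph(p2)
  g_exp <- build_causality_graph(p2, expand_complexes = TRUE)
  expect_identical(seed_reactions(p2, g_exact, "P"), character())
  expect_identical(seed_reactions(p2, g_exp, "P"), "R3")
})

test_that("downstream closure visits each reaction once at its BFS depth", {
  p <- chain_pathway(3L)
  g <- build_causality_graph(p)
  ds <- downstream_of(g, "R1")
  expect_identical(ds$levels, list("R1", "R2", "R3"))

  pc <- cycle_pathway(2L)
  gc <- build_causality_graph(pc)
  dsc <- downstream_of(gc, "R1")
  expect_identical(dsc$levels, list("R1", "R2"))  # the loop back is not revisited

  expect_error(downstream_of(g, "nope"), class = "pc_lookup_error")
})

test_that("downstream closure equals igraph reachability with oracle depths", {
  skip_if_not_installed("igraph")
  for (seed in c(11L, 19L, 27L)) {
    gen <- gen_fixture(seed, n_reactions = 15L, cycle_lengths = c(3L, 3L), extra = 0.2)
    g <- build_causality_graph(gen$pathway)
    seeds <- gen$truth$cycles[[1]][1]
    ds <- downstream_of(g, seeds)
    od <- oracle_reachability(g, seeds)
    expect_setequal(ds$visited, names(od))
    for (d in seq_along(ds$levels))
      expect_setequal(ds$levels[[d]], names(od)[od == d - 1L])
  }
})

test_that("common downstream is the intersection of independent closures", {
  p <- make_pathway(list(R1 = list("A", "B"), R2 = list("B", "C"),
                         R3 = list("D", "E"), R4 = list("E", "F")))
  g <- build_causality_graph(p)
  expect_identical(common_downstream(g, list("R1", "R3")), character())
  expect_error(common_downstream(g, list("R1")), class = "pc_usage_error")
  # identical seeds reduce to the closure minus the seeds
  ds <- downstream_of(g, "R1")
  expect_setequal(common_downstream(g, list("R1", "R1")), setdiff(ds$visited, "R1"))
  expect_setequal(common_downstream(g, list("R1", "R1"), include_seeds = TRUE),
                  ds$visited)

  skip_if_not_installed("igraph")
  for (seed in c(5L, 9L)) {
    gen <- gen_fixture(seed, n_reactions = 14L, cycle_lengths = 3L, extra = 0.25)
    g <- build_causality_graph(gen$pathway)
    s1 <- g$nodes[1L]; s2 <- g$nodes[4L]
    got <- common_downstream(g, list(s1, s2))
    want <- setdiff(intersect(names(oracle_reachability(g, s1)),
                              names(oracle_reachability(g, s2))), c(s1, s2))
    expect_setequal(got, want)
  }
})

test_that("hop distances follow the alternating entity/reaction BFS", {
  p <- chain_pathway(2L)  # X1 -(R1)-> X2 -(R2)-> X3
  h <- shortest_hops(p, "X1")
  expect_identical(h$distances[["X2"]], 1L)
  expect_identical(h$distances[["X3"]], 2L)
  expect_identical(h$distances[["X1"]], 0L)
  expect_error(shortest_hops(p, "nope"), class = "pc_lookup_error")

  # entities in a disconnected component carry no number at all
  p2 <- make_pathway(list(R1 = list("A", "B"), R2 = list("C", "D")))
  h2 <- shortest_hops(p2, "A")
  expect_false(any(c("C", "D") %in% names(h2$distances)))
})

test_that("hop tables match the exhaustive alternating-path oracle", {
  for (seed in c(5L, 15L, 25L)) {
    p <- gen_fixture(seed, n_reactions = 10L, cycle_lengths = 3L, extra = 0.15)$pathway
    src <- p$reactions[[1]]$inputs[1]
    h <- shortest_hops(p, src)
    o <- oracle_hops(p, src)
    expect_identical(sort(h$distances), o)
    # triangle step: a distance-d entity is output of a reaction consuming a
    # distance-(d-1) entity
    for (e in names(h$distances)) {
      d <- h$distances[[e]]
      if (d == 0L) next
      ok <- any(vapply(p$reactions, function(r) {
        e %in% r$outputs &&
          any(vapply(r$inputs, function(i)
            i %in% names(h$distances) && h$distances[[i]] == d - 1L,
            logical(1)))
      }, logical(1)))
      expect_true(ok)
    }
  }
})

test_that("the bundled synthetic ERK1 activation pathway reproduces the worked example", {
  path <- system.file("extdata", "erk1_activation_synthetic.json",
                      package = "pathcausal")
  p <- parse_simple(path)
  g <- build_causality_graph(p)
  expect_identical(length(p$reactions), 6L)
  expect_identical(nrow(g$edges), 5L)
  h <- shortest_hops(p, "ERK1")
  expect_identical(h$distances[["p-S218_222-MEK1"]], 3L)
  expect_false("MEK1" %in% names(h$distances))
  expect_false("p-MEK1" %in% names(h$distances))
  # one branch loops back to the first reaction; the animation has 5 steps
  seeds <- seed_reactions(p, g, "ERK1")
  ds <- downstream_of(g, seeds)
  expect_identical(length(ds$levels), 5L)
  lp <- find_feedback_loops(g)
  expect_identical(length(lp), 1L)
  expect_true(ds$levels[[1]] %in% lp[[1]])
})
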