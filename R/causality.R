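#' Build the reaction-to-reaction causality graph
#'
#' A causal relationship holds from reaction `r1` to reaction `r2` when an
#' output participant of `r1` is an input participant of `r2`; `r2` is then
#' downstream of `r1`. Edges carry the witness entity set that realises the
#' overlap. By default matching is exact participant-id matching; with
#' `expand_complexes = TRUE` an output entity also matches an input complex
#' that transitively contains it (and vice versa), covering participants that
#' enter reactions packaged inside complexes. With `control_edges = TRUE`,
#' an additional edge on a separate `"control"` channel is emitted for every
#' control link whose regulator entity is produced by another reaction.
#' Self-loops (a reaction regenerating its own input) are suppressed unless
#' `self_loops = TRUE`.
#'
#' @param p A `pc_pathway`.
#' @param expand_complexes Match participants through transitive complex
#'   composition as well as by exact id.
#' @param control_edges Also emit control-mediated edges on the `"control"`
#'   channel.
#' @param self_loops Keep edges from a reaction to itself.
#' @return An object of class `pc_causal_graph` with `nodes` (reaction ids in
#'   pathway order), an `edges` data frame (`source`, `target`, `channel`),
#'   a parallel `witness` list, and the `options` used.
#' @export
build_causality_graph <- function(p, expand_complexes = FALSE,
                                  control_edges = FALSE, self_loops = FALSE) {
  nodes <- reaction_ids(p)
  pos <- setNames(seq_along(nodes), nodes)
  mclo <- if (expand_complexes) match_closure(p) else NULL
  keys_of <- function(eid) if (is.null(mclo)) eid else mclo[[eid]]

  # Index: for every match key, the reactions consuming it and through which
  # input entity. Edges then come from producers x consumers per key, which
  # keeps construction independent of the all-pairs definition it implements.
  consumers <- new.env(parent = emptyenv())
  for (rid in nodes) {
    for (ein in p$reactions[[rid]]$inputs) {
      for (k in keys_of(ein)) {
        consumers[[k]] <- rbind(consumers[[k]],
                                data.frame(rid = rid, via = ein,
                                           stringsAsFactors = FALSE))
      }
    }
  }

  acc <- new.env(parent = emptyenv())  # key "src|tgt|channel" -> witness ids
  add_edge <- function(src, tgt, channel, witness) {
    k <- paste(src, tgt, channel, sep = "\r")
    acc[[k]] <- unique(c(acc[[k]], witness))
  }
  for (rid in nodes) {
    for (eout in p$reactions[[rid]]$outputs) {
      hits <- consumers[[eout]]
      if (is.null(hits)) next
      for (j in seq_len(nrow(hits))) {
        tgt <- hits$rid[j]
        if (tgt == rid && !self_loops) next
        add_edge(rid, tgt, "participant", unique(c(eout, hits$via[j])))
      }
    }
  }
  if (control_edges) {
    for (ct in p$controls) {
      for (rid in nodes) {
        hit <- any(vapply(p$reactions[[rid]]$outputs,
                          function(o) ct$controller %in% keys_of(o), logical(1)))
        if (!hit) next
        if (rid == ct$controlled && !self_loops) next
        add_edge(rid, ct$controlled, "control", ct$controller)
      }
    }
  }

  keys <- ls(acc)
  if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- data.frame(source = vapply(parts, `[`, "", 1L),
                        target = vapply(parts, `[`, "", 2L),
                        channel = vapply(parts, `[`, "", 3L),
                        stringsAsFactors = FALSE)
    witness <- lapply(keys, function(k) sort(acc[[k]]))
    ord <- order(pos[edges$source], pos[edges$target], edges$channel)
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
    witness <- witness[ord]
  } else {
    edges <- data.frame(source = character(), target = character(),
                        channel = character(), stringsAsFactors = FALSE)
    witness <- list()
  }
  structure(
    list(nodes = nodes, pos = pos, edges = edges, witness = witness,
         options = list(expand_complexes = expand_complexes,
                        control_edges = control_edges,
                        self_loops = self_loops)),
    class = "pc_causal_graph"
  )
}

#' @export
print.pc_causal_graph <- function(x, ...) {
  cat(sprintf("<causal graph> %d reactions, %d edges (%d participant, %d control)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$channel == "participant"),
              sum(x$edges$channel == "control")))
  invisible(x)
}

# Adjacency list over all channels, successors sorted by node position.
graph_adjacency <- function(g, reverse = FALSE) {
  adj <- setNames(vector("list", length(g$nodes)), g$nodes)
  from <- if (reverse) g$edges$target else g$edges$source
  to   <- if (reverse) g$edges$source else g$edges$target
  for (i in seq_along(from)) adj[[from[i]]] <- c(adj[[from[i]]], to[i])
  lapply(adj, function(v) unique(v[order(g$pos[v])]))
}

#' Reactions seeded by a set of entities
#'
#' All reactions having any of the given entities among their inputs, under
#' the matching mode the graph was built with (so with complex expansion a
#' protein seeds reactions that consume a complex containing it).
#'
#' @param p A `pc_pathway`.
#' @param g A `pc_causal_graph` built from `p`.
#' @param entity_ids Character vector of entity ids.
#' @return Character vector of reaction ids in pathway order.
#' @export
seed_reactions <- function(p, g, entity_ids) {
  unknown <- setdiff(entity_ids, names(p$entities))
  if (length(unknown))
    pc_lookup_error("unknown entity id(s): %s", paste(unknown, collapse = ", "))
  mclo <- if (g$options$expand_complexes) match_closure(p) else NULL
  keys <- if (is.null(mclo)) entity_ids else
    unique(unlist(mclo[entity_ids], use.names = FALSE))
  hits <- vapply(g$nodes, function(rid)
    length(intersect(p$reactions[[rid]]$inputs, keys)) > 0L, logical(1))
  g$nodes[hits]
}

#' Downstream closure of seed reactions
#'
#' Breadth-first closure over causal edges. Each reaction is visited at most
#' once, so branches that loop back onto an already-visited reaction
#' terminate; `levels[[d + 1]]` holds the reactions first reached at BFS
#' depth `d` (depth 0 = the seeds), ordered by pathway reaction order.
#'
#' @param g A `pc_causal_graph`.
#' @param seeds Character vector of seed reaction ids.
#' @return An object of class `pc_downstream` with `levels` (list of
#'   character vectors), `visited` (their union, in discovery order), and
#'   `edges_used` (the edge rows connecting consecutive levels).
#' @export
downstream_of <- function(g, seeds) {
  seeds <- unique(seeds)
  unknown <- setdiff(seeds, g$nodes)
  if (length(unknown))
    pc_lookup_error("seed reaction(s) not in graph: %s", paste(unknown, collapse = ", "))
  adj <- graph_adjacency(g)
  depth <- setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
  frontier <- seeds[order(g$pos[seeds])]
  depth[frontier] <- 0L
  levels <- list(frontier)
  d <- 0L
  while (length(frontier)) {
    nxt <- character()
    for (u in frontier) {
      for (v in adj[[u]]) if (is.na(depth[v])) {
        depth[v] <- d + 1L
        nxt <- c(nxt, v)
      }
    }
    if (!length(nxt)) break
    nxt <- nxt[order(g$pos[nxt])]
    levels[[length(levels) + 1L]] <- nxt
    frontier <- nxt
    d <- d + 1L
  }
  used <- !is.na(depth[g$edges$source]) & !is.na(depth[g$edges$target]) &
    depth[g$edges$target] == depth[g$edges$source] + 1L
  structure(
    list(levels = levels,
         visited = unlist(levels, use.names = FALSE),
         depth = depth[!is.na(depth)],
         edges_used = g$edges[used, , drop = FALSE]),
    class = "pc_downstream"
  )
}

#' Common downstream reactions of several seed sets
#'
#' Intersection of the downstream closures of two or more seed reaction
#' sets. Seeds themselves are excluded from the result unless
#' `include_seeds = TRUE`.
#'
#' @param g A `pc_causal_graph`.
#' @param seed_sets A list of two or more character vectors of reaction ids.
#' @param include_seeds Keep seed reactions in the intersection.
#' @return Character vector of reaction ids in pathway order.
#' @export
common_downstream <- function(g, seed_sets, include_seeds = FALSE) {
  if (!is.list(seed_sets) || length(seed_sets) < 2L)
    pc_usage_error("common_downstream needs at least two seed sets")
  closures <- lapply(seed_sets, function(s) downstream_of(g, s)$visited)
  out <- Reduce(intersect, closures)
  if (!include_seeds) out <- setdiff(out, unlist(seed_sets, use.names = FALSE))
  out[order(g$pos[out])]
}

#' Minimum reaction-hop distances from a source entity
#'
#' Breadth-first search over the alternating entity/reaction relation:
#' an entity feeds every reaction it is an input of, and a reaction yields
#' its output entities. The distance of an entity is the minimum number of
#' reactions on any such alternating path from the source (the source itself
#' is at distance 0). Entities with no path are omitted rather than given a
#' sentinel. With `expand_complexes = TRUE`, an entity also feeds reactions
#' consuming a complex that contains it, and producing a complex also yields
#' the entities packaged inside it.
#'
#' @param p A `pc_pathway`.
#' @param source Source entity id.
#' @param expand_complexes Match through transitive complex composition.
#' @return An object of class `pc_hop_table`: `source` plus `distances`, a
#'   named integer vector sorted by distance then pathway entity order.
#' @export
shortest_hops <- function(p, source, expand_complexes = FALSE) {
  if (!source %in% names(p$entities))
    pc_lookup_error("unknown source entity '%s'", source)
  mclo <- if (expand_complexes) match_closure(p) else NULL
  keys_of <- function(eid) if (is.null(mclo)) eid else mclo[[eid]]
  comp <- if (expand_complexes) transitive_components(p) else NULL

  dist <- setNames(rep(NA_integer_, length(p$entities)), entity_ids(p))
  fired <- setNames(rep(FALSE, length(p$reactions)), reaction_ids(p))
  dist[source] <- 0L
  frontier <- source
  d <- 0L
  while (length(frontier)) {
    fkeys <- unique(unlist(lapply(frontier, keys_of), use.names = FALSE))
    nxt <- character()
    for (rid in reaction_ids(p)) {
      if (fired[rid]) next
      if (!length(intersect(p$reactions[[rid]]$inputs, fkeys))) next
      fired[rid] <- TRUE
      yielded <- p$reactions[[rid]]$outputs
      if (expand_complexes)
        yielded <- unique(c(yielded, unlist(comp[yielded], use.names = FALSE)))
      for (e in yielded) if (is.na(dist[e])) {
        dist[e] <- d + 1L
        nxt <- c(nxt, e)
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  keep <- !is.na(dist)
  dd <- dist[keep]
  dd <- dd[order(dd, match(names(dd), entity_ids(p)))]
  structure(list(source = source, distances = dd), class = "pc_hop_table")
}

#' @export
print.pc_hop_table <- function(x, ...) {
  cat(sprintf("<hop table from '%s'> %d reachable entities\n",
              x$source, sum(x$distances > 0L)))
  if (length(x$distances))
    print(utils::head(x$distances, 20L))
  invisible(x)
}
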