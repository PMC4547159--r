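#' Cycle-tolerant topological ordering of reactions
#'
#' Kahn-style elimination on a working copy of the causality graph.
#' Repeatedly: if any node has residual in-degree 0, remove the earliest such
#' node in pathway order; otherwise (the remaining graph is all cycles)
#' remove the node with the maximum number of outputs, i.e. direct downstream
#' connections, breaking as many cycles as possible (ties resolved by pathway
#' order). Removed nodes are appended to the order and their incident edges
#' deleted. On an acyclic graph this reduces to an ordinary topological sort.
#'
#' @param g A `pc_causal_graph`.
#' @param residual Use the out-degree in the remaining working graph (the
#'   default); with `FALSE`, the original out-degree is used instead.
#' @return An object of class `pc_ordering`: `order` (permutation of the
#'   graph's reaction ids) and `position` (named 0-based index).
#' @export
cyclic_toposort <- function(g, residual = TRUE) {
  nodes <- g$nodes
  n <- length(nodes)
  keep <- g$edges$source != g$edges$target  # self-loops never block elimination
  src <- g$edges$source[keep]
  tgt <- g$edges$target[keep]
  alive_edge <- rep(TRUE, length(src))
  alive <- setNames(rep(TRUE, n), nodes)
  indeg  <- setNames(integer(n), nodes)
  outdeg <- setNames(integer(n), nodes)
  for (i in seq_along(src)) {
    indeg[tgt[i]] <- indeg[tgt[i]] + 1L
    outdeg[src[i]] <- outdeg[src[i]] + 1L
  }
  outdeg0 <- outdeg

  ord <- character(n)
  for (k in seq_len(n)) {
    cand <- nodes[alive & indeg == 0L]
    pick <- if (length(cand)) {
      cand[1L]  # nodes vector is in pathway order already
    } else {
      score <- if (residual) outdeg else outdeg0
      live <- nodes[alive]
      live[which.max(score[live])]  # which.max keeps the earliest on ties
    }
    ord[k] <- pick
    alive[pick] <- FALSE
    inc <- alive_edge & (src == pick | tgt == pick)
    for (i in which(inc)) {
      alive_edge[i] <- FALSE
      if (src[i] == pick) {
        indeg[tgt[i]] <- indeg[tgt[i]] - 1L
        outdeg[src[i]] <- outdeg[src[i]] - 1L
      } else {
        indeg[tgt[i]] <- indeg[tgt[i]] - 1L
        outdeg[src[i]] <- outdeg[src[i]] - 1L
      }
    }
  }
  structure(
    list(order = ord, position = setNames(seq_len(n) - 1L, ord)),
    class = "pc_ordering"
  )
}

#' Back arcs under a reaction ordering
#'
#' Edges whose target precedes their source in the linear order. Every
#' directed cycle contributes at least one back arc, so under the
#' cycle-tolerant ordering the back arcs flag potential feedback loops.
#'
#' @param g A `pc_causal_graph`.
#' @param ordering A `pc_ordering` covering all graph nodes.
#' @return The subset of the graph's `edges` data frame that points backwards.
#' @export
back_arcs <- function(g, ordering) {
  missing <- setdiff(g$nodes, names(ordering$position))
  if (length(missing))
    pc_integrity_error("ordering is missing node(s): %s", paste(missing, collapse = ", "))
  pos <- ordering$position
  bk <- pos[g$edges$target] < pos[g$edges$source]
  out <- g$edges[bk, , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_complex_kind <- function(p, ids) {
  vapply(ids, function(id) p$entities[[id]]$kind == "complex", logical(1))
}

# Participation structure used by the layout: which reactions and complexes
# each non-complex entity belongs to (complex membership is transitive).
participation_index <- function(p) {
  comp <- transitive_components(p)
  in_ids <- lapply(p$reactions, function(r) r$inputs)
  out_ids <- lapply(p$reactions, function(r) r$outputs)
  expand_side <- function(ids) unique(c(ids, unlist(comp[ids], use.names = FALSE)))
  rxn_members <- lapply(reaction_ids(p), function(rid)
    unique(c(expand_side(in_ids[[rid]]), expand_side(out_ids[[rid]]))))
  names(rxn_members) <- reaction_ids(p)
  list(comp = comp, rxn_members = rxn_members,
       inputs_exp = lapply(in_ids, expand_side),
       outputs_exp = lapply(out_ids, expand_side))
}

#' Greedy crossing-reducing participant ordering
#'
#' Produces the five-column arrangement of the reaction-centric view: input
#' proteins, input complexes, reactions, output complexes, output proteins.
#' Non-complex entities (proteins and small molecules) that participate on a
#' side, directly or packaged inside a complex on that side, populate that
#' side's protein column; complexes participating on a side populate that
#' side's complex column; an entity on both sides appears in both its
#' columns.
#'
#' Each protein column is ordered by greedy chaining: starting from `start`
#' (default: the column's first entity in pathway order), repeatedly append
#' the unplaced entity sharing the greatest number of reactions and/or
#' complexes with the most recently placed one (ties resolved by pathway
#' order); when nothing shares, jump to the next unplaced entity in pathway
#' order. Complexes and reactions are then placed at the barycenter (mean
#' normalised position) of their already-placed members/participants, ties by
#' pathway order.
#'
#' @param p A `pc_pathway`.
#' @param start Optional protein (non-complex entity) id to start the chains.
#' @return An object of class `pc_layout`: a list with character-vector
#'   columns `input_proteins`, `input_complexes`, `reactions`,
#'   `output_complexes`, `output_proteins`.
#' @export
order_participants <- function(p, start = NULL) {
  if (!is.null(start)) {
    if (!start %in% names(p$entities))
      pc_lookup_error("unknown entity id '%s'", start)
    if (p$entities[[start]]$kind == "complex")
      pc_usage_error("start id '%s' must be a protein, not a complex", start)
  }
  idx <- participation_index(p)
  eorder <- setNames(seq_along(p$entities), entity_ids(p))

  side_members <- function(side_exp) unique(unlist(side_exp, use.names = FALSE))
  in_all <- side_members(idx$inputs_exp)
  out_all <- side_members(idx$outputs_exp)
  split_side <- function(ids) {
    ids <- ids[order(eorder[ids])]
    cx <- is_complex_kind(p, ids)
    list(proteins = ids[!cx], complexes = ids[cx])
  }
  ins <- split_side(in_all)
  outs <- split_side(out_all)

  # affinity(a, b) = shared reactions + shared complexes
  containers <- transitive_containers(p)
  rxn_of <- lapply(entity_ids(p), function(eid)
    names(idx$rxn_members)[vapply(idx$rxn_members, function(m) eid %in% m, logical(1))])
  names(rxn_of) <- entity_ids(p)
  affinity <- function(a, b)
    length(intersect(rxn_of[[a]], rxn_of[[b]])) +
    length(intersect(containers[[a]], containers[[b]]))

  chain <- function(members, start_id = NULL) {
    if (!length(members)) return(character())
    unplaced <- members
    first <- if (!is.null(start_id) && start_id %in% members) start_id else members[1L]
    placed <- first
    unplaced <- setdiff(unplaced, first)
    while (length(unplaced)) {
      last <- placed[length(placed)]
      aff <- vapply(unplaced, affinity, numeric(1), a = last)
      pick <- if (max(aff) > 0) unplaced[which.max(aff)] else unplaced[1L]
      placed <- c(placed, pick)
      unplaced <- setdiff(unplaced, pick)
    }
    placed
  }

  input_proteins <- chain(ins$proteins, start)
  output_proteins <- chain(outs$proteins, start)

  norm_pos <- function(ids) {
    if (!length(ids)) return(setNames(numeric(), character()))
    setNames(if (length(ids) == 1L) 0.5 else
      (seq_along(ids) - 1) / (length(ids) - 1), ids)
  }

  barycenter_sort <- function(members, anchor_pos, member_anchors) {
    if (!length(members)) return(character())
    bary <- vapply(members, function(id) {
      anchors <- intersect(member_anchors[[id]], names(anchor_pos))
      if (!length(anchors)) return(0.5)
      mean(anchor_pos[anchors])
    }, numeric(1))
    members[order(bary, eorder[members])]
  }

  ip_pos <- norm_pos(input_proteins)
  op_pos <- norm_pos(output_proteins)
  comp <- idx$comp
  input_complexes <- barycenter_sort(ins$complexes, ip_pos, comp)
  output_complexes <- barycenter_sort(outs$complexes, op_pos, comp)

  # reactions: barycenter over all placed participants on either side
  ic_pos <- norm_pos(input_complexes)
  oc_pos <- norm_pos(output_complexes)
  all_pos <- c(ip_pos, ic_pos, oc_pos, op_pos)
  rorder <- setNames(seq_along(p$reactions), reaction_ids(p))
  rids <- reaction_ids(p)
  rbary <- vapply(rids, function(rid) {
    members <- intersect(idx$rxn_members[[rid]], names(all_pos))
    if (!length(members)) return(0.5)
    mean(all_pos[members])
  }, numeric(1))
  reactions <- rids[order(rbary, rorder[rids])]

  structure(
    list(input_proteins = input_proteins, input_complexes = input_complexes,
         reactions = reactions, output_complexes = output_complexes,
         output_proteins = output_proteins),
    class = "pc_layout"
  )
}

#' Randomly permuted layout with the same column membership
#'
#' Baseline for evaluating the greedy ordering: identical columns, uniformly
#' random order within each. Uses the current RNG state.
#'
#' @param layout A `pc_layout`.
#' @return A `pc_layout` with each column shuffled.
#' @export
shuffle_layout <- function(layout) {
  out <- lapply(unclass(layout), function(col)
    if (length(col) > 1L) sample(col) else col)
  class(out) <- "pc_layout"
  out
}

# All drawn straight links: (column a, id a, column b, id b), columns 1..5.
layout_links <- function(p, layout) {
  pos_list <- lapply(layout, function(col)
    setNames(seq_along(col), col))
  has <- function(colidx, id) id %in% layout[[colidx]]
  links <- list()
  add <- function(ca, ia, cb, ib)
    links[[length(links) + 1L]] <<- list(ca = ca, ia = ia, cb = cb, ib = ib)
  # complex membership links (direct components only; nested complexes are
  # intra-column and excluded from the crossing metric)
  for (cxi in layout$input_complexes) {
    for (m in p$entities[[cxi]]$components)
      if (has(1L, m)) add(1L, m, 2L, cxi)
  }
  for (cxo in layout$output_complexes) {
    for (m in p$entities[[cxo]]$components)
      if (has(5L, m)) add(4L, cxo, 5L, m)
  }
  # participation links
  for (rid in layout$reactions) {
    r <- p$reactions[[rid]]
    for (e in r$inputs) {
      if (has(2L, e)) add(2L, e, 3L, rid)
      else if (has(1L, e)) add(1L, e, 3L, rid)
    }
    for (e in r$outputs) {
      if (has(4L, e)) add(3L, rid, 4L, e)
      else if (has(5L, e)) add(3L, rid, 5L, e)
    }
  }
  links
}

#' Count edge crossings of a five-column layout
#'
#' Links are drawn as straight lines between their endpoint columns with
#' vertical positions normalised within each column. For every unordered pair
#' of links whose column spans overlap by at least one inter-column band and
#' that do not share an endpoint, a crossing is counted when their vertical
#' order inverts between the two ends of the shared span
#' ((a_e - a_f)(b_e - b_f) < 0). For links between a single pair of adjacent
#' columns this is exactly the classic bipartite inversion count.
#'
#' @param p A `pc_pathway`.
#' @param layout A `pc_layout` assigning a position to every drawn endpoint.
#' @return Integer crossing count.
#' @export
count_crossings <- function(p, layout) {
  links <- layout_links(p, layout)
  if (length(links) < 2L) return(0L)
  npos <- lapply(layout, function(col) {
    if (!length(col)) return(setNames(numeric(), character()))
    setNames(if (length(col) == 1L) 0.5 else
      (seq_along(col) - 1) / (length(col) - 1), col)
  })
  get_y <- function(l, colidx) {
    # linear interpolation of the straight segment at a given column line
    ya <- npos[[l$ca]][[l$ia]]
    yb <- npos[[l$cb]][[l$ib]]
    if (is.null(ya) || is.null(yb))
      pc_integrity_error("layout is missing a position for a drawn endpoint")
    ya + (yb - ya) * (colidx - l$ca) / (l$cb - l$ca)
  }
  n <- length(links)
  ca <- vapply(links, `[[`, 0L, "ca"); cb <- vapply(links, `[[`, 0L, "cb")
  enda <- vapply(links, function(l) paste0(l$ca, ":", l$ia), character(1))
  endb <- vapply(links, function(l) paste0(l$cb, ":", l$ib), character(1))
  total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- max(ca[i], ca[j]); b <- min(cb[i], cb[j])
      if (b <= a) next
      if (enda[i] == enda[j] || endb[i] == endb[j] ||
          enda[i] == endb[j] || endb[i] == enda[j]) next
      d1 <- get_y(links[[i]], a) - get_y(links[[j]], a)
      d2 <- get_y(links[[i]], b) - get_y(links[[j]], b)
      if (d1 * d2 < 0) total <- total + 1L
    }
  }
  total
}
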