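# Tarjan strongly connected components, iterative to avoid deep recursion.
# Returns a named integer vector: node id -> component label.
scc_components <- function(nodes, adj) {
  n <- length(nodes)
  index <- setNames(rep(NA_integer_, n), nodes)
  low <- setNames(rep(NA_integer_, n), nodes)
  onstack <- setNames(rep(FALSE, n), nodes)
  comp <- setNames(rep(NA_integer_, n), nodes)
  stack <- character()
  counter <- 0L
  ncomp <- 0L
  for (root in nodes) {
    if (!is.na(index[root])) next
    # explicit DFS stack of (node, next-child pointer)
    work <- list(list(v = root, i = 0L))
    while (length(work)) {
      fr <- work[[length(work)]]
      v <- fr$v
      if (fr$i == 0L) {
        counter <- counter + 1L
        index[v] <- counter; low[v] <- counter
        stack <- c(stack, v); onstack[v] <- TRUE
      }
      children <- adj[[v]]
      advanced <- FALSE
      while (fr$i < length(children)) {
        fr$i <- fr$i + 1L
        w <- children[fr$i]
        if (is.na(index[w])) {
          work[[length(work)]] <- fr
          work[[length(work) + 1L]] <- list(v = w, i = 0L)
          advanced <- TRUE
          break
        } else if (onstack[w]) {
          low[v] <- min(low[v], index[w])
        }
      }
      if (advanced) next
      work[[length(work)]] <- NULL
      if (low[v] == index[v]) {
        ncomp <- ncomp + 1L
        repeat {
          w <- stack[length(stack)]
          stack <- stack[-length(stack)]
          onstack[w] <- FALSE
          comp[w] <- ncomp
          if (w == v) break
        }
      }
      if (length(work)) {
        parent <- work[[length(work)]]
        low[parent$v] <- min(low[parent$v], low[v])
        work[[length(work)]] <- parent
      }
    }
  }
  comp
}

#' Enumerate feedback loops in the causality graph
#'
#' A feedback loop is an elementary directed cycle of the reaction-level
#' causality graph: no reaction repeats within one loop. Enumeration is
#' restricted to strongly connected components (a Johnson-style blocked
#' search), is deterministic (nodes explored in pathway order), rotates each
#' cycle to start at its smallest-position reaction, and truncates at
#' `max_loops` with a `truncated` attribute rather than failing — the number
#' of elementary cycles can grow exponentially with graph size. Self-loops
#' appear (as length-1 cycles) only when the graph was built with them
#' enabled. The alternative `method = "backarc"` returns, for every back arc
#' of the cycle-tolerant ordering, the cycle closing it through a shortest
#' return path; it is cheaper but not exhaustive.
#'
#' @param g A `pc_causal_graph`.
#' @param max_loops Hard cap on the number of cycles returned.
#' @param max_len Optional maximum cycle length.
#' @param method `"elementary"` (exhaustive, default) or `"backarc"`.
#' @return An object of class `pc_loops`: a list of character-vector cycles,
#'   with attributes `truncated` (logical) and `nodes`.
#' @export
find_feedback_loops <- function(g, max_loops = 10000L, max_len = NULL,
                                method = c("elementary", "backarc")) {
  method <- match.arg(method)
  loops <- if (method == "elementary")
    loops_elementary(g, max_loops, max_len)
  else
    loops_backarc(g, max_loops, max_len)
  structure(loops$cycles, truncated = loops$truncated, nodes = g$nodes,
            class = "pc_loops")
}

loops_elementary <- function(g, max_loops, max_len) {
  nodes <- g$nodes
  pos <- g$pos
  adj_full <- graph_adjacency(g)
  cycles <- list()
  truncated <- FALSE

  self <- unique(g$edges$source[g$edges$source == g$edges$target])
  for (v in self[order(pos[self])]) {
    if (length(cycles) >= max_loops) { truncated <- TRUE; break }
    if (is.null(max_len) || max_len >= 1L) cycles[[length(cycles) + 1L]] <- v
  }

  remaining <- nodes
  while (length(remaining) && !truncated) {
    sub_adj <- lapply(adj_full[remaining], function(v) intersect(v, remaining))
    comp <- scc_components(remaining, sub_adj)
    s <- remaining[1L]  # least-position remaining node
    cs <- comp[s]
    scc <- remaining[comp == cs]
    if (length(scc) > 1L) {
      adj <- lapply(adj_full[scc], function(v) setdiff(intersect(v, scc), character()))
      blocked <- setNames(rep(FALSE, length(scc)), scc)
      bmap <- setNames(vector("list", length(scc)), scc)
      path <- character()

      unblock <- function(u) {
        blocked[u] <<- FALSE
        for (w in bmap[[u]]) if (blocked[w]) unblock(w)
        bmap[[u]] <<- character()
      }
      circuit <- function(v) {
        if (truncated) return(FALSE)
        found <- FALSE
        path <<- c(path, v)
        blocked[v] <<- TRUE
        if (is.null(max_len) || length(path) < max_len + 1L) {
          for (w in adj[[v]]) {
            if (truncated) break
            if (w == s) {
              if (is.null(max_len) || length(path) <= max_len) {
                if (length(cycles) >= max_loops) { truncated <<- TRUE }
                else cycles[[length(cycles) + 1L]] <<- path
                found <- TRUE
              }
            } else if (!blocked[w]) {
              if (circuit(w)) found <- TRUE
            }
          }
        }
        if (found) {
          unblock(v)
        } else {
          for (w in adj[[v]]) if (!v %in% bmap[[w]]) bmap[[w]] <<- c(bmap[[w]], v)
        }
        path <<- path[-length(path)]
        found
      }
      circuit(s)
    }
    remaining <- setdiff(remaining, s)
  }
  list(cycles = lapply(cycles, function(cy) normalize_cycle(cy, pos)),
       truncated = truncated)
}

normalize_cycle <- function(cycle, pos) {
  k <- which.min(pos[cycle])
  if (k > 1L) c(cycle[k:length(cycle)], cycle[seq_len(k - 1L)]) else cycle
}

loops_backarc <- function(g, max_loops, max_len) {
  ordering <- cyclic_toposort(g)
  bk <- back_arcs(g, ordering)
  adj <- graph_adjacency(g)
  cycles <- list()
  seen <- character()
  truncated <- FALSE
  bfs_path <- function(from, to) {
    if (from == to) return(from)
    prev <- setNames(rep(NA_character_, length(g$nodes)), g$nodes)
    frontier <- from
    prev[from] <- from
    while (length(frontier)) {
      nxt <- character()
      for (u in frontier) for (v in adj[[u]]) if (is.na(prev[v])) {
        prev[v] <- u
        if (v == to) {
          path <- v
          while (path[1L] != from) path <- c(prev[path[1L]], path)
          return(path)
        }
        nxt <- c(nxt, v)
      }
      frontier <- nxt
    }
    NULL
  }
  for (i in seq_len(nrow(bk))) {
    if (length(cycles) >= max_loops) { truncated <- TRUE; break }
    u <- bk$source[i]; v <- bk$target[i]
    path <- bfs_path(v, u)  # cycle = v .. u plus the back arc u -> v
    if (is.null(path)) next
    if (!is.null(max_len) && length(path) > max_len) next
    cy <- normalize_cycle(path, g$pos)
    key <- paste(cy, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    cycles[[length(cycles) + 1L]] <- cy
  }
  list(cycles = cycles, truncated = truncated)
}

#' @export
print.pc_loops <- function(x, ...) {
  cat(sprintf("<feedback loops> %d cycle(s)%s\n", length(x),
              if (isTRUE(attr(x, "truncated"))) " [truncated]" else ""))
  for (cy in utils::head(x, 10L))
    cat(" ", paste(cy, collapse = " -> "), "-> ...\n")
  invisible(x)
}

#' Loops passing through a given reaction
#'
#' @param loops A `pc_loops` object from [find_feedback_loops()].
#' @param reaction_id Reaction id to filter on.
#' @return A `pc_loops` object with the subset of loops containing the
#'   reaction (possibly empty).
#' @export
loops_containing <- function(loops, reaction_id) {
  nodes <- attr(loops, "nodes")
  if (!is.null(nodes) && !reaction_id %in% nodes)
    pc_lookup_error("unknown reaction id '%s'", reaction_id)
  keep <- vapply(loops, function(cy) reaction_id %in% cy, logical(1))
  structure(loops[keep], truncated = attr(loops, "truncated"),
            nodes = nodes, class = "pc_loops")
}
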