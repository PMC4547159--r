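# Independent oracles, deliberately written as naive brute force so they
# share no code path with the package implementation.

# All-ordered-pairs output/input intersection scan (exact matching).
oracle_participant_edges <- function(p) {
  rids <- names(p$reactions)
  out <- data.frame(source = character(), target = character(),
                    stringsAsFactors = FALSE)
  for (r1 in rids) for (r2 in rids) {
    if (r1 == r2) next
    if (length(intersect(p$reactions[[r1]]$outputs, p$reactions[[r2]]$inputs)))
      out <- rbind(out, data.frame(source = r1, target = r2,
                                   stringsAsFactors = FALSE))
  }
  out
}

edge_key <- function(src, tgt) sort(paste(src, tgt, sep = "->"))

# igraph-based reachability: for each seed set, visited nodes and their
# shortest path depth.
oracle_reachability <- function(g, seeds) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = g$nodes))
  d <- igraph::distances(ig, v = seeds, to = igraph::V(ig), mode = "out")
  depth <- apply(d, 2L, min)
  depth[is.finite(depth)]
}

# Brute-force elementary cycle enumeration: DFS from every start node,
# visiting only nodes with position >= start, no node reused in a path.
oracle_cycles <- function(g) {
  adj <- list()
  for (i in seq_len(nrow(g$edges)))
    adj[[g$edges$source[i]]] <- c(adj[[g$edges$source[i]]], g$edges$target[i])
  pos <- g$pos
  found <- list()
  dfs <- function(s, v, path) {
    for (w in adj[[v]]) {
      if (w == s) {
        found[[length(found) + 1L]] <<- path
      } else if (!w %in% path && pos[w] > pos[s]) {
        dfs(s, w, c(path, w))
      }
    }
  }
  for (s in g$nodes) {
    if (any(g$edges$source == s & g$edges$target == s)) found[[length(found) + 1L]] <- s
    dfs(s, s, s)
  }
  found
}

cycle_keys <- function(cycles) sort(vapply(cycles, paste, character(1), collapse = ">"))

# Exhaustive alternating-path hop distances: DFS over entity -> reaction ->
# entity paths, no reaction reused within a path (a shortest chain never
# repeats a reaction), recording the minimum reaction count per entity.
oracle_hops <- function(p, source) {
  best <- new.env(parent = emptyenv())
  best[[source]] <- 0L
  nR <- length(p$reactions)
  walk <- function(e, used, len) {
    if (len >= nR) return(invisible())
    for (rid in names(p$reactions)) {
      if (rid %in% used) next
      r <- p$reactions[[rid]]
      if (!e %in% r$inputs) next
      for (o in r$outputs) {
        cur <- best[[o]]
        if (is.null(cur) || cur > len + 1L) best[[o]] <- len + 1L
        walk(o, c(used, rid), len + 1L)
      }
    }
  }
  walk(source, character(), 0L)
  vals <- vapply(ls(best), function(k) best[[k]], integer(1))
  sort(vals)
}

# Inversion count between two adjacent layers of a bipartite drawing given
# edge endpoint positions (independent of the package link model).
oracle_bipartite_crossings <- function(a_pos, b_pos) {
  n <- length(a_pos)
  total <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (a_pos[i] == a_pos[j] || b_pos[i] == b_pos[j]) next
    if ((a_pos[i] - a_pos[j]) * (b_pos[i] - b_pos[j]) < 0) total <- total + 1L
  }
  total
}
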