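# Run an expression under a private RNG stream: the global .Random.seed is
# saved and restored, so generation never perturbs user randomness.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

REACTION_VERBS <- c("phosphorylates", "binds", "dissociation", "activates",
                    "dephosphorylates", "ubiquitinates", "translocates",
                    "cleaves", "transfers", "hydrolyzes")

#' Parameters for the synthetic pathway generator
#'
#' @param n_reactions Number of core reactions (binding reactions introduced
#'   for complex assembly are additional).
#' @param cycle_lengths Integer vector of planted feedback-loop lengths, each
#'   at least 2; their sum may not exceed `n_reactions`.
#' @param extra_edge_probability Probability of adding a forward causal edge
#'   between any ordered pair of core reactions (forward edges keep the extra
#'   structure acyclic, so planted cycles stay the only cycles).
#' @param complex_probability Probability that a private reaction input is
#'   wrapped into a complex assembled by an explicit binding reaction.
#' @param max_complex_size Maximum number of components per generated complex.
#' @param seed Integer seed; generation is fully deterministic given the
#'   parameters.
#' @return A list of class `pc_gen_params`.
#' @export
pathway_params <- function(n_reactions = 12L, cycle_lengths = integer(),
                           extra_edge_probability = 0.1,
                           complex_probability = 0.15,
                           max_complex_size = 3L, seed = 1L) {
  cycle_lengths <- as.integer(cycle_lengths)
  if (n_reactions < 0L) pc_usage_error("n_reactions must be >= 0")
  if (any(cycle_lengths < 2L)) pc_usage_error("planted cycle lengths must be >= 2")
  if (sum(cycle_lengths) > n_reactions)
    pc_usage_error("sum of cycle lengths (%d) exceeds n_reactions (%d)",
                   sum(cycle_lengths), n_reactions)
  if (extra_edge_probability < 0 || extra_edge_probability > 1 ||
      complex_probability < 0 || complex_probability > 1)
    pc_usage_error("probabilities must lie in [0, 1]")
  if (max_complex_size < 2L) pc_usage_error("max_complex_size must be >= 2")
  structure(list(n_reactions = as.integer(n_reactions),
                 cycle_lengths = cycle_lengths,
                 extra_edge_probability = extra_edge_probability,
                 complex_probability = complex_probability,
                 max_complex_size = as.integer(max_complex_size),
                 seed = as.integer(seed)),
            class = "pc_gen_params")
}

#' Generate a random pathway with planted causal structure
#'
#' Builds `n_reactions` core reactions. Reactions of each planted cycle are
#' chained through dedicated linker entities (reaction i outputs an entity
#' consumed by reaction i+1, wrapping around), so each cycle exists verbatim
#' in the exact-match causality graph. Additional forward edges between core
#' reactions are added independently with `extra_edge_probability`; being
#' forward in pathway order they cannot create new cycles. Every reaction
#' also receives a private input and a private output entity. With
#' `complex_probability`, a private input is wrapped into a complex whose
#' assembly is an explicit binding reaction (inputs = components, output =
#' the complex), mirroring how curated pathway databases model complex
#' formation and keeping exact-id matching valid through complexes. Entity
#' and reaction ids are zero-padded so lexicographic order equals creation
#' order.
#'
#' @param params A `pc_gen_params` from [pathway_params()].
#' @return A list with `pathway` (a `pc_pathway`) and `truth` (the planted
#'   ground truth: `cycles`, a list of reaction-id vectors rotated to their
#'   smallest pathway position, and `edges`, a data frame of all deliberately
#'   planted causal edges).
#' @export
generate_pathway <- function(params) {
  stopifnot(inherits(params, "pc_gen_params"))
  with_local_seed(params$seed, {
    nR <- params$n_reactions
    rw <- max(2L, nchar(as.character(max(1L, nR * 3L))))
    rid <- sprintf(paste0("R%0", rw, "d"), seq_len(max(nR, 0L)))
    ents <- list()
    ecount <- 0L
    new_entity <- function(kind = NULL, components = character(), name = NULL) {
      ecount <<- ecount + 1L
      id <- sprintf("E%04d", ecount)
      if (is.null(kind))
        kind <- if (stats::runif(1) < 0.8) "protein" else "small_molecule"
      if (is.null(name))
        name <- sprintf("%s%d", if (kind == "small_molecule") "MOL" else "PROT", ecount)
      ents[[id]] <<- entity(id = id, name = name, kind = kind,
                            components = components)
      id
    }
    rx_in <- setNames(rep(list(character()), nR), rid)
    rx_out <- setNames(rep(list(character()), nR), rid)

    # assign planted cycles to disjoint random reaction subsets
    pool <- sample(rid)
    cycles <- list()
    edges_src <- character(); edges_tgt <- character()
    for (L in params$cycle_lengths) {
      members <- pool[seq_len(L)]
      pool <- pool[-seq_len(L)]
      for (i in seq_len(L)) {
        a <- members[i]; b <- members[if (i == L) 1L else i + 1L]
        linker <- new_entity()
        rx_out[[a]] <- c(rx_out[[a]], linker)
        rx_in[[b]] <- c(rx_in[[b]], linker)
        edges_src <- c(edges_src, a); edges_tgt <- c(edges_tgt, b)
      }
      cycles[[length(cycles) + 1L]] <- members
    }

    # random forward extra edges between core reactions
    if (nR >= 2L && params$extra_edge_probability > 0) {
      for (i in seq_len(nR - 1L)) {
        for (j in (i + 1L):nR) {
          if (stats::runif(1) >= params$extra_edge_probability) next
          if (any(edges_src == rid[i] & edges_tgt == rid[j])) next
          linker <- new_entity()
          rx_out[[rid[i]]] <- c(rx_out[[rid[i]]], linker)
          rx_in[[rid[j]]] <- c(rx_in[[rid[j]]], linker)
          edges_src <- c(edges_src, rid[i]); edges_tgt <- c(edges_tgt, rid[j])
        }
      }
    }

    # private participants; optionally wrapped into complexes assembled by
    # explicit binding reactions appended after the core reactions
    bind_in <- list(); bind_out <- list(); bind_desc <- character()
    for (r in rid) {
      priv_in <- new_entity()
      if (stats::runif(1) < params$complex_probability) {
        extra_n <- sample(params$max_complex_size - 1L, 1L)
        members <- c(priv_in, replicate(extra_n, new_entity()))
        cx <- new_entity(kind = "complex", components = members,
                         name = sprintf("CPLX%d", ecount + 1L))
        bind_in[[length(bind_in) + 1L]] <- members
        bind_out[[length(bind_out) + 1L]] <- cx
        bind_desc <- c(bind_desc, sprintf("%s binds to form %s",
          paste(vapply(members, function(m) ents[[m]]$name, character(1)),
                collapse = " and "),
          ents[[cx]]$name))
        rx_in[[r]] <- c(rx_in[[r]], cx)
      } else {
        rx_in[[r]] <- c(rx_in[[r]], priv_in)
      }
      rx_out[[r]] <- c(rx_out[[r]], new_entity())
    }

    reactions <- vector("list", nR + length(bind_in))
    for (i in seq_len(nR)) {
      verb <- sample(REACTION_VERBS, 1L)
      subj <- ents[[rx_in[[rid[i]]][1L]]]$name
      obj <- ents[[rx_out[[rid[i]]][1L]]]$name
      reactions[[i]] <- reaction(
        id = rid[i], name = sprintf("%s %s %s", subj, verb, obj),
        description = sprintf("%s %s %s in the synthetic pathway", subj, verb, obj),
        inputs = rx_in[[rid[i]]], outputs = rx_out[[rid[i]]])
    }
    for (k in seq_along(bind_in)) {
      bid <- sprintf(paste0("R%0", rw, "d"), nR + k)
      reactions[[nR + k]] <- reaction(
        id = bid, name = sprintf("Binding %d", k), description = bind_desc[k],
        inputs = bind_in[[k]], outputs = bind_out[[k]])
    }

    p <- pathway(id = sprintf("synthetic_seed%d", params$seed),
                 name = sprintf("Synthetic pathway (seed %d)", params$seed),
                 entities = unname(ents), reactions = reactions)
    pos <- setNames(seq_along(reaction_ids(p)), reaction_ids(p))
    truth <- list(
      cycles = lapply(cycles, function(cy) normalize_cycle(cy, pos)),
      edges = data.frame(source = edges_src, target = edges_tgt,
                         stringsAsFactors = FALSE))
    list(pathway = p, truth = truth)
  })
}
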