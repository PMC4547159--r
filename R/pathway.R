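#' Physical entities, reactions, control links and pathways
#'
#' A pathway is modelled reaction-centrically: biochemical reactions are state
#' transitions with input and output participant lists, participants are
#' physical entities (proteins, small molecules, or complexes with a recursive
#' component list), and control links attach a regulator entity to a reaction.
#'
#' @name pathway-model
NULL

ENTITY_KINDS   <- c("protein", "small_molecule", "complex", "other")
CONTROL_EFFECTS <- c("activation", "inhibition", "catalysis")

#' Create a physical entity
#'
#' @param id Stable identifier, unique within a pathway.
#' @param name Display name; defaults to the id.
#' @param kind One of `"protein"`, `"small_molecule"`, `"complex"`, `"other"`.
#' @param components Character vector of component entity ids; only complexes
#'   may (and must) have components.
#' @param description Free-text description (may be empty).
#' @return An object of class `pc_entity`.
#' @export
entity <- function(id, name = id, kind = "protein",
                   components = character(), description = "") {
  kind <- match.arg(kind, ENTITY_KINDS)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    pc_format_error("entity id must be a nonempty string")
  if (kind != "complex" && length(components) > 0L)
    pc_integrity_error("entity '%s' has kind '%s' but lists components", id, kind)
  structure(
    list(id = id, name = as.character(name)[1L], kind = kind,
         components = unique(as.character(components)),
         description = as.character(description)[1L]),
    class = "pc_entity"
  )
}

#' Create a biochemical reaction
#'
#' Duplicate participants within one side are collapsed on construction
#' (stoichiometry is ignored; the participant model is set-based). An entity
#' may appear on both sides of the same reaction.
#'
#' @param id Stable identifier.
#' @param name Display name; defaults to the id.
#' @param description Free-text description.
#' @param inputs,outputs Character vectors of participant entity ids.
#' @return An object of class `pc_reaction`.
#' @export
reaction <- function(id, name = id, description = "",
                     inputs = character(), outputs = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    pc_format_error("reaction id must be a nonempty string")
  structure(
    list(id = id, name = as.character(name)[1L],
         description = as.character(description)[1L],
         inputs = unique(as.character(inputs)),
         outputs = unique(as.character(outputs))),
    class = "pc_reaction"
  )
}

#' Create a control link
#'
#' @param controller Entity id of the regulator.
#' @param controlled Reaction id being regulated.
#' @param effect One of `"activation"`, `"inhibition"`, `"catalysis"`.
#' @return An object of class `pc_control`.
#' @export
control_link <- function(controller, controlled, effect = "activation") {
  effect <- match.arg(effect, CONTROL_EFFECTS)
  structure(
    list(controller = as.character(controller)[1L],
         controlled = as.character(controlled)[1L],
         effect = effect),
    class = "pc_control"
  )
}

#' Assemble and validate a pathway
#'
#' Checks referential integrity (every component, participant and control
#' reference resolves), id uniqueness, and acyclicity of the
#' complex-composition relation. Reaction order is preserved as given; it is
#' the deterministic tie-break used throughout the package.
#'
#' @param id,name Pathway identifier and display name.
#' @param entities List of [entity()] objects.
#' @param reactions List of [reaction()] objects (order is meaningful).
#' @param controls List of [control_link()] objects.
#' @return An object of class `pc_pathway` with named `entities` and
#'   `reactions` lists keyed by id.
#' @export
pathway <- function(id = "pathway", name = id, entities = list(),
                    reactions = list(), controls = list()) {
  eids <- vapply(entities, function(e) e$id, character(1))
  rids <- vapply(reactions, function(r) r$id, character(1))
  dup <- c(eids[duplicated(eids)], rids[duplicated(rids)])
  if (length(dup))
    pc_integrity_error("duplicate id(s) within pathway: %s",
                       paste(unique(dup), collapse = ", "))
  names(entities) <- eids
  names(reactions) <- rids

  for (e in entities) {
    if (e$kind == "complex" && length(e$components) == 0L)
      pc_integrity_error("complex '%s' has no components", e$id)
    missing <- setdiff(e$components, eids)
    if (length(missing))
      pc_integrity_error("entity '%s' references unknown component(s): %s",
                         e$id, paste(missing, collapse = ", "))
  }
  for (r in reactions) {
    missing <- setdiff(c(r$inputs, r$outputs), eids)
    if (length(missing))
      pc_integrity_error("reaction '%s' references unknown participant(s): %s",
                         r$id, paste(missing, collapse = ", "))
  }
  for (ct in controls) {
    if (!ct$controller %in% eids)
      pc_integrity_error("control references unknown controller entity '%s'",
                         ct$controller)
    if (!ct$controlled %in% rids)
      pc_integrity_error("control references unknown reaction '%s'", ct$controlled)
  }

  p <- structure(
    list(id = id, name = name, entities = entities,
         reactions = reactions, controls = controls),
    class = "pc_pathway"
  )
  check_complex_acyclic(p)
  p
}

# The complex-composition relation must be a DAG: no complex contains itself
# directly or transitively.
check_complex_acyclic <- function(p) {
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack)
      pc_integrity_error("complex composition cycle involving '%s'", id)
    if (isTRUE(state[[id]])) return(invisible())
    for (cid in p$entities[[id]]$components) visit(cid, c(stack, id))
    state[[id]] <- TRUE
    invisible()
  }
  for (e in p$entities) if (e$kind == "complex") visit(e$id, character())
  invisible(p)
}

#' @export
print.pc_pathway <- function(x, ...) {
  cat(sprintf("<pathway '%s'> %d entities, %d reactions, %d controls\n",
              x$id, length(x$entities), length(x$reactions), length(x$controls)))
  kinds <- table(vapply(x$entities, function(e) e$kind, character(1)))
  if (length(kinds))
    cat("  entities:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

entity_ids   <- function(p) names(p$entities)
reaction_ids <- function(p) names(p$reactions)

get_entity <- function(p, id) {
  e <- p$entities[[id]]
  if (is.null(e)) pc_lookup_error("unknown entity id '%s'", id)
  e
}

get_reaction <- function(p, id) {
  r <- p$reactions[[id]]
  if (is.null(r)) pc_lookup_error("unknown reaction id '%s'", id)
  r
}

# Transitive component closure: for every entity id, the set of entity ids
# contained in it (empty for non-complexes). Memoised over the pathway.
transitive_components <- function(p) {
  memo <- list()
  expand <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    comps <- p$entities[[id]]$components
    out <- comps
    for (cid in comps) out <- c(out, expand(cid))
    out <- unique(out)
    memo[[id]] <<- out
    out
  }
  for (id in entity_ids(p)) expand(id)
  memo
}

# Inverse closure: for every entity id, the complexes that (transitively)
# contain it.
transitive_containers <- function(p) {
  comp <- transitive_components(p)
  holders <- lapply(entity_ids(p), function(id) character())
  names(holders) <- entity_ids(p)
  for (cid in entity_ids(p)) {
    for (m in comp[[cid]]) holders[[m]] <- c(holders[[m]], cid)
  }
  holders
}

# The set of ids an entity "matches" under complex-component expansion:
# itself, everything it contains, and every complex containing it.
match_closure <- function(p) {
  comp <- transitive_components(p)
  cont <- transitive_containers(p)
  setNames(
    lapply(entity_ids(p), function(id) unique(c(id, comp[[id]], cont[[id]]))),
    entity_ids(p)
  )
}

#' Role of each complex across reaction sides
#'
#' Classifies every complex entity by where it participates: only among
#' reaction inputs (`input_only`, drawn as a triangle), only among outputs
#' (`output_only`, also a triangle), on both sides across any reactions
#' (`both`, drawn as a diamond), or nowhere (`unused`).
#'
#' @param p A `pc_pathway`.
#' @return Named character vector over complex ids.
#' @export
complex_roles <- function(p) {
  complexes <- entity_ids(p)[vapply(p$entities, function(e) e$kind, character(1)) == "complex"]
  in_in  <- unique(unlist(lapply(p$reactions, function(r) r$inputs)))
  in_out <- unique(unlist(lapply(p$reactions, function(r) r$outputs)))
  roles <- vapply(complexes, function(id) {
    i <- id %in% in_in; o <- id %in% in_out
    if (i && o) "both" else if (i) "input_only" else if (o) "output_only" else "unused"
  }, character(1))
  setNames(roles, complexes)
}

#' Participant count of a reaction
#'
#' Number of distinct input participants plus distinct output participants
#' (duplicates within a side are collapsed at load time; an entity on both
#' sides counts twice). Drives the rendered circle radius.
#'
#' @param p A `pc_pathway`.
#' @param reaction_id Reaction id.
#' @return Integer participant count.
#' @export
reaction_size <- function(p, reaction_id) {
  r <- get_reaction(p, reaction_id)
  length(r$inputs) + length(r$outputs)
}

# Order-insensitive pathway equality on entities (a set keyed by id) and
# order-sensitive equality on reactions. Used by round-trip tests.
pathways_equal <- function(a, b) {
  if (!setequal(entity_ids(a), entity_ids(b))) return(FALSE)
  if (!identical(reaction_ids(a), reaction_ids(b))) return(FALSE)
  for (id in entity_ids(a)) {
    ea <- a$entities[[id]]; eb <- b$entities[[id]]
    if (!identical(ea$name, eb$name) || !identical(ea$kind, eb$kind) ||
        !setequal(ea$components, eb$components) ||
        !identical(ea$description, eb$description)) return(FALSE)
  }
  for (id in reaction_ids(a)) {
    ra <- a$reactions[[id]]; rb <- b$reactions[[id]]
    if (!identical(ra$name, rb$name) || !identical(ra$description, rb$description) ||
        !setequal(ra$inputs, rb$inputs) || !setequal(ra$outputs, rb$outputs))
      return(FALSE)
  }
  ca <- lapply(a$controls, unclass); cb <- lapply(b$controls, unclass)
  key <- function(x) paste(x$controller, x$controlled, x$effect)
  setequal(vapply(ca, key, character(1)), vapply(cb, key, character(1)))
}
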