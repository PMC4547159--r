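#' Read a BioPAX Level-3 OWL pathway
#'
#' Loads the subset of BioPAX Level 3 that the reaction-centric model uses:
#' `Protein`, `SmallMolecule`, `Complex` (with recursive `component`
#' references), other physical-entity classes (`PhysicalEntity`, `Rna`, `Dna`,
#' and region variants, mapped to kind `"other"`), `BiochemicalReaction`
#' (`left` maps to inputs, `right` to outputs, in document order), and
#' `Catalysis`/`Control` links. All other BioPAX classes are skipped; the
#' number skipped is reported with a message. Entity identity is the RDF
#' resource fragment, so post-translationally modified forms are distinct
#' entities. `conversionDirection` is assumed LEFT-TO-RIGHT; a contrary value
#' is reported with a message and the stated orientation kept.
#'
#' @param x A file path or a string of RDF/XML text.
#' @param quiet Suppress the skipped-class / direction messages.
#' @return A `pc_pathway`. Reactions keep document order.
#' @export
parse_biopax <- function(x, quiet = FALSE) {
  doc <- tryCatch(
    suppressWarnings(
      xml2::read_xml(if (length(x) == 1L && !grepl("<", x) && file.exists(x)) x else
        paste(x, collapse = "\n"))),
    error = function(e) pc_parse_error("malformed XML: %s", conditionMessage(e)))
  ns <- c(bp = "http://www.biopax.org/release/biopax-level3.owl#",
          rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#")

  # xml2 exposes namespaced attributes by their local name
  node_id <- function(node) {
    id <- xml2::xml_attr(node, "ID")
    if (is.na(id)) {
      about <- xml2::xml_attr(node, "about")
      if (!is.na(about)) id <- sub("^.*#", "", about)
    }
    id
  }
  ref_id <- function(node) {
    r <- xml2::xml_attr(node, "resource")
    if (is.na(r)) NA_character_ else sub("^.*#", "", r)
  }
  child_text <- function(node, xpath) {
    hit <- xml2::xml_find_first(node, xpath, ns)
    if (inherits(hit, "xml_missing")) "" else xml2::xml_text(hit)
  }

  kind_map <- c(Protein = "protein", SmallMolecule = "small_molecule",
                Complex = "complex", PhysicalEntity = "other", Rna = "other",
                Dna = "other", RnaRegion = "other", DnaRegion = "other",
                Gene = "other")

  root_children <- xml2::xml_children(xml2::xml_root(doc))
  local_name <- xml2::xml_name(root_children)

  entities <- list()
  for (i in seq_along(root_children)) {
    cls <- local_name[i]
    if (!cls %in% names(kind_map)) next
    node <- root_children[[i]]
    id <- node_id(node)
    if (is.na(id)) id <- child_text(node, "./bp:displayName")
    if (!nzchar(id)) pc_integrity_error("BioPAX %s element without an identifier", cls)
    comps <- character()
    kind <- kind_map[[cls]]
    if (cls == "Complex") {
      refs <- xml2::xml_find_all(node, "./bp:component", ns)
      comps <- stats::na.omit(vapply(refs, ref_id, character(1)))
      if (length(comps) == 0L) kind <- "other"  # componentless complex degrades
    }
    nm <- child_text(node, "./bp:displayName")
    if (!nzchar(nm)) nm <- child_text(node, "./bp:name")
    if (!nzchar(nm)) nm <- id
    if (!id %in% names(entities))
      entities[[id]] <- entity(id = id, name = nm, kind = kind,
                               components = as.character(comps),
                               description = child_text(node, "./bp:comment"))
  }

  reactions <- list()
  contrary_dir <- 0L
  for (i in seq_along(root_children)) {
    if (local_name[i] != "BiochemicalReaction") next
    node <- root_children[[i]]
    id <- node_id(node)
    lefts  <- vapply(xml2::xml_find_all(node, "./bp:left", ns), ref_id, character(1))
    rights <- vapply(xml2::xml_find_all(node, "./bp:right", ns), ref_id, character(1))
    dangling <- setdiff(c(lefts, rights), names(entities))
    if (length(dangling))
      pc_integrity_error("reaction '%s' references undeclared participant(s): %s",
                         id, paste(dangling, collapse = ", "))
    dir <- child_text(node, "./bp:conversionDirection")
    if (nzchar(dir) && !identical(dir, "LEFT-TO-RIGHT")) contrary_dir <- contrary_dir + 1L
    nm <- child_text(node, "./bp:displayName")
    if (!nzchar(nm)) nm <- id
    reactions[[id]] <- reaction(id = id, name = nm,
                                description = child_text(node, "./bp:comment"),
                                inputs = lefts, outputs = rights)
  }

  controls <- list()
  skipped_controls <- 0L
  for (i in seq_along(root_children)) {
    cls <- local_name[i]
    if (!cls %in% c("Catalysis", "Control")) next
    node <- root_children[[i]]
    controller <- ref_id(xml2::xml_find_first(node, "./bp:controller", ns))
    controlled <- ref_id(xml2::xml_find_first(node, "./bp:controlled", ns))
    if (is.na(controller) || is.na(controlled) ||
        !controller %in% names(entities) || !controlled %in% names(reactions)) {
      skipped_controls <- skipped_controls + 1L
      next
    }
    ctype <- child_text(node, "./bp:controlType")
    effect <- if (grepl("INHIBITION", ctype)) "inhibition"
      else if (cls == "Catalysis") "catalysis" else "activation"
    controls[[length(controls) + 1L]] <- control_link(controller, controlled, effect)
  }

  n_skipped <- sum(!local_name %in% c(names(kind_map), "BiochemicalReaction",
                                      "Catalysis", "Control", "Ontology",
                                      "Pathway"))
  if (!quiet) {
    if (n_skipped > 0L)
      message(sprintf("parse_biopax: skipped %d element(s) outside the supported subset", n_skipped))
    if (skipped_controls > 0L)
      message(sprintf("parse_biopax: skipped %d control(s) with unresolvable references", skipped_controls))
    if (contrary_dir > 0L)
      message(sprintf("parse_biopax: %d reaction(s) declare a non LEFT-TO-RIGHT direction; left/right orientation kept", contrary_dir))
  }

  pw_node <- xml2::xml_find_first(doc, ".//bp:Pathway", ns)
  pid <- if (inherits(pw_node, "xml_missing")) "pathway" else {
    v <- node_id(pw_node); if (is.na(v) || !nzchar(v)) "pathway" else v
  }
  pname <- if (inherits(pw_node, "xml_missing")) pid else {
    v <- child_text(pw_node, "./bp:displayName"); if (nzchar(v)) v else pid
  }
  pathway(id = pid, name = pname, entities = unname(entities),
          reactions = unname(reactions), controls = controls)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Serialise a pathway to BioPAX Level-3 OWL
#'
#' Emits exactly the subset that [parse_biopax()] reads, so the two invert
#' each other up to isomorphism (identical ids and edge lists). Entities are
#' written in stored order, reactions in pathway order.
#'
#' @param p A `pc_pathway`.
#' @param path Optional output file; when `NULL` the OWL text is returned.
#' @return The RDF/XML text (invisibly when written to a file).
#' @export
write_biopax <- function(p, path = NULL) {
  tag_for_kind <- c(protein = "Protein", small_molecule = "SmallMolecule",
                    complex = "Complex", other = "PhysicalEntity")
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#"',
    '         xml:base="http://pathcausal.local/synthetic#">',
    sprintf('  <bp:Pathway rdf:ID="%s">', xml_escape(p$id)),
    sprintf('    <bp:displayName>%s</bp:displayName>', xml_escape(p$name)),
    "  </bp:Pathway>")
  for (e in p$entities) {
    tag <- tag_for_kind[[e$kind]]
    block <- c(
      sprintf('  <bp:%s rdf:ID="%s">', tag, xml_escape(e$id)),
      sprintf('    <bp:displayName>%s</bp:displayName>', xml_escape(e$name)))
    if (nzchar(e$description))
      block <- c(block, sprintf('    <bp:comment>%s</bp:comment>', xml_escape(e$description)))
    for (cid in e$components)
      block <- c(block, sprintf('    <bp:component rdf:resource="#%s"/>', xml_escape(cid)))
    out <- c(out, block, sprintf("  </bp:%s>", tag))
  }
  for (r in p$reactions) {
    block <- c(
      sprintf('  <bp:BiochemicalReaction rdf:ID="%s">', xml_escape(r$id)),
      sprintf('    <bp:displayName>%s</bp:displayName>', xml_escape(r$name)))
    if (nzchar(r$description))
      block <- c(block, sprintf('    <bp:comment>%s</bp:comment>', xml_escape(r$description)))
    block <- c(block,
      sprintf('    <bp:left rdf:resource="#%s"/>', xml_escape(r$inputs)),
      sprintf('    <bp:right rdf:resource="#%s"/>', xml_escape(r$outputs)),
      '    <bp:conversionDirection>LEFT-TO-RIGHT</bp:conversionDirection>')
    out <- c(out, block, "  </bp:BiochemicalReaction>")
  }
  for (i in seq_along(p$controls)) {
    ct <- p$controls[[i]]
    tag <- if (ct$effect == "catalysis") "Catalysis" else "Control"
    ctype <- switch(ct$effect, catalysis = "ACTIVATION",
                    activation = "ACTIVATION", inhibition = "INHIBITION")
    out <- c(out,
      sprintf('  <bp:%s rdf:ID="control_%d">', tag, i),
      sprintf('    <bp:controller rdf:resource="#%s"/>', xml_escape(ct$controller)),
      sprintf('    <bp:controlled rdf:resource="#%s"/>', xml_escape(ct$controlled)),
      sprintf('    <bp:controlType>%s</bp:controlType>', ctype),
      sprintf("  </bp:%s>", tag))
  }
  out <- c(out, "</rdf:RDF>")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
  invisible(txt)
}
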