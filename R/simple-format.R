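#' Read and write the simple JSON pathway dialect
#'
#' A UTF-8 JSON document with top-level keys `id`, `name`, `entities`
#' (objects with `id`, `name`, `kind`, `components`, `description`),
#' `reactions` (objects with `id`, `name`, `description`, `inputs`,
#' `outputs`) and `controls` (objects with `controller`, `controlled`,
#' `effect`). Serialisation is deterministic: entities are sorted by id,
#' reactions keep their stored order, so the same pathway always produces
#' byte-identical output and `parse_simple()` inverts `write_simple()`.
#'
#' @param x For `parse_simple()`, a file path or a JSON string.
#' @param p A `pc_pathway`.
#' @param path Optional output file; when `NULL` the JSON text is returned.
#' @return `parse_simple()` returns a `pc_pathway`; `write_simple()` returns
#'   the JSON text (invisibly when written to a file).
#' @export
parse_simple <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[{\n]", x) && file.exists(x))
    paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n") else x
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) pc_parse_error("invalid JSON: %s", conditionMessage(e)))
  fld <- function(obj, key, default = "") {
    v <- obj[[key]]
    if (is.null(v)) default else v
  }
  entities <- lapply(doc$entities, function(e) {
    kind <- fld(e, "kind", "protein")
    if (!kind %in% ENTITY_KINDS)
      pc_format_error("unknown entity kind '%s' for '%s'", kind, fld(e, "id", "?"))
    entity(id = fld(e, "id"), name = fld(e, "name", fld(e, "id")), kind = kind,
           components = as.character(unlist(fld(e, "components", list()))),
           description = fld(e, "description", ""))
  })
  reactions <- lapply(doc$reactions, function(r) {
    reaction(id = fld(r, "id"), name = fld(r, "name", fld(r, "id")),
             description = fld(r, "description", ""),
             inputs = as.character(unlist(fld(r, "inputs", list()))),
             outputs = as.character(unlist(fld(r, "outputs", list()))))
  })
  controls <- lapply(doc$controls, function(ct) {
    eff <- fld(ct, "effect", "activation")
    if (!eff %in% CONTROL_EFFECTS)
      pc_format_error("unknown control effect '%s'", eff)
    control_link(fld(ct, "controller"), fld(ct, "controlled"), eff)
  })
  pathway(id = fld(doc, "id", "pathway"), name = fld(doc, "name", fld(doc, "id", "pathway")),
          entities = entities, reactions = reactions, controls = controls)
}

#' @rdname parse_simple
#' @export
write_simple <- function(p, path = NULL) {
  ord <- order(entity_ids(p))
  ents <- lapply(p$entities[ord], function(e) list(
    id = e$id, name = e$name, kind = e$kind,
    components = as.list(e$components), description = e$description))
  rxns <- lapply(p$reactions, function(r) list(
    id = r$id, name = r$name, description = r$description,
    inputs = as.list(r$inputs), outputs = as.list(r$outputs)))
  ctls <- lapply(p$controls, function(ct) list(
    controller = ct$controller, controlled = ct$controlled, effect = ct$effect))
  doc <- list(id = p$id, name = p$name, entities = unname(ents),
              reactions = unname(rxns), controls = unname(ctls))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  txt <- paste0(as.character(txt), "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
  invisible(txt)
}
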