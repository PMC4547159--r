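#' Export a causality graph to GraphML
#'
#' Nodes are reactions; edges carry `channel` and a space-joined `witness`
#' attribute. Element order is deterministic (nodes in pathway order, edges
#' in the graph's stored order), so identical graphs serialise to identical
#' bytes.
#'
#' @param g A `pc_causal_graph`.
#' @param path Optional output file; when `NULL` the XML text is returned.
#' @return GraphML text (invisibly when written to a file).
#' @export
export_graphml <- function(g, path = NULL) {
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="channel" for="edge" attr.name="channel" attr.type="string"/>',
    '  <key id="witness" for="edge" attr.name="witness" attr.type="string"/>',
    '  <graph id="causality" edgedefault="directed">',
    sprintf('    <node id="%s"/>', xml_escape(g$nodes)))
  for (i in seq_len(nrow(g$edges))) {
    out <- c(out,
      sprintf('    <edge source="%s" target="%s">',
              xml_escape(g$edges$source[i]), xml_escape(g$edges$target[i])),
      sprintf('      <data key="channel">%s</data>', g$edges$channel[i]),
      sprintf('      <data key="witness">%s</data>',
              xml_escape(paste(g$witness[[i]], collapse = " "))),
      '    </edge>')
  }
  out <- c(out, "  </graph>", "</graphml>")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
  invisible(txt)
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a causality graph to Graphviz DOT
#'
#' @inheritParams export_graphml
#' @return DOT text (invisibly when written to a file).
#' @export
export_dot <- function(g, path = NULL) {
  out <- c("digraph causality {", sprintf("  %s;", dot_quote(g$nodes)))
  for (i in seq_len(nrow(g$edges))) {
    out <- c(out, sprintf('  %s -> %s [channel=%s, witness="%s"];',
                          dot_quote(g$edges$source[i]), dot_quote(g$edges$target[i]),
                          g$edges$channel[i],
                          gsub('"', "", paste(g$witness[[i]], collapse = " "))))
  }
  out <- c(out, "}")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
  invisible(txt)
}

#' Re-read an exported GraphML causality graph
#'
#' Returns the node ids and the edge table (source, target, channel,
#' witness) of a GraphML document written by [export_graphml()]. Used for
#' round-trip verification.
#'
#' @param x GraphML text or file path.
#' @return List with `nodes` and an `edges` data frame.
#' @export
read_graphml <- function(x) {
  doc <- xml2::read_xml(if (length(x) == 1L && !grepl("<", x) && file.exists(x)) x
                        else paste(x, collapse = "\n"))
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:node", ns), "id")
  enodes <- xml2::xml_find_all(doc, ".//g:edge", ns)
  grab <- function(e, key) {
    hit <- xml2::xml_find_first(e, sprintf("./g:data[@key='%s']", key), ns)
    if (inherits(hit, "xml_missing")) "" else xml2::xml_text(hit)
  }
  edges <- data.frame(
    source = xml2::xml_attr(enodes, "source"),
    target = xml2::xml_attr(enodes, "target"),
    channel = vapply(enodes, grab, character(1), key = "channel"),
    witness = vapply(enodes, grab, character(1), key = "witness"),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
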