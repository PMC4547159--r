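# Fixed geometry of the five-column figure. The source data carries no
# coordinates, so these are rendering constants, not parameters of the model.
RENDER_GEOM <- list(
  col_x = c(100, 250, 400, 550, 700),
  top = 60, row_h = 26, margin = 40,
  base_radius = 4, radius_per_participant = 1.5,
  base_glyph = 6, glyph_per_component = 2,
  fade_opacity = 0.15
)

HIGHLIGHT_COLORS <- c(seed = "#e69500", downstream = "#cc2222",
                      common = "#2255cc", loop = "#7722cc")

#' Build a render specification
#'
#' Bundles a five-column layout with highlight roles, an optional animation
#' frame index, and per-link-class fade flags, validated against the layout.
#'
#' @param layout A `pc_layout`.
#' @param highlights Named character vector: names are element ids present in
#'   the layout, values are roles among `"seed"`, `"downstream"`, `"common"`,
#'   `"loop"`.
#' @param frame_index Optional 0-based BFS level for an animation frame.
#' @param fade Character vector among `"reaction_links"`, `"complex_links"`,
#'   `"causal_arcs"`: link classes to render at low opacity.
#' @return An object of class `pc_render_spec`.
#' @export
render_spec <- function(layout, highlights = character(), frame_index = NULL,
                        fade = character()) {
  all_ids <- unique(unlist(unclass(layout), use.names = FALSE))
  bad <- setdiff(names(highlights), all_ids)
  if (length(bad))
    pc_integrity_error("highlight id(s) not in layout: %s", paste(bad, collapse = ", "))
  badrole <- setdiff(unique(highlights), names(HIGHLIGHT_COLORS))
  if (length(badrole))
    pc_integrity_error("unknown highlight role(s): %s", paste(badrole, collapse = ", "))
  badfade <- setdiff(fade, c("reaction_links", "complex_links", "causal_arcs"))
  if (length(badfade))
    pc_usage_error("unknown fade class(es): %s", paste(badfade, collapse = ", "))
  structure(list(layout = layout, highlights = highlights,
                 frame_index = frame_index, fade = fade),
            class = "pc_render_spec")
}

fmt_num <- function(x) sprintf("%.2f", x)

svg_y <- function(i) RENDER_GEOM$top + (i - 1L) * RENDER_GEOM$row_h

#' Render the reaction-centric view as a static SVG figure
#'
#' Draws the five columns (input proteins, input complexes, reactions,
#' output complexes, output proteins). Reactions are circles sized by
#' participant count; complexes are triangles (single-role) or diamonds
#' (dual-role) sized by transitive component count; straight links connect
#' participants to reactions and members to complexes. Causal arcs between
#' center-column reactions are semicircles — on the right for forward edges,
#' on the left for back arcs (potential feedback) — filled with a
#' yellow-to-black gradient oriented from source to target. Output is
#' deterministic: the same pathway and spec always produce identical bytes.
#'
#' @param p A `pc_pathway`.
#' @param spec A `pc_render_spec`; defaults to the greedy layout with no
#'   highlights.
#' @param g Optional `pc_causal_graph`; built from `p` when `NULL`.
#' @param path Optional output file; when `NULL` the SVG text is returned.
#' @return SVG text (invisibly when written to a file).
#' @export
render_static <- function(p, spec = NULL, g = NULL, path = NULL) {
  if (is.null(spec)) spec <- render_spec(order_participants(p))
  if (is.null(g)) g <- build_causality_graph(p)
  layout <- spec$layout
  geom <- RENDER_GEOM
  roles <- complex_roles(p)
  comp <- transitive_components(p)

  pos_of <- function(colidx, id) match(id, layout[[colidx]])
  colname <- names(layout)

  height <- geom$top + geom$row_h *
    max(1L, vapply(layout, length, integer(1))) + geom$margin
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="800" height="%d">',
            as.integer(height)),
    "  <defs>")
  # one gradient per causal arc, oriented source -> target
  draw_edges <- which(g$edges$channel == "participant" |
                      g$edges$channel == "control")
  for (i in draw_edges) {
    si <- pos_of(3L, g$edges$source[i]); ti <- pos_of(3L, g$edges$target[i])
    if (is.na(si) || is.na(ti)) next
    y1 <- svg_y(si); y2 <- svg_y(ti)
    out <- c(out, sprintf(
      '    <linearGradient id="arc%d" gradientUnits="userSpaceOnUse" x1="%s" y1="%s" x2="%s" y2="%s"><stop offset="0" stop-color="yellow"/><stop offset="1" stop-color="black"/></linearGradient>',
      i, fmt_num(geom$col_x[3]), fmt_num(y1), fmt_num(geom$col_x[3]), fmt_num(y2)))
  }
  out <- c(out, "  </defs>")

  # column scaffolding
  for (ci in 1:5) {
    out <- c(out, sprintf(
      '  <line class="column" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#dddddd"/>',
      fmt_num(geom$col_x[ci]), fmt_num(geom$top - 20),
      fmt_num(geom$col_x[ci]), fmt_num(height - geom$margin / 2)))
  }

  link_cls_opacity <- function(cls)
    if (cls %in% spec$fade) geom$fade_opacity else 1

  # straight participant / membership links
  for (l in layout_links(p, layout)) {
    cls <- if (l$ca == 3L || l$cb == 3L) "reaction_links" else "complex_links"
    ya <- svg_y(pos_of(l$ca, l$ia)); yb <- svg_y(pos_of(l$cb, l$ib))
    color <- if (cls == "complex_links") "#2e8b57" else {
      eid <- if (l$ca == 3L) l$ib else l$ia  # the non-reaction endpoint
      if (is_complex_kind(p, eid)) "#4169aa" else "#cc4444"
    }
    out <- c(out, sprintf(
      '  <line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-opacity="%s"/>',
      cls, fmt_num(geom$col_x[l$ca]), fmt_num(ya),
      fmt_num(geom$col_x[l$cb]), fmt_num(yb), color,
      fmt_num(link_cls_opacity(cls))))
  }

  # causal arcs in the center column: right side forward, left side backward
  for (i in draw_edges) {
    si <- pos_of(3L, g$edges$source[i]); ti <- pos_of(3L, g$edges$target[i])
    if (is.na(si) || is.na(ti) || si == ti) next
    y1 <- svg_y(si); y2 <- svg_y(ti)
    sweep <- if (ti > si) 1L else 0L  # forward arcs bow right, back arcs left
    r <- abs(y2 - y1) / 2
    out <- c(out, sprintf(
      '  <path class="causal_arcs" d="M %s %s A %s %s 0 0 %d %s %s" fill="none" stroke="url(#arc%d)" stroke-width="2" stroke-opacity="%s"/>',
      fmt_num(geom$col_x[3]), fmt_num(y1), fmt_num(r), fmt_num(r), sweep,
      fmt_num(geom$col_x[3]), fmt_num(y2), i,
      fmt_num(link_cls_opacity("causal_arcs"))))
  }

  stroke_for <- function(id) {
    if (!id %in% names(spec$highlights)) return("#333333")
    HIGHLIGHT_COLORS[[spec$highlights[[id]]]]
  }

  # glyphs: proteins as small squares, complexes as triangles/diamonds,
  # reactions as circles
  for (ci in c(1L, 5L)) {
    for (i in seq_along(layout[[ci]])) {
      id <- layout[[ci]][i]
      y <- svg_y(i)
      out <- c(out, sprintf(
        '  <rect class="protein" data-id="%s" x="%s" y="%s" width="6" height="6" fill="%s"/>',
        xml_escape(id), fmt_num(geom$col_x[ci] - 3), fmt_num(y - 3), stroke_for(id)))
    }
  }
  for (ci in c(2L, 4L)) {
    for (i in seq_along(layout[[ci]])) {
      id <- layout[[ci]][i]
      y <- svg_y(i)
      size <- RENDER_GEOM$base_glyph +
        RENDER_GEOM$glyph_per_component * length(comp[[id]])
      x <- geom$col_x[ci]
      pts <- if (identical(roles[[id]], "both")) {
        # diamond: complex used on both sides of reactions
        sprintf("%s,%s %s,%s %s,%s %s,%s",
                fmt_num(x), fmt_num(y - size / 2), fmt_num(x + size / 2), fmt_num(y),
                fmt_num(x), fmt_num(y + size / 2), fmt_num(x - size / 2), fmt_num(y))
      } else {
        # triangle: single-role complex
        sprintf("%s,%s %s,%s %s,%s",
                fmt_num(x), fmt_num(y - size / 2),
                fmt_num(x + size / 2), fmt_num(y + size / 2),
                fmt_num(x - size / 2), fmt_num(y + size / 2))
      }
      out <- c(out, sprintf(
        '  <polygon class="complex" data-id="%s" points="%s" fill="#4169aa" stroke="%s"/>',
        xml_escape(id), pts, stroke_for(id)))
    }
  }
  for (i in seq_along(layout$reactions)) {
    id <- layout$reactions[i]
    r <- RENDER_GEOM$base_radius +
      RENDER_GEOM$radius_per_participant * reaction_size(p, id)
    out <- c(out, sprintf(
      '  <circle class="reaction" data-id="%s" cx="%s" cy="%s" r="%s" fill="#f5f5f5" stroke="%s" stroke-width="2"/>',
      xml_escape(id), fmt_num(geom$col_x[3]), fmt_num(svg_y(i)), fmt_num(r),
      stroke_for(id)))
  }
  out <- c(out, "</svg>")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
  invisible(txt)
}

#' Animation frames of a downstream closure
#'
#' Frame `i` (0-based) highlights BFS levels `0..i` of the downstream
#' closure of the seeds: the cumulative step-by-step flow of activity.
#' The number of frames equals the number of levels, so a loop back to an
#' already-visited reaction never extends the sequence.
#'
#' @param p A `pc_pathway`.
#' @param g A `pc_causal_graph` built from `p`.
#' @param seeds Character vector of seed reaction ids.
#' @param layout Optional `pc_layout`; defaults to the greedy layout.
#' @return List of `pc_render_spec`, one per BFS level.
#' @export
animation_frames <- function(p, g, seeds, layout = NULL) {
  if (is.null(layout)) layout <- order_participants(p)
  ds <- downstream_of(g, seeds)
  lapply(seq_along(ds$levels) - 1L, function(i) {
    ids <- unlist(ds$levels[seq_len(i + 1L)], use.names = FALSE)
    roles <- ifelse(ids %in% ds$levels[[1L]], "seed", "downstream")
    render_spec(layout, highlights = setNames(roles, ids), frame_index = i)
  })
}
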