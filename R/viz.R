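# Standalone hierarchical visualizations: multi-layer (Krona-style) pie
# wedge layouts, self-contained HTML exports with inline SVG and script,
# and a global-view tree with per-sample abundance bars. All exports are
# deterministic byte-for-byte for identical inputs.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

# deterministic path -> color: polynomial string hash to a hue
hash_color <- function(path) {
  vapply(path, function(s) {
    h <- 0
    for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 360
    grDevices::hsv(h / 360, 0.55, 0.85)
  }, character(1), USE.NAMES = FALSE)
}

# core layout: rows (path, value) at the deepest level -> wedges for every
# path prefix, sibling sweeps proportional to value within the parent
wedge_layout_from_paths <- function(paths, values) {
  if (!length(paths) || sum(values) <= 0) {
    out <- data.frame(path = "no data", label = "no data", depth = 1L,
                      start = 0, sweep = 360, color = "#999999",
                      value = 0, stringsAsFactors = FALSE)
    class(out) <- c("wedge_layout", "data.frame")
    return(out)
  }
  split_paths <- strsplit(paths, ";", fixed = TRUE)
  node_value <- new.env(parent = emptyenv())
  for (i in seq_along(split_paths)) {
    parts <- split_paths[[i]]
    for (d in seq_along(parts)) {
      key <- paste(parts[seq_len(d)], collapse = ";")
      node_value[[key]] <- (node_value[[key]] %||% 0) + values[i]
    }
  }
  children_of <- function(prefix) {
    depth <- if (nzchar(prefix)) length(strsplit(prefix, ";",
                                                 fixed = TRUE)[[1L]]) else 0L
    kids <- unique(vapply(split_paths[vapply(split_paths, function(pp) {
      length(pp) > depth &&
        (depth == 0L || paste(pp[seq_len(depth)], collapse = ";") == prefix)
    }, logical(1))], function(pp)
      paste(pp[seq_len(depth + 1L)], collapse = ";"), character(1)))
    if (!length(kids)) return(character(0))
    vals <- vapply(kids, function(k) node_value[[k]], numeric(1))
    kids[order(-vals, kids)]
  }
  rows <- list()
  recurse <- function(prefix, start, sweep, parent_value) {
    for (kid in children_of(prefix)) {
      v <- node_value[[kid]]
      ks <- sweep * v / parent_value
      parts <- strsplit(kid, ";", fixed = TRUE)[[1L]]
      label <- parts[length(parts)]
      rows[[length(rows) + 1L]] <<- data.frame(
        path = kid, label = label, depth = length(parts), start = start,
        sweep = ks,
        color = if (label == UNCLASSIFIED) "#999999" else hash_color(kid),
        value = v, stringsAsFactors = FALSE)
      recurse(kid, start, ks, v)
      start <- start + ks
    }
  }
  total <- sum(values)
  recurse("", 0, 360, total)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wedge_layout", "data.frame")
  out
}

#' Multi-layer pie (sample view) layout
#'
#' Converts a hierarchical profile into a multi-ring wedge layout: wedge
#' angles are proportional to counts, rings correspond to hierarchy depth,
#' sibling sweeps always sum to their parent's sweep and the rings sum to
#' 360 degrees. Colors are a deterministic hash of the lineage path;
#' Unclassified is gray. One layout engine serves taxonomic profiles,
#' 4-level SEED profiles and (flat) GOSlim profiles alike.
#'
#' @param profile a `taxonomic_profile`, `functional_profile`, or a data
#'   frame with `path` and `count` columns.
#' @return a `wedge_layout` data frame (`path`, `label`, `depth`, `start`,
#'   `sweep`, `color`, `value`).
#' @export
layout_sample_view <- function(profile) UseMethod("layout_sample_view")

#' @export
layout_sample_view.taxonomic_profile <- function(profile) {
  df <- profile$ranks$species
  vals <- if (all(is.na(df$count))) df$rel else df$count
  wedge_layout_from_paths(df$path, vals)
}

#' @export
layout_sample_view.functional_profile <- function(profile) {
  if (profile$engine == "seed") {
    wedge_layout_from_paths(profile$table$path, profile$table$count)
  } else {
    wedge_layout_from_paths(gsub(";", " ", profile$table$name, fixed = TRUE),
                            profile$table$count)
  }
}

#' @export
layout_sample_view.data.frame <- function(profile) {
  wedge_layout_from_paths(profile$path, profile$count)
}

# polar helper: angles clockwise from 12 o'clock
polar_xy <- function(cx, cy, r, angle) {
  a <- angle * pi / 180
  c(cx + r * sin(a), cy - r * cos(a))
}

wedge_svg_path <- function(cx, cy, r0, r1, start, sweep) {
  if (sweep >= 360 - 1e-9) {
    # full annulus: two half-arcs
    return(sprintf(
      paste0("M %.4f %.4f A %.4f %.4f 0 1 1 %.4f %.4f ",
             "A %.4f %.4f 0 1 1 %.4f %.4f M %.4f %.4f ",
             "A %.4f %.4f 0 1 0 %.4f %.4f A %.4f %.4f 0 1 0 %.4f %.4f Z"),
      cx, cy - r1, r1, r1, cx, cy + r1, r1, r1, cx, cy - r1,
      cx, cy - r0, r0, r0, cx, cy + r0, r0, r0, cx, cy - r0))
  }
  p1 <- polar_xy(cx, cy, r1, start)
  p2 <- polar_xy(cx, cy, r1, start + sweep)
  p3 <- polar_xy(cx, cy, r0, start + sweep)
  p4 <- polar_xy(cx, cy, r0, start)
  large <- if (sweep > 180) 1L else 0L
  sprintf(paste0("M %.4f %.4f A %.4f %.4f 0 %d 1 %.4f %.4f ",
                 "L %.4f %.4f A %.4f %.4f 0 %d 0 %.4f %.4f Z"),
          p1[1], p1[2], r1, r1, large, p2[1], p2[2],
          p3[1], p3[2], r0, r0, large, p4[1], p4[2])
}

layout_svg_group <- function(layout, group_id, visible) {
  cx <- 400; cy <- 400; r0 <- 40; ring <- 44
  wedges <- vapply(seq_len(nrow(layout)), function(i) {
    d <- layout$depth[i]
    paste0("<path d=\"",
           wedge_svg_path(cx, cy, r0 + (d - 1) * ring, r0 + d * ring,
                          layout$start[i], layout$sweep[i]),
           "\" fill=\"", layout$color[i],
           "\" stroke=\"#ffffff\" stroke-width=\"0.5\" class=\"wedge\">",
           "<title>", xml_escape(layout$path[i]), ": ",
           sprintf("%g", layout$value[i]), "</title></path>")
  }, character(1))
  paste0("<g id=\"", xml_escape(group_id), "\" display=\"",
         if (visible) "inline" else "none", "\">\n",
         paste(wedges, collapse = "\n"), "\n</g>")
}

#' Export sample views as one standalone HTML file
#'
#' One self-contained page (inline SVG and script, no external fetches)
#' with one SVG group per sample, switchable buttons, and click-to-zoom on
#' the pie. Re-export with identical inputs is byte-identical.
#'
#' @param layouts named list of `wedge_layout`s (one per sample).
#' @param metadata optional list; `title` is used when present.
#' @param path output HTML path.
#' @return `path`, invisibly.
#' @export
export_html <- function(layouts, metadata = list(), path) {
  if (!length(layouts)) {
    stop("parameter error: at least one layout required", call. = FALSE)
  }
  if (is.null(names(layouts)) || any(!nzchar(names(layouts)))) {
    names(layouts) <- paste0("sample", seq_along(layouts))
  }
  title <- xml_escape(metadata$title %||% "metaprof sample view")
  ids <- paste0("s", seq_along(layouts))
  groups <- vapply(seq_along(layouts), function(i)
    layout_svg_group(layouts[[i]], ids[i], i == 1L), character(1))
  buttons <- vapply(seq_along(layouts), function(i)
    paste0("<button onclick=\"showSample('", ids[i], "')\">",
           xml_escape(names(layouts)[i]), "</button>"), character(1))
  js <- paste(
    "var ids = [", paste0("'", ids, "'", collapse = ","), "];",
    "function showSample(id){",
    "  ids.forEach(function(g){",
    "    document.getElementById(g).setAttribute('display',",
    "      g === id ? 'inline' : 'none');",
    "  });",
    "}",
    "var zoomed = false;",
    "function toggleZoom(){",
    "  zoomed = !zoomed;",
    "  document.getElementById('pie').setAttribute('transform',",
    "    zoomed ? 'scale(1.6) translate(-150,-150)' : '');",
    "}", sep = "\n")
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    paste0("<title>", title, "</title>"),
    "<style>body{font-family:sans-serif}button{margin:2px}</style>",
    "</head><body>",
    paste0("<h1>", title, "</h1>"),
    paste0("<div>", paste(buttons, collapse = ""), "</div>"),
    "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"800\" height=\"800\" viewBox=\"0 0 800 800\">",
    paste0("<g id=\"pie\" onclick=\"toggleZoom()\">"),
    groups,
    "</g>",
    "</svg>",
    paste0("<script>", js, "</script>"),
    "</body></html>")
  write_lines_utf8(html, path)
}

#' Export the global view: lineage tree with per-sample abundance bars
#'
#' Draws the lineage tree spanned by a [compare_profiles()] table (one
#' node per distinct lineage prefix) and, at each node, one horizontal bar
#' per sample with length proportional to that sample's relative
#' abundance.
#'
#' @param comparison a `comparison_table`.
#' @param path output SVG path.
#' @return `path`, invisibly.
#' @export
export_global_view <- function(comparison, path) {
  mat <- comparison$abundances
  paths <- rownames(mat)
  split_paths <- strsplit(paths, ";", fixed = TRUE)
  nodes <- sort(unique(unlist(lapply(split_paths, function(pp)
    vapply(seq_along(pp), function(d) paste(pp[seq_len(d)],
                                            collapse = ";"),
           character(1))))))
  depth <- vapply(strsplit(nodes, ";", fixed = TRUE), length, integer(1))
  leaves <- sort(nodes[nodes %in% paths])
  leaf_y <- setNames(seq_along(leaves) * 22 * (1L + ncol(mat) %/% 3L),
                     leaves)
  under_node <- function(set, nd) {
    set[set == nd | startsWith(set, paste0(nd, ";"))]
  }
  node_y <- vapply(nodes, function(nd) {
    mean(leaf_y[under_node(leaves, nd)])
  }, numeric(1))
  node_x <- 40 + (depth - 1) * 130
  parent_of <- function(nd) {
    parts <- strsplit(nd, ";", fixed = TRUE)[[1L]]
    if (length(parts) <= 1L) return(NA_character_)
    paste(parts[-length(parts)], collapse = ";")
  }
  edges <- vapply(nodes, function(nd) {
    pa <- parent_of(nd)
    if (is.na(pa) || !(pa %in% nodes)) return("")
    i <- match(nd, nodes); j <- match(pa, nodes)
    sprintf(paste0("<polyline points=\"%.2f,%.2f %.2f,%.2f %.2f,%.2f\" ",
                   "fill=\"none\" stroke=\"#555555\"/>"),
            node_x[j], node_y[j], node_x[j], node_y[i], node_x[i],
            node_y[i])
  }, character(1))
  bars <- unlist(lapply(seq_along(nodes), function(i) {
    nd <- nodes[i]
    rows <- under_node(paths, nd)
    ab <- colSums(mat[rows, , drop = FALSE])
    vapply(seq_along(ab), function(s)
      sprintf(paste0("<rect x=\"%.2f\" y=\"%.2f\" width=\"%.4f\" ",
                     "height=\"4\" fill=\"%s\"><title>%s %s: %.6f",
                     "</title></rect>"),
              node_x[i] + 6, node_y[i] + 2 + (s - 1) * 6, ab[s] * 80,
              hash_color(colnames(mat)[s]),
              xml_escape(colnames(mat)[s]), xml_escape(nd), ab[s]),
      character(1))
  }))
  labels <- vapply(seq_along(nodes), function(i) {
    parts <- strsplit(nodes[i], ";", fixed = TRUE)[[1L]]
    sprintf("<text x=\"%.2f\" y=\"%.2f\" font-size=\"10\">%s</text>",
            node_x[i] + 6, node_y[i] - 3,
            xml_escape(parts[length(parts)]))
  }, character(1))
  dots <- vapply(seq_along(nodes), function(i)
    sprintf("<circle cx=\"%.2f\" cy=\"%.2f\" r=\"2.5\" fill=\"#333333\"/>",
            node_x[i], node_y[i]), character(1))
  w <- max(node_x) + 220
  h <- max(node_y) + 40
  svg <- c(sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                          "width=\"%d\" height=\"%d\">"),
                   ceiling(w), ceiling(h)),
           edges[nzchar(edges)], dots, labels, bars, "</svg>")
  write_lines_utf8(svg, path)
}
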