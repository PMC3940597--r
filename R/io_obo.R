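# OBO 1.2 ontology reader and ancestor-closure queries over the GO DAG.
#
# Only the subset of OBO needed for GOSlim rollups is parsed: [Term] stanzas
# with id, name, namespace, is_a, relationship: part_of and is_obsolete.
# Obsolete terms are recorded but excluded from the edge set; the graph must
# be acyclic (checked at load; a violation is a hard error naming one cycle).

#' Read an OBO 1.2 ontology file
#'
#' @param path path to an OBO file.
#' @param relations edge relations to retain; `is_a` and `part_of` are the
#'   two followed for slim rollups.
#' @return an `ontology_graph`: list with `terms` (data frame `id`, `name`,
#'   `namespace`), `edges` (data frame `child`, `parent`, `relation`) and
#'   `obsolete` (character vector of excluded ids).
#' @export
read_obo <- function(path, relations = c("is_a", "part_of")) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  terms <- list()
  edges <- list()
  obsolete <- character(0)
  bounds <- c(stanza_starts, length(lines) + 1L)
  for (s in seq_along(stanza_starts)) {
    block <- lines[seq(bounds[s] + 1L, bounds[s + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      sub("\\s*!.*$", "", substring(v, nchar(key) + 3L))
    }
    id <- field("id")
    if (length(id) != 1L) {
      stop("OBO format error: [Term] stanza ", s,
           " must have exactly one id", call. = FALSE)
    }
    if (any(field("is_obsolete") == "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    name <- field("name")
    ns <- field("namespace")
    terms[[id]] <- c(name = if (length(name)) name[1L] else id,
                     namespace = if (length(ns)) ns[1L] else "")
    for (p in field("is_a")) {
      edges[[length(edges) + 1L]] <- c(id, trimws(p), "is_a")
    }
    for (r in field("relationship")) {
      bits <- strsplit(trimws(r), "\\s+")[[1L]]
      if (length(bits) >= 2L) {
        edges[[length(edges) + 1L]] <- c(id, bits[2L], bits[1L])
      }
    }
  }
  tids <- names(terms)
  emat <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), ncol = 3L)
  edf <- data.frame(child = emat[, 1L], parent = emat[, 2L],
                    relation = emat[, 3L], stringsAsFactors = FALSE)
  edf <- edf[edf$relation %in% relations, , drop = FALSE]
  # Obsolete terms take no part in the graph; unknown endpoints are errors.
  edf <- edf[!(edf$parent %in% obsolete) & !(edf$child %in% obsolete), ,
             drop = FALSE]
  unknown <- setdiff(unique(c(edf$child, edf$parent)), tids)
  if (length(unknown)) {
    stop("OBO format error: edge references unknown term '", unknown[1L],
         "'", call. = FALSE)
  }
  g <- list(terms = data.frame(
              id = tids,
              name = vapply(terms, `[[`, character(1), "name"),
              namespace = vapply(terms, `[[`, character(1), "namespace"),
              stringsAsFactors = FALSE, row.names = NULL),
            edges = edf[order(edf$child, edf$parent, edf$relation), ,
                        drop = FALSE],
            obsolete = sort(obsolete))
  rownames(g$edges) <- NULL
  class(g) <- "ontology_graph"
  check_acyclic(g)
  g
}

# Hard acyclicity check; reports one offending cycle when present.
check_acyclic <- function(ontology) {
  if (!nrow(ontology$edges)) return(invisible(TRUE))
  ig <- igraph::graph_from_data_frame(
    ontology$edges[, c("child", "parent")], directed = TRUE)
  if (igraph::is_dag(ig)) return(invisible(TRUE))
  # locate one cycle by walking parents from each vertex
  for (start in ontology$terms$id) {
    seen <- character(0)
    frontier <- start
    trail <- list(start)
    repeat {
      nxt <- ontology$edges$parent[ontology$edges$child == frontier]
      if (!length(nxt)) break
      frontier <- nxt[1L]
      if (frontier == start) {
        stop("OBO format error: cycle detected: ",
             paste(c(unlist(trail), start), collapse = " -> "),
             call. = FALSE)
      }
      if (frontier %in% seen) break
      seen <- c(seen, frontier)
      trail <- c(trail, frontier)
    }
  }
  stop("OBO format error: ontology graph contains a cycle", call. = FALSE)
}

#' Ancestor closure of ontology terms
#'
#' Follows `is_a` and `part_of` edges from child to parent; the closure is
#' reflexive (each term is its own ancestor).
#'
#' @param ontology an `ontology_graph`.
#' @param term_ids character vector of term ids.
#' @return sorted character vector: the union of reflexive ancestor sets.
#' @export
ontology_ancestors <- function(ontology, term_ids) {
  unknown <- setdiff(term_ids, ontology$terms$id)
  if (length(unknown)) {
    stop("unknown ontology term '", unknown[1L], "'", call. = FALSE)
  }
  out <- character(0)
  frontier <- unique(term_ids)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(
      unique(ontology$edges$parent[ontology$edges$child %in% frontier]), out)
  }
  sort(unique(out))
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", nrow(x$terms), "terms,", nrow(x$edges), "edges,",
      length(x$obsolete), "obsolete\n")
  invisible(x)
}
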