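# Tab-separated table dialects: lineage tables, profile tables, SEED
# hierarchy tables. All writers emit UTF-8, Unix newlines, deterministic row
# order; all readers validate and name the first malformed record.

#' Read a reference lineage table
#'
#' Dialect: two tab-separated columns, `ref_id` and a semicolon-joined
#' lineage. Missing trailing ranks are padded with `"Unclassified"`; every
#' lineage must have at most seven ranks (domain, phylum, class, order,
#' family, genus, species) and no empty entries.
#'
#' @param path path to the table (no header line).
#' @return a data frame with columns `ref_id` and the seven rank columns,
#'   class `lineage_table`.
#' @export
read_lineage_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 8L),
                                  c("ref_id", TAX_RANKS)))
    class(out) <- c("lineage_table", "data.frame")
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("lineage table error at line ", bad[1L],
         ": expected 2 tab-separated fields", call. = FALSE)
  }
  ref_id <- vapply(parts, `[`, character(1), 1L)
  dup <- which(duplicated(ref_id))
  if (length(dup)) {
    stop("lineage table error at line ", dup[1L], ": duplicate ref_id '",
         ref_id[dup[1L]], "'", call. = FALSE)
  }
  lin <- strsplit(vapply(parts, `[`, character(1), 2L), ";", fixed = TRUE)
  mat <- matrix(UNCLASSIFIED, nrow = length(lin), ncol = 7L,
                dimnames = list(NULL, TAX_RANKS))
  for (i in seq_along(lin)) {
    v <- trimws(lin[[i]])
    if (length(v) > 7L) {
      stop("lineage table error at line ", i, ": more than 7 ranks",
           call. = FALSE)
    }
    if (any(!nzchar(v))) {
      stop("lineage table error at line ", i, ": empty lineage entry",
           call. = FALSE)
    }
    if (length(v)) mat[i, seq_along(v)] <- v
  }
  out <- data.frame(ref_id = ref_id, mat, stringsAsFactors = FALSE)
  class(out) <- c("lineage_table", "data.frame")
  out
}

#' Write a reference lineage table
#'
#' @param lineages a `lineage_table` data frame (see [read_lineage_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(lineages, path) {
  lin <- apply(as.matrix(lineages[, TAX_RANKS, drop = FALSE]), 1L,
               paste, collapse = ";")
  write_lines_utf8(paste(lineages$ref_id, lin, sep = "\t"), path)
}

#' Look up the lineage of a reference sequence
#'
#' @param lineages a `lineage_table`.
#' @param ref_id a single reference id.
#' @return named character vector of the 7 ranks.
#' @export
lineage_of <- function(lineages, ref_id) {
  i <- match(ref_id, lineages$ref_id)
  if (is.na(i)) {
    stop("annotation error: ref_id '", ref_id,
         "' is absent from the lineage table", call. = FALSE)
  }
  setNames(as.character(lineages[i, TAX_RANKS]), TAX_RANKS)
}

# Canonical sort order of the `rank` column in profile tables.
rank_sort_key <- function(rank) {
  known <- c(TAX_RANKS, paste0("seed_l", 1:4),
             "biological_process", "cellular_component", "molecular_function")
  i <- match(rank, known)
  ifelse(is.na(i), length(known) + 1L, i)
}

#' Write a profile table
#'
#' Serializes a taxonomic or functional profile as a tab-separated table
#' with header `rank`, `full_path` (semicolon-joined), `count` and
#' `relative_abundance` (6 decimal places). Rows are sorted by rank order,
#' then descending count, then path; the ordering is deterministic so
#' re-exports are byte-identical.
#'
#' @param profile a `taxonomic_profile`, `functional_profile`, or a data
#'   frame already in table layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  tab <- as_profile_table(profile)
  if (nrow(tab)) {
    cnt <- ifelse(is.na(tab$count), -1, tab$count)
    ord <- order(rank_sort_key(tab$rank), -cnt, tab$full_path)
    tab <- tab[ord, , drop = FALSE]
  }
  lines <- c("rank\tfull_path\tcount\trelative_abundance",
             if (nrow(tab)) {
               paste(tab$rank, tab$full_path,
                     ifelse(is.na(tab$count), "NA", format(tab$count,
                                                           scientific = FALSE)),
                     fmt_abund(tab$relative_abundance), sep = "\t")
             })
  write_lines_utf8(lines, path)
}

#' Read a profile table written by [write_profile_table()]
#'
#' @param path path to the table.
#' @return data frame with columns `rank`, `full_path`, `count`,
#'   `relative_abundance`.
#' @export
read_profile_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) ||
      lines[1L] != "rank\tfull_path\tcount\trelative_abundance") {
    stop("profile table error: missing or malformed header line",
         call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(data.frame(rank = character(0), full_path = character(0),
                      count = integer(0), relative_abundance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop("profile table error at line ", bad[1L] + 1L,
         ": expected 4 tab-separated fields", call. = FALSE)
  }
  data.frame(rank = vapply(parts, `[`, character(1), 1L),
             full_path = vapply(parts, `[`, character(1), 2L),
             count = suppressWarnings(
               as.integer(vapply(parts, `[`, character(1), 3L))),
             relative_abundance = as.numeric(
               vapply(parts, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

#' Read a 4-level SEED-style hierarchy table
#'
#' Dialect: tab-separated with header `level1 level2 level3 level4
#' function_id`. Each function id must map to exactly one 4-level path and
#' no level may be empty.
#'
#' @param path path to the table.
#' @return data frame with the five columns, class `seed_hierarchy`.
#' @export
read_seed_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- "level1\tlevel2\tlevel3\tlevel4\tfunction_id"
  if (!length(lines) || lines[1L] != header) {
    stop("SEED table error: missing or malformed header line", call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad)) {
    stop("SEED table error at line ", bad[1L] + 1L,
         ": expected 5 tab-separated fields", call. = FALSE)
  }
  mat <- do.call(rbind, parts)
  if (is.null(mat)) mat <- matrix(character(0), ncol = 5L)
  empty <- which(apply(mat, 1L, function(r) any(!nzchar(trimws(r)))))
  if (length(empty)) {
    stop("SEED table error at line ", empty[1L] + 1L, ": empty field",
         call. = FALSE)
  }
  dup <- which(duplicated(mat[, 5L]))
  if (length(dup)) {
    stop("SEED table error at line ", dup[1L] + 1L,
         ": duplicate function_id '", mat[dup[1L], 5L], "'", call. = FALSE)
  }
  out <- data.frame(level1 = mat[, 1L], level2 = mat[, 2L],
                    level3 = mat[, 3L], level4 = mat[, 4L],
                    function_id = mat[, 5L], stringsAsFactors = FALSE)
  class(out) <- c("seed_hierarchy", "data.frame")
  out
}

#' Write a 4-level SEED-style hierarchy table
#'
#' @param hierarchy a `seed_hierarchy` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seed_table <- function(hierarchy, path) {
  lines <- c("level1\tlevel2\tlevel3\tlevel4\tfunction_id",
             if (nrow(hierarchy)) {
               paste(hierarchy$level1, hierarchy$level2, hierarchy$level3,
                     hierarchy$level4, hierarchy$function_id, sep = "\t")
             })
  write_lines_utf8(lines, path)
}

#' Look up the 4-level path of a SEED function id
#'
#' @param hierarchy a `seed_hierarchy`.
#' @param function_id character vector of function ids.
#' @return character matrix with columns `level1`..`level4`, one row per id.
#' @export
seed_path_of <- function(hierarchy, function_id) {
  i <- match(function_id, hierarchy$function_id)
  if (anyNA(i)) {
    stop("annotation error: unknown SEED function_id '",
         function_id[which(is.na(i))[1L]], "'", call. = FALSE)
  }
  as.matrix(hierarchy[i, c("level1", "level2", "level3", "level4"),
                      drop = FALSE])
}
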