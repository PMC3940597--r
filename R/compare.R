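# Multi-sample comparison: the Euclidean error-rate statistic, cross-sample
# abundance tables, and a neighbor-joining phylogenetic view.

#' Error rate between actual and predicted abundance vectors
#'
#' For N taxa with actual abundances V and predicted abundances V', the
#' error rate is `E = 100 * sqrt(sum((V - V')^2))` -- the Euclidean distance
#' between the two community structures on a percent scale; a larger E
#' means a higher error. Vectors are matched by name over the union of
#' their supports, with absent taxa contributing 0.
#'
#' @param actual named numeric vector of actual relative abundances.
#' @param predicted named numeric vector of predicted relative abundances.
#' @param normalize `"none"` (default), `"sqrt_n"` (divide by sqrt(N)) or
#'   `"half"` (divide by 2) -- alternative scalings of the same distance.
#' @return E, in percent.
#' @export
error_rate <- function(actual, predicted,
                       normalize = c("none", "sqrt_n", "half")) {
  normalize <- match.arg(normalize)
  if (is.null(names(actual)) || is.null(names(predicted))) {
    if (length(actual) != length(predicted)) {
      stop("parameter error: unnamed vectors must have equal length",
           call. = FALSE)
    }
    v <- actual
    w <- predicted
  } else {
    taxa <- sort(union(names(actual), names(predicted)))
    v <- setNames(rep(0, length(taxa)), taxa)
    w <- v
    v[names(actual)] <- actual
    w[names(predicted)] <- predicted
  }
  if (any(v < 0 | v > 1) || any(w < 0 | w > 1)) {
    stop("parameter error: abundances must lie in [0, 1]", call. = FALSE)
  }
  e <- 100 * sqrt(sum((v - w)^2))
  switch(normalize,
         none = e,
         sqrt_n = e / sqrt(length(v)),
         half = e / 2)
}

#' Cross-sample comparison table at one rank
#'
#' Takes the union of lineage paths at `rank` over all profiles, filling
#' absent taxa with 0; rows are sorted by descending mean abundance, then
#' path. Per-sample column sums equal each profile's rank-level total, so
#' no abundance mass is lost.
#'
#' @param profiles list of >= 2 `taxonomic_profile`s.
#' @param rank one of the 7 ranks.
#' @param labels sample labels; defaults to the profiles' database labels.
#' @return a `comparison_table`: list with `rank`, `labels` and
#'   `abundances` (matrix, rows = paths, columns = samples).
#' @export
compare_profiles <- function(profiles, rank,
                             labels = vapply(profiles, `[[`, character(1),
                                             "database")) {
  if (length(profiles) < 2L) {
    stop("parameter error: at least two profiles required", call. = FALSE)
  }
  rank <- match.arg(rank, TAX_RANKS)
  paths <- sort(unique(unlist(lapply(profiles, function(p)
    p$ranks[[rank]]$path))))
  mat <- vapply(profiles, function(p) {
    df <- p$ranks[[rank]]
    out <- setNames(df$rel, df$path)[paths]
    out[is.na(out)] <- 0
    out
  }, numeric(length(paths)))
  mat <- matrix(mat, nrow = length(paths),
                dimnames = list(paths, labels))
  ord <- order(-rowMeans(mat), rownames(mat))
  structure(list(rank = rank, labels = labels,
                 abundances = mat[ord, , drop = FALSE]),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("comparison_table at rank", x$rank, ":", nrow(x$abundances),
      "taxa x", length(x$labels), "samples\n")
  invisible(x)
}

#' Write a comparison table
#'
#' Tab-separated: `full_path` then one 6-decimal abundance column per
#' sample.
#'
#' @param comparison a `comparison_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(comparison, path) {
  mat <- comparison$abundances
  lines <- c(paste(c("full_path", comparison$labels), collapse = "\t"),
             if (nrow(mat)) {
               vapply(seq_len(nrow(mat)), function(i)
                 paste(c(rownames(mat)[i], fmt_abund(mat[i, ])),
                       collapse = "\t"), character(1))
             })
  write_lines_utf8(lines, path)
}

#' Pairwise p-distance matrix
#'
#' p-distance = proportion of differing residues among aligned residue
#' pairs of a global pairwise alignment (gap columns excluded).
#'
#' @param records a [seq_records()] data frame (>= 2 sequences).
#' @return symmetric numeric matrix with the record ids as dimnames.
#' @export
p_distance_matrix <- function(records) {
  n <- nrow(records)
  if (anyDuplicated(records$id)) {
    stop("parameter error: duplicate sequence ids", call. = FALSE)
  }
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- .align_pair_cpp(records$seq[i], records$seq[j], 1, -1, 2, 1,
                           TRUE)
      d[i, j] <- d[j, i] <- if (a$aligned_pairs > 0) {
        (a$aligned_pairs - a$matches) / a$aligned_pairs
      } else 1
    }
  }
  d
}

#' Neighbor-joining tree of rRNA fragments
#'
#' Builds a pairwise p-distance matrix over the fragments and reconstructs
#' a neighbor-joining tree; for two sequences the tree is the single cherry
#' with each branch d/2.
#'
#' @param fragments a [seq_records()] data frame (>= 2, unique ids).
#' @return Newick string with branch lengths.
#' @export
build_phylo_tree <- function(fragments) {
  if (nrow(fragments) < 2L) {
    stop("parameter error: at least two sequences required", call. = FALSE)
  }
  d <- p_distance_matrix(fragments)
  if (nrow(fragments) == 2L) {
    return(sprintf("(%s:%g,%s:%g);", fragments$id[1L], d[1L, 2L] / 2,
                   fragments$id[2L], d[1L, 2L] / 2))
  }
  tree <- ape::nj(stats::as.dist(d))
  ape::write.tree(tree)
}
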