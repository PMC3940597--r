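# Taxonomic profiling: identity-thresholded lineage assignment, per-rank
# abundance aggregation, and multi-database integration.

#' Default per-rank identity thresholds
#'
#' Percent-identity floors below which a rank is reported as Unclassified;
#' the values follow common rRNA practice (species 97, genus 95, family 90,
#' order 85, class 80, phylum 75; domain always assigned).
#'
#' @return named numeric vector over the seven ranks.
#' @export
default_rank_thresholds <- function() {
  c(domain = 0, phylum = 75, class = 80, order = 85, family = 90,
    genus = 95, species = 97)
}

#' Assign a (possibly truncated) lineage to a reference hit
#'
#' The reference lineage is kept down to the deepest rank whose identity
#' threshold is at most the hit's percent identity; deeper ranks become
#' `"Unclassified"`.
#'
#' @param hit a one-row hit data frame from [map_query()].
#' @param lineages a `lineage_table` containing `hit$ref_id`.
#' @param rank_thresholds named thresholds as in
#'   [default_rank_thresholds()].
#' @return named character vector of the 7 ranks.
#' @export
assign_lineage <- function(hit, lineages,
                           rank_thresholds = default_rank_thresholds()) {
  lin <- lineage_of(lineages, hit$ref_id)
  thr <- rank_thresholds[TAX_RANKS]
  too_deep <- which(thr > hit$identity)
  if (length(too_deep)) {
    lin[seq(min(too_deep), 7L)] <- UNCLASSIFIED
  }
  lin
}

#' Assign lineages to a table of hits
#'
#' @param hits data frame of best hits ([map_all()] output).
#' @inheritParams assign_lineage
#' @return character matrix, one row per hit, columns the 7 ranks.
#' @export
assign_lineages <- function(hits, lineages,
                            rank_thresholds = default_rank_thresholds()) {
  out <- t(vapply(seq_len(nrow(hits)), function(i) {
    assign_lineage(hits[i, , drop = FALSE], lineages, rank_thresholds)
  }, character(7)))
  colnames(out) <- TAX_RANKS
  out
}

#' Build a per-rank taxonomic abundance profile
#'
#' Counts are aggregated at every rank over full lineage paths (truncated
#' assignments contribute Unclassified-terminated paths); relative
#' abundance is count over total assigned reads, so abundances at each rank
#' sum to 1.
#'
#' @param assignments character matrix of lineages (rows = assigned reads,
#'   columns = the 7 ranks), e.g. from [assign_lineages()].
#' @param database_label label of the reference database.
#' @return a `taxonomic_profile`: list with `database`, `total`, `ranks`
#'   (per rank a data frame `path`, `count`, `rel`) and `unclassified`
#'   (per-rank count of reads unclassified at that rank).
#' @export
build_taxonomic_profile <- function(assignments, database_label) {
  assignments <- as.matrix(assignments)
  total <- nrow(assignments)
  ranks <- list()
  unclassified <- setNames(integer(7L), TAX_RANKS)
  for (r in seq_along(TAX_RANKS)) {
    paths <- if (total) {
      apply(assignments[, seq_len(r), drop = FALSE], 1L, paste,
            collapse = ";")
    } else character(0)
    tab <- table(paths)
    df <- data.frame(path = as.character(names(tab) %||% character(0)),
                     count = as.integer(tab), stringsAsFactors = FALSE)
    df$rel <- if (total) df$count / total else numeric(0)
    df <- df[order(-df$count, df$path), , drop = FALSE]
    rownames(df) <- NULL
    ranks[[TAX_RANKS[r]]] <- df
    unclassified[r] <- if (total) {
      sum(df$count[vapply(strsplit(df$path, ";", fixed = TRUE),
                          function(x) x[r] == UNCLASSIFIED, logical(1))])
    } else 0L
  }
  prof <- structure(list(database = database_label, total = total,
                         ranks = ranks, unclassified = unclassified),
                    class = "taxonomic_profile")
  validate_profile(prof)
  prof
}

# mass conservation is asserted on every constructed profile
validate_profile <- function(profile) {
  for (r in TAX_RANKS) {
    df <- profile$ranks[[r]]
    if (!is.na(profile$total) && sum(df$count) != profile$total) {
      stop("profile invariant violated: counts at rank ", r,
           " do not sum to the total", call. = FALSE)
    }
    if (!is.na(profile$total) && profile$total > 0 &&
        abs(sum(df$rel) - 1) > 1e-9) {
      stop("profile invariant violated: relative abundances at rank ", r,
           " do not sum to 1", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat("taxonomic_profile [", x$database, "]: ", x$total,
      " assigned reads; ", nrow(x$ranks$species), " species-level paths\n",
      sep = "")
  invisible(x)
}

#' Relative abundances of a profile at one rank
#'
#' @param profile a `taxonomic_profile`.
#' @param rank one of the 7 ranks.
#' @param by `"taxon"` keys the vector by the rank-level name (aggregating
#'   paths sharing it), `"path"` by the full lineage path.
#' @return named numeric vector summing to 1 (when the profile is
#'   non-empty).
#' @export
abundance_vector <- function(profile, rank, by = c("taxon", "path")) {
  by <- match.arg(by)
  rank <- match.arg(rank, TAX_RANKS)
  df <- profile$ranks[[rank]]
  if (by == "path") return(setNames(df$rel, df$path))
  taxon <- vapply(strsplit(df$path, ";", fixed = TRUE), function(x)
    x[length(x)], character(1))
  v <- tapply(df$rel, taxon, sum)
  setNames(as.numeric(v), names(v))
}

#' Integrate profiles of one sample across reference databases
#'
#' Per rank, the arithmetic mean of relative abundances over the databases
#' (taxa absent from a database contribute 0), renormalized to sum to 1.
#' Counts are not meaningful after averaging and are reported as `NA`.
#'
#' @param profiles non-empty list of `taxonomic_profile`s of the same
#'   sample.
#' @return a `taxonomic_profile` labelled `"integrated"`.
#' @export
integrate_profiles <- function(profiles) {
  if (!length(profiles)) {
    stop("parameter error: at least one profile required", call. = FALSE)
  }
  ranks <- list()
  for (r in TAX_RANKS) {
    paths <- sort(unique(unlist(lapply(profiles, function(p)
      p$ranks[[r]]$path))))
    if (!length(paths)) {
      ranks[[r]] <- data.frame(path = character(0), count = integer(0),
                               rel = numeric(0), stringsAsFactors = FALSE)
      next
    }
    mat <- vapply(profiles, function(p) {
      df <- p$ranks[[r]]
      setNames(df$rel, df$path)[paths]
    }, numeric(length(paths)))
    mat <- matrix(mat, nrow = length(paths))
    mat[is.na(mat)] <- 0
    m <- rowMeans(mat)
    if (sum(m) > 0) m <- m / sum(m)
    df <- data.frame(path = paths, count = NA_integer_, rel = m,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$rel, df$path), , drop = FALSE]
    rownames(df) <- NULL
    ranks[[r]] <- df
  }
  structure(list(database = "integrated", total = NA_integer_,
                 ranks = ranks,
                 unclassified = setNames(rep(NA_integer_, 7L), TAX_RANKS)),
            class = "taxonomic_profile")
}

#' Rebuild a taxonomic profile from a profile table
#'
#' Inverse of [write_profile_table()] for taxonomic profiles (the on-disk
#' table keeps every rank's counts, so the profile is fully recoverable).
#'
#' @param tab data frame from [read_profile_table()].
#' @param database_label label for the rebuilt profile.
#' @return a `taxonomic_profile`.
#' @export
profile_from_table <- function(tab, database_label) {
  ranks <- list()
  for (r in TAX_RANKS) {
    df <- tab[tab$rank == r, , drop = FALSE]
    ranks[[r]] <- data.frame(path = df$full_path, count = df$count,
                             rel = df$relative_abundance,
                             stringsAsFactors = FALSE)
  }
  total <- if (nrow(ranks$domain)) sum(ranks$domain$count) else 0L
  unclassified <- vapply(TAX_RANKS, function(r) {
    df <- ranks[[r]]
    ri <- match(r, TAX_RANKS)
    if (!nrow(df) || anyNA(df$count)) return(NA_integer_)
    as.integer(sum(df$count[vapply(strsplit(df$path, ";", fixed = TRUE),
                                   function(x) x[ri] == UNCLASSIFIED,
                                   logical(1))]))
  }, integer(1))
  structure(list(database = database_label,
                 total = if (anyNA(unlist(lapply(ranks, `[[`, "count")))) {
                   NA_integer_
                 } else total,
                 ranks = ranks, unclassified = unclassified),
            class = "taxonomic_profile")
}

#' @rdname write_profile_table
#' @export
as_profile_table <- function(profile) UseMethod("as_profile_table")

#' @export
as_profile_table.data.frame <- function(profile) profile

#' @export
as_profile_table.taxonomic_profile <- function(profile) {
  do.call(rbind, lapply(TAX_RANKS, function(r) {
    df <- profile$ranks[[r]]
    if (!nrow(df)) return(NULL)
    data.frame(rank = r, full_path = df$path, count = df$count,
               relative_abundance = df$rel, stringsAsFactors = FALSE)
  })) %||% data.frame(rank = character(0), full_path = character(0),
                      count = integer(0), relative_abundance = numeric(0))
}
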