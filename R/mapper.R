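# k-mer seeded best-hit mapping against a reference database.
#
# Replaces a general-purpose aligner with an explicit seed-then-align
# scheme: exact k-mer seeds nominate candidate references, each candidate is
# aligned with an affine-gap Smith-Waterman (match +1, mismatch -1, gap open
# -2, gap extend -1; a gap of length g costs 2 + g), and the single best hit
# is kept. Results are a pure function of (queries, index, parameters), so
# chunked multi-worker execution cannot change any output.

#' Build an exact k-mer index over reference sequences
#'
#' Indexes the forward strand of every reference; query reverse complements
#' are handled at lookup time. References shorter than `k` contribute no
#' seeds (a warning is emitted) but are retained for id lookups.
#'
#' @param refs a [seq_records()] data frame.
#' @param k k-mer size (>= 4).
#' @param alphabet `"dna"` or `"protein"` (controls query strand handling
#'   downstream).
#' @return a `kmer_index`.
#' @export
build_kmer_index <- function(refs, k = 8L, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  k <- as.integer(k)
  if (k < 4L) stop("parameter error: k must be >= 4", call. = FALSE)
  short <- refs$id[nchar(refs$seq) < k]
  if (length(short)) {
    warning("reference(s) shorter than k indexed with zero seeds: ",
            paste(short, collapse = ", "), call. = FALSE)
  }
  ref_idx <- integer(0)
  pos <- integer(0)
  kmer <- character(0)
  for (i in seq_len(nrow(refs))) {
    L <- nchar(refs$seq[i])
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmer <- c(kmer, substring(refs$seq[i], starts, starts + k - 1L))
    ref_idx <- c(ref_idx, rep.int(i, length(starts)))
    pos <- c(pos, starts - 1L)
  }
  tab <- split(seq_along(kmer), kmer)
  env <- new.env(parent = emptyenv(), size = max(1L, length(tab)))
  for (nm in names(tab)) assign(nm, tab[[nm]], envir = env)
  structure(list(k = k, alphabet = alphabet, refs = refs, tab = env,
                 ref_idx = ref_idx, pos = pos,
                 n_positions = length(kmer)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, "|", nrow(x$refs), "refs |",
      x$n_positions, "indexed positions\n")
  invisible(x)
}

#' Look up a k-mer in the index
#'
#' @param index a `kmer_index`.
#' @param kmer a single k-mer string.
#' @return data frame `ref_id`, `pos` (0-based), empty when absent.
#' @export
kmer_lookup <- function(index, kmer) {
  hit <- if (exists(kmer, envir = index$tab, inherits = FALSE)) {
    get(kmer, envir = index$tab)
  } else integer(0)
  data.frame(ref_id = index$refs$id[index$ref_idx[hit]],
             pos = index$pos[hit], stringsAsFactors = FALSE)
}

# candidate reference row indices sharing >= 1 k-mer with `seq`
seed_candidates <- function(index, seq) {
  L <- nchar(seq)
  k <- index$k
  if (L < k) return(integer(0))
  kmers <- unique(substring(seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
  hits <- unlist(lapply(kmers, function(km) {
    if (exists(km, envir = index$tab, inherits = FALSE)) {
      get(km, envir = index$tab)
    } else integer(0)
  }), use.names = FALSE)
  sort(unique(index$ref_idx[hits]))
}

#' Map one query to its best reference hit
#'
#' Both strands of the query are seeded (DNA alphabet only); every
#' seed-nominated reference is aligned with affine-gap Smith-Waterman and
#' the best hit is returned if its percent identity (matches over all
#' alignment columns, gaps included) reaches `min_identity`. Ties are
#' broken by score, then identity, then lexicographically smallest
#' `ref_id`, then `+` strand. Query coordinates always refer to the
#' original (+) orientation.
#'
#' @param query_id id reported in the hit.
#' @param query a single sequence.
#' @param index a `kmer_index`.
#' @param min_identity minimum percent identity (default 75).
#' @param match,mismatch,gap_open,gap_extend alignment scoring.
#' @return one-row data frame (`query_id`, `ref_id`, `identity`, `aln_len`,
#'   `score`, `qstart`, `qend`, `rstart`, `rend`, `strand`) or `NULL`.
#' @export
map_query <- function(query_id, query, index, min_identity = 75,
                      match = 1, mismatch = -1, gap_open = 2,
                      gap_extend = 1) {
  query <- toupper(query)
  strands <- if (index$alphabet == "dna") c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    qseq <- if (strand == "+") query else revcomp(query)
    cand <- seed_candidates(index, qseq)
    for (ci in cand) {
      rseq <- index$refs$seq[ci]
      a <- .align_pair_cpp(qseq, rseq, match, mismatch, gap_open,
                           gap_extend, FALSE)
      if (a$aln_len == 0L) next
      qlen <- nchar(qseq)
      qs <- a$qstart; qe <- a$qend
      if (strand == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = query_id, ref_id = index$refs$id[ci],
        identity = 100 * a$matches / a$aln_len, aln_len = a$aln_len,
        score = a$score, qstart = qs, qend = qe,
        rstart = a$rstart, rend = a$rend, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$score, -hits$identity, hits$ref_id,
                     match(hits$strand, c("+", "-"))), , drop = FALSE]
  best <- hits[1L, , drop = FALSE]
  rownames(best) <- NULL
  if (best$identity < min_identity) return(NULL)
  best
}

#' Map many queries, optionally across workers
#'
#' Queries are split into contiguous chunks processed independently (via
#' [parallel::mclapply()] when `n_workers > 1`) and reassembled in input
#' order; because every per-query result is a pure function of the query
#' and the index, the output is identical for every worker count and chunk
#' size.
#'
#' @param queries a [seq_records()] data frame.
#' @param index a `kmer_index`.
#' @param n_workers number of workers (>= 1).
#' @param ... passed to [map_query()].
#' @return data frame of best hits (queries without a hit are absent),
#'   ordered by query input order.
#' @export
map_all <- function(queries, index, n_workers = 1L, ...) {
  stopifnot(n_workers >= 1L)
  empty <- data.frame(query_id = character(0), ref_id = character(0),
                      identity = numeric(0), aln_len = integer(0),
                      score = numeric(0), qstart = integer(0),
                      qend = integer(0), rstart = integer(0),
                      rend = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  n <- nrow(queries)
  if (!n) return(empty)
  chunk_of <- rep(seq_len(n_workers), each = ceiling(n / n_workers),
                  length.out = n)
  chunks <- split(seq_len(n), chunk_of)
  run_chunk <- function(idx) {
    res <- lapply(idx, function(i) {
      map_query(queries$id[i], queries$seq[i], index, ...)
    })
    do.call(rbind, res[!vapply(res, is.null, logical(1))])
  }
  parts <- if (n_workers == 1L) {
    lapply(chunks, run_chunk)
  } else {
    parallel::mclapply(chunks, run_chunk, mc.cores = n_workers,
                       mc.preschedule = FALSE)
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(empty)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
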