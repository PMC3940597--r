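# Independent oracles used to validate the package's algorithmic cores.
# Each is a deliberately naive implementation (enumeration, dense
# group-by, boolean matrix closure) kept separate from the code it checks.

# ---- exhaustive profile-HMM path enumeration ------------------------------
# Enumerates every legal state path (enter at any match state, traverse
# M/I/D, exit at any match state, emissions mapped to consecutive read
# residues) and returns the maximum total log2-odds score.
enum_viterbi_score <- function(hmm, seq) {
  x <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]],
             c("A", "C", "G", "T", "N"))
  n <- length(x)
  L <- hmm$L
  trM <- log2(hmm$trM); trI <- log2(hmm$trI); trD <- log2(hmm$trD)
  em <- function(j, i) if (x[i] == 5L) 0 else hmm$match_emis[j, x[i]]
  ei <- function(j, i) if (x[i] == 5L) 0 else hmm$insert_emis[j + 1L, x[i]]
  best <- -Inf
  recurse <- function(type, j, i, score) {
    if (type == "M") best <<- max(best, score)
    tr_row <- switch(type, M = trM[j + 1L, ], I = trI[j + 1L, ],
                     D = trD[j + 1L, ])
    if (j + 1L <= L && i + 1L <= n) {
      recurse("M", j + 1L, i + 1L, score + tr_row["M"] + em(j + 1L, i + 1L))
    }
    if (i + 1L <= n) {
      recurse("I", j, i + 1L, score + tr_row["I"] + ei(j, i + 1L))
    }
    if (j + 1L <= L) {
      recurse("D", j + 1L, i, score + tr_row["D"])
    }
  }
  for (i1 in seq_len(n)) {
    for (j0 in seq_len(L)) recurse("M", j0, i1, em(j0, i1))
  }
  best
}

# ---- exhaustive affine-gap Smith-Waterman ---------------------------------
# Plain-R local alignment score (match +1, mismatch -1, gap of length g
# costs gap_open + g * gap_ext) with no seeding heuristics.
sw_oracle_score <- function(q, r, match = 1, mismatch = -1, gap_open = 2,
                            gap_ext = 1) {
  qs <- strsplit(q, "", fixed = TRUE)[[1L]]
  rs <- strsplit(r, "", fixed = TRUE)[[1L]]
  n <- length(qs); m <- length(rs)
  M <- matrix(-Inf, n + 1L, m + 1L)
  X <- M; Y <- M
  M[1L, 1L] <- 0
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (qs[i] == rs[j]) match else mismatch
      M[i + 1L, j + 1L] <- s + max(0, M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_ext,
                               X[i, j + 1L] - gap_ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_ext,
                               Y[i + 1L, j] - gap_ext)
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

# best reference by exhaustive SW over all refs; ties by ref id
sw_oracle_best_ref <- function(query, refs) {
  sc_f <- vapply(refs$seq, sw_oracle_score, numeric(1), q = query,
                 USE.NAMES = FALSE)
  sc_r <- vapply(refs$seq, sw_oracle_score, numeric(1), q = revcomp(query),
                 USE.NAMES = FALSE)
  sc <- pmax(sc_f, sc_r)
  cand <- which(sc == max(sc))
  list(ref_id = min(refs$id[cand]), score = max(sc))
}

# ---- transitive-closure oracle for ontology ancestors ---------------------
# Boolean reachability by repeated matrix multiplication (reflexive).
closure_oracle <- function(ontology) {
  ids <- ontology$terms$id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(ontology$edges))) {
    A[ontology$edges$child[k], ontology$edges$parent[k]] <- TRUE
  }
  R <- diag(n) > 0
  dimnames(R) <- dimnames(A)
  repeat {
    R2 <- R | (R %*% A) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# ---- brute-force 6-frame ORF scan -----------------------------------------
# Straightforward per-frame while-loop scan used to validate predict_genes;
# returns (start, end, strand) triples on forward coordinates.
orf_oracle <- function(seq, min_len_nt) {
  stops <- c("TAA", "TAG", "TGA")
  starts <- c("ATG", "GTG", "TTG")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    L <- nchar(s)
    for (fr in 0:2) {
      pos <- fr + 1L
      orf_start <- NA_integer_
      while (pos + 2L <= L) {
        codon <- substr(s, pos, pos + 2L)
        if (codon %in% stops) {
          if (!is.na(orf_start) && pos + 3L - orf_start >= min_len_nt) {
            out[[length(out) + 1L]] <- c(orf_start - 1L, pos + 2L, strand)
          }
          orf_start <- NA_integer_
        } else if (is.na(orf_start) && codon %in% starts) {
          orf_start <- pos
        }
        pos <- pos + 3L
      }
      if (!is.na(orf_start)) {
        last_full <- pos - 1L # end of last complete codon
        if (last_full - orf_start + 1L >= min_len_nt) {
          out[[length(out) + 1L]] <- c(orf_start - 1L, last_full, strand)
        }
      }
    }
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  names(df) <- c("start", "end", "strand")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  L <- nchar(seq)
  flip <- df$strand == "-"
  tmp <- df$start[flip]
  df$start[flip] <- L - df$end[flip]
  df$end[flip] <- L - tmp
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

# sequences whose pairwise p-distances are exactly additive on the tree
# ((A,B),(C,D)): disjoint mutated blocks per taxon plus a shared internal
# block for the A/B side
additive_quartet <- function(a, b, c, d, e, N = 600L) {
  base <- strrep("A", N)
  mut <- function(s, from, len) {
    substr(s, from, from + len - 1L) <- strrep("C", len)
    s
  }
  A <- mut(mut(base, 1L, a), 401L, e)
  B <- mut(mut(base, 51L, b), 401L, e)
  C <- mut(base, 101L, c)
  D <- mut(base, 151L, d)
  seq_records(c("A", "B", "C", "D"), c(A, B, C, D))
}

# four-point condition: index (1..3) of the best split for a 4x4 additive
# distance matrix over taxa in row order (1 = {12|34}, 2 = {13|24},
# 3 = {14|23})
four_point_split <- function(d) {
  sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  which.min(sums)
}
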