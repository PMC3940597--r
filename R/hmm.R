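# Profile hidden Markov model for rRNA fragment detection.
#
# Architecture: match/insert/delete states estimated from a reference
# multiple alignment, scored as log2-odds against the alignment's background
# base composition, with free local entry into and exit out of any match
# state. Free local alignment is essential here: a 100 bp shotgun read
# covers only a small window of a full-length rRNA model.

#' Build a profile HMM from a reference alignment
#'
#' Columns whose gap fraction is below `match_frac` become match states;
#' remaining columns feed the flanking insert states. Emissions and
#' transitions are estimated with Laplace (+1) pseudocounts. The background
#' distribution is the overall base composition of the alignment (also
#' Laplace-smoothed so log-odds stay finite).
#'
#' @param alignment a [seq_records()] data frame of equal-length aligned
#'   sequences (gaps `-` or `.`).
#' @param match_frac gap-fraction cutoff in (0, 1] for match columns.
#' @return a `profile_hmm` object.
#' @export
build_profile_hmm <- function(alignment, match_frac = 0.5) {
  if (!nrow(alignment)) stop("model error: empty alignment", call. = FALSE)
  if (match_frac <= 0 || match_frac > 1) {
    stop("model error: match_frac must be in (0, 1]", call. = FALSE)
  }
  seqs <- toupper(alignment$seq)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("model error: aligned sequences differ in length", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  is_gap <- chars == "-" | chars == "."
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac < match_frac)
  L <- length(match_cols)
  if (L == 0L) {
    stop("model error: no match columns at match_frac = ", match_frac,
         call. = FALSE)
  }
  nseq <- nrow(chars)
  ncol_aln <- ncol(chars)

  base_counts <- vapply(DNA_BASES, function(b) sum(chars == b & !is_gap),
                        numeric(1))
  background <- (base_counts + 1) / sum(base_counts + 1)

  count_row <- function(col_chars) {
    vapply(DNA_BASES, function(b) sum(col_chars == b), numeric(1))
  }
  match_probs <- t(vapply(match_cols, function(j) {
    cnt <- count_row(chars[!is_gap[, j], j])
    (cnt + 1) / (sum(cnt) + 4)
  }, numeric(4)))
  colnames(match_probs) <- DNA_BASES

  # insert region k = columns between match columns k and k+1 (k = 0..L)
  col2match <- findInterval(seq_len(ncol_aln), match_cols)
  insert_probs <- t(vapply(0:L, function(k) {
    cols <- setdiff(which(col2match == k), match_cols)
    cnt <- if (length(cols)) count_row(chars[, cols][!is_gap[, cols]]) else
      numeric(4)
    (cnt + 1) / (sum(cnt) + 4)
  }, numeric(4)))
  colnames(insert_probs) <- DNA_BASES

  # per-sequence state paths for transition counts; begin acts as M_0 and
  # the end state is counted as a match target.
  cM <- matrix(0, L + 1L, 3L, dimnames = list(NULL, c("M", "I", "D")))
  cI <- matrix(0, L + 1L, 3L, dimnames = list(NULL, c("M", "I", "D")))
  cD <- matrix(0, L + 1L, 3L, dimnames = list(NULL, c("M", "I", "D")))
  for (s in seq_len(nseq)) {
    st <- "M"; pos <- 0L
    add <- function(mat, pos, to) {
      mat[pos + 1L, to] <- mat[pos + 1L, to] + 1
      mat
    }
    for (j in seq_len(ncol_aln)) {
      k <- match(j, match_cols)
      if (!is.na(k)) {
        to <- if (is_gap[s, j]) "D" else "M"
        if (st == "M") cM <- add(cM, pos, to)
        else if (st == "I") cI <- add(cI, pos, to)
        else cD <- add(cD, pos, to)
        st <- to; pos <- k
      } else if (!is_gap[s, j]) {
        # residue in an insert column: I at current position
        if (st == "M") cM <- add(cM, pos, "I")
        else if (st == "I") cI <- add(cI, pos, "I")
        else cD <- add(cD, pos, "I")
        st <- "I" # pos unchanged
      }
    }
    # exit transition counted toward M
    if (st == "M") cM <- add(cM, pos, "M")
    else if (st == "I") cI <- add(cI, pos, "M")
    else cD <- add(cD, pos, "M")
  }
  norm <- function(cnt) {
    p <- cnt + 1
    p / rowSums(p)
  }
  trM <- norm(cM); trI <- norm(cI); trD <- norm(cD)

  consensus <- paste(DNA_BASES[max.col(match_probs, ties.method = "first")],
                     collapse = "")
  hmm <- list(L = L,
              match_probs = match_probs,
              insert_probs = insert_probs,
              trM = trM, trI = trI, trD = trD,
              background = background,
              match_emis = log2(sweep(match_probs, 2L, background, "/")),
              insert_emis = log2(sweep(insert_probs, 2L, background, "/")),
              consensus = consensus)
  class(hmm) <- "profile_hmm"
  hmm
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm: L =", x$L, "match states; consensus",
      substr(x$consensus, 1L, 40L),
      if (x$L > 40L) "..." else "", "\n")
  invisible(x)
}

# log2 transition matrices in the layout the C++ scanner expects
hmm_log_trans <- function(hmm) {
  list(trM = log2(hmm$trM), trI = log2(hmm$trI), trD = log2(hmm$trD))
}

encode_dna <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_ALPHABET) - 1L
  if (anyNA(x)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  x
}

#' Score a sequence against a profile HMM (local Viterbi)
#'
#' Finds the best-scoring local alignment of `seq` to the model: the path
#' enters at any match state, moves through match/insert/delete states and
#' exits at any match state; flanking residues are unpenalized, `N` emits at
#' background (log-odds 0), and scores are in bits (log2-odds).
#'
#' @param hmm a `profile_hmm`.
#' @param seq a single nucleotide sequence.
#' @return list with `score` (bits; `-Inf` for an empty sequence),
#'   `qstart`/`qend` (0-based half-open emitted interval), `mstart`/`mend`
#'   (1-based match-state span) and `path` (data frame `state`, `model_pos`,
#'   `read_pos`).
#' @export
viterbi_score <- function(hmm, seq) {
  if (is.na(seq) || !nzchar(seq)) {
    return(list(score = -Inf, qstart = 0L, qend = 0L, mstart = 0L,
                mend = 0L, path = data.frame(state = character(0),
                                             model_pos = integer(0),
                                             read_pos = integer(0))))
  }
  tr <- hmm_log_trans(hmm)
  r <- .viterbi_cpp(encode_dna(toupper(seq)), hmm$match_emis,
                    hmm$insert_emis, tr$trM, tr$trI, tr$trD, TRUE)
  list(score = r$score, qstart = r$qstart, qend = r$qend,
       mstart = r$mstart, mend = r$mend,
       path = data.frame(state = c("M", "I", "D")[r$path_state],
                         model_pos = r$path_mpos,
                         read_pos = r$path_qpos))
}

#' Default fragment-calling threshold
#'
#' 0.25 bits per match state of the model.
#'
#' @param hmm a `profile_hmm`.
#' @return threshold in bits.
#' @export
default_hmm_threshold <- function(hmm) 0.25 * hmm$L

#' Extract rRNA-like fragments from reads
#'
#' Scans every read on the forward strand and on its reverse complement
#' (computed in memory), keeps the higher-scoring strand (ties broken toward
#' `+`) when the score reaches `threshold_bits`, and reports the fragment
#' re-oriented to the model strand. Coordinates are 0-based half-open on the
#' original read.
#'
#' @param reads a [seq_records()] data frame.
#' @param hmm a `profile_hmm`.
#' @param threshold_bits calling threshold; default
#'   [default_hmm_threshold()].
#' @return data frame with columns `read_id`, `strand`, `start`, `end`,
#'   `score`, `fragment`, sorted by read order.
#' @export
extract_fragments <- function(reads, hmm,
                              threshold_bits = default_hmm_threshold(hmm)) {
  stopifnot(is.finite(threshold_bits))
  empty <- data.frame(read_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), fragment = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(reads)) return(empty)
  fwd <- toupper(reads$seq)
  rev <- revcomp(fwd)
  tr <- hmm_log_trans(hmm)
  enc <- lapply(c(fwd, rev), encode_dna)
  sc <- .viterbi_batch_cpp(enc, hmm$match_emis, hmm$insert_emis,
                           tr$trM, tr$trI, tr$trD)
  n <- nrow(reads)
  sf <- sc[seq_len(n), , drop = FALSE]
  sr <- sc[n + seq_len(n), , drop = FALSE]
  use_rev <- sr[, 1L] > sf[, 1L] # strict: ties go to +
  score <- ifelse(use_rev, sr[, 1L], sf[, 1L])
  keep <- which(is.finite(score) & score >= threshold_bits)
  if (!length(keep)) return(empty)
  len <- nchar(fwd)
  out <- lapply(keep, function(i) {
    if (use_rev[i]) {
      qs <- sr[i, 2L]; qe <- sr[i, 3L]
      frag <- substr(rev[i], qs + 1L, qe)
      data.frame(read_id = reads$id[i], strand = "-",
                 start = len[i] - qe, end = len[i] - qs,
                 score = sr[i, 1L], fragment = frag,
                 stringsAsFactors = FALSE)
    } else {
      qs <- sf[i, 2L]; qe <- sf[i, 3L]
      data.frame(read_id = reads$id[i], strand = "+",
                 start = qs, end = qe, score = sf[i, 1L],
                 fragment = substr(fwd[i], qs + 1L, qe),
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a profile HMM to a versioned text file
#'
#' @param hmm a `profile_hmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(hmm, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = "\t")
  lines <- c("metaprof-hmm\t1",
             paste0("L\t", hmm$L),
             paste0("background\t", num(hmm$background)),
             paste0("consensus\t", hmm$consensus),
             vapply(seq_len(hmm$L), function(j)
               paste0("match\t", j, "\t", num(hmm$match_probs[j, ])),
               character(1)),
             vapply(seq_len(hmm$L + 1L), function(j)
               paste0("insert\t", j - 1L, "\t", num(hmm$insert_probs[j, ])),
               character(1)),
             vapply(seq_len(hmm$L + 1L), function(j)
               paste0("trans\t", j - 1L, "\t",
                      num(c(hmm$trM[j, ], hmm$trI[j, ], hmm$trD[j, ]))),
               character(1)))
  write_lines_utf8(lines, path)
}

#' Read a profile HMM written by [write_hmm()]
#'
#' @param path path to the model file.
#' @return a `profile_hmm`.
#' @export
read_hmm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], "metaprof-hmm\t1")) {
    stop("HMM file error: not a metaprof-hmm version 1 file", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[`, character(1), 1L)
  L <- as.integer(fields[[which(tag == "L")[1L]]][2L])
  background <- setNames(as.numeric(fields[[which(tag == "background")[1L]]][-1L]),
                         DNA_BASES)
  consensus <- fields[[which(tag == "consensus")[1L]]][2L]
  grab <- function(t, n, ncols) {
    rows <- fields[which(tag == t)]
    ord <- order(as.integer(vapply(rows, `[`, character(1), 2L)))
    m <- do.call(rbind, lapply(rows[ord], function(f) as.numeric(f[-(1:2)])))
    stopifnot(nrow(m) == n, ncol(m) == ncols)
    m
  }
  match_probs <- grab("match", L, 4L)
  insert_probs <- grab("insert", L + 1L, 4L)
  trans <- grab("trans", L + 1L, 9L)
  colnames(match_probs) <- colnames(insert_probs) <- DNA_BASES
  hmm <- list(L = L, match_probs = match_probs, insert_probs = insert_probs,
              trM = trans[, 1:3, drop = FALSE],
              trI = trans[, 4:6, drop = FALSE],
              trD = trans[, 7:9, drop = FALSE],
              background = background,
              match_emis = log2(sweep(match_probs, 2L, background, "/")),
              insert_emis = log2(sweep(insert_probs, 2L, background, "/")),
              consensus = consensus)
  colnames(hmm$trM) <- colnames(hmm$trI) <- colnames(hmm$trD) <-
    c("M", "I", "D")
  class(hmm) <- "profile_hmm"
  hmm
}
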