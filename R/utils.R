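# Shared internal helpers: alphabets, sequence records, seeding.

# Canonical taxonomic ranks, shallowest to deepest.
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

UNCLASSIFIED <- "Unclassified"

DNA_BASES <- c("A", "C", "G", "T")
DNA_ALPHABET <- c(DNA_BASES, "N")
# 20 standard amino acids plus X (unknown) and * (stop).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a set of sequence records
#'
#' A sequence record set is a plain `data.frame` with columns `id`, `desc`
#' and `seq`, plus an optional `qual` list-column of integer Phred scores
#' (same length as the sequence). It is the in-memory carrier for FASTA and
#' FASTQ data throughout the package.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of sequences (upper case).
#' @param desc optional descriptions (header text after the first
#'   whitespace); recycled empty string by default.
#' @param qual optional list of integer vectors of per-base Phred scores.
#' @return a `data.frame` with class `seq_records`.
#' @export
seq_records <- function(id, seq, desc = "", qual = NULL) {
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq)) {
    stop("`id` and `seq` must have the same length", call. = FALSE)
  }
  if (any(!nzchar(id))) stop("record ids must be non-empty", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate record id: ", id[duplicated(id)][1L], call. = FALSE)
  }
  out <- data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
                    seq = seq, stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    if (length(qual) != length(id)) {
      stop("`qual` must have one entry per record", call. = FALSE)
    }
    bad <- which(lengths(qual) != nchar(seq))
    if (length(bad)) {
      stop("quality length differs from sequence length for record '",
           id[bad[1L]], "'", call. = FALSE)
    }
    out$qual <- I(lapply(qual, as.integer))
  }
  class(out) <- c("seq_records", "data.frame")
  out
}

# Validate sequence alphabet; returns invisibly, errors naming the offender.
check_alphabet <- function(seqs, ids, alphabet = c("dna", "protein"),
                           allow_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  allowed <- if (alphabet == "dna") DNA_ALPHABET else AA_ALPHABET
  if (allow_gaps) allowed <- c(allowed, "-", ".")
  pat <- paste0("^[", gsub("([*.-])", "\\\\\\1", paste(allowed, collapse = "")),
                "]*$")
  bad <- which(!grepl(pat, seqs))
  if (length(bad)) {
    stop("sequence '", ids[bad[1L]], "' contains characters outside the ",
         alphabet, " alphabet", call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse-complement nucleotide sequences
#'
#' @param x character vector of DNA sequences (may contain N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic text writer: UTF-8, Unix newlines.
write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Fixed-notation formatting used by all table writers (6 decimal places).
fmt_abund <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6f", x))
}
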