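# FASTA / FASTQ readers and writers.
#
# Strict single-dialect parsers: FASTA with '>'-headers and free sequence
# wrapping, FASTQ as 4-line records with Phred+33 qualities. All readers
# reject (never skip) the first malformed record and name its location.

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` (A,C,G,T,N) or `"protein"`; validated on load.
#' @param allow_gaps allow `-` and `.` characters (aligned FASTA input for
#'   profile-HMM construction).
#' @return a [seq_records()] data frame, in file order; multi-line sequences
#'   are concatenated and upper-cased; `desc` is the header text after the
#'   first whitespace.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein"),
                       allow_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(seq_records(character(0), character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("FASTA format error at line ", lineno[1L],
         ": expected a '>' header", call. = FALSE)
  }
  hdr_idx <- which(is_hdr)
  hdr_txt <- sub("^>", "", lines[hdr_idx])
  id <- sub("\\s.*$", "", hdr_txt)
  desc <- ifelse(grepl("\\s", hdr_txt), sub("^\\S+\\s+", "", hdr_txt), "")
  empty_hdr <- which(!nzchar(id))
  if (length(empty_hdr)) {
    stop("FASTA format error at line ", lineno[hdr_idx[empty_hdr[1L]]],
         ": empty header id", call. = FALSE)
  }
  dup <- which(duplicated(id))
  if (length(dup)) {
    stop("FASTA format error at line ", lineno[hdr_idx[dup[1L]]],
         ": duplicate id '", id[dup[1L]], "'", call. = FALSE)
  }
  grp <- cumsum(is_hdr)
  seqs <- vapply(split(lines[!is_hdr], factor(grp[!is_hdr], levels = seq_along(hdr_idx))),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop("FASTA format error at line ", lineno[hdr_idx[empty[1L]]],
         ": record '", id[empty[1L]], "' has an empty sequence",
         call. = FALSE)
  }
  check_alphabet(seqs, id, alphabet, allow_gaps = allow_gaps)
  seq_records(id, unname(seqs), desc)
}

#' Write sequence records as FASTA
#'
#' @param records a [seq_records()] data frame.
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    hdr <- if (nzchar(records$desc[i])) {
      paste0(">", records$id[i], " ", records$desc[i])
    } else paste0(">", records$id[i])
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    c(hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }), use.names = FALSE)
  write_lines_utf8(lines %||% character(0), path)
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' @param path path to a FASTQ file.
#' @return a [seq_records()] data frame with a `qual` list-column of integer
#'   Phred scores.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(seq_records(character(0), character(0)))
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ format error: file length is not a multiple of 4 lines",
         call. = FALSE)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qstr <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("FASTQ format error at line ", (bad[1L] - 1L) * 4L + 1L,
         ": expected '@' header", call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("FASTQ format error at line ", (bad[1L] - 1L) * 4L + 3L,
         ": expected '+' separator", call. = FALSE)
  }
  hdr_txt <- sub("^@", "", hdr)
  id <- sub("\\s.*$", "", hdr_txt)
  desc <- ifelse(grepl("\\s", hdr_txt), sub("^\\S+\\s+", "", hdr_txt), "")
  bad <- which(nchar(seq) != nchar(qstr))
  if (length(bad)) {
    stop("FASTQ format error: sequence and quality lengths differ for ",
         "record '", id[bad[1L]], "'", call. = FALSE)
  }
  check_alphabet(seq, id, "dna")
  qual <- lapply(qstr, function(q) utf8ToInt(q) - 33L)
  neg <- which(vapply(qual, function(q) any(q < 0L), logical(1)))
  if (length(neg)) {
    stop("FASTQ format error: quality characters below '!' (Phred+33) in ",
         "record '", id[neg[1L]], "'", call. = FALSE)
  }
  seq_records(id, seq, desc, qual = qual)
}

#' Write sequence records as FASTQ (Phred+33)
#'
#' Records without a `qual` column are written with a constant quality of 40.
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  n <- nrow(records)
  qual <- if (!is.null(records$qual)) {
    records$qual
  } else {
    lapply(nchar(records$seq), function(l) rep.int(40L, l))
  }
  lines <- unlist(lapply(seq_len(n), function(i) {
    hdr <- if (nzchar(records$desc[i])) {
      paste0("@", records$id[i], " ", records$desc[i])
    } else paste0("@", records$id[i])
    c(hdr, records$seq[i], "+",
      intToUtf8(pmin(qual[[i]], 93L) + 33L, multiple = FALSE))
  }), use.names = FALSE)
  write_lines_utf8(lines %||% character(0), path)
}
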