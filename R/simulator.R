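# Synthetic shotgun community simulator with ground-truth tracking.
#
# Emulates a whole-genome read simulator at the level the evaluation needs:
# reads of fixed length drawn multinomially across genomes according to a
# community abundance vector, uniform start positions, uniform strand, and
# independent per-base substitutions at a configurable rate (no indels, no
# position- or quality-dependent error structure).

#' Draw a community abundance vector
#'
#' The most abundant 2-3 taxa are fixed manually; the remaining probability
#' mass is split among the other taxa by a symmetric Dirichlet(1) draw
#' (i.e., uniformly on the simplex).
#'
#' @param n_taxa total number of taxa.
#' @param n_manual number of manually fixed taxa (2 or 3).
#' @param manual_values descending abundances in (0,1) for the manual taxa;
#'   their sum must be < 1.
#' @param seed RNG seed.
#' @return numeric vector of length `n_taxa` summing to 1; the first
#'   `n_manual` entries equal `manual_values`.
#' @export
draw_abundances <- function(n_taxa, n_manual = length(manual_values),
                            manual_values, seed = NULL) {
  if (n_manual < 2L || n_manual > 3L) {
    stop("parameter error: n_manual must be 2 or 3", call. = FALSE)
  }
  if (length(manual_values) != n_manual) {
    stop("parameter error: manual_values must have length n_manual",
         call. = FALSE)
  }
  if (any(diff(manual_values) > 0) || any(manual_values <= 0) ||
      any(manual_values >= 1)) {
    stop("parameter error: manual_values must be descending and in (0,1)",
         call. = FALSE)
  }
  rest_mass <- 1 - sum(manual_values)
  n_rest <- n_taxa - n_manual
  if (n_rest < 0L) {
    stop("parameter error: n_manual exceeds n_taxa", call. = FALSE)
  }
  if (n_rest == 0L) {
    if (abs(rest_mass) > 1e-9) {
      stop("parameter error: manual abundances must sum to 1 when ",
           "n_taxa == n_manual", call. = FALSE)
    }
    return(manual_values)
  }
  if (rest_mass <= 0) {
    stop("parameter error: manual abundances sum to >= 1", call. = FALSE)
  }
  rest <- with_seed(seed, {
    g <- rgamma(n_rest, shape = 1)
    g / sum(g) * rest_mass
  })
  c(manual_values, rest)
}

#' Specify a synthetic community sample
#'
#' @param genomes a [seq_records()] data frame of source genomes.
#' @param abundances relative abundances, one per genome, summing to 1
#'   (within 1e-9).
#' @param n_reads number of reads to emit.
#' @param read_len read length in bases (default 100).
#' @param err_rate per-base substitution probability (default 0.01).
#' @param seed RNG seed driving all randomness of the sample.
#' @return a `community_spec`.
#' @export
community_spec <- function(genomes, abundances, n_reads, read_len = 100L,
                           err_rate = 0.01, seed = 1L) {
  if (length(abundances) != nrow(genomes)) {
    stop("parameter error: one abundance per genome required",
         call. = FALSE)
  }
  if (any(abundances < 0 | abundances > 1)) {
    stop("parameter error: abundances must be in [0,1]", call. = FALSE)
  }
  if (abs(sum(abundances) - 1) > 1e-9) {
    stop("parameter error: abundances must sum to 1", call. = FALSE)
  }
  if (read_len > min(nchar(genomes$seq))) {
    stop("parameter error: read_len exceeds the shortest genome",
         call. = FALSE)
  }
  if (err_rate < 0 || err_rate >= 1) {
    stop("parameter error: err_rate must be in [0,1)", call. = FALSE)
  }
  structure(list(genomes = genomes, abundances = abundances,
                 n_reads = as.integer(n_reads),
                 read_len = as.integer(read_len),
                 err_rate = err_rate, seed = as.integer(seed)),
            class = "community_spec")
}

# substitute `n_err` uniformly chosen positions of `seq` with a uniformly
# chosen *different* base
inject_errors <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate shotgun reads from a community
#'
#' For each read: a source genome is drawn from the abundance vector, a
#' start position uniformly over valid positions, a strand uniformly; the
#' oriented read then receives independent per-base substitutions at
#' `err_rate`. Fully reproducible from `spec$seed`.
#'
#' @param spec a [community_spec()].
#' @return list with `reads` (a [seq_records()] data frame) and `truth`
#'   (data frame `read_id`, `genome_id`, `start`, `end` -- 0-based
#'   half-open on the forward genome --, `strand`, `n_errors`).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  n <- spec$n_reads
  rl <- spec$read_len
  with_seed(spec$seed, {
    gidx <- sample.int(nrow(spec$genomes), n, replace = TRUE,
                       prob = spec$abundances)
    glen <- nchar(spec$genomes$seq)[gidx]
    start0 <- vapply(glen - rl, function(m) sample.int(m + 1L, 1L) - 1L,
                     integer(1))
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    seqs <- substring(spec$genomes$seq[gidx], start0 + 1L, start0 + rl)
    flip <- strand == "-"
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    n_err <- rbinom(n, rl, spec$err_rate)
    has_err <- which(n_err > 0L)
    for (i in has_err) {
      seqs[i] <- inject_errors(seqs[i], sample.int(rl, n_err[i]))
    }
    ids <- sprintf("r%06d", seq_len(n))
    list(reads = seq_records(ids, seqs,
                             desc = spec$genomes$id[gidx]),
         truth = data.frame(read_id = ids,
                            genome_id = spec$genomes$id[gidx],
                            start = start0, end = start0 + rl,
                            strand = strand, n_errors = n_err,
                            stringsAsFactors = FALSE))
  })
}

#' Species-level truth abundances of a simulated sample
#'
#' @param truth the truth table from [simulate_reads()].
#' @return named numeric vector of per-genome read fractions.
#' @export
truth_abundances <- function(truth) {
  tab <- table(truth$genome_id)
  setNames(as.numeric(tab) / nrow(truth), names(tab))
}

#' Recompute per-read mismatch counts against the source genomes
#'
#' Independent of the simulator's own `n_errors` bookkeeping: extracts each
#' read's recorded source interval, orients it to the read strand and
#' counts differing bases.
#'
#' @param reads simulated reads.
#' @param truth matching truth table.
#' @param genomes the source genomes.
#' @return integer vector of mismatch counts, one per read.
#' @export
count_read_mismatches <- function(reads, truth, genomes) {
  stopifnot(nrow(reads) == nrow(truth))
  gi <- match(truth$genome_id, genomes$id)
  src <- substring(genomes$seq[gi], truth$start + 1L, truth$end)
  flip <- truth$strand == "-"
  if (any(flip)) src[flip] <- revcomp(src[flip])
  mapply(function(a, b) {
    sum(strsplit(a, "", fixed = TRUE)[[1L]] !=
          strsplit(b, "", fixed = TRUE)[[1L]])
  }, reads$seq, src, USE.NAMES = FALSE)
}

#' Write a simulated sample to disk
#'
#' @param sim result of [simulate_reads()].
#' @param prefix output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.fastq` and `<prefix>_truth.tsv`.
#' @return character vector of the three paths, invisibly.
#' @export
write_simulated_sample <- function(sim, prefix) {
  fa <- paste0(prefix, ".fasta")
  fq <- paste0(prefix, ".fastq")
  tr <- paste0(prefix, "_truth.tsv")
  write_fasta(sim$reads, fa)
  write_fastq(sim$reads, fq)
  write_lines_utf8(
    c("read_id\tgenome_id\tstart\tend\tstrand\tn_errors",
      paste(sim$truth$read_id, sim$truth$genome_id, sim$truth$start,
            sim$truth$end, sim$truth$strand, sim$truth$n_errors,
            sep = "\t")),
    tr)
  invisible(c(fa, fq, tr))
}
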