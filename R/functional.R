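# Functional analysis: ORF-based gene prediction on assembled contigs,
# best-hit annotation transfer, GOSlim rollup and 4-level SEED rollup.
#
# Gene prediction is an explicit 6-frame ORF finder (documented stand-in
# for HMM-trained gene callers); external gene calls can be ingested as
# FASTA through the same downstream functions.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

translate_dna <- function(seq) {
  p <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(seq), if.fuzzy.codon = "X"))
  sub("\\*$", "", p)
}

# ORFs of one strand of one contig; coordinates on that strand.
scan_orfs_strand <- function(seq, min_len_nt) {
  L <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    starts <- seq(frame + 1L, L - 2L, by = 3L)
    if (frame + 3L > L) next
    codons <- substring(seq, starts, starts + 2L)
    pending <- NA_integer_ # index (into codons) of first start since stop
    for (ci in seq_along(codons)) {
      if (codons[ci] %in% STOP_CODONS) {
        if (!is.na(pending)) {
          s <- starts[pending] - 1L # 0-based
          e <- starts[ci] + 2L      # includes stop codon
          if (e - s >= min_len_nt) {
            out[[length(out) + 1L]] <- list(start = s, end = e,
                                            frame = frame, partial = FALSE)
          }
        }
        pending <- NA_integer_
      } else if (is.na(pending) && codons[ci] %in% START_CODONS) {
        pending <- ci
      }
    }
    if (!is.na(pending)) { # open ORF running into the contig edge
      s <- starts[pending] - 1L
      e <- starts[length(codons)] + 2L
      if (e - s >= min_len_nt) {
        out[[length(out) + 1L]] <- list(start = s, end = e, frame = frame,
                                        partial = TRUE)
      }
    }
  }
  out
}

#' Predict genes on assembled contigs (6-frame ORF scan)
#'
#' Scans all six reading frames for open reading frames starting at ATG,
#' GTG or TTG (the leftmost start after the previous in-frame stop) and
#' ending at a stop codon or the contig edge. The reported nucleotide
#' sequence includes the stop codon when one terminates the ORF; the
#' protein is the standard-code translation with the trailing stop removed.
#' Coordinates are 0-based half-open on the forward contig strand; calls
#' are ordered by (contig, start, strand).
#'
#' @param contigs a [seq_records()] data frame of assembled contigs.
#' @param min_len_nt minimum ORF length in nucleotides (>= 30, default
#'   300).
#' @return data frame with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `frame`, `seq`, `protein`.
#' @export
predict_genes <- function(contigs, min_len_nt = 300L) {
  if (min_len_nt < 30L) {
    stop("parameter error: min_len_nt must be >= 30", call. = FALSE)
  }
  check_alphabet(toupper(contigs$seq), contigs$id, "dna")
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    fwd <- toupper(contigs$seq[i])
    L <- nchar(fwd)
    rev <- revcomp(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      for (orf in scan_orfs_strand(s, min_len_nt)) {
        gseq <- substr(s, orf$start + 1L, orf$end)
        cs <- if (strand == "+") orf$start else L - orf$end
        ce <- if (strand == "+") orf$end else L - orf$start
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = contigs$id[i], start = cs, end = ce,
          strand = strand, frame = orf$frame, seq = gseq,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      seq = character(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$contig_id, genes$start, genes$strand), ,
                 drop = FALSE]
  coding <- ifelse(substring(genes$seq, nchar(genes$seq) - 2L) %in%
                     STOP_CODONS, substring(genes$seq, 1L,
                                            nchar(genes$seq) - 3L),
                   genes$seq)
  genes$protein <- vapply(coding, translate_dna, character(1),
                          USE.NAMES = FALSE)
  genes$gene_id <- paste(genes$contig_id, genes$start, genes$end,
                         genes$strand, sep = "_")
  rownames(genes) <- NULL
  genes[, c("gene_id", "contig_id", "start", "end", "strand", "frame",
            "seq", "protein")]
}

#' Identify predicted genes by best-hit mapping to annotated proteins
#'
#' Maps each predicted protein to an annotated reference protein set with
#' the k-mer seeded aligner (identity scoring, protein alphabet) and
#' transfers the top hit's annotations. Genes without a hit are absent
#' from the result.
#'
#' @param genes output of [predict_genes()] (or a compatible data frame
#'   with `gene_id` and `protein`).
#' @param annotated_refs protein [seq_records()]; ids must match
#'   `annotations$ref_id`.
#' @param annotations data frame `ref_id`, `go_terms` (pipe-separated,
#'   possibly empty), `seed_function_id`.
#' @param k protein k-mer size for seeding (default 4).
#' @param min_identity minimum percent identity for transfer.
#' @param n_workers mapping workers.
#' @return data frame `gene_id`, `ref_id`, `identity`, `go_terms`,
#'   `seed_function_id`.
#' @export
identify_genes <- function(genes, annotated_refs, annotations, k = 4L,
                           min_identity = 75, n_workers = 1L) {
  idx <- build_kmer_index(annotated_refs, k = k, alphabet = "protein")
  queries <- seq_records(genes$gene_id, genes$protein)
  hits <- map_all(queries, idx, n_workers = n_workers,
                  min_identity = min_identity)
  if (!nrow(hits)) {
    return(data.frame(gene_id = character(0), ref_id = character(0),
                      identity = numeric(0), go_terms = character(0),
                      seed_function_id = character(0),
                      stringsAsFactors = FALSE))
  }
  ai <- match(hits$ref_id, annotations$ref_id)
  data.frame(gene_id = hits$query_id, ref_id = hits$ref_id,
             identity = hits$identity,
             go_terms = annotations$go_terms[ai],
             seed_function_id = annotations$seed_function_id[ai],
             stringsAsFactors = FALSE)
}

#' Roll GO annotations up to GOSlim terms
#'
#' For each gene, the reflexive ancestor closure (over `is_a` and
#' `part_of`) of its GO terms is intersected with the slim set; each slim
#' term is counted at most once per gene. The profile keeps the `top_n`
#' most abundant slim terms per namespace (ties broken by term id).
#'
#' @param annotations data frame with `gene_id` and `go_terms`
#'   (pipe-separated), e.g. from [identify_genes()].
#' @param ontology an `ontology_graph` from [read_obo()].
#' @param slim_ids character vector of slim term ids (must exist in the
#'   ontology).
#' @param top_n slim terms kept per namespace (default 20).
#' @return a `functional_profile` with engine `"goslim"`.
#' @export
rollup_goslim <- function(annotations, ontology, slim_ids, top_n = 20L) {
  missing <- setdiff(slim_ids, ontology$terms$id)
  if (length(missing)) {
    stop("parameter error: slim id '", missing[1L],
         "' is absent from the ontology", call. = FALSE)
  }
  counts <- setNames(integer(length(slim_ids)), slim_ids)
  n_genes <- nrow(annotations)
  for (i in seq_len(n_genes)) {
    terms <- setdiff(strsplit(annotations$go_terms[i], "|",
                              fixed = TRUE)[[1L]], "")
    if (!length(terms)) next
    anc <- ontology_ancestors(ontology, unique(terms))
    hit <- intersect(anc, slim_ids)
    counts[hit] <- counts[hit] + 1L
  }
  ti <- match(names(counts), ontology$terms$id)
  tab <- data.frame(term = names(counts),
                    name = ontology$terms$name[ti],
                    namespace = ontology$terms$namespace[ti],
                    count = as.integer(counts), stringsAsFactors = FALSE)
  tab <- tab[tab$count > 0L, , drop = FALSE]
  tab <- do.call(rbind, lapply(split(tab, tab$namespace), function(d) {
    d <- d[order(-d$count, d$term), , drop = FALSE]
    head(d, top_n)
  }))
  tab <- tab[order(tab$namespace, -tab$count, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(engine = "goslim", table = tab,
                 total_genes = n_genes),
            class = "functional_profile")
}

#' Roll SEED function annotations up to the 4-level hierarchy
#'
#' Each annotated gene contributes one count to its full 4-level path;
#' counts aggregate consistently at every level (see [seed_marginal()]).
#'
#' @param annotations data frame with `gene_id` and `seed_function_id`.
#' @param hierarchy a `seed_hierarchy` from [read_seed_table()].
#' @return a `functional_profile` with engine `"seed"`.
#' @export
rollup_seed <- function(annotations, hierarchy) {
  ann <- annotations[!is.na(annotations$seed_function_id) &
                       nzchar(annotations$seed_function_id), ,
                     drop = FALSE]
  paths <- seed_path_of(hierarchy, ann$seed_function_id)
  key <- apply(paths, 1L, paste, collapse = ";")
  tab <- table(key)
  lv <- do.call(rbind, strsplit(names(tab), ";", fixed = TRUE))
  if (is.null(lv)) lv <- matrix(character(0), ncol = 4L)
  out <- data.frame(level1 = lv[, 1L], level2 = lv[, 2L],
                    level3 = lv[, 3L], level4 = lv[, 4L],
                    path = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$path), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(engine = "seed", table = out, total_genes = nrow(ann)),
            class = "functional_profile")
}

#' Marginal counts of a SEED profile at one level
#'
#' @param profile a SEED `functional_profile`.
#' @param level level 1..4.
#' @return named integer vector of counts by the level-`level` prefix
#'   path; the counts always sum to the total annotated genes.
#' @export
seed_marginal <- function(profile, level) {
  stopifnot(profile$engine == "seed", level %in% 1:4)
  key <- apply(profile$table[, paste0("level", seq_len(level)),
                             drop = FALSE], 1L, paste, collapse = ";")
  v <- tapply(profile$table$count, key, sum)
  setNames(as.integer(v), names(v))
}

#' @export
print.functional_profile <- function(x, ...) {
  cat("functional_profile [", x$engine, "]: ", nrow(x$table),
      " terms/paths over ", x$total_genes, " annotated genes\n", sep = "")
  invisible(x)
}

#' @export
as_profile_table.functional_profile <- function(profile) {
  if (profile$engine == "seed") {
    # rows at all four levels so the hierarchy is recoverable from disk
    do.call(rbind, lapply(1:4, function(k) {
      m <- seed_marginal(profile, k)
      data.frame(rank = paste0("seed_l", k), full_path = names(m),
                 count = as.integer(m),
                 relative_abundance = if (sum(m)) as.numeric(m) / sum(m)
                 else numeric(length(m)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    tot <- sum(profile$table$count)
    data.frame(rank = profile$table$namespace,
               full_path = paste(profile$table$term, profile$table$name,
                                 sep = ";"),
               count = profile$table$count,
               relative_abundance = if (tot) profile$table$count / tot
               else numeric(0),
               stringsAsFactors = FALSE)
  }
}
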