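# Shared fixtures, built once per test run and memoized.

.fix <- new.env(parent = emptyenv())

fixture_bundle <- function() {
  if (is.null(.fix$bundle)) {
    .fix$bundle <- make_fixture_bundle(
      file.path(tempdir(), "metaprof-fixtures"), seed = 42L)
  }
  .fix$bundle
}

fixture_hmm <- function() {
  if (is.null(.fix$hmm)) {
    b <- fixture_bundle()
    .fix$hmm <- build_profile_hmm(read_fasta(b$rrna_alignment,
                                             allow_gaps = TRUE))
  }
  .fix$hmm
}

fixture_genomes <- function() read_fasta(fixture_bundle()$genomes)

fixture_rrna_truth <- function() {
  read.delim(fixture_bundle()$rrna_truth, stringsAsFactors = FALSE)
}

# random sequence records for round-trip tests
random_records <- function(n, min_len = 20L, max_len = 120L,
                           with_qual = FALSE, seed = 1L) {
  withr::with_seed(seed, {
    lens <- sample(min_len:max_len, n, replace = TRUE)
    seqs <- vapply(lens, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = ""), character(1))
    qual <- if (with_qual) lapply(lens, function(l)
      sample(0:41, l, replace = TRUE))
    seq_records(sprintf("rec%03d", seq_len(n)), seqs,
                desc = ifelse(seq_len(n) %% 2L == 0L,
                              paste("description", seq_len(n)), ""),
                qual = qual)
  })
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small toy model shared by a few HMM tests: ungapped alignment
toy_alignment <- function(seqs) {
  seq_records(sprintf("a%02d", seq_along(seqs)), seqs)
}

# the end-to-end profiling run used by the recovery and conservation
# checks: fixture community at the default read length and error rate,
# computed once
e2e_run <- function(n_reads = 20000L) {
  key <- paste0("e2e_", n_reads)
  if (!is.null(.fix[[key]])) return(.fix[[key]])
  b <- fixture_bundle()
  genomes <- fixture_genomes()
  ab <- draw_abundances(nrow(genomes), 3L, c(0.30, 0.20, 0.15), seed = 7L)
  spec <- community_spec(genomes, ab, n_reads = n_reads, seed = 11L)
  sim <- simulate_reads(spec)
  hmm <- fixture_hmm()
  frags <- extract_fragments(sim$reads, hmm)
  queries <- seq_records(frags$read_id, frags$fragment)
  profiles <- list()
  for (db in c("general", "habitat")) {
    refs <- read_fasta(b[[paste0("db_", db)]])
    lineages <- read_lineage_table(b[[paste0("db_", db, "_lineage")]])
    idx <- build_kmer_index(refs, k = 8L)
    hits <- map_all(queries, idx)
    asg <- assign_lineages(hits, lineages)
    profiles[[db]] <- build_taxonomic_profile(asg, db)
  }
  truth_genus <- truth_abundances(sim$truth)
  names(truth_genus) <- sprintf("Genus_%d",
                                as.integer(sub("genome0?", "",
                                               names(truth_genus))))
  .fix[[key]] <- list(sim = sim, spec = spec, frags = frags,
                      profiles = profiles, truth_genus = truth_genus)
  .fix[[key]]
}

# annotated-gene identification on the fixture contigs, computed once
functional_run <- function() {
  if (!is.null(.fix$functional)) return(.fix$functional)
  b <- fixture_bundle()
  genes <- predict_genes(read_fasta(b$contigs))
  refs <- read_fasta(b$proteins, alphabet = "protein")
  ann <- read.delim(b$protein_annotations, stringsAsFactors = FALSE)
  idents <- identify_genes(genes, refs, ann)
  .fix$functional <- list(genes = genes, refs = refs, ann = ann,
                          idents = idents,
                          hierarchy = read_seed_table(b$seed_table),
                          ontology = read_obo(b$obo),
                          slim = readLines(b$slim))
  .fix$functional
}
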