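# Fixture bundle generator: a miniature, fully ground-truthed test universe
# emulating the data a real profiling run consumes -- toy genomes with one
# planted rRNA-like region each, a general and a habitat-specific reference
# database with lineage tables, a small GO DAG with a slim subset, a
# 4-level SEED-style hierarchy, and an annotated protein set with contigs
# carrying planted genes. Everything is derived from one seed and written
# deterministically, so a bundle is byte-identical across runs.

# one fixed codon per amino acid (used for reverse-translation of planted
# genes; M -> ATG keeps every planted gene startable)
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# point-mutate each base independently with probability `rate`
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate the fixture bundle
#'
#' Writes the full set of miniature inputs for an end-to-end run into
#' `dir`:
#' \itemize{
#'   \item `genomes.fasta` + `genome_lineage.tsv` + `rrna_truth.tsv`: 8
#'     genomes of 10 kb, each with one planted 300 bp rRNA-like region
#'     derived from a shared consensus (about 5\% divergence per genome),
#'     its coordinates recorded in the sidecar truth file;
#'   \item `db_general.fasta`/`db_general_lineage.tsv`: one reference per
#'     genome, further diverged (~3\%) from the genome's own rRNA (a
#'     broad, less specific database);
#'   \item `db_habitat.fasta`/`db_habitat_lineage.tsv`: exact copies of
#'     each genome's rRNA (a specialized, habitat-matched database);
#'   \item `rrna_alignment.fasta`: the 16 reference rRNAs (equal length,
#'     ungapped) used to train the profile HMM;
#'   \item `go.obo` + `go_slim.txt`: a 30-term GO DAG over three
#'     namespaces with one obsolete term and a 9-term slim subset;
#'   \item `seed_hierarchy.tsv`: 12 function ids over a 4-level hierarchy;
#'   \item `proteins.fasta` + `protein_annotations.tsv`: 15 annotated
#'     proteins (GO leaf terms and SEED function ids);
#'   \item `contigs.fasta` + `gene_truth.tsv`: 6 contigs, 10 planted genes
#'     (reverse-translations of proteins 1-10, both strands).
#' }
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed; the same seed yields a byte-identical bundle.
#' @return named list of file paths plus the generation parameters,
#'   invisibly classed `fixture_bundle`.
#' @export
make_fixture_bundle <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  n_genomes <- 8L
  genome_len <- 10000L
  rrna_len <- 300L

  with_seed(seed, {
    consensus <- random_dna(rrna_len)

    phylum <- rep(c("Phylum_A", "Phylum_B"), each = 4L)
    class_ <- paste0("Class_", rep(1:4, each = 2L))
    lineages <- data.frame(
      ref_id = sprintf("genome%02d", 1:n_genomes),
      domain = "Bacteria", phylum = phylum, class = class_,
      order = paste0("Order_", 1:n_genomes),
      family = paste0("Family_", 1:n_genomes),
      genus = paste0("Genus_", 1:n_genomes),
      species = paste0("Species_", 1:n_genomes),
      stringsAsFactors = FALSE)
    class(lineages) <- c("lineage_table", "data.frame")

    gseq <- character(n_genomes)
    rrna <- character(n_genomes)
    rstart <- integer(n_genomes)
    for (i in seq_len(n_genomes)) {
      g <- random_dna(genome_len)
      rrna[i] <- mutate_seq(consensus, 0.05)
      rstart[i] <- sample.int(genome_len - rrna_len + 1L, 1L) - 1L
      substr(g, rstart[i] + 1L, rstart[i] + rrna_len) <- rrna[i]
      gseq[i] <- g
    }
    genomes <- seq_records(lineages$ref_id, gseq)
    write_fasta(genomes, p("genomes.fasta"))
    write_lineage_table(lineages, p("genome_lineage.tsv"))
    write_lines_utf8(
      c("genome_id\tstart\tend",
        paste(lineages$ref_id, rstart, rstart + rrna_len, sep = "\t")),
      p("rrna_truth.tsv"))

    gen_refs <- seq_records(sprintf("gen%02d", 1:n_genomes),
                            vapply(rrna, mutate_seq, character(1),
                                   rate = 0.03))
    hab_refs <- seq_records(sprintf("hab%02d", 1:n_genomes), rrna)
    write_fasta(gen_refs, p("db_general.fasta"))
    write_fasta(hab_refs, p("db_habitat.fasta"))
    lin_of <- function(ids) {
      out <- lineages
      out$ref_id <- ids
      out
    }
    write_lineage_table(lin_of(gen_refs$id), p("db_general_lineage.tsv"))
    write_lineage_table(lin_of(hab_refs$id), p("db_habitat_lineage.tsv"))
    write_fasta(rbind(gen_refs, hab_refs), p("rrna_alignment.fasta"))

    # --- GO DAG: 3 namespaces x 10 terms, mid-level slim, 1 obsolete ----
    namespaces <- c("biological_process", "molecular_function",
                    "cellular_component")
    obo <- c("format-version: 1.2", "")
    slim_ids <- character(0)
    leaf_ids <- character(0)
    tid <- function(i) sprintf("GO:%07d", i)
    for (ns_i in seq_along(namespaces)) {
      o <- (ns_i - 1L) * 10L
      obo <- c(obo, "[Term]", paste0("id: ", tid(o + 1L)),
               paste0("name: ", namespaces[ns_i], " root"),
               paste0("namespace: ", namespaces[ns_i]), "")
      for (m in 2:4) {
        obo <- c(obo, "[Term]", paste0("id: ", tid(o + m)),
                 paste0("name: slim term ", o + m),
                 paste0("namespace: ", namespaces[ns_i]),
                 paste0("is_a: ", tid(o + 1L), " ! root"), "")
        slim_ids <- c(slim_ids, tid(o + m))
      }
      for (l in 5:10) {
        parents <- sample(2:4, sample(1:2, 1L))
        rel <- sample(c("is_a", "part_of"), length(parents),
                      replace = TRUE)
        plines <- ifelse(rel == "is_a",
                         paste0("is_a: ", tid(o + parents)),
                         paste0("relationship: part_of ", tid(o + parents)))
        obo <- c(obo, "[Term]", paste0("id: ", tid(o + l)),
                 paste0("name: leaf term ", o + l),
                 paste0("namespace: ", namespaces[ns_i]), plines, "")
        leaf_ids <- c(leaf_ids, tid(o + l))
      }
    }
    obo <- c(obo, "[Term]", paste0("id: ", tid(31L)),
             "name: withdrawn term", "namespace: biological_process",
             "is_obsolete: true", "")
    write_lines_utf8(obo, p("go.obo"))
    write_lines_utf8(slim_ids, p("go_slim.txt"))

    # --- SEED-style 4-level hierarchy --------------------------------
    l1 <- c("Metabolism", "Information_Processing", "Cellular_Processes")
    seed_tab <- do.call(rbind, lapply(1:12, function(i) {
      a <- l1[(i - 1L) %% 3L + 1L]
      data.frame(level1 = a,
                 level2 = paste0(a, "_sub", (i - 1L) %/% 6L + 1L),
                 level3 = paste0("Pathway_", (i - 1L) %/% 2L + 1L),
                 level4 = paste0("Role_", i),
                 function_id = sprintf("F%03d", i),
                 stringsAsFactors = FALSE)
    }))
    class(seed_tab) <- c("seed_hierarchy", "data.frame")
    write_seed_table(seed_tab, p("seed_hierarchy.tsv"))

    # --- annotated proteins and contigs with planted genes ------------
    n_prot <- 15L
    prot_len <- sample(100:150, n_prot, replace = TRUE)
    prot_seq <- vapply(prot_len, function(l) {
      paste0("M", paste(sample(names(CODON_OF), l - 1L, replace = TRUE),
                        collapse = ""))
    }, character(1))
    prots <- seq_records(sprintf("prot%02d", 1:n_prot), prot_seq)
    write_fasta(prots, p("proteins.fasta"))
    ann <- vapply(seq_len(n_prot), function(i) {
      gos <- sort(sample(leaf_ids, sample(1:3, 1L)))
      paste(prots$id[i], paste(gos, collapse = "|"),
            sprintf("F%03d", (i - 1L) %% 12L + 1L), sep = "\t")
    }, character(1))
    write_lines_utf8(c("ref_id\tgo_terms\tseed_function_id", ann),
                     p("protein_annotations.tsv"))

    rev_translate <- function(prot) {
      paste0(paste(CODON_OF[strsplit(prot, "", fixed = TRUE)[[1L]]],
                   collapse = ""), "TAA")
    }
    contig_len <- 2600L
    contigs <- character(6L)
    gene_truth <- list()
    for (ci in 1:5) {
      cseq <- random_dna(contig_len)
      for (slot in 1:2) {
        pi <- (ci - 1L) * 2L + slot
        gene <- rev_translate(prot_seq[pi])
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") gene else revcomp(gene)
        start <- (slot - 1L) * 1300L +
          sample.int(1300L - nchar(ins) - 10L, 1L)
        substr(cseq, start + 1L, start + nchar(ins)) <- ins
        gene_truth[[length(gene_truth) + 1L]] <- data.frame(
          contig_id = sprintf("contig%d", ci), start = start,
          end = start + nchar(ins), strand = strand,
          protein_id = prots$id[pi], stringsAsFactors = FALSE)
      }
      contigs[ci] <- cseq
    }
    contigs[6L] <- random_dna(contig_len)
    write_fasta(seq_records(sprintf("contig%d", 1:6), contigs),
                p("contigs.fasta"))
    gt <- do.call(rbind, gene_truth)
    write_lines_utf8(
      c("contig_id\tstart\tend\tstrand\tprotein_id",
        paste(gt$contig_id, gt$start, gt$end, gt$strand, gt$protein_id,
              sep = "\t")),
      p("gene_truth.tsv"))
  })

  out <- list(
    dir = dir, seed = seed,
    genomes = p("genomes.fasta"),
    genome_lineage = p("genome_lineage.tsv"),
    rrna_truth = p("rrna_truth.tsv"),
    db_general = p("db_general.fasta"),
    db_general_lineage = p("db_general_lineage.tsv"),
    db_habitat = p("db_habitat.fasta"),
    db_habitat_lineage = p("db_habitat_lineage.tsv"),
    rrna_alignment = p("rrna_alignment.fasta"),
    obo = p("go.obo"),
    slim = p("go_slim.txt"),
    seed_table = p("seed_hierarchy.tsv"),
    proteins = p("proteins.fasta"),
    protein_annotations = p("protein_annotations.tsv"),
    contigs = p("contigs.fasta"),
    gene_truth = p("gene_truth.tsv"),
    params = list(n_genomes = n_genomes, genome_len = genome_len,
                  rrna_len = rrna_len, genome_divergence = 0.05,
                  general_db_divergence = 0.03))
  class(out) <- "fixture_bundle"
  invisible(out)
}
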