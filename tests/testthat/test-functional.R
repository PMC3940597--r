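# gene prediction, annotation transfer, GOSlim and SEED rollups

test_that("a constructed ORF is called exactly once with the stop codon
           included", {
  set.seed(71)
  sense <- paste(sample(c("GCT", "GAA", "CTT", "ACT"), 100L,
                        replace = TRUE), collapse = "")
  contig <- paste0("CC", "ATG", sense, "TAA", "GG")
  genes <- predict_genes(seq_records("c1", contig), min_len_nt = 300L)
  plus <- genes[genes$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(nchar(plus$seq), 306L)
  expect_equal(plus$start, 2L)
  expect_equal(plus$end, 308L)
  expect_equal(substr(plus$seq, 1L, 3L), "ATG")
  expect_equal(substr(plus$protein, 1L, 1L), "M")
  expect_equal(nchar(plus$protein), 101L)
})

test_that("gene calls commute with reverse complement (strands flip)", {
  b <- fixture_bundle()
  contigs <- read_fasta(b$contigs)
  fwd <- predict_genes(contigs)
  rc <- seq_records(contigs$id, revcomp(contigs$seq))
  bwd <- predict_genes(rc)
  L <- setNames(nchar(contigs$seq), contigs$id)
  key <- function(g, flip) {
    s <- if (flip) L[g$contig_id] - g$end else g$start
    e <- if (flip) L[g$contig_id] - g$start else g$end
    st <- if (flip) ifelse(g$strand == "+", "-", "+") else g$strand
    sort(paste(g$contig_id, s, e, st, g$seq))
  }
  expect_identical(key(bwd, TRUE), key(fwd, FALSE))
})

test_that("the ORF set matches a brute-force 6-frame scan on random
           contigs", {
  set.seed(72)
  for (i in 1:50) {
    contig <- random_dna_str(1000L)
    got <- predict_genes(seq_records("c", contig), min_len_nt = 60L)
    want <- orf_oracle(contig, 60L)
    got <- got[order(got$start, got$end, got$strand),
               c("start", "end", "strand")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("contig", i))
  }
})

test_that("planted genes are recovered and inherit their protein's
           annotations", {
  fr <- functional_run()
  gt <- read.delim(fixture_bundle()$gene_truth, stringsAsFactors = FALSE)
  # every planted gene interval is covered by a call on the same strand
  for (i in seq_len(nrow(gt))) {
    g <- fr$genes[fr$genes$contig_id == gt$contig_id[i] &
                    fr$genes$strand == gt$strand[i] &
                    fr$genes$start <= gt$start[i] &
                    fr$genes$end >= gt$end[i], ]
    expect_gte(nrow(g), 1L)
  }
  # identification transfers the right annotation at high identity
  expect_gte(nrow(fr$idents), nrow(gt))
  merged <- merge(fr$idents, fr$genes, by = "gene_id")
  for (i in seq_len(nrow(gt))) {
    hit <- merged[merged$contig_id == gt$contig_id[i] &
                    merged$start <= gt$start[i] &
                    merged$end >= gt$end[i], ]
    expect_true(gt$protein_id[i] %in% hit$ref_id)
  }
})

test_that("a gene with no reference similarity stays unannotated", {
  fr <- functional_run()
  fake <- data.frame(gene_id = "g0", protein = strrep("W", 120L),
                     stringsAsFactors = FALSE)
  out <- identify_genes(fake, fr$refs, fr$ann)
  expect_equal(nrow(out), 0L)
})

test_that("GOSlim rollup counts each slim ancestor once per gene", {
  onto <- functional_run()$ontology
  slim <- functional_run()$slim
  # pick a slim term with at least two distinct leaf descendants
  kids_of <- function(s) onto$edges$child[onto$edges$parent == s]
  slim2 <- slim[vapply(slim, function(s) length(kids_of(s)) >= 2L,
                       logical(1))][1L]
  kids <- kids_of(slim2)[1:2]
  ann <- data.frame(gene_id = c("g1", "g2"),
                    go_terms = c(paste(kids, collapse = "|"), slim2),
                    stringsAsFactors = FALSE)
  prof <- rollup_goslim(ann, onto, slim, top_n = 20L)
  expect_equal(prof$table$count[prof$table$term == slim2], 2L)

  # duplicated GO lists do not change a gene's contribution
  ann_dup <- ann
  ann_dup$go_terms <- paste(ann$go_terms, ann$go_terms, sep = "|")
  prof_dup <- rollup_goslim(ann_dup, onto, slim, top_n = 20L)
  expect_equal(prof_dup$table, prof$table)

  expect_error(rollup_goslim(ann, onto, c(slim, "GO:9999999")),
               "GO:9999999")
})

test_that("GOSlim rollup equals brute-force transitive closure on a
           random DAG with 50 genes", {
  set.seed(73)
  f <- withr::local_tempfile(fileext = ".obo")
  lines <- c("format-version: 1.2", "")
  for (i in 1:30) {
    parents <- if (i > 1L) sample(seq_len(i - 1L),
                                  min(i - 1L, sample(0:2, 1L)))
    rel <- if (length(parents)) sample(c("is_a", "part_of"),
                                       length(parents), replace = TRUE)
    plines <- if (length(parents)) ifelse(
      rel == "is_a", sprintf("is_a: N:%02d", parents),
      sprintf("relationship: part_of N:%02d", parents))
    lines <- c(lines, "[Term]", sprintf("id: N:%02d", i),
               sprintf("name: node %d", i), "namespace: test", plines, "")
  }
  writeLines(lines, f)
  onto <- read_obo(f)
  slim <- sprintf("N:%02d", sample(30L, 8L))
  R <- closure_oracle(onto)
  genes <- sprintf("g%02d", 1:50)
  gos <- lapply(genes, function(g)
    sprintf("N:%02d", sample(30L, sample(1:4, 1L))))
  ann <- data.frame(gene_id = genes,
                    go_terms = vapply(gos, paste, character(1),
                                      collapse = "|"),
                    stringsAsFactors = FALSE)
  prof <- rollup_goslim(ann, onto, slim, top_n = 30L)
  want <- setNames(integer(length(slim)), slim)
  for (gi in seq_along(genes)) {
    anc <- colnames(R)[colSums(R[gos[[gi]], , drop = FALSE]) > 0]
    hit <- intersect(anc, slim)
    want[hit] <- want[hit] + 1L
  }
  want <- want[want > 0L]
  got <- setNames(prof$table$count, prof$table$term)
  expect_equal(got[sort(names(got))], want[sort(names(want))])
})

test_that("SEED rollup assigns exactly 4 levels with conserved marginals", {
  fr <- functional_run()
  prof <- rollup_seed(fr$idents, fr$hierarchy)
  expect_true(all(lengths(strsplit(prof$table$path, ";",
                                   fixed = TRUE)) == 4L))
  totals <- vapply(1:4, function(k) sum(seed_marginal(prof, k)),
                   integer(1))
  expect_equal(unname(totals), rep(prof$total_genes, 4L))

  # level-k marginals equal a direct group-by of the gene table
  paths <- seed_path_of(fr$hierarchy, fr$idents$seed_function_id)
  for (k in 1:4) {
    key <- apply(paths[, seq_len(k), drop = FALSE], 1L, paste,
                 collapse = ";")
    want <- table(key)
    got <- seed_marginal(prof, k)
    expect_equal(got[sort(names(got))],
                 setNames(as.integer(want), names(want))[sort(names(want))])
  }

  one <- rollup_seed(data.frame(gene_id = "g", seed_function_id = "F001"),
                     fr$hierarchy)
  expect_equal(one$table$count, 1L)
  expect_equal(sum(seed_marginal(one, 1L)), 1L)
  expect_error(
    rollup_seed(data.frame(gene_id = "g", seed_function_id = "FX"),
                fr$hierarchy), "FX")
})
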