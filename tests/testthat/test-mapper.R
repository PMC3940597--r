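# k-mer index and best-hit mapping vs exhaustive alignment oracles

test_that("index position counts and lookups match a brute-force scan", {
  refs <- seq_records("r1", "ACGTACGTAC")
  idx <- build_kmer_index(refs, k = 8L)
  expect_equal(idx$n_positions, 3L)

  expect_equal(build_kmer_index(refs[0L, ], k = 8L)$n_positions, 0L)
  expect_warning(build_kmer_index(seq_records("tiny", "ACGT"), k = 8L),
                 "tiny")

  set.seed(41)
  refs <- seq_records(sprintf("ref%d", 1:5),
                      replicate(5L, random_dna_str(60L)))
  idx <- build_kmer_index(refs, k = 8L)
  expect_equal(idx$n_positions, sum(nchar(refs$seq) - 8L + 1L))
  # every k-mer of every ref resolves to exactly the brute-force positions
  for (i in 1:5) {
    for (p in seq_len(nchar(refs$seq[i]) - 7L)) {
      km <- substr(refs$seq[i], p, p + 7L)
      got <- kmer_lookup(idx, km)
      want <- do.call(rbind, lapply(1:5, function(j) {
        hits <- gregexpr(km, refs$seq[j], fixed = TRUE)[[1L]]
        # gregexpr misses overlapping occurrences; scan manually
        starts <- which(vapply(seq_len(nchar(refs$seq[j]) - 7L),
                               function(s) substr(refs$seq[j], s, s + 7L) == km,
                               logical(1)))
        if (!length(starts)) return(NULL)
        data.frame(ref_id = refs$id[j], pos = starts - 1L,
                   stringsAsFactors = FALSE)
      }))
      got <- got[order(got$ref_id, got$pos), , drop = FALSE]
      want <- want[order(want$ref_id, want$pos), , drop = FALSE]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("an exact substring maps at identity 100 with correct intervals", {
  set.seed(42)
  refs <- seq_records(c("alpha", "beta"),
                      c(random_dna_str(200L), random_dna_str(200L)))
  idx <- build_kmer_index(refs, k = 8L)
  q <- substr(refs$seq[2L], 41L, 100L)
  hit <- map_query("q1", q, idx)
  expect_equal(hit$ref_id, "beta")
  expect_equal(hit$identity, 100)
  expect_equal(hit$aln_len, 60L)
  expect_equal(c(hit$rstart, hit$rend), c(40L, 100L))
  expect_equal(hit$strand, "+")
  # reverse-complement query: same score and identity, strand flagged
  hit_rc <- map_query("q1rc", revcomp(q), idx)
  expect_equal(hit_rc$score, hit$score)
  expect_equal(hit_rc$identity, hit$identity)
  expect_equal(hit_rc$strand, "-")
})

test_that("best hit equals exhaustive Smith-Waterman over all references", {
  set.seed(43)
  for (case in 1:12) {
    n_refs <- sample(2:5, 1L)
    refs <- seq_records(sprintf("ref%02d", seq_len(n_refs)),
                        replicate(n_refs, random_dna_str(sample(40:60, 1L))))
    idx <- build_kmer_index(refs, k = 8L)
    # query: mutated substring of a random ref (seeds guaranteed present)
    src <- sample.int(n_refs, 1L)
    from <- sample.int(nchar(refs$seq[src]) - 30L, 1L)
    q <- substr(refs$seq[src], from, from + sample(25:30, 1L))
    nmut <- sample(0:2, 1L)
    if (nmut) {
      ch <- strsplit(q, "", fixed = TRUE)[[1L]]
      at <- sample(seq(10L, length(ch) - 9L), nmut)
      for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                            ch[p]), 1L)
      q <- paste(ch, collapse = "")
    }
    if (sample(c(TRUE, FALSE), 1L)) q <- revcomp(q)
    hit <- map_query("q", q, idx, min_identity = 0)
    oracle <- sw_oracle_best_ref(q, refs)
    expect_equal(hit$score, oracle$score, info = paste("case", case))
    expect_equal(hit$ref_id, oracle$ref_id, info = paste("case", case))
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  set.seed(44)
  for (i in 1:5) {
    a <- random_dna_str(50L)
    b <- random_dna_str(70L)
    mine <- sw_oracle_score(a, b)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 2, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(mine, ref)
  }
})

test_that("equal-score hits resolve to the lexicographically smallest ref", {
  set.seed(45)
  s <- random_dna_str(80L)
  refs <- seq_records(c("zeta", "alpha"), c(s, s))
  idx <- build_kmer_index(refs, k = 8L)
  hit <- map_query("q", substr(s, 11L, 60L), idx)
  expect_equal(hit$ref_id, "alpha")
})

test_that("mapping results are invariant to worker count and query order", {
  set.seed(46)
  b <- fixture_bundle()
  refs <- read_fasta(b$db_habitat)
  idx <- build_kmer_index(refs, k = 8L)
  starts <- sample(200L, 60L)
  queries <- seq_records(
    sprintf("q%03d", 1:60),
    substring(refs$seq[rep(1:8, length.out = 60L)], starts,
              starts + 79L))
  h1 <- map_all(queries, idx, n_workers = 1L)
  h8 <- map_all(queries, idx, n_workers = 8L)
  expect_identical(h1, h8)
  expect_equal(nrow(map_all(queries[0L, ], idx)), 0L)

  perm <- sample(nrow(queries))
  hp <- map_all(queries[perm, ], idx)
  ord <- function(d) {
    d <- d[order(d$query_id), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  expect_identical(ord(hp), ord(h1))
})

test_that("error-free fragments recover their true source reference", {
  set.seed(47)
  b <- fixture_bundle()
  refs <- read_fasta(b$db_habitat)
  idx <- build_kmer_index(refs, k = 8L)
  n <- 200L
  src <- sample.int(nrow(refs), n, replace = TRUE)
  len <- sample(60:100, n, replace = TRUE)
  from <- vapply(len, function(l) sample.int(300L - l, 1L), integer(1))
  queries <- seq_records(sprintf("f%03d", 1:n),
                         substring(refs$seq[src], from, from + len))
  hits <- map_all(queries, idx)
  expect_equal(nrow(hits), n)
  correct <- hits$ref_id == refs$id[src][match(hits$query_id, queries$id)]
  expect_gte(mean(correct), 0.99)
})
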