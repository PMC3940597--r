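# profile HMM: construction, Viterbi scoring vs exhaustive enumeration,
# fragment extraction on the fixture bundle

test_that("a degenerate ungapped alignment yields one match state per
           column with the column's base as mode", {
  aln <- toy_alignment(rep("ACGTACGTAC", 3L))
  hmm <- build_profile_hmm(aln)
  expect_equal(hmm$L, 10L)
  expect_equal(hmm$consensus, "ACGTACGTAC")
  # every transition row is a distribution
  for (m in list(hmm$trM, hmm$trI, hmm$trD)) {
    expect_equal(rowSums(m), rep(1, hmm$L + 1L), tolerance = 1e-9)
  }
  # emissions exponentiate to distributions
  expect_equal(rowSums(hmm$match_probs), rep(1, hmm$L), tolerance = 1e-9)
  expect_equal(rowSums(hmm$insert_probs), rep(1, hmm$L + 1L),
               tolerance = 1e-9)
})

test_that("emission estimates equal hand-computed Laplace counts on a
           two-column alignment", {
  aln <- toy_alignment(c("AC", "AG", "AG"))
  hmm <- build_profile_hmm(aln)
  # column 1: 3 x A -> (3+1)/(3+4); column 2: C,G,G
  expect_equal(unname(hmm$match_probs[1L, ]),
               c(4, 1, 1, 1) / 7, tolerance = 1e-12)
  expect_equal(unname(hmm$match_probs[2L, ]),
               c(1, 2, 3, 1) / 7, tolerance = 1e-12)
  expect_error(build_profile_hmm(toy_alignment(character(0))),
               "model error")
  expect_error(build_profile_hmm(toy_alignment(c("--", "--"))),
               "model error")
})

test_that("Viterbi equals exhaustive path enumeration on an L<=4 grid", {
  set.seed(21)
  for (L in 2:4) {
    for (rep in 1:3) {
      seqs <- replicate(4L, random_dna_str(L))
      # one aligned gap exercises delete-state transitions without
      # changing the match-column count
      substr(seqs[1L], 1L, 1L) <- "-"
      hmm <- build_profile_hmm(toy_alignment(seqs), match_frac = 0.9)
      expect_equal(hmm$L, L)
      for (n in c(1L, 3L, 6L)) {
        s <- random_dna_str(n)
        expect_equal(viterbi_score(hmm, s)$score,
                     enum_viterbi_score(hmm, s), tolerance = 1e-9,
                     info = paste("L", hmm$L, "seq", s))
      }
      # N-containing and consensus sequences too
      expect_equal(viterbi_score(hmm, "ANGT")$score,
                   enum_viterbi_score(hmm, "ANGT"), tolerance = 1e-9)
      expect_equal(viterbi_score(hmm, hmm$consensus)$score,
                   enum_viterbi_score(hmm, hmm$consensus),
                   tolerance = 1e-9)
    }
  }
})

test_that("the consensus outscores every single-mismatch variant and all-N
           scores at most 0 bits", {
  hmm <- build_profile_hmm(toy_alignment(rep("ACGTACGT", 4L)))
  cons <- hmm$consensus
  best <- viterbi_score(hmm, cons)$score
  for (i in seq_len(nchar(cons))) {
    for (b in setdiff(c("A", "C", "G", "T"),
                      substr(cons, i, i))) {
      var <- cons
      substr(var, i, i) <- b
      expect_lte(viterbi_score(hmm, var)$score, best)
    }
  }
  expect_lte(viterbi_score(hmm, strrep("N", 8L))$score, 0)
  # empty sequence is a no-hit result, not an error
  expect_identical(viterbi_score(hmm, "")$score, -Inf)
})

test_that("model serialization round-trips scoring exactly", {
  hmm <- fixture_hmm()
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmm(hmm, f)
  hmm2 <- read_hmm(f)
  expect_equal(hmm2$L, hmm$L)
  s <- substr(fixture_genomes()$seq[1L], 1L, 120L)
  expect_identical(viterbi_score(hmm, s)$score,
                   viterbi_score(hmm2, s)$score)
})

test_that("planted rRNA reads are extracted and re-oriented; random reads
           are not called", {
  hmm <- fixture_hmm()
  genomes <- fixture_genomes()
  rt <- fixture_rrna_truth()
  # a read wholly inside a planted region is recovered covering >=90%
  g <- match(rt$genome_id[1L], genomes$id)
  read <- substr(genomes$seq[g], rt$start[1L] + 51L, rt$start[1L] + 150L)
  hit <- extract_fragments(seq_records("q1", read), hmm)
  expect_equal(nrow(hit), 1L)
  expect_gte(hit$end - hit$start, 90L)
  expect_equal(hit$strand, "+")

  # its reverse complement gives the same fragment, flipped strand and
  # mirrored coordinates
  hit_rc <- extract_fragments(seq_records("q1rc", revcomp(read)), hmm)
  expect_equal(hit_rc$strand, "-")
  expect_identical(hit_rc$fragment, hit$fragment)
  expect_equal(hit_rc$start, 100L - hit$end)
  expect_equal(hit_rc$end, 100L - hit$start)

  set.seed(31)
  rand <- seq_records(sprintf("n%03d", 1:50),
                      replicate(50L, random_dna_str(100L)))
  expect_equal(nrow(extract_fragments(rand, hmm)), 0L)
})

test_that("recall on planted regions is >= 95% and the false-positive rate
           on planted-free windows is <= 1%", {
  hmm <- fixture_hmm()
  genomes <- fixture_genomes()
  rt <- fixture_rrna_truth()
  pos <- list()
  neg <- list()
  for (i in seq_len(nrow(rt))) {
    g <- genomes$seq[match(rt$genome_id[i], genomes$id)]
    starts <- seq(rt$start[i], rt$end[i] - 100L, by = 7L)
    pos[[i]] <- substring(g, starts + 1L, starts + 100L)
    # windows clear of the planted region
    nstart <- if (rt$start[i] > 1500L) seq(0L, rt$start[i] - 200L,
                                           by = 301L)
              else seq(rt$end[i] + 50L, nchar(g) - 150L, by = 301L)
    neg[[i]] <- substring(g, nstart + 1L, nstart + 100L)
  }
  pos <- unlist(pos)
  neg <- unlist(neg)
  hits_pos <- extract_fragments(
    seq_records(sprintf("p%04d", seq_along(pos)), pos), hmm)
  hits_neg <- extract_fragments(
    seq_records(sprintf("n%04d", seq_along(neg)), neg), hmm)
  expect_gte(nrow(hits_pos) / length(pos), 0.95)
  expect_lte(nrow(hits_neg) / length(neg), 0.01)
})

test_that("fragment extraction is strand-symmetric over a read set", {
  hmm <- fixture_hmm()
  e <- e2e_run(2000L)
  reads <- e$sim$reads[1:300, ]
  fwd <- extract_fragments(reads, hmm)
  rc <- seq_records(reads$id, revcomp(reads$seq))
  bwd <- extract_fragments(rc, hmm)
  expect_identical(sort(fwd$fragment), sort(bwd$fragment))
})
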