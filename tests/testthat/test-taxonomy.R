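# lineage assignment, per-rank aggregation, database integration

mk_hit <- function(ref_id, identity) {
  data.frame(query_id = "q", ref_id = ref_id, identity = identity,
             stringsAsFactors = FALSE)
}

fixture_lineages <- function() {
  read_lineage_table(fixture_bundle()$db_habitat_lineage)
}

test_that("lineages truncate at the identity thresholds", {
  lin <- fixture_lineages()
  full <- assign_lineage(mk_hit("hab01", 100), lin)
  expect_equal(unname(full[["species"]]), "Species_1")
  # identity 92 passes family (90) but not genus (95)
  l92 <- assign_lineage(mk_hit("hab01", 92), lin)
  expect_equal(unname(l92[["family"]]), "Family_1")
  expect_equal(unname(l92[["genus"]]), "Unclassified")
  expect_equal(unname(l92[["species"]]), "Unclassified")
  # below the phylum threshold only the domain survives
  l50 <- assign_lineage(mk_hit("hab01", 50), lin)
  expect_equal(unname(l50[["domain"]]), "Bacteria")
  expect_true(all(l50[-1L] == "Unclassified"))
  expect_error(assign_lineage(mk_hit("missing", 99), lin), "missing")
})

test_that("a single-species sample has abundance 1 along its whole path", {
  lin <- fixture_lineages()
  hits <- do.call(rbind, replicate(10L, mk_hit("hab03", 100),
                                   simplify = FALSE))
  prof <- build_taxonomic_profile(assign_lineages(hits, lin), "db")
  expect_equal(prof$total, 10L)
  for (r in c("domain", "phylum", "class", "order", "family", "genus",
              "species")) {
    expect_equal(nrow(prof$ranks[[r]]), 1L)
    expect_equal(prof$ranks[[r]]$rel, 1)
    expect_equal(prof$ranks[[r]]$count, 10L)
  }
  expect_equal(unname(prof$unclassified), rep(0L, 7L))
})

test_that("profiles conserve mass at every rank and child paths extend
           parents", {
  set.seed(51)
  lin <- fixture_lineages()
  hits <- data.frame(query_id = sprintf("q%03d", 1:400),
                     ref_id = sample(lin$ref_id, 400L, replace = TRUE),
                     identity = runif(400L, 70, 100),
                     stringsAsFactors = FALSE)
  prof <- build_taxonomic_profile(assign_lineages(hits, lin), "db")
  for (r in seq_along(prof$ranks)) {
    df <- prof$ranks[[r]]
    expect_equal(sum(df$count), prof$total)
    expect_equal(sum(df$rel), 1, tolerance = 1e-9)
    if (r > 1L) {
      parent <- prof$ranks[[r - 1L]]
      # each child path's prefix is a parent path, and parent counts are
      # the sums of their children
      pref <- vapply(strsplit(df$path, ";", fixed = TRUE), function(x)
        paste(x[-length(x)], collapse = ";"), character(1))
      expect_true(all(pref %in% parent$path))
      agg <- tapply(df$count, pref, sum)
      expect_equal(as.integer(agg[parent$path]), parent$count)
    }
  }
  # named + unclassified = total at every rank
  for (r in seq_len(7L)) {
    df <- prof$ranks[[r]]
    named <- sum(df$count) - prof$unclassified[[r]]
    expect_equal(named + prof$unclassified[[r]], prof$total)
  }
})

test_that("species-level recovery matches simulator truth on an
           error-free sample", {
  b <- fixture_bundle()
  genomes <- fixture_genomes()
  ab <- c(0.35, 0.25, 0.1, 0.1, 0.08, 0.06, 0.04, 0.02)
  spec <- community_spec(genomes, ab, n_reads = 4000L, err_rate = 0,
                         seed = 19L)
  sim <- simulate_reads(spec)
  frags <- extract_fragments(sim$reads, fixture_hmm())
  idx <- build_kmer_index(read_fasta(b$db_habitat), k = 8L)
  hits <- map_all(seq_records(frags$read_id, frags$fragment), idx)
  lin <- fixture_lineages()
  prof <- build_taxonomic_profile(assign_lineages(hits, lin), "habitat")
  pred <- abundance_vector(prof, "species")
  truth <- truth_abundances(sim$truth)
  names(truth) <- sprintf("Species_%d",
                          as.integer(sub("genome0?", "", names(truth))))
  # recovered species abundances within multinomial sampling error of the
  # per-read truth (the rRNA-bearing subsample is ~100x smaller)
  n_assigned <- prof$total
  for (sp in names(truth)) {
    p <- truth[[sp]]
    tol <- 4 * sqrt(p * (1 - p) / n_assigned) + 0.01
    got <- if (sp %in% names(pred)) pred[[sp]] else 0
    expect_lt(abs(got - p), tol)
  }
})

test_that("integration averages relative abundances and is idempotent", {
  lin <- fixture_lineages()
  h1 <- do.call(rbind, replicate(6L, mk_hit("hab01", 100),
                                 simplify = FALSE))
  h2 <- do.call(rbind, replicate(4L, mk_hit("hab05", 100),
                                 simplify = FALSE))
  p1 <- build_taxonomic_profile(assign_lineages(h1, lin), "db1")
  p2 <- build_taxonomic_profile(assign_lineages(h2, lin), "db2")

  # single profile: identity on relative abundances
  i1 <- integrate_profiles(list(p1))
  expect_equal(i1$ranks$species$rel, p1$ranks$species$rel)
  expect_equal(i1$ranks$species$path, p1$ranks$species$path)
  expect_equal(i1$database, "integrated")

  # two disjoint single-taxon profiles split the mass evenly
  i2 <- integrate_profiles(list(p1, p2))
  expect_equal(sort(i2$ranks$species$rel), c(0.5, 0.5))
  expect_equal(sum(i2$ranks$genus$rel), 1, tolerance = 1e-9)

  # K copies of one profile integrate to that profile
  i3 <- integrate_profiles(list(p1, p1, p1, p1))
  expect_equal(i3$ranks$species$rel, p1$ranks$species$rel)
  expect_error(integrate_profiles(list()), "parameter error")
})
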