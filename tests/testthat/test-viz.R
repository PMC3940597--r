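# wedge layouts, HTML/SVG exports: conservation and determinism

ranks7 <- c("domain", "phylum", "class", "order", "family", "genus",
            "species")

single_species_profile <- function(n = 10L) {
  asg <- matrix(rep(c("Bacteria", "P", "C", "O", "F", "G", "S"),
                    each = n), nrow = n)
  colnames(asg) <- ranks7
  build_taxonomic_profile(asg, "db")
}

test_that("a single-species profile is one full wedge per ring", {
  lay <- layout_sample_view(single_species_profile())
  expect_equal(nrow(lay), 7L)
  expect_equal(lay$sweep, rep(360, 7L))
  expect_equal(lay$depth, 1:7)
})

test_that("two equal species split into 180-degree wedges", {
  asg <- rbind(
    matrix(rep(c("Bacteria", "P", "C", "O", "F", "G", "S1"), each = 5L),
           nrow = 5L),
    matrix(rep(c("Bacteria", "P", "C", "O", "F", "G", "S2"), each = 5L),
           nrow = 5L))
  colnames(asg) <- ranks7
  lay <- layout_sample_view(build_taxonomic_profile(asg, "db"))
  leaves <- lay[lay$depth == 7L, ]
  expect_equal(nrow(leaves), 2L)
  expect_equal(leaves$sweep, c(180, 180))
  expect_equal(sort(leaves$start), c(0, 180))
})

test_that("sibling sweeps sum to the parent sweep on random profiles", {
  set.seed(81)
  for (i in 1:50) {
    n <- sample(5:40, 1L)
    asg <- t(replicate(n, {
      p <- sample(2L, 1L)
      g <- sample(4L, 1L)
      c("Bacteria", paste0("P", p), paste0("C", g), paste0("O", g),
        paste0("F", g), paste0("G", g), paste0("S", sample(8L, 1L)))
    }))
    colnames(asg) <- ranks7
    lay <- layout_sample_view(build_taxonomic_profile(asg, "db"))
    # ring 1 sums to the full circle
    expect_equal(sum(lay$sweep[lay$depth == 1L]), 360, tolerance = 1e-6)
    for (d in 2:7) {
      kids <- lay[lay$depth == d, ]
      par <- lay[lay$depth == d - 1L, ]
      for (pi in seq_len(nrow(par))) {
        mine <- kids[startsWith(kids$path, paste0(par$path[pi], ";")), ]
        expect_equal(sum(mine$sweep), par$sweep[pi], tolerance = 1e-6)
      }
    }
  }
})

test_that("an empty profile renders a single gray placeholder wedge", {
  asg <- matrix(character(0), ncol = 7L,
                dimnames = list(NULL, ranks7))
  lay <- layout_sample_view(build_taxonomic_profile(asg, "db"))
  expect_equal(nrow(lay), 1L)
  expect_equal(lay$sweep, 360)
  expect_equal(lay$color, "#999999")
  expect_equal(lay$label, "no data")
})

test_that("unclassified wedges are gray and colors are deterministic", {
  asg <- rbind(c("Bacteria", "P", "Unclassified", "Unclassified",
                 "Unclassified", "Unclassified", "Unclassified"))
  asg <- asg[rep(1L, 3L), ]
  colnames(asg) <- ranks7
  lay <- layout_sample_view(build_taxonomic_profile(asg, "db"))
  expect_true(all(lay$color[lay$label == "Unclassified"] == "#999999"))
  lay2 <- layout_sample_view(build_taxonomic_profile(asg, "db"))
  expect_identical(lay, lay2)
})

test_that("HTML export is well-formed, one group per sample, and
           byte-deterministic", {
  lays <- list(s_one = layout_sample_view(single_species_profile()),
               s_two = layout_sample_view(single_species_profile(4L)))
  f1 <- withr::local_tempfile(fileext = ".html")
  f2 <- withr::local_tempfile(fileext = ".html")
  export_html(lays, list(title = "fixture <sample> view"), f1)
  export_html(lays, list(title = "fixture <sample> view"), f2)
  expect_identical(readLines(f1), readLines(f2))
  html <- paste(readLines(f1), collapse = "\n")
  svg <- regmatches(html, regexpr("<svg.*</svg>", html))
  doc <- xml2::read_xml(svg)
  groups <- xml2::xml_find_all(doc, "//*[local-name()='g']")
  ids <- xml2::xml_attr(groups, "id")
  expect_equal(sum(ids %in% c("s1", "s2")), 2L)
})

test_that("the global view draws one node per distinct lineage prefix
           with zero-length bars for absent samples", {
  lin <- read_lineage_table(fixture_bundle()$db_habitat_lineage)
  mk <- function(refs, label) {
    hits <- data.frame(query_id = seq_along(refs), ref_id = refs,
                       identity = 100, stringsAsFactors = FALSE)
    build_taxonomic_profile(assign_lineages(hits, lin), label)
  }
  p1 <- mk(c("hab01", "hab02"), "s1")
  p2 <- mk(c("hab05"), "s2")
  comp <- compare_profiles(list(p1, p2), "genus")
  f <- withr::local_tempfile(fileext = ".svg")
  export_global_view(comp, f)
  doc <- xml2::read_xml(paste(readLines(f), collapse = "\n"))
  circles <- xml2::xml_find_all(doc, "//*[local-name()='circle']")
  paths <- rownames(comp$abundances)
  prefixes <- unique(unlist(lapply(strsplit(paths, ";", fixed = TRUE),
                                   function(pp) vapply(seq_along(pp),
                                     function(d) paste(pp[seq_len(d)],
                                                       collapse = ";"),
                                     character(1)))))
  expect_equal(length(circles), length(prefixes))
  rects <- xml2::xml_find_all(doc, "//*[local-name()='rect']")
  widths <- as.numeric(xml2::xml_attr(rects, "width"))
  # s2 has no mass under s1-only clades: those bars have zero width
  expect_true(any(widths == 0))
  expect_true(all(widths >= 0))
})
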