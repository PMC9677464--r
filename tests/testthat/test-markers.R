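test_that("marker set serialization parses bracketed lists", {
  expect_equal(parse_marker_sets("[[m1,m2],[m3]]"),
               list(c("m1", "m2"), "m3"))
  expect_equal(parse_marker_sets("[[a]]"), list("a"))
  expect_error(parse_marker_sets("m1,m2"), "malformed")
})

test_that("hierarchy loading builds the graph and honors exclusions", {
  h <- load_marker_hierarchy(write_hierarchy(list(
    c("domain", "dA", "root", "[[a,b],[c]]"),
    c("phylum", "pA", "dA", "[[p1]]"),
    c("class", "cA", "pA", "[[q1,q2]]"))))
  expect_s3_class(h, "marker_hierarchy")
  expect_equal(h$domains, "dA")
  expect_length(h$nodes[["dA"]]$sets, 2)

  # excluding a taxon drops its subtree
  h2 <- load_marker_hierarchy(write_hierarchy(list(
    c("domain", "dA", "root", "[[a,b]]"),
    c("phylum", "pA", "dA", "[[p1]]"),
    c("class", "cA", "pA", "[[q1]]"))), excluded_taxa = "pA")
  expect_false("pA" %in% names(h2$nodes))
  expect_false("cA" %in% names(h2$nodes))

  # orphans and empty tables are integrity errors
  expect_error(load_marker_hierarchy(write_hierarchy(list(
    c("phylum", "pX", "dMissing", "[[p1]]")))), "orphan|pX")
  empty <- tempfile(); writeLines("#rank\ttaxon\tparent_taxon\tmarker_sets", empty)
  expect_error(load_marker_hierarchy(empty), "empty")
})

test_that("marker counting aggregates multiplicities additively", {
  tab <- data.frame(contig_id = c("c1", "c1", "c1", "c2", "c3"),
                    orf_id = paste0("o", 1:5),
                    marker_accession = c("m1", "m1", "m2", "m3", "m1"))
  expect_equal(marker_counts("c1", tab), c(m1 = 2L, m2 = 1L))
  expect_length(marker_counts(character(0), tab), 0)
  u <- marker_counts(c("c1", "c2"), tab)
  a <- marker_counts("c1", tab); b <- marker_counts("c2", tab)
  all_m <- union(names(a), names(b))
  gets <- function(v, n) ifelse(is.na(v[n]), 0L, v[n])
  expect_equal(unname(u[all_m]), unname(gets(a, all_m) + gets(b, all_m)))
})

test_that("completeness and purity match hand-worked examples", {
  node <- list(sets = list(c("a", "b"), c("c", "d"), "e"))
  expect_equal(marker_completeness(c(a = 1L, c = 1L, d = 2L), node), 0.5)
  expect_equal(marker_completeness(c(a = 1L, b = 1L, c = 1L, d = 1L, e = 1L),
                                   node), 1.0)
  expect_equal(marker_completeness(setNames(integer(0), character(0)), node), 0)

  expect_equal(marker_purity(c(a = 2L, b = 1L), list(sets = list(c("a", "b")))),
               0.75)
  expect_equal(marker_purity(c(a = 1L, c = 1L), node), 1.0)
  # absent genes and empty sets excluded from the averages
  expect_equal(marker_purity(c(a = 3L), list(sets = list(c("a", "b"), "c"))),
               1 / 3)
  # markerless group is vacuously pure
  expect_equal(marker_purity(setNames(integer(0), character(0)), node), 1.0)
})

test_that("completeness and purity equal the brute-force oracle on 1000 fuzzed instances", {
  set.seed(7)
  for (i in 1:1000) {
    inst <- random_marker_instance()
    node <- list(sets = inst$sets)
    expect_equal(marker_completeness(inst$counts, node),
                 oracle_completeness(inst$counts, inst$sets),
                 tolerance = 1e-12)
    expect_equal(marker_purity(inst$counts, node),
                 oracle_purity(inst$counts, inst$sets),
                 tolerance = 1e-12)
    p <- marker_purity(inst$counts, node)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("completeness is monotone under adding contigs to a group", {
  set.seed(11)
  tab <- data.frame(
    contig_id = sample(paste0("c", 1:10), 60, replace = TRUE),
    orf_id = paste0("o", 1:60),
    marker_accession = sample(paste0("m", 1:25), 60, replace = TRUE))
  node <- list(sets = list(paste0("m", 1:8), paste0("m", 9:20)))
  for (r in 1:20) {
    g1 <- sample(paste0("c", 1:10), sample(1:5, 1))
    g2 <- union(g1, sample(paste0("c", 1:10), sample(1:5, 1)))
    expect_gte(marker_completeness(marker_counts(g2, tab), node),
               marker_completeness(marker_counts(g1, tab), node))
  }
})

test_that("assessment traverses the lineage with domain averaging and argmax selection", {
  # single-domain hierarchy: assessment equals the domain's own values
  h1 <- load_marker_hierarchy(write_hierarchy(list(
    c("domain", "dA", "root", "[[a,b],[c,d]]"))))
  q1 <- assess_quality(c(a = 1L, b = 2L), h1)
  expect_equal(q1$taxon, "dA")
  expect_equal(q1$completeness, marker_completeness(c(a = 1L, b = 2L),
                                                    h1$nodes$dA))

  # domain 0.8/1.0; class X raw 1.0/0.9 -> reported (0.9, 0.95), selected
  h2 <- load_marker_hierarchy(write_hierarchy(list(
    c("domain", "dA", "root", "[[a1,a2,a3,a4,a5]]"),
    c("class", "cX", "dA", "[[x1,x2]]"))))
  counts <- c(a1 = 1L, a2 = 1L, a3 = 1L, a4 = 1L,   # domain comp 0.8, pur 1
              x1 = 1L, x2 = 2L)                     # class comp 1.0, pur 0.75
  q2 <- assess_quality(counts, h2)
  expect_equal(q2$taxon, "cX")
  expect_equal(q2$completeness, (1.0 + 0.8) / 2)
  expect_equal(q2$purity, (0.75 + 1.0) / 2)

  # the more complete of two sibling classes wins
  h3 <- load_marker_hierarchy(write_hierarchy(list(
    c("domain", "dA", "root", "[[a1,a2]]"),
    c("class", "cHi", "dA", "[[h1,h2]]"),
    c("class", "cLo", "dA", "[[l1,l2]]"))))
  q3 <- assess_quality(c(a1 = 1L, a2 = 1L, h1 = 1L, h2 = 1L, l1 = 1L), h3)
  expect_equal(q3$taxon, "cHi")

  # empty counts give a domain-level estimate with completeness 0
  q4 <- assess_quality(setNames(integer(0), character(0)), h2)
  expect_equal(q4$rank, "domain")
  expect_equal(q4$completeness, 0)

  # max_rank bounds the traversal depth
  h5 <- two_level_hierarchy()
  cnt <- c(a1 = 1L, a2 = 1L, a3 = 1L, a4 = 1L, p1 = 1L, p2 = 1L,
           x1 = 1L, x2 = 1L, x3 = 1L)
  q5 <- assess_quality(cnt, h5, max_rank = "phylum")
  expect_true(q5$rank %in% c("domain", "phylum"))
  q6 <- assess_quality(cnt, h5, max_rank = "class")
  expect_equal(q6$rank, "class")
  expect_equal(q6$taxon, "cA")
})
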