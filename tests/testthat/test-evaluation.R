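test_that("bin scoring follows the majority-bp definitions", {
  gold <- data.frame(contig_id = c("a1", "a2", "b1"),
                     genome_id = c("gA", "gA", "gB"))
  lengths <- c(a1 = 900, a2 = 900, b1 = 100)
  sc <- score_bins(list(bin1 = c("a1", "b1")), gold, lengths)
  expect_equal(sc$reference, "gA")
  expect_equal(sc$bp_purity, 0.9)
  expect_equal(sc$bp_completeness, 900 / 1800)
  # a bin equal to a genome is perfect
  sc2 <- score_bins(list(bin1 = c("a1", "a2")), gold, lengths)
  expect_equal(sc2$bp_purity, 1)
  expect_equal(sc2$bp_completeness, 1)
  # 50/50 bp ties break to the lexicographically smaller genome
  gold3 <- data.frame(contig_id = c("x", "y"), genome_id = c("gB", "gA"))
  len3 <- c(x = 500, y = 500)
  expect_equal(score_bins(list(b = c("x", "y")), gold3, len3)$reference, "gA")
  # empty bins are skipped with a warning
  expect_warning(out <- score_bins(list(e = character(0)), gold, lengths),
                 "empty")
  expect_equal(nrow(out), 0)
})

test_that("overall metrics aggregate majority bp and ignore bin order", {
  gold <- data.frame(contig_id = c("a1", "a2", "b1", "b2"),
                     genome_id = c("gA", "gA", "gB", "gB"))
  lengths <- c(a1 = 600, a2 = 400, b1 = 500, b2 = 500)
  bins <- list(b1 = c("a1", "a2"), b2 = c("b1", "b2"))
  m <- overall_metrics(bins, gold, lengths)
  expect_equal(unname(m), c(1, 1))
  bins_mixed <- list(b1 = c("a1", "a2", "b1"))
  m2 <- overall_metrics(bins_mixed, gold, lengths)
  expect_equal(unname(m2["purity"]), 1000 / 1500)
  expect_equal(m2, overall_metrics(rev(bins_mixed), gold, lengths))
  expect_equal(unname(overall_metrics(list(), gold, lengths)["completeness"]),
               0)
})

test_that("ARI matches brute-force pair counting on fuzzed partitions", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1.0)
  # hand case: {a,b}{c,d} vs {a,c}{b,d}
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               oracle_ari(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI of random labelings is near zero and unbinned contigs are excluded", {
  set.seed(23)
  aris <- replicate(100, {
    g <- sample(1:10, 300, replace = TRUE)
    b <- sample(1:10, 300, replace = TRUE)
    adjusted_rand_index(b, g)
  })
  expect_lt(mean(abs(aris)), 0.05)
  # NA bin labels are dropped before comparison
  expect_equal(adjusted_rand_index(c(1, 1, NA, 2, 2), c(1, 1, 9, 2, 2)), 1.0)
  expect_equal(adjusted_rand_index(c(1, 1), c(2, 2)), 1.0)  # single classes
})

test_that("tier classification applies the strict MIMAG/NC/HQ thresholds", {
  q <- function(p, c) structure(list(purity = p / 100, completeness = c / 100,
                                     taxon = "t", rank = "class",
                                     marker_set_size = 10),
                                class = "quality_estimate")
  t1 <- classify_tiers(q(96, 91), trna_isotypes = 20,
                       rrna_types = c("5S", "16S", "23S"))
  expect_true(all(t1))
  t2 <- classify_tiers(q(92, 75))
  expect_equal(unname(t2), c(TRUE, FALSE, FALSE))
  t3 <- classify_tiers(q(96, 91), trna_isotypes = 17,
                       rrna_types = c("5S", "16S", "23S"))
  expect_true(t3["nc"]); expect_false(t3["mimag_hq"])
  # boundaries are strict
  expect_false(classify_tiers(q(90, 75))["hq"])
  expect_false(classify_tiers(q(96, 90))["nc"])
})

test_that("bp scores equal a brute-force evaluator on fuzzed small partitions", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    gold <- data.frame(contig_id = paste0("c", 1:n),
                       genome_id = paste0("g", sample(1:3, n, replace = TRUE)))
    lengths <- setNames(sample(100:2000, n), gold$contig_id)
    labels <- sample(1:3, n, replace = TRUE)
    bins <- split(gold$contig_id, labels)
    sc <- score_bins(bins, gold, lengths)
    for (r in seq_len(nrow(sc))) {
      ids <- bins[[sc$bin_id[r]]]
      gof <- gold$genome_id[match(ids, gold$contig_id)]
      bp_by_g <- sapply(sort(unique(gof)), function(g) sum(lengths[ids[gof == g]]))
      best <- names(bp_by_g)[order(-bp_by_g, names(bp_by_g))][1]
      expect_identical(sc$reference[r], best)
      expect_equal(sc$bp_purity[r], bp_by_g[best] / sum(lengths[ids]),
                   tolerance = 1e-12, ignore_attr = TRUE)
      gtot <- sum(lengths[gold$contig_id[gold$genome_id == best]])
      expect_equal(sc$bp_completeness[r], bp_by_g[best] / gtot,
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})
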