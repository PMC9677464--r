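test_that("minimum cluster size follows round-half-up ln(n) with floor 2", {
  expect_equal(min_cluster_size_for(1000), 7L)
  expect_equal(min_cluster_size_for(10), 2L)
  expect_equal(min_cluster_size_for(3), 2L)
  for (n in round(exp(seq(log(2), log(1e6), length.out = 40)))) {
    expect_equal(min_cluster_size_for(n),
                 max(2L, as.integer(floor(log(n) + 0.5))))
  }
})

test_that("required purity escalates with falling completeness and relaxes in the final stage", {
  st_hi <- threshold_state(92.5, 72.5, FALSE)
  expect_equal(required_purity(st_hi, 95, "class"), 95)
  st_lo <- threshold_state(82.5, 72.5, FALSE)
  expect_equal(required_purity(st_lo, 70, "class"), 95)
  expect_equal(required_purity(st_lo, 70, "domain"), 99)
  expect_equal(required_purity(st_lo, 95, "class"), 92.5)
  # linear interpolation between completeness 90 and 70
  expect_equal(required_purity(st_lo, 80, "class"), 92.5 + (95 - 92.5) / 2)
  # final stage: 87.5 for near-complete clusters only
  st_fin <- threshold_state(72.5, 72.5, TRUE)
  expect_equal(required_purity(st_fin, 92, "class"), 87.5)
  expect_gt(required_purity(st_fin, 80, "class"), 87.5)
})

test_that("cluster acceptance respects thresholds and splitting separates planted mixtures", {
  h <- load_marker_hierarchy(mini_marker_db())
  # two genomes, same composition chain, very different depth profiles:
  # force them into one candidate by passing all contigs as one cluster
  ab <- matrix(c(80, 5, 40, 5, 70, 4), nrow = 2, byrow = TRUE)
  spec <- community_spec(n_genomes = 2, n_samples = 3,
                         contigs_per_genome = c(40, 60),
                         genome_length_range = c(3e5, 4e5),
                         composition_groups = c(1, 1), abundance = ab,
                         seed = 5)
  b <- generate_community(spec)
  feats <- build_features(b$assembly, b$depths, b$masks)
  prm <- suppressWarnings(embedding_params(length(b$assembly), 0, 0))
  coords <- embed_contigs(feats, prm)
  st <- threshold_state(92.5, 70, FALSE)
  mixed <- rownames(coords)
  res <- accept_or_split(mixed, coords, b$depths, b$hit_table, h, st,
                         max_split_attempts = 1L)
  expect_gte(length(res$mags), 2)
  refs <- vapply(res$mags, function(m) {
    g <- b$gold$genome_id[match(m$contig_ids, b$gold$contig_id)]
    names(sort(table(g), decreasing = TRUE))[1]
  }, "")
  expect_setequal(unique(refs), c("genome_1", "genome_2"))
  # every accepted sub-MAG satisfies the purity rule that was active
  for (m in res$mags) {
    expect_gte(m$quality$completeness * 100, st$completeness_threshold)
    expect_gte(m$quality$purity * 100,
               required_purity(st, m$quality$completeness * 100,
                               m$quality$rank))
  }
})

test_that("candidates failing thresholds with no split structure return to the pool", {
  h <- load_marker_hierarchy(mini_marker_db())
  set.seed(4)
  coords <- matrix(rnorm(20), 10, 2,
                   dimnames = list(paste0("c", 1:10), NULL))
  depths <- matrix(5, 10, 1, dimnames = list(paste0("c", 1:10), "s1"))
  # no markers at all: completeness 0, can never pass
  tab <- data.frame(contig_id = character(0), orf_id = character(0),
                    marker_accession = character(0))
  st <- threshold_state(92.5, 72.5, FALSE)
  res <- accept_or_split(paste0("c", 1:10), coords, depths, tab, h, st,
                         max_split_attempts = 1L)
  expect_length(res$mags, 0)
  expect_setequal(res$leftover, paste0("c", 1:10))
})

test_that("single-contig rescue applies the marker-count and quality gates", {
  h <- load_marker_hierarchy(mini_marker_db())
  dom <- unlist(h$nodes[["d__SynBacteria"]]$sets)   # 104 markers
  mk_tab <- function(contig, markers, dup = character(0)) {
    data.frame(contig_id = contig,
               orf_id = paste0(contig, "_o", seq_len(length(markers) + length(dup))),
               marker_accession = c(markers, dup))
  }
  # 41 distinct markers but low completeness would fail; use a near-complete
  # contig: 100 of 104 domain markers, all single copy
  tab <- rbind(mk_tab("good", dom[1:100]),
               mk_tab("few", dom[1:39]),
               mk_tab("impure", dom[1:97], dup = rep(dom[1:30], 2)))
  res <- extract_single_contig_mags(c("good", "few", "impure", "plain"),
                                    tab, h)
  expect_equal(vapply(res$mags, `[[`, "", "contig_ids"), "good")
  expect_setequal(res$remaining, c("few", "impure", "plain"))
  # the rescued contig passes the stated thresholds
  q <- res$mags[[1]]$quality
  expect_gte(q$purity * 100, 90)
  expect_gte(q$completeness * 100, 92.5)
})
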