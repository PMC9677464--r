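test_that("Nx selection keeps the shortest qualifying prefix", {
  expect_setequal(nx_select(c(c1 = 600, c2 = 300, c3 = 100), 90),
                  c("c1", "c2"))
  expect_setequal(nx_select(c(c1 = 600, c2 = 300, c3 = 100), 100),
                  c("c1", "c2", "c3"))
  expect_equal(nx_select(c(only = 123), 5), "only")
  expect_length(nx_select(setNames(numeric(0), character(0)), 90), 0)
})

test_that("Nx selection equals exhaustive prefix search on fuzzed inputs", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(1:30, 1)
    lens <- setNames(sample(100:5000, n, replace = TRUE), paste0("c", 1:n))
    x <- runif(1, 1, 100)
    expect_identical(nx_select(lens, x), oracle_nx(lens, x))
  }
})

test_that("size selection is the union of the Nx prefix and category minimums", {
  cfg <- selection_config()
  lens <- c(big1 = 50000, big2 = 40000, mk = 2300, nomk1 = 2000, nomk2 = 2400,
            small = 600)
  hm <- c(big1 = FALSE, big2 = FALSE, mk = TRUE, nomk1 = FALSE, nomk2 = FALSE,
          small = FALSE)
  kept <- size_select(lens, hm, cfg)
  expect_true("mk" %in% kept)        # 2300 >= 2250 with markers
  expect_false("nomk1" %in% kept)    # 2000 < 2250, outside N90
  expect_true("nomk2" %in% kept)     # 2400 >= 2250
  expect_true(all(c("big1", "big2") %in% kept))
  # contigs inside the Nx prefix are kept regardless of length
  lens2 <- c(a = 600, b = 100)
  hm2 <- c(a = FALSE, b = FALSE)
  expect_true("a" %in% size_select(lens2, hm2, cfg))
})

test_that("masked window starts are exactly the overlap-enumerated windows", {
  expect_equal(masked_window_starts(10, cbind(start = 6L, end = 6L), 2),
               c(5L, 6L))
  expect_length(masked_window_starts(10, NULL, 2), 0)
  expect_equal(masked_window_starts(5, cbind(start = 1L, end = 5L), 3),
               1:3)
  set.seed(13)
  for (i in 1:100) {
    len <- sample(10:60, 1); k <- sample(2:5, 1)
    st <- sample(1:len, 2); en <- pmin(len, st + sample(0:10, 2))
    m <- microbin:::normalize_intervals(st, en, len)
    got <- masked_window_starts(len, m, k)
    want <- Filter(function(p)
      any(p <= m[, "end"] & (p + k - 1) >= m[, "start"]),
      seq_len(len - k + 1))
    expect_equal(got, as.integer(want))
  }
})

test_that("canonical k-mer counting matches hand enumeration", {
  s <- Biostrings::DNAStringSet(c(c1 = "ACGT"))
  f <- kmer_frequencies(s, ks = 2L)
  expect_equal(unname(f[1, "AC"]), 2)   # AC + GT (reverse complement)
  expect_equal(unname(f[1, "CG"]), 1)
  expect_equal(sum(f), 3)
  # masked windows drop out
  s2 <- Biostrings::DNAStringSet(c(x = "AAAAACAAAA"))
  f2 <- kmer_frequencies(s2, list(x = cbind(start = 6L, end = 6L)), ks = 2L)
  expect_equal(unname(f2[1, "AA"]), 7)
  expect_equal(sum(f2), 7)
  # windows containing N are not counted
  s3 <- Biostrings::DNAStringSet(c(y = "ACNGT"))
  expect_equal(sum(kmer_frequencies(s3, ks = 2L)), 2)  # AC and GT only
})

test_that("masked k-mer counting equals the window-enumeration oracle on fuzzed cases", {
  set.seed(99)
  for (i in 1:500) {
    len <- sample(8:80, 1)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    k <- sample(2:4, 1)
    m <- NULL
    if (runif(1) < 0.7) {
      st <- sample(1:len, sample(1:3, 1), replace = TRUE)
      en <- pmin(len, st + sample(0:15, length(st), replace = TRUE))
      m <- microbin:::normalize_intervals(st, en, len)
    }
    got <- kmer_frequencies(Biostrings::DNAStringSet(c(z = seq)),
                            if (is.null(m)) list() else list(z = m), ks = k)
    want <- oracle_kmer_counts(seq, m, k)
    nz <- got[1, ]
    nz <- nz[nz > 0]
    if (length(want) == 0) {
      expect_length(nz, 0)
    } else {
      expect_equal(nz[order(names(nz))],
                   want[order(names(want))], ignore_attr = TRUE)
      expect_setequal(names(nz), names(want))
    }
  }
})

test_that("CLR rows sum to zero and match closed forms", {
  expect_equal(unname(clr(matrix(c(2, 8), 1, 2), pseudocount = 0)[1, ]),
               c(log(2 / 4), log(8 / 4)))
  expect_equal(unname(clr(matrix(5, 1, 4))[1, ]), rep(0, 4))
  set.seed(3)
  m <- matrix(rpois(600, 4), 20, 30)
  out <- clr(m, 1)
  expect_true(all(abs(rowSums(out)) < 1e-9))
  expect_error(clr(matrix(c(0, 1), 1, 2), pseudocount = 0), "pseudocount")
})

test_that("feature building concatenates CLR blocks with the right shapes", {
  set.seed(8)
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(1:6, function(i) paste(sample(c("A", "C", "G", "T"), 400,
                                         replace = TRUE), collapse = ""), ""),
    paste0("c", 1:6)))
  dep1 <- matrix(runif(6, 1, 10), 6, 1, dimnames = list(names(seqs), "s1"))
  f1 <- build_features(seqs, dep1, ks = 2L)
  expect_equal(ncol(f1$x), 10 + 1)       # 10 canonical 2-mers + 1 sample
  expect_equal(f1$n_samples, 1)
  dep3 <- matrix(runif(18, 1, 10), 6, 3,
                 dimnames = list(names(seqs), paste0("s", 1:3)))
  f3 <- build_features(seqs, dep3, ks = c(2L, 3L, 4L))
  expect_equal(ncol(f3$x), 10 + 32 + 136 + 3)
  expect_true(all(is.finite(f3$x)))
  # identical contigs with identical depths give identical rows
  seqs2 <- Biostrings::DNAStringSet(c(a = as.character(seqs[[1]]),
                                      b = as.character(seqs[[1]])))
  dep2 <- matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  f2 <- build_features(seqs2, dep2, ks = 2L)
  expect_equal(f2$x["a", ], f2$x["b", ])
})

test_that("feature building is permutation-equivariant", {
  set.seed(12)
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(1:8, function(i) paste(sample(c("A", "C", "G", "T"), 300,
                                         replace = TRUE), collapse = ""), ""),
    paste0("c", 1:8)))
  dep <- matrix(runif(16, 1, 20), 8, 2,
                dimnames = list(names(seqs), c("s1", "s2")))
  f <- build_features(seqs, dep, ks = c(2L, 3L))
  perm <- sample(names(seqs))
  fp <- build_features(seqs[perm], dep, ks = c(2L, 3L))
  expect_equal(fp$x[names(seqs), ], f$x[names(seqs), ])
})
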