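# Independent brute-force oracles and tiny fixture builders shared across
# the suite. These are written directly from the stated definitions and are
# kept free of any package internals beyond exported constructors.

# --- marker math oracles (mean-of-fractions completeness, Eq.-style purity)

oracle_completeness <- function(counts, sets) {
  fr <- sapply(sets, function(ms) {
    sum(vapply(ms, function(g) !is.na(counts[g]) && counts[g] >= 1,
               logical(1))) / length(ms)
  })
  mean(fr)
}

oracle_purity <- function(counts, sets) {
  per <- c()
  for (ms in sets) {
    pres <- ms[vapply(ms, function(g) !is.na(counts[g]) && counts[g] >= 1,
                      logical(1))]
    if (length(pres) == 0) next
    per <- c(per, sum(1 / counts[pres]) / length(pres))
  }
  if (length(per) == 0) return(1.0)
  sum(per) / length(per)
}

random_marker_instance <- function() {
  n_sets <- sample(1:5, 1)
  pool <- paste0("m", 1:30)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(pool, sample(1:6, 1)))
  present <- sample(pool, sample(0:20, 1))
  counts <- setNames(sample(1:5, length(present), replace = TRUE), present)
  list(counts = counts, sets = sets)
}

# --- masked canonical k-mer window oracle

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_kmer_counts <- function(seq, intervals, k) {
  n <- nchar(seq)
  out <- list()
  if (n >= k) {
    for (p in 1:(n - k + 1)) {
      if (!is.null(intervals) && nrow(intervals) > 0) {
        if (any(p <= intervals[, "end"] & (p + k - 1) >= intervals[, "start"]))
          next
      }
      w <- substr(seq, p, p + k - 1)
      if (grepl("[^ACGT]", w)) next
      rc <- oracle_revcomp(w)
      key <- if (w <= rc) w else rc
      out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + 1
    }
  }
  unlist(out)
}

# --- Nx prefix oracle: exhaustive search for the smallest qualifying prefix

oracle_nx <- function(lengths, x) {
  ord <- order(-lengths, names(lengths))
  lens <- lengths[ord]
  total <- sum(lengths)
  for (m in seq_along(lens)) {
    if (sum(lens[1:m]) >= total * x / 100) return(names(lens)[1:m])
  }
  names(lens)
}

# --- ARI by explicit pair counting

oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1.0)
  num / den
}

# --- tiny custom hierarchy written to a temp file

write_hierarchy <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("#rank\ttaxon\tparent_taxon\tmarker_sets",
               vapply(rows, function(r) paste(r, collapse = "\t"), "")),
             path)
  path
}

two_level_hierarchy <- function() {
  # one domain with two classes reachable through one phylum each is
  # overkill for the traversal examples; domain -> phylum -> class chain
  load_marker_hierarchy(write_hierarchy(list(
    c("domain", "dA", "root", "[[a1,a2],[a3,a4]]"),
    c("phylum", "pA", "dA", "[[p1,p2]]"),
    c("class", "cA", "pA", "[[x1,x2],[x3]]"),
    c("class", "cB", "pA", "[[y1,y2]]"))))
}
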