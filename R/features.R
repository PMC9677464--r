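# Contig selection and the CLR composition + depth feature matrix.

#' Selection configuration for the main binning routine
#'
#' Everything shorter than `global_min_len` is discarded outright. The main
#' routine then keeps a contig if it falls in the Nx prefix (longest contigs
#' jointly covering `nx`% of the assembly) OR meets the category minimum
#' length (with/without marker genes). The union keeps as much information
#' as possible: only short, marker-free, low-information contigs are left
#' out.
#'
#' @param global_min_len hard minimum contig length in bp (default 500).
#' @param nx Nx percentage in (0, 100\] (default 90).
#' @param min_len_with_markers minimum length (bp) to keep a marker-bearing
#'   contig outside the Nx prefix (default 2250).
#' @param min_len_without_markers same for contigs without markers
#'   (default 2250).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(global_min_len = 500, nx = 90,
                             min_len_with_markers = 2250,
                             min_len_without_markers = 2250) {
  stopifnot(global_min_len > 0, nx > 0, nx <= 100,
            min_len_with_markers > 0, min_len_without_markers > 0)
  structure(list(global_min_len = global_min_len, nx = nx,
                 min_len_with_markers = min_len_with_markers,
                 min_len_without_markers = min_len_without_markers),
            class = "selection_config")
}

#' Nx contig selection
#'
#' Sorts contigs by length in descending order (ties broken by contig id so
#' the selection is deterministic) and keeps the shortest prefix whose
#' cumulative length reaches `x`% of the total assembly length.
#'
#' @param lengths named vector contig id -> length (bp), all positive.
#' @param x percentage in (0, 100\].
#' @return character vector of kept contig ids.
#' @export
nx_select <- function(lengths, x) {
  if (length(lengths) == 0L) return(character(0))
  stopifnot(all(lengths > 0), x > 0, x <= 100)
  ord <- order(-lengths, names(lengths))
  lens <- lengths[ord]
  need <- sum(as.numeric(lengths)) * x / 100
  keep <- seq_len(which(cumsum(as.numeric(lens)) >= need)[1])
  names(lens)[keep]
}

#' Combined Nx + minimum-length contig selection
#'
#' @param lengths named vector contig id -> length (bp), pre-filtered to
#'   `cfg$global_min_len`.
#' @param has_markers named logical vector (same ids): does the contig carry
#'   any marker-gene hit?
#' @param cfg a [selection_config()].
#' @param min_len_override optional single bp value replacing both category
#'   minimums (used by the iterative schedule as it relaxes contig size).
#' @return character vector of kept contig ids.
#' @export
size_select <- function(lengths, has_markers, cfg,
                        min_len_override = NULL) {
  if (length(lengths) == 0L) return(character(0))
  stopifnot(setequal(names(lengths), names(has_markers)))
  has_markers <- has_markers[names(lengths)]
  in_nx <- names(lengths) %in% nx_select(lengths, cfg$nx)
  min_with <- if (is.null(min_len_override)) cfg$min_len_with_markers else min_len_override
  min_without <- if (is.null(min_len_override)) cfg$min_len_without_markers else min_len_override
  cat_min <- ifelse(has_markers, min_with, min_without)
  names(lengths)[in_nx | lengths >= cat_min]
}

# maximal unmasked runs of a contig as an IRanges; intervals is the
# normalized start/end matrix from normalize_intervals()
unmasked_segments <- function(len, intervals) {
  mask <- if (is.null(intervals) || nrow(intervals) == 0L)
    IRanges::IRanges()
  else
    IRanges::IRanges(start = intervals[, "start"], end = intervals[, "end"])
  IRanges::gaps(mask, start = 1L, end = as.integer(len))
}

#' Starts of k-mer windows skipped due to masking
#'
#' A k-window starting at 1-based position p is skipped iff \[p, p+k-1\]
#' overlaps any masked interval. The sequence itself is never modified;
#' masking only removes windows from the k-mer counts.
#'
#' @param len contig length (bp).
#' @param intervals normalized interval matrix (columns `start`, `end`) or
#'   NULL.
#' @param k window width.
#' @return integer vector of skipped window start positions.
#' @export
masked_window_starts <- function(len, intervals, k) {
  n_win <- len - k + 1L
  if (n_win < 1L) return(integer(0))
  starts <- seq_len(n_win)
  if (is.null(intervals) || nrow(intervals) == 0L) return(integer(0))
  skip <- rep(FALSE, n_win)
  for (i in seq_len(nrow(intervals))) {
    lo <- max(1L, intervals[i, "start"] - k + 1L)
    hi <- min(n_win, intervals[i, "end"])
    if (lo <= hi) skip[lo:hi] <- TRUE
  }
  starts[skip]
}

#' Canonical k-mers of size k
#'
#' A k-mer and its reverse complement are pooled under the lexicographically
#' smaller of the two, making counts strand-invariant (assemblies have no
#' consistent strand).
#'
#' @param k k-mer size.
#' @return list with `all` (4^k k-mers), `canonical` (sorted unique
#'   representatives) and `map` (named: k-mer -> its representative).
#' @export
canonical_kmers <- function(k) {
  all_k <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(all_k)))
  canon <- ifelse(all_k <= rc, all_k, rc)
  list(all = all_k, canonical = sort(unique(canon)),
       map = setNames(canon, all_k))
}

#' Canonical k-mer counts of masked contigs
#'
#' Counts every k-window that (i) does not overlap a masked interval and
#' (ii) contains only A/C/G/T, pooling each k-mer with its reverse
#' complement. Per-k blocks are concatenated in ascending k.
#'
#' @param seqs named [Biostrings::DNAStringSet].
#' @param masks named list contig id -> normalized interval matrix (ids
#'   absent from the list are unmasked).
#' @param ks integer vector of k values (default 2, 3, 4).
#' @return numeric matrix: rows contigs (in `seqs` order), columns canonical
#'   k-mers, per-k blocks in ascending k.
#' @export
kmer_frequencies <- function(seqs, masks = list(), ks = c(2L, 3L, 4L)) {
  stopifnot(length(ks) > 0L)
  ks <- sort(as.integer(ks))
  ids <- names(seqs)
  lens <- Biostrings::width(seqs)
  # fragment each contig into its maximal unmasked runs; windows fully inside
  # a run are exactly the windows overlapping no mask
  seg_ir <- lapply(seq_along(seqs), function(i)
    unmasked_segments(lens[i], masks[[ids[i]]]))
  n_seg <- vapply(seg_ir, length, 1L)
  owner <- rep(seq_along(seqs), n_seg)
  all_ir <- do.call(c, seg_ir)
  segs <- Biostrings::DNAStringSet(
    substring(rep(as.character(seqs), n_seg),
              IRanges::start(all_ir), IRanges::end(all_ir)))
  blocks <- lapply(ks, function(k) {
    ck <- canonical_kmers(k)
    cnt <- Biostrings::oligonucleotideFrequency(segs, width = k)
    by_contig <- rowsum(cnt, group = owner)  # segments -> contigs
    full <- matrix(0, nrow = length(seqs), ncol = ncol(by_contig),
                   dimnames = list(ids, colnames(by_contig)))
    full[as.integer(rownames(by_contig)), ] <- by_contig
    # fold onto canonical representatives
    canon <- t(rowsum(t(full), group = ck$map[colnames(full)]))
    canon[, ck$canonical, drop = FALSE]
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- ids
  out
}

#' Centered log-ratio transform
#'
#' Per row: add `pseudocount`, divide by the row geometric mean, take the
#' natural log. Output rows sum to zero (within floating-point error), the
#' defining property of the CLR of compositional data.
#'
#' @param mat non-negative numeric matrix.
#' @param pseudocount value added before the log (default 1; use a small
#'   value such as 1e-5 for depths).
#' @return transformed matrix of the same shape.
#' @export
clr <- function(mat, pseudocount = 1) {
  stopifnot(is.matrix(mat), all(mat >= 0), pseudocount >= 0)
  lg <- log(mat + pseudocount)
  if (any(!is.finite(lg))) stop("CLR on zero entries requires pseudocount > 0")
  sweep(lg, 1, rowMeans(lg), "-")
}

#' Build the contig feature matrix
#'
#' Concatenates CLR-transformed canonical k-mer counts (CLR applied per k
#' block, per row) with CLR-transformed per-sample depths. With a single
#' sample a per-row CLR would be identically zero, so the depth column is
#' instead log-transformed and centered by its median across contigs.
#'
#' @param seqs named [Biostrings::DNAStringSet] of the selected contigs.
#' @param depths numeric matrix (rownames = contig ids, one column per
#'   sample).
#' @param masks named list of normalized mask interval matrices.
#' @param ks k-mer sizes (default 2, 3, 4).
#' @param kmer_pseudocount,depth_pseudocount CLR pseudocounts.
#' @return list of class `feature_matrix`: `ids`, `x` (numeric matrix),
#'   `ks`, `n_samples`.
#' @export
build_features <- function(seqs, depths, masks = list(), ks = c(2L, 3L, 4L),
                           kmer_pseudocount = 1, depth_pseudocount = 1e-5) {
  ids <- names(seqs)
  stopifnot(length(ids) > 0L, all(ids %in% rownames(depths)))
  depths <- depths[ids, , drop = FALSE]
  ks <- sort(as.integer(ks))
  counts <- kmer_frequencies(seqs, masks, ks)
  # per-k CLR blocks
  sizes <- vapply(ks, function(k) length(canonical_kmers(k)$canonical), 1L)
  stops <- cumsum(sizes); starts <- stops - sizes + 1L
  kblocks <- lapply(seq_along(ks), function(i)
    clr(counts[, starts[i]:stops[i], drop = FALSE], kmer_pseudocount))
  if (ncol(depths) > 1L) {
    dblock <- clr(depths, depth_pseudocount)
  } else {
    ld <- log(depths + depth_pseudocount)
    dblock <- ld - median(ld)
  }
  x <- cbind(do.call(cbind, kblocks), dblock)
  if (ncol(x) == 0L) stop("empty feature matrix")
  if (any(!is.finite(x))) stop("non-finite feature values")
  rownames(x) <- ids
  structure(list(ids = ids, x = x, ks = ks, n_samples = ncol(depths)),
            class = "feature_matrix")
}
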