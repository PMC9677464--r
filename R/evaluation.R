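# Gold-standard evaluation: base-pair purity/completeness per bin, overall
# metrics, adjusted Rand index, and MAG quality tiers.

#' Score bins against a gold standard, in base pairs
#'
#' For each bin the reference is the gold-standard genome contributing the
#' most bp (ties to the lexicographically smaller genome id);
#' `bp_purity` = reference bp in bin / bin bp and `bp_completeness` =
#' reference bp in bin / reference total bp (over all gold contigs, binned
#' or not).
#'
#' @param bins named list: bin id -> character vector of contig ids.
#' @param gold data.frame with `contig_id`, `genome_id`.
#' @param lengths named vector contig id -> length (bp).
#' @return data.frame: `bin_id`, `reference`, `bin_bp`, `ref_bp_in_bin`,
#'   `bp_purity`, `bp_completeness`.
#' @export
score_bins <- function(bins, gold, lengths) {
  genome_of <- setNames(gold$genome_id, gold$contig_id)
  genome_bp <- tapply(as.numeric(lengths[gold$contig_id]), gold$genome_id, sum)
  out <- list()
  for (bid in names(bins)) {
    ids <- bins[[bid]]
    if (length(ids) == 0L) {
      warning("empty bin skipped: ", bid)
      next
    }
    miss <- setdiff(ids, names(genome_of))
    if (length(miss))
      stop("bin ", bid, " contains contig(s) absent from the gold standard: ",
           paste(head(miss, 3), collapse = ", "))
    bp <- tapply(as.numeric(lengths[ids]), genome_of[ids], sum)
    bp <- bp[order(-bp, names(bp))]
    ref <- names(bp)[1]
    out[[length(out) + 1L]] <- data.frame(
      bin_id = bid, reference = ref,
      bin_bp = sum(as.numeric(lengths[ids])),
      ref_bp_in_bin = unname(bp[1]),
      bp_purity = unname(bp[1]) / sum(as.numeric(lengths[ids])),
      bp_completeness = unname(bp[1]) / unname(genome_bp[ref]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(bin_id = character(0), reference = character(0),
                      bin_bp = numeric(0), ref_bp_in_bin = numeric(0),
                      bp_purity = numeric(0), bp_completeness = numeric(0)))
  do.call(rbind, out)
}

#' Overall bp purity and completeness over a set of bins
#'
#' Overall purity: sum over bins of majority-genome bp divided by the total
#' bp in all bins. Overall completeness: the same majority-bp sum divided
#' by the total bp of all gold-standard genomes.
#'
#' @inheritParams score_bins
#' @return named numeric vector `c(purity = ..., completeness = ...)`;
#'   purity is `NA` when there are no bins.
#' @export
overall_metrics <- function(bins, gold, lengths) {
  sc <- score_bins(bins, gold, lengths)
  if (nrow(sc) == 0L) return(c(purity = NA_real_, completeness = 0))
  total_gold <- sum(as.numeric(lengths[gold$contig_id]))
  c(purity = sum(sc$ref_bp_in_bin) / sum(sc$bin_bp),
    completeness = sum(sc$ref_bp_in_bin) / total_gold)
}

#' Adjusted Rand index between a binning and the gold standard
#'
#' Pair-counting agreement, chance corrected. Un-binned contigs (label
#' `NA`) are excluded: agreement is measured over binned contigs only.
#'
#' @param bin_labels named or plain vector of bin labels; `NA` = un-binned.
#' @param gold_labels vector of gold genome labels, same contig order.
#' @return ARI in \[-1, 1\]; 1.0 when both labelings are a single class.
#' @export
adjusted_rand_index <- function(bin_labels, gold_labels) {
  stopifnot(length(bin_labels) == length(gold_labels))
  keep <- !is.na(bin_labels)
  b <- bin_labels[keep]; g <- gold_labels[keep]
  if (length(b) == 0L) return(NA_real_)
  if (length(unique(b)) == 1L && length(unique(g)) == 1L) return(1.0)
  mclust::adjustedRandIndex(b, g)
}

#' Classify a MAG into quality tiers
#'
#' Tiers use the marker-based quality (as a CheckM-style filter would), not
#' the gold-standard bp metrics: HQ means purity > 90% and completeness
#' > 70%; NC (near-complete) means purity > 95% and completeness > 90%;
#' the MIMAG high-quality draft additionally requires at least 18 unique
#' tRNA isotypes and all three rRNA subunit types (5S, 16S, 23S). All
#' inequalities are strict.
#'
#' @param quality a `quality_estimate` (fractions in \[0,1\]).
#' @param trna_isotypes number of unique tRNA isotypes in the MAG.
#' @param rrna_types character vector of rRNA types present.
#' @return named logical vector `c(hq = , nc = , mimag_hq = )`.
#' @export
classify_tiers <- function(quality, trna_isotypes = 0L,
                           rrna_types = character(0)) {
  pur <- quality$purity * 100
  comp <- quality$completeness * 100
  hq <- pur > 90 && comp > 70
  nc <- pur > 95 && comp > 90
  mimag <- nc && trna_isotypes >= 18L &&
    all(c("5S", "16S", "23S") %in% rrna_types)
  c(hq = hq, nc = nc, mimag_hq = mimag)
}

#' Per-MAG RNA inventory from parsed GFF RNA features
#'
#' Pools the unique tRNA isotypes and rRNA types of a MAG's contigs.
#'
#' @param contig_ids MAG members.
#' @param rna output of [parse_gff_rna_counts()].
#' @return list `trna_isotypes` (count) and `rrna_types` (character).
#' @export
mag_rna_inventory <- function(contig_ids, rna) {
  hit <- rna[intersect(names(rna), contig_ids)]
  iso <- unique(unlist(lapply(hit, `[[`, "trna_isotypes")))
  rr <- unique(unlist(lapply(hit, `[[`, "rrna_types")))
  list(trna_isotypes = length(iso), rrna_types = sort(rr))
}
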