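# Cluster candidate assessment: dynamic purity requirements, iterative
# splitting of contaminated clusters with raw depth as extra dimensions, and
# up-front rescue of single-contig genomes.

#' Minimum HDBSCAN cluster size for a pool of n contigs
#'
#' ln(n), rounded half-up, floored at 2 (density clustering needs an integer
#' of at least 2).
#'
#' @param n_contigs pool size (>= 2).
#' @return integer.
#' @export
min_cluster_size_for <- function(n_contigs) {
  stopifnot(n_contigs >= 2)
  pmax(2L, as.integer(floor(log(n_contigs) + 0.5)))
}

#' Threshold state of the iterative schedule
#'
#' @param completeness_threshold current completeness requirement (percent).
#' @param floor lowest completeness the schedule will reach (72.5 single
#'   sample, 70 co-assembly).
#' @param final_stage logical; in the final recovery stage the purity
#'   requirement drops to 87.5 for clusters at >= 90 completeness and the
#'   split budget doubles.
#' @return list of class `threshold_state`.
#' @export
threshold_state <- function(completeness_threshold = 92.5, floor = 72.5,
                            final_stage = FALSE) {
  stopifnot(completeness_threshold >= floor)
  structure(list(completeness_threshold = completeness_threshold,
                 floor = floor, final_stage = final_stage),
            class = "threshold_state")
}

#' Purity required to accept a cluster
#'
#' The base requirement is 95 while the completeness threshold is at or
#' above 90, and 92.5 below that. To keep low-completeness clusters from
#' sneaking in impure, the requirement rises linearly as the cluster's own
#' completeness falls from 90 to 70, reaching 95 (or 99 when the assessment
#' settled on a domain-level marker set, whose generality warrants extra
#' caution). In the final stage, clusters at completeness >= 90 only need
#' purity 87.5.
#'
#' @param state a [threshold_state()].
#' @param cluster_completeness the cluster's assessed completeness (percent).
#' @param marker_rank rank of the chosen marker set (`"domain"` escalates to
#'   99).
#' @return required purity in percent.
#' @export
required_purity <- function(state, cluster_completeness, marker_rank) {
  stopifnot(cluster_completeness >= 0, cluster_completeness <= 100)
  if (state$final_stage && cluster_completeness >= 90) return(87.5)
  base <- if (state$completeness_threshold >= 90) 95 else 92.5
  cap <- if (identical(marker_rank, "domain")) 99 else 95
  frac <- min(1, max(0, (90 - cluster_completeness) / 20))
  base + (max(cap, base) - base) * frac
}

#' Cluster a 2-D embedding
#'
#' HDBSCAN with Manhattan metric; noise points stay un-binned.
#'
#' @param coords n x 2 coordinate matrix (rownames = contig ids).
#' @param min_cluster_size,min_samples,cluster_selection_epsilon passed to
#'   [hdbscan()].
#' @return named list: cluster label -> character vector of contig ids.
#' @export
cluster_embedding <- function(coords, min_cluster_size, min_samples = 1L,
                              cluster_selection_epsilon = 0.0) {
  if (nrow(coords) < min_cluster_size)
    return(list())
  labels <- hdbscan(coords, min_cluster_size = min_cluster_size,
                    min_samples = min_samples,
                    cluster_selection_epsilon = cluster_selection_epsilon,
                    metric = "manhattan")
  ids <- rownames(coords)
  keep <- labels > 0L
  split(ids[keep], labels[keep])
}

# assess a contig group; returns quality_estimate
.assess_group <- function(contig_ids, hit_table, hierarchy, max_rank) {
  assess_quality(marker_counts(contig_ids, hit_table), hierarchy,
                 max_rank = max_rank)
}

.passes <- function(quality, state) {
  comp <- quality$completeness * 100
  pur <- quality$purity * 100
  comp >= state$completeness_threshold &&
    pur >= required_purity(state, comp, quality$rank)
}

#' Accept a candidate cluster or split it on raw depth
#'
#' A candidate passing the active completeness threshold and
#' [required_purity()] is accepted as-is. Otherwise its points are
#' re-clustered in (2-D embedding coordinates || raw per-sample depths) --
#' the depth columns rescaled to the coordinate spread so no single
#' high-coverage sample drowns the geometry -- and each sub-cluster is
#' re-assessed, recursing until the split budget is exhausted or no new
#' clusters emerge. Contigs of rejected (sub-)clusters return to the
#' un-binned pool.
#'
#' @param contig_ids candidate cluster members.
#' @param coords embedding coordinates (rownames superset of `contig_ids`).
#' @param raw_depths depth matrix (rownames superset of `contig_ids`).
#' @param hit_table marker hit table.
#' @param hierarchy marker hierarchy.
#' @param state a [threshold_state()].
#' @param max_split_attempts split budget (default 1; 2 in the final stage).
#' @param min_samples HDBSCAN min_samples used for splitting.
#' @param max_rank deepest assessment rank.
#' @return list with `mags` (list of `list(contig_ids, quality)`) and
#'   `leftover` (character vector).
#' @export
accept_or_split <- function(contig_ids, coords, raw_depths, hit_table,
                            hierarchy, state, max_split_attempts = 1L,
                            min_samples = 1L, max_rank = "class") {
  quality <- .assess_group(contig_ids, hit_table, hierarchy, max_rank)
  if (.passes(quality, state))
    return(list(mags = list(list(contig_ids = contig_ids, quality = quality)),
                leftover = character(0)))
  if (max_split_attempts < 1L || length(contig_ids) < 4L)
    return(list(mags = list(), leftover = contig_ids))

  sub <- coords[contig_ids, , drop = FALSE]
  dep <- raw_depths[contig_ids, , drop = FALSE]
  spread <- mean(apply(sub, 2, sd))
  dscaled <- apply(dep, 2, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s == 0 || spread == 0) rep(0, length(col))
    else col / s * spread
  })
  aug <- cbind(sub, dscaled)
  clusters <- cluster_embedding(aug,
                                min_cluster_size = min_cluster_size_for(nrow(aug)),
                                min_samples = min_samples)
  # no progress: a single sub-cluster equal to the candidate cannot improve
  if (length(clusters) == 0L ||
      (length(clusters) == 1L && length(clusters[[1]]) == length(contig_ids)))
    return(list(mags = list(), leftover = contig_ids))

  mags <- list()
  leftover <- setdiff(contig_ids, unlist(clusters))
  for (cl in clusters) {
    res <- accept_or_split(cl, coords, raw_depths, hit_table, hierarchy,
                           state, max_split_attempts - 1L, min_samples,
                           max_rank)
    mags <- c(mags, res$mags)
    leftover <- c(leftover, res$leftover)
  }
  list(mags = mags, leftover = leftover)
}

#' Rescue single-contig genomes before iterative binning
#'
#' Complete genomes on one contig risk being swallowed by clusters of
#' similar fragmented genomes or dismissed as noise. Contigs carrying at
#' least `min_markers` distinct marker accessions are assessed alone; those
#' at purity >= 90% and completeness >= 92.5% become single-contig MAGs and
#' leave the iterative pool.
#'
#' @param contig_ids pool to screen.
#' @param hit_table marker hit table.
#' @param hierarchy marker hierarchy.
#' @param min_markers distinct-marker requirement (default 40).
#' @param min_purity,min_completeness acceptance thresholds in percent.
#' @param max_rank deepest assessment rank.
#' @return list with `mags` (list of `list(contig_ids, quality)`) and
#'   `remaining` (character vector).
#' @export
extract_single_contig_mags <- function(contig_ids, hit_table, hierarchy,
                                       min_markers = 40L, min_purity = 90,
                                       min_completeness = 92.5,
                                       max_rank = "class") {
  tab <- hit_table[hit_table$contig_id %in% contig_ids, , drop = FALSE]
  n_distinct <- vapply(split(tab$marker_accession, tab$contig_id),
                       function(a) length(unique(a)), 1L)
  cand <- names(n_distinct)[n_distinct >= min_markers]
  mags <- list()
  for (cid in sort(cand)) {
    q <- .assess_group(cid, hit_table, hierarchy, max_rank)
    if (q$purity * 100 >= min_purity && q$completeness * 100 >= min_completeness)
      mags[[length(mags) + 1L]] <- list(contig_ids = cid, quality = q)
  }
  rescued <- unlist(lapply(mags, `[[`, "contig_ids"))
  list(mags = mags, remaining = setdiff(contig_ids, rescued))
}
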