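# The iterative binning state machine: embed the un-binned pool, cluster,
# assess, accept, and loosen thresholds on a fixed schedule until the final
# recovery stage yields nothing new.

#' Binning engine configuration
#'
#' @param ks k-mer sizes (default 2, 3, 4).
#' @param selection a [selection_config()].
#' @param completeness_start starting completeness threshold in percent.
#' @param completeness_floor_single,completeness_floor_coassembly schedule
#'   floors for the two modes.
#' @param min_samples_sweep ordered HDBSCAN min_samples values tried per
#'   embedding (default 1, 5, 10).
#' @param max_split_attempts split budget outside the final stage.
#' @param epsilon_cycle cluster_selection_epsilon values cycled per
#'   iteration.
#' @param max_rank deepest marker rank used by assessment.
#' @param seed master seed; iteration i embeds with seed + i.
#' @param mode `"auto"` (co-assembly iff more than one depth column),
#'   `"single"` or `"coassembly"`.
#' @param single_contig_min_markers distinct-marker requirement for the
#'   single-contig rescue.
#' @param max_iterations safety cap on binning iterations per routine.
#' @param verbose print per-iteration progress.
#' @return list of class `binny_config`.
#' @export
binny_config <- function(ks = c(2L, 3L, 4L), selection = selection_config(),
                         completeness_start = 92.5,
                         completeness_floor_single = 72.5,
                         completeness_floor_coassembly = 70,
                         min_samples_sweep = c(1L, 5L, 10L),
                         max_split_attempts = 1L,
                         epsilon_cycle = c(0.25, 0.125, 0),
                         max_rank = "class", seed = 0L,
                         mode = c("auto", "single", "coassembly"),
                         single_contig_min_markers = 40L,
                         max_iterations = 60L, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(completeness_start <= 100,
            completeness_floor_single <= completeness_start,
            completeness_floor_coassembly <= completeness_start,
            length(min_samples_sweep) >= 1L)
  structure(list(ks = as.integer(ks), selection = selection,
                 completeness_start = completeness_start,
                 completeness_floor_single = completeness_floor_single,
                 completeness_floor_coassembly = completeness_floor_coassembly,
                 min_samples_sweep = as.integer(min_samples_sweep),
                 max_split_attempts = as.integer(max_split_attempts),
                 epsilon_cycle = epsilon_cycle, max_rank = max_rank,
                 seed = as.integer(seed), mode = mode,
                 single_contig_min_markers = as.integer(single_contig_min_markers),
                 max_iterations = as.integer(max_iterations),
                 verbose = isTRUE(verbose)),
            class = "binny_config")
}

#' Cluster-selection epsilon for a binning iteration
#'
#' Cycles 0.25, 0.125, 0.0 with the iteration index; the larger values merge
#' micro-clusters early on, the zero value lets fine structure through
#' later.
#'
#' @param i 0-based iteration index.
#' @param cycle the epsilon cycle.
#' @return epsilon value.
#' @export
epsilon_for_iteration <- function(i, cycle = c(0.25, 0.125, 0)) {
  stopifnot(i >= 0)
  cycle[(i %% length(cycle)) + 1L]
}

#' Minimum contig size update for the single-sample schedule
#'
#' Drops the category minimum by 500 bp when fewer than half of the
#' min_samples sweep runs yielded a MAG, floored at 500 bp. The caller
#' resets the size to its initial maximum when the completeness threshold is
#' decremented.
#'
#' @param current_size current minimum contig size (bp).
#' @param fraction_yielding fraction of sweep runs that accepted >= 1 MAG.
#' @return new minimum size (bp).
#' @export
update_size_threshold <- function(current_size, fraction_yielding) {
  stopifnot(current_size >= 500)
  if (fraction_yielding < 0.5) max(500, current_size - 500) else current_size
}

# run the epsilon-cycled min_samples sweep on one embedding; returns
# accepted mags, leftover pool and the per-sweep yield flags
.sweep_embedding <- function(coords, pool, raw_depths, hit_table, hierarchy,
                             state, cfg, epsilon, split_budget) {
  mags <- list()
  yields <- logical(length(cfg$min_samples_sweep))
  remaining <- pool
  for (si in seq_along(cfg$min_samples_sweep)) {
    ms <- cfg$min_samples_sweep[si]
    sub <- coords[remaining, , drop = FALSE]
    if (nrow(sub) < 2L) break
    clusters <- cluster_embedding(
      sub, min_cluster_size = min_cluster_size_for(max(2L, nrow(sub))),
      min_samples = ms, cluster_selection_epsilon = epsilon)
    accepted_here <- 0L
    for (cl in clusters) {
      res <- accept_or_split(cl, coords, raw_depths, hit_table, hierarchy,
                             state, max_split_attempts = split_budget,
                             min_samples = ms, max_rank = cfg$max_rank)
      for (m in res$mags) {
        m$accepted_at <- list(
          completeness_threshold = state$completeness_threshold,
          required_purity = required_purity(
            state, m$quality$completeness * 100, m$quality$rank),
          final_stage = state$final_stage)
        mags[[length(mags) + 1L]] <- m
        accepted_here <- accepted_here + 1L
      }
    }
    yields[si] <- accepted_here > 0L
    claimed <- unlist(lapply(mags, `[[`, "contig_ids"))
    remaining <- setdiff(remaining, claimed)
  }
  list(mags = mags, remaining = remaining, yields = yields)
}

.log_iteration <- function(log, ...) {
  rec <- data.frame(..., stringsAsFactors = FALSE)
  rbind(log, rec)
}

.empty_log <- function() {
  data.frame(iteration = integer(0), pool = integer(0), selected = integer(0),
             nuc = integer(0), ex = numeric(0), lr = numeric(0),
             perp_small = numeric(0), perp_large = numeric(0),
             epsilon = numeric(0), completeness_threshold = numeric(0),
             min_size = numeric(0), final_stage = logical(0),
             mags_accepted = integer(0))
}

# shared per-iteration body: select -> embed -> sweep; returns NULL when the
# selection is too small to embed
.run_iteration <- function(i, pool_ids, seqs, masks, depths, hit_table,
                           hierarchy, state, cfg, min_size_override,
                           split_budget, use_size_select) {
  lens <- setNames(Biostrings::width(seqs[pool_ids]), pool_ids)
  if (use_size_select) {
    hm <- setNames(pool_ids %in% hit_table$contig_id, pool_ids)
    selected <- size_select(lens, hm, cfg$selection,
                            min_len_override = min_size_override)
  } else {
    selected <- names(lens)[lens >= min_size_override]
  }
  if (length(selected) < 5L) return(NULL)
  feats <- build_features(seqs[selected], depths, masks, ks = cfg$ks)
  params <- suppressWarnings(
    embedding_params(length(selected), iteration = i, seed = cfg$seed + i))
  coords <- embed_contigs(feats, params)
  epsilon <- epsilon_for_iteration(i, cfg$epsilon_cycle)
  sw <- .sweep_embedding(coords, selected, depths, hit_table, hierarchy,
                         state, cfg, epsilon, split_budget)
  sw$params <- params
  sw$epsilon <- epsilon
  sw$selected <- selected
  sw
}

#' Run the single-sample iterative binning routine
#'
#' Order of operations: single-contig rescue, then repeat \{size-select the
#' un-binned pool, build features, embed, run the epsilon-cycled
#' min_samples sweep, accept/split clusters, update the size and
#' completeness schedules\}. The completeness threshold walks
#' 92.5 -> 82.5 -> 72.5; at the floor the final recovery stage begins
#' (purity 87.5 for clusters at completeness >= 90, split budget 2) and the
#' routine ends once a final-stage iteration accepts nothing.
#'
#' @param seqs named [Biostrings::DNAStringSet] (the assembly).
#' @param masks named list of mask interval matrices (see
#'   [parse_gff_masks()]).
#' @param hit_table marker hit table (see [read_marker_hits()]).
#' @param depths depth matrix (see [read_depth_table()]).
#' @param hierarchy marker hierarchy (see [load_marker_hierarchy()]).
#' @param cfg a [binny_config()].
#' @return list: `mags` (each with `bin_id`, `contig_ids`, `quality`,
#'   `accepted_at`), `unbinned`, `log` (per-iteration data.frame).
#' @export
run_single_sample <- function(seqs, masks, hit_table, depths, hierarchy,
                              cfg = binny_config()) {
  seqs <- seqs[Biostrings::width(seqs) >= cfg$selection$global_min_len]
  if (length(seqs) == 0L) {
    warning("no contigs pass the global length filter")
    return(list(mags = list(), unbinned = character(0), log = .empty_log()))
  }
  rescue <- extract_single_contig_mags(
    names(seqs), hit_table, hierarchy,
    min_markers = cfg$single_contig_min_markers, max_rank = cfg$max_rank)
  mags <- lapply(rescue$mags, function(m) { m$iteration <- 0L; m })
  pool <- rescue$remaining

  init_size <- max(cfg$selection$min_len_with_markers,
                   cfg$selection$min_len_without_markers)
  state <- threshold_state(cfg$completeness_start,
                           cfg$completeness_floor_single,
                           cfg$completeness_start <= cfg$completeness_floor_single)
  cur_size <- init_size
  log <- .empty_log()
  i <- 0L
  while (i < cfg$max_iterations && length(pool) >= 2L) {
    split_budget <- if (state$final_stage) 2L else cfg$max_split_attempts
    it <- .run_iteration(i, pool, seqs, masks, depths, hit_table, hierarchy,
                         state, cfg, cur_size, split_budget,
                         use_size_select = TRUE)
    accepted <- if (is.null(it)) 0L else length(it$mags)
    frac <- if (is.null(it)) 0 else mean(it$yields)
    if (!is.null(it)) {
      for (m in it$mags) { m$iteration <- i + 1L; mags[[length(mags) + 1L]] <- m }
      pool <- setdiff(pool, unlist(lapply(it$mags, `[[`, "contig_ids")))
      log <- .log_iteration(log, iteration = i, pool = length(pool),
                            selected = length(it$selected),
                            nuc = it$params$nuc, ex = it$params$ex,
                            lr = it$params$lr,
                            perp_small = it$params$perplexities[1],
                            perp_large = it$params$perplexities[2],
                            epsilon = it$epsilon,
                            completeness_threshold = state$completeness_threshold,
                            min_size = cur_size,
                            final_stage = state$final_stage,
                            mags_accepted = accepted)
      if (cfg$verbose)
        message(sprintf(
          "iter %d: NUC=%d eps=%.3f thr=%.1f size=%d -> %d MAG(s)",
          i, it$params$nuc, it$epsilon, state$completeness_threshold,
          cur_size, accepted))
    }
    if (state$final_stage && accepted == 0L) break
    if (frac < 0.5) {
      if (cur_size > 500) {
        cur_size <- update_size_threshold(cur_size, frac)
      } else if (state$completeness_threshold > state$floor) {
        state$completeness_threshold <-
          max(state$floor, state$completeness_threshold - 10)
        state$final_stage <- state$completeness_threshold <= state$floor
        cur_size <- init_size
      } else {
        state$final_stage <- TRUE
      }
    }
    i <- i + 1L
  }
  .finalize_run(mags, pool, log)
}

#' Run the co-assembly iterative binning routine
#'
#' With depth profiles from several samples, differential coverage carries
#' enough signal that no Nx size selection is applied: every un-binned
#' contig at or above 500 bp enters each embedding. The completeness
#' threshold drops by 10 every iteration down to the floor (default 70);
#' at the floor the final-stage relaxation applies and iterations continue
#' while they keep producing MAGs, followed by terminal rounds restricted
#' to contigs of at least 2000, 1500, 1000 and 500 bp.
#'
#' @inheritParams run_single_sample
#' @return as [run_single_sample()].
#' @export
run_coassembly <- function(seqs, masks, hit_table, depths, hierarchy,
                           cfg = binny_config()) {
  if (ncol(depths) < 2L) {
    warning("single depth column: deferring to the single-sample routine")
    return(run_single_sample(seqs, masks, hit_table, depths, hierarchy, cfg))
  }
  seqs <- seqs[Biostrings::width(seqs) >= cfg$selection$global_min_len]
  if (length(seqs) == 0L) {
    warning("no contigs pass the global length filter")
    return(list(mags = list(), unbinned = character(0), log = .empty_log()))
  }
  rescue <- extract_single_contig_mags(
    names(seqs), hit_table, hierarchy,
    min_markers = cfg$single_contig_min_markers, max_rank = cfg$max_rank)
  mags <- lapply(rescue$mags, function(m) { m$iteration <- 0L; m })
  pool <- rescue$remaining

  state <- threshold_state(cfg$completeness_start,
                           cfg$completeness_floor_coassembly,
                           cfg$completeness_start <= cfg$completeness_floor_coassembly)
  log <- .empty_log()
  i <- 0L
  min_size <- 500
  while (i < cfg$max_iterations && length(pool) >= 2L) {
    split_budget <- if (state$final_stage) 2L else cfg$max_split_attempts
    it <- .run_iteration(i, pool, seqs, masks, depths, hit_table, hierarchy,
                         state, cfg, min_size, split_budget,
                         use_size_select = FALSE)
    accepted <- if (is.null(it)) 0L else length(it$mags)
    if (!is.null(it)) {
      for (m in it$mags) { m$iteration <- i + 1L; mags[[length(mags) + 1L]] <- m }
      pool <- setdiff(pool, unlist(lapply(it$mags, `[[`, "contig_ids")))
      log <- .log_iteration(log, iteration = i, pool = length(pool),
                            selected = length(it$selected),
                            nuc = it$params$nuc, ex = it$params$ex,
                            lr = it$params$lr,
                            perp_small = it$params$perplexities[1],
                            perp_large = it$params$perplexities[2],
                            epsilon = it$epsilon,
                            completeness_threshold = state$completeness_threshold,
                            min_size = min_size,
                            final_stage = state$final_stage,
                            mags_accepted = accepted)
      if (cfg$verbose)
        message(sprintf(
          "iter %d: NUC=%d eps=%.3f thr=%.1f -> %d MAG(s)",
          i, it$params$nuc, it$epsilon, state$completeness_threshold,
          accepted))
    }
    at_floor <- state$completeness_threshold <= state$floor
    if (at_floor && accepted == 0L) break
    if (!at_floor) {
      state$completeness_threshold <-
        max(state$floor, state$completeness_threshold - 10)
      state$final_stage <- state$completeness_threshold <= state$floor
    }
    i <- i + 1L
  }
  # terminal rounds with relaxing minimum contig sizes
  state$final_stage <- TRUE
  state$completeness_threshold <- state$floor
  for (ms_size in c(2000, 1500, 1000, 500)) {
    if (i >= cfg$max_iterations || length(pool) < 2L) break
    it <- .run_iteration(i, pool, seqs, masks, depths, hit_table, hierarchy,
                         state, cfg, ms_size, 2L, use_size_select = FALSE)
    if (!is.null(it)) {
      for (m in it$mags) { m$iteration <- i + 1L; mags[[length(mags) + 1L]] <- m }
      pool <- setdiff(pool, unlist(lapply(it$mags, `[[`, "contig_ids")))
      log <- .log_iteration(log, iteration = i, pool = length(pool),
                            selected = length(it$selected),
                            nuc = it$params$nuc, ex = it$params$ex,
                            lr = it$params$lr,
                            perp_small = it$params$perplexities[1],
                            perp_large = it$params$perplexities[2],
                            epsilon = it$epsilon,
                            completeness_threshold = state$completeness_threshold,
                            min_size = ms_size, final_stage = TRUE,
                            mags_accepted = length(it$mags))
      if (cfg$verbose)
        message(sprintf("terminal round (>=%d bp): %d MAG(s)", ms_size,
                        length(it$mags)))
    }
    i <- i + 1L
  }
  .finalize_run(mags, pool, log)
}

# assign deterministic bin ids: bin_<iteration>_<ordinal>, ordinal by
# descending total bp handled by the caller-supplied order of contig ids;
# here ordinals follow descending contig count then first contig id, which
# is stable across runs
.finalize_run <- function(mags, pool, log) {
  if (length(mags)) {
    iters <- vapply(mags, `[[`, 0L, "iteration")
    for (it in sort(unique(iters))) {
      idx <- which(iters == it)
      sizes <- vapply(mags[idx], function(m) length(m$contig_ids), 1L)
      first <- vapply(mags[idx], function(m) sort(m$contig_ids)[1], "")
      ord <- idx[order(-sizes, first)]
      for (k in seq_along(ord))
        mags[[ord[k]]]$bin_id <- sprintf("bin_%d_%d", it, k)
    }
  }
  list(mags = mags, unbinned = pool, log = log)
}

#' Run the full binning engine
#'
#' Joins the inputs, picks the routine (co-assembly iff the depth table has
#' more than one column, unless `cfg$mode` forces one), and returns accepted
#' MAGs with their acceptance provenance. Bin ids are deterministic, so
#' repeated runs with the same seed produce identical contig-to-bin tables;
#' total bp is attached to each MAG and used to re-rank bin ordinals.
#'
#' @inheritParams run_single_sample
#' @return list: `mags`, `unbinned`, `log`, `mode`.
#' @export
run_binny <- function(seqs, masks, hit_table, depths, hierarchy,
                      cfg = binny_config()) {
  stopifnot(inherits(seqs, "DNAStringSet"))
  missing_depth <- setdiff(names(seqs), rownames(depths))
  if (length(missing_depth)) {
    warning(length(missing_depth), " contig(s) missing from the depth ",
            "table; filled with zero depth")
    fill <- matrix(0, length(missing_depth), ncol(depths),
                   dimnames = list(missing_depth, colnames(depths)))
    depths <- rbind(depths, fill)
  }
  depths <- depths[names(seqs), , drop = FALSE]
  mode <- cfg$mode
  if (mode == "auto")
    mode <- if (ncol(depths) > 1L) "coassembly" else "single"
  res <- if (mode == "coassembly")
    run_coassembly(seqs, masks, hit_table, depths, hierarchy, cfg)
  else
    run_single_sample(seqs, masks, hit_table, depths, hierarchy, cfg)
  # re-rank ordinals within iteration by descending total bp for stable,
  # size-meaningful bin ids
  if (length(res$mags)) {
    lens <- setNames(Biostrings::width(seqs), names(seqs))
    iters <- vapply(res$mags, `[[`, 0L, "iteration")
    for (it in sort(unique(iters))) {
      idx <- which(iters == it)
      bp <- vapply(res$mags[idx], function(m) sum(lens[m$contig_ids]), 0)
      first <- vapply(res$mags[idx], function(m) sort(m$contig_ids)[1], "")
      ord <- idx[order(-bp, first)]
      for (k in seq_along(ord)) {
        res$mags[[ord[k]]]$bin_id <- sprintf("bin_%d_%d", it, k)
        res$mags[[ord[k]]]$total_bp <- unname(bp[match(ord[k], idx)])
      }
    }
  }
  res$mode <- mode
  res
}
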