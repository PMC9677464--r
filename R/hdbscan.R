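# Hierarchical density-based clustering (HDBSCAN) on small point sets.
#
# Exact O(n^2) pipeline: pairwise distances -> core distances -> mutual
# reachability graph -> minimum spanning tree -> single-linkage dendrogram ->
# condensed tree (min_cluster_size) -> excess-of-mass cluster selection with
# the cluster_selection_epsilon merge of micro-clusters. Points not inside a
# selected cluster are noise. Matches the reference implementation's
# conventions: core distance is the distance to the min_samples-th nearest
# neighbour (self excluded), and a lone root cluster yields all-noise.

# Prim MST over a dense symmetric weight matrix; returns (n-1) x 3 matrix
# (i, j, w)
.mst_prim <- function(w) {
  n <- nrow(w)
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best_w <- w[1, ]
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_w[cand])]
    edges[e, ] <- c(best_from[j], j, best_w[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & w[j, ] < best_w
    best_from[upd] <- j
    best_w[upd] <- w[j, upd]
  }
  edges
}

#' HDBSCAN clustering
#'
#' @param x numeric matrix of points (rows).
#' @param min_cluster_size smallest group treated as a cluster (>= 2).
#' @param min_samples neighbourhood size for the core distance (density
#'   smoothing); larger values declare more points noise.
#' @param cluster_selection_epsilon micro-cluster merge radius: selected
#'   clusters born below this distance are replaced by their smallest
#'   ancestor spanning at least `cluster_selection_epsilon`.
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @return integer vector of labels, 0 = noise, clusters numbered 1..K in
#'   order of first member point (deterministic).
#' @export
hdbscan <- function(x, min_cluster_size, min_samples = 1L,
                    cluster_selection_epsilon = 0.0,
                    metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  if (n < max(2L, min_cluster_size)) return(rep(0L, n))
  d <- as.matrix(stats::dist(x, method = metric))

  # core distance: min_samples-th nearest neighbour, self excluded
  k <- min(as.integer(min_samples), n - 1L)
  core <- apply(d, 1L, function(row) sort(row)[k + 1L])
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0

  edges <- .mst_prim(mr)
  edges <- edges[order(edges[, 3], edges[, 1], edges[, 2]), , drop = FALSE]

  # single-linkage dendrogram via union-find; internal nodes n+1 .. 2n-1
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {     # path compression
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  comp_node <- seq_len(n)               # component -> current tree node
  sizes <- c(rep(1L, n), integer(n - 1L))
  left <- right <- integer(n - 1L)
  height <- numeric(n - 1L)
  for (e in seq_len(n - 1L)) {
    a <- find(as.integer(edges[e, 1])); b <- find(as.integer(edges[e, 2]))
    node <- n + e
    left[e] <- comp_node[a]; right[e] <- comp_node[b]
    height[e] <- edges[e, 3]
    sizes[node] <- sizes[comp_node[a]] + sizes[comp_node[b]]
    parent[a] <- b
    comp_node[b] <- node
  }

  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v)
      else stack <- c(stack, left[v - n], right[v - n])
    }
    out
  }

  # condensed tree: clusters persist through small-side fallouts; a split
  # into two subtrees of size >= min_cluster_size creates two child clusters
  lam_of <- function(h) 1 / max(h, 1e-12)
  cp <- cc <- integer(0); cl <- numeric(0); cs <- integer(0)  # edges
  birth <- 0; parent_cluster <- 0L                             # per cluster
  n_clusters <- 1L
  stack <- list(list(node = 2L * n - 1L, cluster = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    node <- fr$node; cl_id <- fr$cluster
    e <- node - n
    l <- left[e]; r <- right[e]
    sl <- sizes[l]; sr <- sizes[r]
    lam <- lam_of(height[e])
    kids <- list(list(nd = l, sz = sl), list(nd = r, sz = sr))
    big <- Filter(function(z) z$sz >= min_cluster_size, kids)
    small <- Filter(function(z) z$sz < min_cluster_size, kids)
    if (length(big) == 2L) {
      for (z in kids) {
        n_clusters <- n_clusters + 1L
        birth[n_clusters] <- lam
        parent_cluster[n_clusters] <- cl_id
        cp <- c(cp, cl_id); cc <- c(cc, n_clusters)
        cl <- c(cl, lam); cs <- c(cs, z$sz)
        if (z$nd > n)
          stack[[length(stack) + 1L]] <- list(node = z$nd, cluster = n_clusters)
        else {  # size->min_cluster_size can't be a leaf, but keep safe
          cp <- c(cp, n_clusters); cc <- c(cc, -z$nd)
          cl <- c(cl, lam); cs <- c(cs, 1L)
        }
      }
    } else {
      for (z in small) {
        pts <- leaves_under(z$nd)
        cp <- c(cp, rep(cl_id, length(pts))); cc <- c(cc, -pts)
        cl <- c(cl, rep(lam, length(pts))); cs <- c(cs, rep(1L, length(pts)))
      }
      for (z in big) {
        if (z$nd > n)
          stack[[length(stack) + 1L]] <- list(node = z$nd, cluster = cl_id)
        else {
          cp <- c(cp, cl_id); cc <- c(cc, -z$nd)
          cl <- c(cl, lam); cs <- c(cs, 1L)
        }
      }
    }
  }

  if (n_clusters == 1L) return(rep(0L, n))  # no split: lone root, all noise

  # excess-of-mass stability
  stab <- numeric(n_clusters)
  for (i in seq_along(cp))
    stab[cp[i]] <- stab[cp[i]] + (cl[i] - birth[cp[i]]) * cs[i]

  children_of <- split(seq_len(n_clusters)[-1],
                       factor(parent_cluster[-1], levels = seq_len(n_clusters)))
  selected <- logical(n_clusters)
  subtree_val <- stab
  descendants <- function(c0) {
    out <- integer(0); q <- children_of[[c0]]
    while (length(q)) {
      out <- c(out, q)
      q <- unlist(children_of[q], use.names = FALSE)
    }
    out
  }
  for (c0 in seq.int(n_clusters, 2L)) {
    kids <- children_of[[c0]]
    if (length(kids) == 0L) {
      selected[c0] <- TRUE
    } else {
      child_sum <- sum(subtree_val[kids])
      if (stab[c0] >= child_sum) {
        selected[c0] <- TRUE
        selected[descendants(c0)] <- FALSE
      } else {
        subtree_val[c0] <- child_sum
      }
    }
  }

  # epsilon merge of micro-clusters (Malzer & Baum)
  if (cluster_selection_epsilon > 0) {
    chosen <- integer(0)
    for (c0 in which(selected)) {
      if (1 / birth[c0] >= cluster_selection_epsilon) {
        chosen <- c(chosen, c0)
      } else {
        cur <- c0
        repeat {
          p <- parent_cluster[cur]
          if (p == 1L) break                      # never merge into the root
          if (1 / birth[p] >= cluster_selection_epsilon) { cur <- p; break }
          cur <- p
        }
        chosen <- c(chosen, cur)
      }
    }
    chosen <- unique(chosen)
    # keep an antichain: drop any cluster with a chosen ancestor
    has_anc <- vapply(chosen, function(c0) {
      p <- parent_cluster[c0]
      while (p != 0L) {
        if (p %in% chosen) return(TRUE)
        p <- parent_cluster[p]
      }
      FALSE
    }, logical(1))
    selected <- logical(n_clusters)
    selected[chosen[!has_anc]] <- TRUE
  }

  # labels: a point belongs to the selected ancestor of the cluster it fell
  # out of; points falling out above the selected antichain are noise
  point_parent <- integer(n)
  point_parent[-cc[cc < 0]] <- cp[cc < 0]
  labels <- integer(n)
  sel_ids <- which(selected)
  for (p in seq_len(n)) {
    c0 <- point_parent[p]
    while (c0 != 0L && !selected[c0]) c0 <- parent_cluster[c0]
    labels[p] <- if (c0 != 0L) match(c0, sel_ids) else 0L
  }
  # renumber clusters by first member point for determinism
  seen <- unique(labels[labels > 0L])
  labels[labels > 0L] <- match(labels[labels > 0L], seen)
  labels
}
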