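# Per-iteration 2-D embedding: PCA pre-reduction plus a t-SNE schedule whose
# exaggeration, learning rates and stopping rule adapt to the number of
# un-binned contigs (NUC).

#' Early exaggeration factor for a pool of NUC un-binned contigs
#'
#' EX = NUC x 2.5e-4, clamped to \[4, 100\]: exaggeration grows with dataset
#' size so that global structure forms before local refinement.
#'
#' @param nuc number of un-binned contigs entering the embedding.
#' @return exaggeration factor in \[4, 100\].
#' @export
early_exaggeration <- function(nuc) {
  stopifnot(nuc >= 1)
  pmin(100, pmax(4, nuc * 2.5e-4))
}

#' Learning rates for the early-exaggeration and main phases
#'
#' LR_EX = max(2, NUC / EX) and LR = max(200, min(64000, NUC x 0.1)).
#'
#' @param nuc number of un-binned contigs.
#' @param ex early exaggeration factor (see [early_exaggeration()]).
#' @return named numeric vector `c(lr_ex = ..., lr = ...)`.
#' @export
learning_rates <- function(nuc, ex) {
  stopifnot(ex > 0)
  c(lr_ex = pmax(2, nuc / ex), lr = pmax(200, pmin(64000, nuc * 0.1)))
}

#' Multi-scale perplexity pair for a binning iteration
#'
#' The small scale starts at 10 and grows by 2 per iteration (cap 20); the
#' large starts at 100 and grows by 5 (cap 130). Two scales balance local
#' versus global structure in the embedding.
#'
#' @param iteration 0-based binning iteration index.
#' @return numeric vector `c(small, large)`.
#' @export
perplexity_pair <- function(iteration) {
  stopifnot(iteration >= 0)
  c(small = pmin(20, 10 + 2 * iteration), large = pmin(130, 100 + 5 * iteration))
}

#' KLD plateau stopping rule
#'
#' Checked every 250 optimization iterations: stop when the decrease in
#' Kullback-Leibler divergence since the last checkpoint falls below 1% of
#' the current divergence (strictly).
#'
#' @param kld current KL divergence.
#' @param kld_diff change since the previous checkpoint.
#' @return logical.
#' @export
should_stop <- function(kld, kld_diff) {
  stopifnot(kld >= 0)
  kld_diff < kld * 0.01
}

#' PCA pre-reduction of the feature matrix
#'
#' Keeps the smallest number of principal components explaining at least 75%
#' of the variance, capped at 75 components. Inputs already at or below the
#' target dimensionality pass through unchanged.
#'
#' @param x numeric matrix (rows = contigs).
#' @param var_target fraction of variance to retain (default 0.75).
#' @param max_dims component cap (default 75).
#' @return numeric matrix of PCA scores (or `x` itself if passed through).
#' @export
pca_reduce <- function(x, var_target = 0.75, max_dims = 75L) {
  if (nrow(x) < 2L) stop("need at least 2 rows to embed")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) return(x[, 1, drop = FALSE] * 0)
  cum <- cumsum(v) / sum(v)
  ncomp <- min(which(cum >= var_target)[1], max_dims, length(v))
  if (ncol(x) <= ncomp) return(x)
  pc$x[, seq_len(ncomp), drop = FALSE]
}

#' Embedding parameters for one binning iteration
#'
#' Bundles the NUC-derived schedule. When the pool is too small to support
#' the large perplexity (NUC < 3 x large), both perplexities are shrunk
#' proportionally so that the large one equals (NUC - 1) / 3, with a
#' warning.
#'
#' @param nuc number of un-binned contigs.
#' @param iteration 0-based binning iteration.
#' @param seed integer seed for the embedding initialization.
#' @return list of class `embedding_params`.
#' @export
embedding_params <- function(nuc, iteration = 0L, seed = 0L) {
  ex <- early_exaggeration(nuc)
  lr <- learning_rates(nuc, ex)
  perp <- perplexity_pair(iteration)
  if (nuc < 3 * perp["large"]) {
    shrink <- ((nuc - 1) / 3) / perp["large"]
    perp <- pmax(2, perp * shrink)
    warning("pool of ", nuc, " contigs too small for the multi-scale ",
            "perplexities; shrunk to (", round(perp["small"], 1), ", ",
            round(perp["large"], 1), ")")
  }
  structure(list(nuc = nuc, ex = ex, lr_ex = unname(lr["lr_ex"]),
                 lr = unname(lr["lr"]), perplexities = unname(perp),
                 metric = "manhattan", seed = as.integer(seed)),
            class = "embedding_params")
}

#' Embed a feature matrix in 2-D
#'
#' PCA pre-reduction followed by exact t-SNE with a multi-scale Gaussian
#' kernel at the two scheduled perplexities, Manhattan input metric, an
#' early-exaggeration phase (factor EX, learning rate LR_EX) and a main
#' phase (learning rate LR). Both phases stop when the KL divergence,
#' checked every 250 iterations, plateaus per [should_stop()]. Deterministic
#' under a fixed seed.
#'
#' @param features a `feature_matrix` from [build_features()] or a plain
#'   numeric matrix.
#' @param params an [embedding_params()] object.
#' @param max_iter_early,max_iter_main per-phase iteration caps.
#' @return numeric matrix (n x 2) of embedding coordinates, rownames
#'   preserved; attribute `kld_trace` holds the checkpoint divergences.
#' @export
embed_contigs <- function(features, params,
                          max_iter_early = 1000L, max_iter_main = 1500L) {
  x <- if (inherits(features, "feature_matrix")) features$x else features
  stopifnot(is.matrix(x), all(is.finite(x)))
  red <- pca_reduce(x)
  n <- nrow(red)
  y0 <- withr_seed(params$seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  res <- .tsne_core(red, y0,
                    params$perplexities[1], params$perplexities[2],
                    params$ex, params$lr_ex, params$lr,
                    250L, as.integer(max_iter_early),
                    as.integer(max_iter_main), 0.01)
  y <- res$Y
  rownames(y) <- rownames(x)
  colnames(y) <- c("dim1", "dim2")
  attr(y, "kld_trace") <- res$kld
  y
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
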