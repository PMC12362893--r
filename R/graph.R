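#' Bank of Gaussian radial basis kernels
#'
#' Turns one log-ratio scalar x into a dense feature vector with components
#' \deqn{RBF(x, c_k) = \exp(-(x - c_k)^2 / r_k^2).}
#' Pairwise log-ratios of counts concentrate near 0 and rarely leave
#' \[-6, 6\], so the default 8 centers are unevenly spaced over that range,
#' denser near the origin. By default each kernel's width r_k is half the
#' gap to its nearest neighboring center; a scalar `width_r` overrides all
#' of them.
#'
#' @param centers strictly increasing numeric vector of kernel centers
#'   within \[-6, 6\].
#' @param width_r optional positive scalar (or vector, one per kernel)
#'   overriding the per-kernel widths.
#' @return an `RbfBank`: list with `centers` and `width_r` (vector, one per
#'   kernel).
#' @export
rbf_bank <- function(centers = c(-6, -3, -1.5, -0.5, 0.5, 1.5, 3, 6),
                     width_r = NULL) {
  centers <- as.numeric(centers)
  if (is.unsorted(centers, strictly = TRUE))
    stop("centers must be strictly increasing")
  if (min(centers) < -6 || max(centers) > 6)
    stop("centers must lie within [-6, 6]")
  if (is.null(width_r)) {
    gaps <- diff(centers)
    width_r <- pmin(c(gaps, Inf), c(Inf, gaps)) / 2
  } else {
    width_r <- rep_len(as.numeric(width_r), length(centers))
  }
  if (any(width_r <= 0)) stop("kernel widths must be positive")
  structure(list(centers = centers, width_r = width_r), class = "RbfBank")
}

#' Vectorize scalars through an RBF bank
#'
#' @param x numeric scalar or vector of log-ratio values.
#' @param bank an [rbf_bank()].
#' @return matrix with `length(x)` rows and one column per kernel; every
#'   entry lies in (0, 1\], and the k-th component equals 1 exactly when
#'   `x == centers[k]`.
#' @export
rbf_featurize <- function(x, bank) {
  stopifnot(inherits(bank, "RbfBank"))
  d <- outer(as.numeric(x), bank$centers, "-")
  exp(-(d * d) * rep(1 / bank$width_r^2, each = nrow(d)))
}

#' Add positive Gaussian noise to a count vector
#'
#' Raw counts are mostly zero, so log-ratios would hit log(0). A Gaussian
#' perturbation with positive mean (default 0.5) keeps every entry strictly
#' positive — it doubles as stochastic regularization during training. The
#' result is floored at a small positive value so the log is always defined.
#'
#' @param counts_row nonnegative numeric vector (one cell's counts).
#' @param noise_mean mean of the Gaussian noise; default 0.5.
#' @param noise_sd standard deviation; default 0.1.
#' @param seed optional integer; when given, draws are made reproducible
#'   without disturbing the caller's RNG stream.
#' @return strictly positive numeric vector of the same length.
#' @export
add_count_noise <- function(counts_row, noise_mean = 0.5, noise_sd = 0.1,
                            seed = NULL) {
  stopifnot(noise_mean > 0, noise_sd >= 0)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  noisy <- counts_row + stats::rnorm(length(counts_row), noise_mean,
                                     noise_sd)
  pmax(noisy, 1e-6)
}

#' Pairwise log-ratio matrix of one cell
#'
#' Entry \[j, k\] is log(X_j) - log(X_k) (natural log): how strongly gene j
#' dominates gene k within this cell. The matrix is antisymmetric with a
#' zero diagonal, and is invariant to rescaling the whole count vector —
#' the property that makes log-ratio features stable across platforms.
#'
#' @param noisy_row strictly positive numeric vector of length m.
#' @return m x m numeric matrix.
#' @export
logratio_matrix <- function(noisy_row) {
  if (any(noisy_row <= 0))
    stop("domain error: log-ratios need strictly positive entries ",
         "(apply add_count_noise first)")
  lg <- log(noisy_row)
  outer(lg, lg, "-")
}

#' Prune a dense log-ratio graph to fixed out-degree
#'
#' For each source gene j, keeps directed edges to the `k_top` genes with
#' the largest and the `k_bottom` genes with the smallest values of
#' L\[j, .\] — the most extreme dominance relations, 16 outgoing edges per
#' node by default. The self-ratio (always 0) is excluded. Ties are broken
#' by gene index ascending; a target appearing in both extremes (possible
#' only for near-constant rows) is kept once. With m <= k_top + k_bottom
#' genes, all m - 1 neighbors are kept.
#'
#' @param L m x m log-ratio matrix.
#' @param k_top,k_bottom number of largest / smallest targets per source
#'   (defaults 8 and 8).
#' @return integer matrix with columns `src`, `tgt` (1-based indices).
#' @export
prune_edges <- function(L, k_top = 8, k_bottom = 8) {
  m <- nrow(L)
  stopifnot(ncol(L) == m)
  if (m < 2) return(matrix(integer(0), 0, 2,
                           dimnames = list(NULL, c("src", "tgt"))))
  keep_all <- m <= k_top + k_bottom
  res <- vector("list", m)
  idx <- seq_len(m)
  for (j in idx) {
    others <- idx[-j]
    if (keep_all) {
      tgt <- others
    } else {
      vals <- L[j, others]
      # secondary key = gene index ascending on ties
      lo <- order(vals, others)[seq_len(k_bottom)]
      hi <- order(-vals, others)[seq_len(k_top)]
      tgt <- unique(others[c(lo, hi)])
    }
    res[[j]] <- cbind(src = j, tgt = sort(tgt))
  }
  do.call(rbind, res)
}

#' Build the graph representation of one cell
#'
#' Composes the full per-cell pipeline: positive Gaussian noise on the raw
#' counts, the pairwise log-ratio matrix, extreme-value edge pruning, and
#' RBF vectorization of each surviving edge's log-ratio. Node features are
#' looked up from the embedding table.
#'
#' @param x an [expression_matrix()] (typically after [qc_filter()] and
#'   [select_hvgs()]).
#' @param cell_index 1-based row index of the cell.
#' @param embeddings a [node_embeddings()] table covering `x$gene_ids`.
#' @param bank an [rbf_bank()].
#' @param seed integer seed for the noise draw (fixed seed => bit-identical
#'   graph).
#' @param noise_mean,noise_sd passed to [add_count_noise()]; `noise_sd = 0`
#'   with `noise_mean` the only offset makes the graph deterministic given
#'   the counts.
#' @param k_top,k_bottom passed to [prune_edges()].
#' @return a `CellGraph`: list with `gene_ids`, `node_features`
#'   (genes x node_dim), `edges` (E x 2 integer matrix, columns src/tgt),
#'   `edge_logratio` (length E), `edge_features` (E x n_kernels).
#' @export
build_cell_graph <- function(x, cell_index, embeddings, bank = rbf_bank(),
                             seed = NULL, noise_mean = 0.5, noise_sd = 0.1,
                             k_top = 8, k_bottom = 8) {
  stopifnot(inherits(x, "ExpressionMatrix"),
            inherits(embeddings, "NodeEmbeddingTable"))
  row <- x$counts[cell_index, ]
  noisy <- add_count_noise(row, noise_mean, noise_sd, seed = seed)
  L <- logratio_matrix(noisy)
  edges <- prune_edges(L, k_top, k_bottom)
  lr <- L[edges]
  hit <- match(x$gene_ids, rownames(embeddings$vectors))
  if (anyNA(hit)) stop("embedding table does not cover all graph genes")
  structure(list(gene_ids = x$gene_ids,
                 node_features = embeddings$vectors[hit, , drop = FALSE],
                 edges = edges,
                 edge_logratio = lr,
                 edge_features = rbf_featurize(lr, bank)),
            class = "CellGraph")
}

#' @export
print.CellGraph <- function(x, ...) {
  cat(sprintf("CellGraph: %d gene nodes (dim %d), %d directed edges (%d RBF kernels)\n",
              length(x$gene_ids), ncol(x$node_features), nrow(x$edges),
              ncol(x$edge_features)))
  invisible(x)
}

# Fast pruning path for log-ratio matrices: because L[j, k] = lg[j] -
# lg[k], the within-row ranking of targets is a single global ordering of
# lg shared by all source nodes — one sort replaces m of them. Equivalent
# to prune_edges(outer(lg, lg, "-")) (property-tested).
prune_edges_logratio <- function(lg, k_top = 8, k_bottom = 8) {
  m <- length(lg)
  idx <- seq_len(m)
  if (m < 2) return(matrix(integer(0), 0, 2,
                           dimnames = list(NULL, c("src", "tgt"))))
  if (m <= k_top + k_bottom) {
    out <- cbind(src = rep(idx, each = m - 1),
                 tgt = unlist(lapply(idx, function(j) idx[-j])))
    return(out)
  }
  # smallest L[j,.] targets have the largest lg; ties -> index ascending
  ord_desc <- order(-lg, idx)[seq_len(k_bottom + 1)]
  ord_asc <- order(lg, idx)[seq_len(k_top + 1)]
  # sources outside both extreme lists share one common target set
  common <- sort(unique(c(ord_desc[seq_len(k_bottom)],
                          ord_asc[seq_len(k_top)])))
  special <- unique(c(ord_desc, ord_asc))
  res <- rep(list(common), m)
  for (j in special) {
    lo <- ord_desc[ord_desc != j][seq_len(k_bottom)]
    hi <- ord_asc[ord_asc != j][seq_len(k_top)]
    res[[j]] <- sort(unique(c(lo, hi)))
  }
  deg <- lengths(res)
  cbind(src = rep(idx, deg), tgt = unlist(res))
}

# Save/restore .Random.seed so seeded helpers do not disturb callers.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
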