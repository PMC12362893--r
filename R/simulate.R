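#' Specification of a synthetic ordered-state experiment
#'
#' Describes a negative-binomial scRNA-seq-like experiment along a sequence
#' of cell states. Informative genes shift their mean log-expression
#' monotonically (up or down, random sign per gene) by `drift_per_state`
#' between adjacent states, so that neighboring states overlap — the
#' structure an ordinal classifier is designed for. The remaining genes are
#' state-independent noise. Per-cell library-size factors and mean-dependent
#' dropout (zero inflation) emulate the technical variation of real data.
#'
#' The default geometry mirrors a six-timepoint embryonic epiblast series,
#' including its class imbalance (one state near 2% of cells), with 1200
#' cells, 300 genes of which 60 are informative, drift 0.8 (strong
#' separation), dispersion 0.3, library factors U(0.75, 1.25), and
#' moderate dropout.
#'
#' @param n_states number of ordered states.
#' @param cells_per_state integer vector of cells per state; default: 1200
#'   cells split by the epiblast imbalance pattern
#'   (17.0/6.4/37.9/31.1/6.9/1.7% for 6 states, equal split otherwise).
#' @param n_genes,n_informative_genes total and state-informative gene
#'   counts.
#' @param drift_per_state mean log-expression shift between adjacent
#'   states for informative genes.
#' @param dispersion negative-binomial overdispersion (size = 1 /
#'   dispersion).
#' @param library_size_range range of the uniform per-cell library factor.
#' @param dropout_logit_slope dropout-intensity parameter: a gene with
#'   scaled mean mu is zeroed with probability
#'   `plogis(dropout_logit_slope - log1p(mu))`, so larger values give
#'   sparser matrices.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_states = 6, cells_per_state = NULL,
                           n_genes = 300, n_informative_genes = 60,
                           drift_per_state = 0.8, dispersion = 0.3,
                           library_size_range = c(0.75, 1.25),
                           dropout_logit_slope = 1, seed = 1) {
  if (is.null(cells_per_state)) {
    props <- if (n_states == 6)
      c(0.1701, 0.0640, 0.3789, 0.3106, 0.0691, 0.0173)
    else rep(1 / n_states, n_states)
    cells_per_state <- pmax(1L, round(1200 * props))
  }
  stopifnot(n_states >= 2, length(cells_per_state) == n_states,
            n_informative_genes <= n_genes, drift_per_state >= 0,
            dispersion > 0, length(library_size_range) == 2,
            all(library_size_range > 0))
  structure(as.list(environment())[c("n_states", "cells_per_state",
                                     "n_genes", "n_informative_genes",
                                     "drift_per_state", "dispersion",
                                     "library_size_range",
                                     "dropout_logit_slope", "seed")],
            class = "synthetic_spec")
}

#' Simulate an ordered-state count matrix
#'
#' Draws counts gene by gene: informative gene g in state s has mean
#' \eqn{\mu_{g,s} = \exp(\beta_{g0} + \beta_{g1}\, d\, (s - (K+1)/2))}
#' with baseline \eqn{\beta_{g0} \sim N(\log 2, 0.5^2)}, random sign
#' \eqn{\beta_{g1} \in \{-1, +1\}} and drift d (centering the state index
#' keeps the overall expression scale stable across K). Counts are negative
#' binomial with the spec's dispersion, scaled by the cell's library
#' factor, then zero-inflated with mean-dependent dropout.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `expression` ([expression_matrix()]), `states`
#'   ([ordinal_states()]), and `truth` (per-gene baseline, sign,
#'   informative index set, per-cell library factors and state means).
#' @export
simulate_states <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  K <- spec$n_states
  G <- spec$n_genes
  n <- sum(spec$cells_per_state)
  y <- rep(seq_len(K), spec$cells_per_state)
  gene_ids <- sprintf("gene%04d", seq_len(G))
  cell_ids <- sprintf("cell%05d", seq_len(n))
  states <- paste0("S", seq_len(K))

  info <- sort(sample.int(G, spec$n_informative_genes))
  beta0 <- stats::rnorm(G, log(2), 0.5)
  beta1 <- numeric(G)
  beta1[info] <- sample(c(-1, 1), length(info), replace = TRUE)
  s_center <- seq_len(K) - (K + 1) / 2
  # K x G matrix of state means
  mu <- exp(outer(s_center * spec$drift_per_state, beta1) +
              matrix(beta0, K, G, byrow = TRUE))
  lib <- stats::runif(n, spec$library_size_range[1],
                      spec$library_size_range[2])
  cell_mu <- mu[y, , drop = FALSE] * lib
  counts <- matrix(stats::rnbinom(n * G, mu = cell_mu,
                                  size = 1 / spec$dispersion), n, G)
  p_drop <- stats::plogis(spec$dropout_logit_slope - log1p(cell_mu))
  counts[matrix(stats::runif(n * G), n, G) < p_drop] <- 0L
  dimnames(counts) <- list(cell_ids, gene_ids)

  labels <- stats::setNames(states[y], cell_ids)
  list(expression = expression_matrix(counts),
       states = ordinal_states(states, labels),
       truth = list(informative = info, beta0 = beta0, beta1 = beta1,
                    state_means = mu, library_factors = lib,
                    state_index = stats::setNames(y, cell_ids)))
}

#' Build a synthetic distributed gene-embedding table
#'
#' Random unit-norm vectors standing in for a co-expression embedding such
#' as Gene2vec. Optionally, genes named in `blocks` share a correlated
#' direction (common component weight `sqrt(informative_block_corr)`), so
#' co-regulated informative genes look related in embedding space — the
#' signal the dual-layer architecture exploits. This table is synthetic:
#' it encodes no real biology.
#'
#' @param gene_ids character vector of genes to cover.
#' @param dim embedding dimension (default 200).
#' @param informative_block_corr within-block correlation in \[0, 1)
#'   (default 0 — fully independent vectors).
#' @param blocks list of gene-id (or index) vectors, one correlated block
#'   each; ignored when `informative_block_corr` is 0.
#' @param seed integer seed.
#' @return a [node_embeddings()] table in `distributed` mode.
#' @export
make_fixture_embeddings <- function(gene_ids, dim = 200,
                                    informative_block_corr = 0,
                                    blocks = NULL, seed = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  gene_ids <- as.character(gene_ids)
  G <- length(gene_ids)
  v <- matrix(stats::rnorm(G * dim), G, dim)
  if (informative_block_corr > 0 && length(blocks)) {
    for (blk in blocks) {
      idx <- if (is.character(blk)) match(blk, gene_ids) else as.integer(blk)
      idx <- idx[!is.na(idx)]
      if (length(idx) < 2) next
      u <- stats::rnorm(dim)
      v[idx, ] <- sqrt(informative_block_corr) *
        matrix(u, length(idx), dim, byrow = TRUE) +
        sqrt(1 - informative_block_corr) * v[idx, , drop = FALSE]
    }
  }
  v <- v / sqrt(rowSums(v^2))
  rownames(v) <- gene_ids
  node_embeddings("distributed", gene_ids, table = v)
}
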