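# Shared fixtures and oracles: everything is generated in code at test time.

# independent brute-force implementation of the conditional-subset masked
# binary cross-entropy loss (plain log/sigmoid arithmetic)
naive_ordinal_loss <- function(logits, labels) {
  K <- ncol(logits) + 1
  total <- 0
  n_terms <- 0
  for (j in seq_len(K - 1)) {
    Sj <- which(labels > j - 1)
    n_terms <- n_terms + length(Sj)
    for (i in Sj) {
      s <- 1 / (1 + exp(-logits[i, j]))
      total <- total + if (labels[i] > j) log(s) else log(1 - s)
    }
  }
  if (n_terms == 0) 0 else -total / n_terms
}


# tiny labelled count matrix (deterministic)
tiny_expression <- function(n_cells = 12, n_genes = 10, seed = 42) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, 3), n_cells, n_genes)
  expression_matrix(counts,
                    cell_ids = sprintf("c%02d", seq_len(n_cells)),
                    gene_ids = sprintf("g%02d", seq_len(n_genes)))
}

# small ordered-state simulation used across training tests
small_sim <- function(seed = 7, n_states = 3, cells = 40, genes = 30,
                      drift = 1.2) {
  simulate_states(synthetic_spec(
    n_states = n_states, cells_per_state = rep(cells, n_states),
    n_genes = genes, n_informative_genes = max(6, genes %/% 3),
    drift_per_state = drift, dispersion = 0.2, seed = seed))
}

# fast training configuration for unit tests (overrides win)
tiny_config <- function(...) {
  defaults <- list(n_hvg = 20, hidden = 8, mlp_hidden = c(16, 8),
                   batch_size = 8, max_epochs = 3,
                   early_stopping_patience = 10, learning_rate = 5e-3,
                   val_fraction = 0, seed = 1)
  do.call(training_config, utils::modifyList(defaults, list(...)))
}

# block-correlated fixture embeddings matching a simulation's truth
sim_embeddings <- function(sim, dim = 24, corr = 0.6, seed = 99) {
  info <- sim$truth$informative
  make_fixture_embeddings(sim$expression$gene_ids, dim = dim,
    informative_block_corr = corr,
    blocks = list(info[sim$truth$beta1[info] > 0],
                  info[sim$truth$beta1[info] < 0]),
    seed = seed)
}

# exact optimal-transport cost between equal-size uniform point clouds via
# the Hungarian assignment in scipy (independent oracle; python and scipy
# are part of the toolchain this package is developed and tested on)
exact_ot_oracle <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(list(P = P, Q = Q), f, digits = NA, matrix = "rowmajor")
  script <- sprintf("
import json, numpy as np
from scipy.optimize import linear_sum_assignment
d = json.load(open(%s))
P = np.array(d['P']); Q = np.array(d['Q'])
C = np.linalg.norm(P[:, None, :] - Q[None, :, :], axis=2)
r, c = linear_sum_assignment(C)
print(repr(float(C[r, c].mean())))
", deparse(f))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  as.numeric(out[length(out)])
}
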