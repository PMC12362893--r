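make_graph <- function(m = 20, seed = 1, mode = "one_hot", dim = NULL) {
  x <- tiny_expression(n_cells = 2, n_genes = m, seed = seed)
  emb <- node_embeddings(mode, x$gene_ids, dim = dim)
  build_cell_graph(x, 1, emb, rbf_bank(), seed = seed)
}

small_params <- function(m = 20, n_states = 3, hidden = 6, seed = 2,
                         node_dim = m, head = "ordinal") {
  mpnn_params(mpnn_config(node_dim = node_dim, n_states = n_states,
                          hidden = hidden, mlp_hidden = c(10, 6),
                          head = head), seed = seed)
}

test_that("input alignment projects features to the hidden width", {
  g <- make_graph(20)
  p <- small_params(20)
  st <- align_inputs(g, p)
  expect_equal(dim(st$node_states), c(20, 6))
  expect_equal(nrow(st$edge_states), nrow(g$edges))
  expect_length(st$cell_embedding, 6)
  # zeros mode: every initial node state equals the aligner bias
  gz <- make_graph(20, mode = "zeros", dim = 4)
  pz <- small_params(20, node_dim = 4)
  sz <- align_inputs(gz, pz)
  expect_true(all(abs(sweep(sz$node_states, 2, sz$node_states[1, ])) <
                    1e-12))
  expect_error(align_inputs(gz, p), "node_dim")
})

test_that("encoding runs exactly three rounds and pools by mean", {
  g <- make_graph(15, seed = 3)
  p <- small_params(15)
  enc <- encode(g, p)
  manual <- align_inputs(g, p)
  for (r in 1:3) manual <- encoder_round(manual, g, p, round = r)
  expect_equal(enc$node_states, manual$node_states)
  expect_equal(enc$cell_embedding, colMeans(enc$node_states))
  # deterministic with dropout off
  expect_identical(encode(g, p), enc)
})

test_that("encoder and predictions are equivariant under gene permutation", {
  set.seed(8)
  m <- 30
  x <- tiny_expression(n_cells = 1, n_genes = m, seed = 8)
  emb <- node_embeddings("one_hot", x$gene_ids)
  g <- build_cell_graph(x, 1, emb, rbf_bank(), seed = 4)
  perm <- sample(m)
  # permuted graph: same cell, genes relabeled, embeddings permuted rows
  gp <- g
  gp$gene_ids <- g$gene_ids[perm]
  gp$node_features <- g$node_features[perm, ]
  inv <- order(perm)
  gp$edges <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
  # hidden states must permute identically; params must not favor node
  # identity, so use a node_dim-independent filler (zeros) for weights
  p <- small_params(m, node_dim = m)
  # align on permuted one-hot features maps node i to row of its gene, so
  # comparing requires permuting weights too; instead check with the
  # original features attached to permuted structure:
  gp$node_features <- g$node_features[perm, ]
  e1 <- encode(g, p)
  e2 <- encode(gp, p)
  expect_equal(e2$node_states[inv[seq_len(m)], ], e1$node_states,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(e2$cell_embedding, e1$cell_embedding, tolerance = 1e-6)
})

test_that("a graph with no edges passes node states through the residual", {
  x <- tiny_expression(n_cells = 1, n_genes = 1, seed = 2)
  emb <- node_embeddings("zeros", x$gene_ids, dim = 3)
  g <- build_cell_graph(x, 1, emb, rbf_bank(), seed = 1)
  expect_equal(nrow(g$edges), 0)
  p <- small_params(1, node_dim = 3)
  st <- align_inputs(g, p)
  enc <- encoder_round(st, g, p)
  # layer normalization of the untouched state
  ln <- scstate:::op_layernorm(NULL, st$node_states,
                               p$params[["enc1.ln.gamma"]],
                               p$params[["enc1.ln.beta"]])
  expect_equal(enc$node_states, ln)
})

test_that("decoding reconstructs per-gene vectors in the embedding dimension", {
  g <- make_graph(12, seed = 5)
  p <- small_params(12)
  enc <- encode(g, p)
  Q <- decode(enc, g, p)
  expect_equal(dim(Q), c(12, 12))   # one_hot: embedding dim = n_genes
  expect_identical(decode(enc, g, p), Q)
  # decoding leaves the encoded edge states untouched
  expect_identical(enc$edge_states, encode(g, p)$edge_states)
})

test_that("fused edge-perceptron kernel matches the pure-R composition", {
  set.seed(13)
  N <- 12; E <- 40; hd <- 5; ed <- 4
  h <- matrix(rnorm(N * hd), N)
  e <- matrix(rnorm(E * ed), E)
  edges <- cbind(sample(N, E, TRUE), sample(N, E, TRUE))
  P <- scstate:::add_mlp(list(), "m", 2 * hd + ed, 9, 7, 5)
  ref <- scstate:::mlp3_fwd(NULL, cbind(h[edges[, 1], ], h[edges[, 2], ], e),
                            P, "m")
  fused <- scstate:::op_edge_mlp(NULL, h, e, edges, P, "m")
  expect_equal(fused, ref, tolerance = 1e-5)
})

test_that("backpropagated gradients match finite differences", {
  sim <- small_sim(seed = 31, cells = 4, genes = 12)
  cfg <- tiny_config(n_hvg = 12, mask_rate = 0.25)
  emb <- node_embeddings("one_hot", sim$expression$gene_ids)
  arch <- scstate:::mpnn_config(node_dim = emb$dim, n_states = 3,
                                hidden = 6, mlp_hidden = c(10, 6))
  mp <- mpnn_params(arch, seed = 7)
  set.seed(2)
  graphs <- lapply(1:4, function(i)
    build_cell_graph(sim$expression, i, emb, rbf_bank(), seed = i))
  labels <- sim$states$label_of_cell[1:4]
  batch <- scstate:::assemble_batch(graphs)

  loss_at <- function(params) {
    out <- scstate:::mpnn_forward(batch, params, arch)
    scstate:::op_ordinal_loss(NULL, out$logits, labels)
  }
  tape <- scstate:::ad_tape()
  out <- scstate:::mpnn_forward(batch, mp$params, arch, tape = tape)
  loss <- scstate:::op_ordinal_loss(tape, out$logits, labels)
  scstate:::ad_backward(tape, loss)
  grads <- lapply(out$leaves, function(l) l$grad)

  set.seed(77)
  # decoder parameters and the last round's edge-update perceptron feed
  # only the reconstruction path, not this ordinal-only objective
  enc_params <- grep("^dec\\.|^enc3\\.edge", names(mp$params),
                     value = TRUE, invert = TRUE)
  for (nm in sample(enc_params, 10)) {
    expect_false(is.null(grads[[nm]]), info = nm)
    k <- sample(length(mp$params[[nm]]), 1)
    eps <- 1e-4
    pp <- mp$params; pp[[nm]][k] <- pp[[nm]][k] + eps
    pm <- mp$params; pm[[nm]][k] <- pm[[nm]][k] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    rel <- abs(num - grads[[nm]][k]) /
      max(0.01, abs(num), abs(grads[[nm]][k]))
    expect_lt(rel, 5e-2, label = paste("grad mismatch at", nm, k))
  }
})

test_that("every parameter tensor receives gradient from the combined loss", {
  sim <- small_sim(seed = 32, cells = 4, genes = 12)
  cfg <- tiny_config(n_hvg = 12, mask_rate = 0.25, lambda_rec = 0.1)
  emb <- node_embeddings("one_hot", sim$expression$gene_ids)
  arch <- scstate:::mpnn_config(node_dim = emb$dim, n_states = 3,
                                hidden = 6, mlp_hidden = c(10, 6))
  mp <- mpnn_params(arch, seed = 3)
  set.seed(5)
  graphs <- lapply(1:6, function(i)
    build_cell_graph(sim$expression, i, emb, rbf_bank(), seed = i))
  batch <- scstate:::assemble_batch(graphs)
  step <- scstate:::train_step(batch, sim$states$label_of_cell[1:6],
                               mp$params, arch, cfg)
  expect_true(all(!vapply(step$grads, is.null, TRUE)))
  nonzero <- vapply(step$grads, function(g) any(g != 0), TRUE)
  expect_true(all(nonzero))
})

test_that("layer normalization gradients are exact", {
  set.seed(4)
  x <- matrix(rnorm(18), 6)
  gam <- runif(3, 0.5, 1.5); bet <- rnorm(3)
  R <- matrix(rnorm(18), 6)
  tape <- scstate:::ad_tape()
  xn <- scstate:::ad_leaf(tape, x)
  gn <- scstate:::ad_leaf(tape, gam)
  bn <- scstate:::ad_leaf(tape, bet)
  y <- scstate:::op_layernorm(tape, xn, gn, bn)
  loss <- scstate:::ad_record(tape, sum(scstate:::vof(y) * R), list(y),
                              function(g) list(g * R))
  scstate:::ad_backward(tape, loss)
  f <- function(x2, g2, b2)
    sum(scstate:::op_layernorm(NULL, x2, g2, b2) * R)
  for (k in sample(length(x), 4)) {
    xp <- x; xp[k] <- xp[k] + 1e-6
    xm <- x; xm[k] <- xm[k] - 1e-6
    expect_equal(xn$grad[k], (f(xp, gam, bet) - f(xm, gam, bet)) / 2e-6,
                 tolerance = 1e-4)
  }
  for (k in 1:3) {
    gp <- gam; gp[k] <- gp[k] + 1e-6
    gm <- gam; gm[k] <- gm[k] - 1e-6
    expect_equal(gn$grad[k], (f(x, gp, bet) - f(x, gm, bet)) / 2e-6,
                 tolerance = 1e-4)
  }
})
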