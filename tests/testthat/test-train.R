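test_that("node masking zeroes the stated fraction and is reproducible", {
  x <- tiny_expression(n_cells = 1, n_genes = 100)
  emb <- node_embeddings("one_hot", x$gene_ids)
  g <- build_cell_graph(x, 1, emb, rbf_bank(), seed = 1)
  m0 <- mask_nodes(g, 0, seed = 2)
  expect_identical(m0$graph, g)
  expect_length(m0$mask, 0)
  m <- mask_nodes(g, 0.15, seed = 2)
  expect_length(m$mask, 15)
  expect_true(all(m$graph$node_features[m$mask, ] == 0))
  expect_identical(m$targets, g$node_features[m$mask, ])
  expect_identical(mask_nodes(g, 0.15, seed = 2)$mask, m$mask)
})

test_that("zero-epoch training returns an initialized model with empty log", {
  sim <- small_sim(seed = 18, cells = 6, genes = 20)
  fit <- train_scstate(sim$expression, sim$states, "one_hot",
                       tiny_config(max_epochs = 0))
  expect_s3_class(fit, "scstate_model")
  expect_null(fit$log)
  pred <- predict(fit, sim$expression)
  expect_equal(nrow(pred), nrow(sim$expression$counts))
  expect_true(all(pred$q %in% 1:3))
})

test_that("training reduces the loss on an easy ordered problem", {
  losses <- sapply(1:3, function(sd) {
    sim <- small_sim(seed = sd, cells = 25, genes = 30)
    fit <- train_scstate(sim$expression, sim$states,
                         sim_embeddings(sim, dim = 12),
                         tiny_config(max_epochs = 5, seed = sd,
                                     learning_rate = 5e-3))
    c(first = fit$log$train_loss[1], last = tail(fit$log$train_loss, 1))
  })
  expect_lt(median(losses["last", ]), median(losses["first", ]))
})

test_that("prediction is deterministic and permutation invariant", {
  sim <- small_sim(seed = 23, cells = 10, genes = 24)
  fit <- train_scstate(sim$expression, sim$states, "one_hot",
                       tiny_config(max_epochs = 2, n_hvg = 16))
  p1 <- predict(fit, sim$expression)
  p2 <- predict(fit, sim$expression)
  expect_identical(p1, p2)
  # permuting the query's gene columns must not change predictions
  perm <- sample(ncol(sim$expression$counts))
  xp <- expression_matrix(sim$expression$counts[, perm])
  p3 <- predict(fit, xp)
  expect_identical(p1$q, p3$q)
  expect_equal(p1[, grep("^p_", names(p1))], p3[, grep("^p_", names(p3))])
})

test_that("query gene mismatches are imputed or rejected", {
  sim <- small_sim(seed = 29, cells = 10, genes = 24)
  fit <- train_scstate(sim$expression, sim$states, "one_hot",
                       tiny_config(max_epochs = 1, n_hvg = 16))
  # drop one model gene -> zero imputation with a warning
  drop1 <- setdiff(sim$expression$gene_ids, fit$gene_ids[1])
  xq <- expression_matrix(sim$expression$counts[, drop1])
  expect_warning(pq <- predict(fit, xq), "imputed")
  expect_equal(nrow(pq), 30)
  # <50% overlap -> hard error
  few <- expression_matrix(
    sim$expression$counts[, fit$gene_ids[1:4], drop = FALSE],
    gene_ids = fit$gene_ids[1:4])
  expect_error(predict(fit, few), "reference")
})

test_that("training rejects degenerate label sets", {
  sim <- small_sim(seed = 40, cells = 6, genes = 20)
  labs <- sim$states
  labs$label_of_cell[] <- 1L
  expect_error(train_scstate(sim$expression, labs, "one_hot",
                             tiny_config()), "empty-state")
})

test_that("cross-validation partitions every cell once per repeat", {
  sim <- small_sim(seed = 44, cells = 15, genes = 20)
  cv <- cross_validate(sim$expression, sim$states, "one_hot",
                       tiny_config(max_epochs = 1, n_hvg = 16),
                       folds = 2, repeats = 1)
  expect_equal(nrow(cv), 2)
  expect_equal(sum(cv$n_test), 45)          # every cell in one test fold
  conf <- attr(cv, "confusion")
  expect_equal(sum(conf), 45)
  expect_equal(attr(cv, "summary")[["mean"]], mean(cv$accuracy))
  per <- attr(cv, "per_state")
  expect_equal(nrow(per), 3)
  expect_true(all(per$precision >= 0 & per$precision <= 1))
})

test_that("the softmax ablation head trains and predicts", {
  sim <- small_sim(seed = 51, cells = 12, genes = 20)
  fit <- train_scstate(sim$expression, sim$states, "one_hot",
                       tiny_config(max_epochs = 2, n_hvg = 16,
                                   head = "softmax"))
  p <- predict(fit, sim$expression)
  expect_true(all(p$q %in% 1:3))
  probs <- as.matrix(p[, paste0("p_", fit$states)])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(p)), tolerance = 1e-8)
})

test_that("threshold calibration stores a tuned decision threshold", {
  sim <- small_sim(seed = 52, cells = 20, genes = 24)
  fit <- train_scstate(sim$expression, sim$states,
                       sim_embeddings(sim, dim = 12),
                       tiny_config(max_epochs = 3,
                                   calibrate_threshold = TRUE))
  expect_true(fit$cfg$threshold >= 0.3 && fit$cfg$threshold <= 0.7)
})
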