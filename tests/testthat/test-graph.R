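test_that("rbf_featurize matches the Gaussian kernel closed form", {
  bank <- rbf_bank(width_r = 2)
  f <- rbf_featurize(bank$centers[3], bank)
  expect_equal(f[1, 3], 1)                       # x = c -> exactly 1
  f2 <- rbf_featurize(bank$centers[3] + 2, bank) # x = c + r -> exp(-1)
  expect_equal(f2[1, 3], exp(-1))
  # independent scalar recomputation at x = 0
  x <- 0
  expected <- exp(-(x - bank$centers)^2 / bank$width_r^2)
  expect_equal(as.numeric(rbf_featurize(x, bank)), expected)
  expect_true(all(rbf_featurize(rnorm(20), rbf_bank()) > 0))
  expect_true(all(rbf_featurize(rnorm(20), rbf_bank()) <= 1))
})

test_that("rbf bank validates its centers", {
  expect_error(rbf_bank(c(0, -1)), "increasing")
  expect_error(rbf_bank(c(-7, 0)), "within")
  b <- rbf_bank()           # default: per-kernel width = half nearest gap
  expect_equal(b$width_r[4], 0.5)   # centers -0.5, 0.5, 1.5
  expect_equal(b$width_r[1], 1.5)   # centers -6, -3
})

test_that("count noise keeps entries positive and is seed-reproducible", {
  z <- rep(0, 5)
  expect_equal(add_count_noise(z, noise_sd = 0), rep(0.5, 5))
  a <- add_count_noise(1:5, seed = 11)
  b <- add_count_noise(1:5, seed = 11)
  expect_identical(a, b)
  expect_true(all(add_count_noise(rep(0, 1000), seed = 1) > 0))
  # Monte-Carlo mean of the added noise
  n <- 1e5
  raw <- rpois(n, 2)
  noisy <- add_count_noise(raw, noise_mean = 0.5, noise_sd = 0.1, seed = 2)
  se <- 0.1 / sqrt(n)
  expect_lt(abs(mean(noisy - raw) - 0.5), 3 * se)
})

test_that("log-ratio matrix matches its closed form and is antisymmetric", {
  L <- logratio_matrix(c(exp(1), 1))
  expect_equal(L, matrix(c(0, -1, 1, 0), 2), ignore_attr = TRUE)
  set.seed(4)
  v <- runif(5, 0.1, 9)
  L5 <- logratio_matrix(v)
  oracle <- matrix(0, 5, 5)
  for (j in 1:5) for (k in 1:5) oracle[j, k] <- log(v[j]) - log(v[k])
  expect_equal(L5, oracle)
  expect_equal(L5, -t(L5))
  expect_equal(diag(L5), rep(0, 5))
  expect_error(logratio_matrix(c(1, 0)), "positive")
})

test_that("pruning keeps the 8 largest and 8 smallest ratios per source", {
  set.seed(9)
  v <- add_count_noise(rpois(17, 4), seed = 1)
  ed <- prune_edges(logratio_matrix(v))
  deg <- table(ed[, "src"])
  expect_true(all(deg == 16))                  # m = 17 -> out-degree 16
  expect_true(all(ed[, "src"] != ed[, "tgt"])) # no self-edges

  ed5 <- prune_edges(logratio_matrix(add_count_noise(rpois(5, 4), seed = 2)))
  expect_true(all(table(ed5[, "src"]) == 4))   # small-graph fallback

  # full-sort oracle on a random 30-gene profile
  L <- logratio_matrix(add_count_noise(rpois(30, 4), seed = 3))
  ed30 <- prune_edges(L)
  for (j in c(1, 13, 30)) {
    others <- setdiff(1:30, j)
    o <- others[order(L[j, others])]
    expected <- sort(c(head(o, 8), tail(o, 8)))
    expect_equal(sort(ed30[ed30[, "src"] == j, "tgt"]), expected)
  }
})

test_that("the one-sort log-ratio pruning path equals the generic path", {
  set.seed(21)
  for (m in c(5, 16, 17, 18, 25, 48)) {
    lg <- log(add_count_noise(rpois(m, 3), seed = m))
    a <- prune_edges(outer(lg, lg, "-"))
    b <- scstate:::prune_edges_logratio(lg)
    expect_identical(unname(a), unname(b))
  }
})

test_that("build_cell_graph composes noise, ratios, pruning and RBF", {
  x <- tiny_expression(n_cells = 3, n_genes = 20)
  emb <- node_embeddings("one_hot", x$gene_ids)
  bank <- rbf_bank()
  g <- build_cell_graph(x, 2, emb, bank, seed = 5)
  expect_equal(g$node_features, diag(20), ignore_attr = TRUE)
  g2 <- build_cell_graph(x, 2, emb, bank, seed = 5)
  expect_identical(g, g2)                      # same seed -> bit-identical
  # every stored edge feature equals rbf_featurize of its stored log-ratio
  expect_equal(g$edge_features,
               rbf_featurize(g$edge_logratio, bank))
  expect_true(all(table(g$edges[, "src"]) == 16))
})

test_that("log-ratios are invariant to rescaling the count vector", {
  set.seed(2)
  v <- rpois(15, 5) + 0.5                 # noise-free positive profile
  expect_equal(logratio_matrix(v), logratio_matrix(7.3 * v))
  e1 <- prune_edges(logratio_matrix(v))
  e2 <- prune_edges(logratio_matrix(7.3 * v))
  expect_identical(e1, e2)                # topology unchanged too
})

test_that("embedding tables honor their mode invariants", {
  ids <- paste0("g", 1:6)
  z <- node_embeddings("zeros", ids, dim = 5)
  expect_true(all(z$vectors == 0))
  oh <- node_embeddings("one_hot", ids)
  expect_equal(oh$vectors, diag(6), ignore_attr = TRUE)
  expect_equal(oh$dim, 6L)
  tab <- matrix(rnorm(12), 4, dimnames = list(paste0("g", 1:4), NULL))
  expect_warning(d <- node_embeddings("distributed", ids, table = tab),
                 "missing")
  expect_equal(d$vectors["g2", ], tab["g2", ], ignore_attr = TRUE)
  expect_true(all(d$vectors[c("g5", "g6"), ] == 0))
})

test_that("gene-embedding tables read the headerless TSV layout", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TP53\t0.1\t-0.2\t0.3", "MYC\t1\t2\t3"), f)
  m <- read_gene_embeddings(f)
  expect_equal(dim(m), c(2, 3))
  expect_equal(m["MYC", ], c(1, 2, 3), ignore_attr = TRUE)
})
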