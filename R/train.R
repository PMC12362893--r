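#' Training configuration
#'
#' Collects every tunable of the training pipeline with its default:
#' minibatches of 16 cells, at most 28 epochs with early stopping on the
#' validation ordinal loss (patience 5, 10% stratified validation split),
#' 15% node masking for the reconstruction objective, loss weights
#' lambda_ord = 1 and lambda_rec = 0.1, Adam with learning rate 1e-3,
#' decision threshold 0.5, 600 highly variable genes, and count noise
#' N(0.5, 0.1^2).
#'
#' `hidden` and `mlp_hidden` size the network ([mpnn_config()]); the
#' published-scale defaults (128, c(384, 128)) suit full references, while
#' small studies train well with e.g. `hidden = 24, mlp_hidden = c(72, 24)`.
#'
#' @param batch_size cells per minibatch.
#' @param max_epochs maximum training epochs.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping.
#' @param mask_rate fraction of gene nodes masked per graph in \[0, 1).
#' @param lambda_ord,lambda_rec loss weights (lambda1, lambda2).
#' @param learning_rate Adam step size.
#' @param seed master seed for initialization, splits, noise and masking.
#' @param threshold ordinal decision threshold.
#' @param n_hvg number of highly variable genes.
#' @param noise_mean,noise_sd Gaussian count-noise parameters.
#' @param val_fraction fraction of cells held out for early stopping.
#' @param max_train_cells cap on the number of training cells actually
#'   used per run (stratified subsample; `Inf` = use all). Large
#'   references train well below full size; the cap bounds runtime.
#' @param lr_decay multiplicative learning-rate decay per epoch (1 = a
#'   constant rate).
#' @param warmup_epochs epochs over which the learning rate ramps linearly
#'   from 1/10th to its full value (0 = no warmup).
#' @param clip_norm global gradient-norm clip (Inf = off).
#' @param calibrate_threshold after training, tune the single decision
#'   threshold of the ordinal decoder on the training cells (grid search
#'   maximizing training accuracy; the paper-style fixed value is kept
#'   when `FALSE`, the default). The calibrated value is stored in the
#'   model and used by `predict()`.
#' @param balance_alpha state-rebalancing strength in \[0, 1\]: each
#'   epoch's minibatches are drawn with replacement with weight
#'   `1 / n_state^balance_alpha`, oversampling rare states (0 = plain
#'   shuffling, the default).
#' @param monitor early-stopping/model-selection signal on the validation
#'   split: `"loss"` (ordinal loss, default) or `"accuracy"`.
#' @param hidden,mlp_hidden,dropout,head network architecture, see
#'   [mpnn_config()].
#' @param rbf_centers,rbf_width RBF bank, see [rbf_bank()].
#' @param k_top,k_bottom edges kept per node, see [prune_edges()].
#' @return a `training_config` list.
#' @export
training_config <- function(batch_size = 16, max_epochs = 28,
                            early_stopping_patience = 5, mask_rate = 0.15,
                            lambda_ord = 1, lambda_rec = 0.1,
                            learning_rate = 1e-3, seed = 1,
                            threshold = 0.5, n_hvg = 600, noise_mean = 0.5,
                            noise_sd = 0.1, val_fraction = 0.1,
                            max_train_cells = Inf, lr_decay = 1,
                            warmup_epochs = 0, clip_norm = Inf,
                            calibrate_threshold = FALSE,
                            balance_alpha = 0,
                            monitor = c("loss", "accuracy"),
                            hidden = 128, mlp_hidden = c(384, 128),
                            dropout = 0.1,
                            head = c("ordinal", "softmax"),
                            rbf_centers = c(-6, -3, -1.5, -0.5, 0.5, 1.5,
                                            3, 6),
                            rbf_width = NULL, k_top = 8, k_bottom = 8) {
  head <- match.arg(head)
  monitor <- match.arg(monitor)
  stopifnot(mask_rate >= 0, mask_rate < 1, batch_size >= 1,
            lambda_ord >= 0, lambda_rec >= 0, threshold > 0,
            threshold < 1)
  structure(as.list(environment()), class = "training_config")
}

#' Mask gene nodes of a cell graph
#'
#' Replaces a random `floor(mask_rate * n_genes)` subset of node-feature
#' rows with the zero vector and keeps the originals as reconstruction
#' targets — the masked-modeling objective the decoder is trained against.
#'
#' @param g a [build_cell_graph()] result.
#' @param mask_rate fraction in \[0, 1).
#' @param seed optional seed for a reproducible mask.
#' @return list with `graph` (masked copy), `mask` (integer node indices),
#'   `targets` (original feature rows of the masked nodes).
#' @export
mask_nodes <- function(g, mask_rate, seed = NULL) {
  stopifnot(mask_rate >= 0, mask_rate < 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  m <- length(g$gene_ids)
  k <- floor(mask_rate * m)
  mask <- if (k > 0) sort(sample.int(m, k)) else integer(0)
  targets <- g$node_features[mask, , drop = FALSE]
  g$node_features[mask, ] <- 0
  list(graph = g, mask = mask, targets = targets)
}

# resolve user-supplied embeddings (table object, mode name, or raw
# matrix) against a gene set
resolve_embeddings <- function(embeddings, gene_ids) {
  if (inherits(embeddings, "NodeEmbeddingTable"))
    return(node_embeddings(embeddings$mode, gene_ids,
                           dim = embeddings$dim,
                           table = if (embeddings$mode == "distributed")
                             embeddings$vectors))
  if (is.character(embeddings) && length(embeddings) == 1)
    return(node_embeddings(embeddings, gene_ids))
  if (is.matrix(embeddings))
    return(node_embeddings("distributed", gene_ids, table = embeddings))
  stop("embeddings must be a NodeEmbeddingTable, a mode name, or a matrix")
}

# edge construction for one count row against a fixed node-feature block;
# draws noise from the current RNG stream
fast_cell_graph <- function(row, node_features, gene_ids, bank, cfg) {
  noisy <- pmax(row + stats::rnorm(length(row), cfg$noise_mean,
                                   cfg$noise_sd), 1e-6)
  lg <- log(noisy)
  edges <- prune_edges_logratio(lg, cfg$k_top, cfg$k_bottom)
  lr <- lg[edges[, 1]] - lg[edges[, 2]]
  structure(list(gene_ids = gene_ids, node_features = node_features,
                 edges = edges, edge_logratio = lr,
                 edge_features = rbf_featurize(lr, bank)),
            class = "CellGraph")
}

build_graphs <- function(counts, rows, node_features, gene_ids, bank,
                         cfg) {
  lapply(rows, function(i)
    fast_cell_graph(counts[i, ], node_features, gene_ids, bank, cfg))
}

# Vectorized per-epoch graph construction for a set of cells: one noise
# draw for the whole block, per-cell pruning, and a single RBF call over
# every edge. Edges are stored cell-locally (1..m) with a pointer vector,
# so minibatches are cheap row slices.
epoch_graph_set <- function(counts, rows, bank, cfg) {
  n <- length(rows)
  m <- ncol(counts)
  noisy <- pmax(counts[rows, , drop = FALSE] +
                  stats::rnorm(n * m, cfg$noise_mean, cfg$noise_sd), 1e-6)
  LG <- log(noisy)
  src <- tgt <- vector("list", n)
  for (i in seq_len(n)) {
    ed <- prune_edges_logratio(LG[i, ], cfg$k_top, cfg$k_bottom)
    src[[i]] <- ed[, 1]
    tgt[[i]] <- ed[, 2]
  }
  cnt <- lengths(src)
  src <- unlist(src, use.names = FALSE)
  tgt <- unlist(tgt, use.names = FALSE)
  cell <- rep(seq_len(n), cnt)
  lr <- LG[cbind(cell, src)] - LG[cbind(cell, tgt)]
  list(src = src, tgt = tgt, cnt = cnt,
       start = cumsum(c(1L, cnt[-n])),
       edge_feat = rbf_featurize(lr, bank), m = m, n_cells = n)
}

# assemble the disjoint-union batch for cells `bi` of a graph set;
# NFrep is the node-feature block pre-repeated to >= length(bi) copies
batch_from_set <- function(gs, bi, NFrep) {
  B <- length(bi)
  m <- gs$m
  sel <- sequence(gs$cnt[bi], from = gs$start[bi])
  off <- (rep(seq_len(B), gs$cnt[bi]) - 1L) * m
  list(node_feat = NFrep[seq_len(B * m), , drop = FALSE],
       edges = cbind(gs$src[sel] + off, gs$tgt[sel] + off),
       edge_feat = gs$edge_feat[sel, , drop = FALSE],
       node_graph = rep(seq_len(B), each = m),
       n_nodes = B * m, n_graphs = B)
}

# mask nodes across an assembled batch; returns batch + mask bookkeeping
apply_batch_mask <- function(batch, mask_rate) {
  m <- batch$n_nodes / batch$n_graphs
  k <- floor(mask_rate * m)
  if (k == 0)
    return(c(batch, list(mask_rows = integer(0),
                         targets = batch$node_feat[0, , drop = FALSE],
                         mask_groups = integer(0))))
  mask_rows <- unlist(lapply(seq_len(batch$n_graphs), function(b)
    (b - 1L) * m + sample.int(m, k)))
  targets <- batch$node_feat[mask_rows, , drop = FALSE]
  batch$node_feat[mask_rows, ] <- 0
  c(batch, list(mask_rows = mask_rows, targets = targets,
                mask_groups = rep(seq_len(batch$n_graphs), each = k)))
}

# forward + loss for one assembled training batch
train_step <- function(batch, labels, params, arch, cfg) {
  batch <- apply_batch_mask(batch, cfg$mask_rate)
  tape <- ad_tape()
  out <- mpnn_forward(batch, params, arch, tape = tape, train = TRUE)
  ord <- if (arch$head == "ordinal")
    op_ordinal_loss(tape, out$logits, labels)
  else op_softmax_ce(tape, out$logits, labels)
  use_rec <- cfg$lambda_rec > 0 && length(batch$mask_rows) > 0
  if (use_rec) {
    qm <- op_gather(tape, out$recon, batch$mask_rows)
    # few masked points per graph: capped Sinkhorn iterations suffice for
    # a training signal
    rec <- op_recon_loss(tape, qm, batch$targets, batch$mask_groups,
                         batch$n_graphs, max_iter = 60, tol = 1e-5)
    total <- op_axpby(tape, ord, cfg$lambda_ord, rec, cfg$lambda_rec)
  } else {
    rec <- NULL
    total <- op_axpby(tape, ord, cfg$lambda_ord, ord, 0)
  }
  ad_backward(tape, total)
  grads <- lapply(out$leaves, function(l) l$grad)
  list(loss = vof(total), ord = vof(ord),
       rec = if (use_rec) vof(rec) else 0, grads = grads)
}

# tape-free forward over many graphs in chunks; returns logits matrix and
# cell embeddings
infer_forward <- function(graphs, params, arch, chunk = 64) {
  n <- length(graphs)
  logits <- NULL
  embs <- NULL
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    out <- mpnn_forward(assemble_batch(graphs[idx]), params, arch)
    logits <- rbind(logits, out$logits)
    embs <- rbind(embs, out$emb)
  }
  list(logits = logits, emb = embs)
}

# tape-free forward over a whole graph set in chunks
infer_forward_set <- function(gs, params, arch, NFrep, chunk = 64) {
  n <- gs$n_cells
  logits <- NULL
  embs <- NULL
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    out <- mpnn_forward(batch_from_set(gs, idx, NFrep), params, arch)
    logits <- rbind(logits, out$logits)
    embs <- rbind(embs, out$emb)
  }
  list(logits = logits, emb = embs)
}

logits_to_state <- function(logits, arch, threshold) {
  if (arch$head == "ordinal") decode_state(logits, threshold)
  else max.col(logits, ties.method = "first")
}

#' Train a sequential cell-state classifier
#'
#' End-to-end training on a labelled reference: selects highly variable
#' genes, builds per-cell log-ratio graphs (count noise redrawn every
#' epoch), and optimizes the combined ordinal + reconstruction objective by
#' minibatch Adam, with early stopping on a stratified validation split's
#' ordinal loss. Fully reproducible given `cfg$seed`.
#'
#' @param x an [expression_matrix()] of raw counts (run [qc_filter()]
#'   first for real data).
#' @param labels an [ordinal_states()] object covering the training cells.
#' @param embeddings node filler: a [node_embeddings()] table, a mode name
#'   (`"zeros"`, `"one_hot"`), or a distributed embedding matrix with gene
#'   rownames.
#' @param cfg a [training_config()].
#' @return an object of class `scstate_model`: model parameters, the
#'   architecture, the training gene list and state order, the embedding
#'   table, the RBF bank, and a per-epoch `log` data.frame (train loss,
#'   validation ordinal loss and accuracy). With `max_epochs = 0` the
#'   initialized, untrained model is returned with an empty log.
#' @export
train_scstate <- function(x, labels, embeddings = "one_hot",
                          cfg = training_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"),
            inherits(labels, "OrdinalStateSet"),
            inherits(cfg, "training_config"))
  cells <- intersect(x$cell_ids, names(labels$label_of_cell))
  if (length(cells) < 4) stop("too few labelled cells present in the matrix")
  K <- length(labels$states)
  y <- labels$label_of_cell[cells]
  counts_state <- tabulate(y, K)
  if (any(counts_state == 0))
    stop("empty-state labels: state(s) ",
         paste(labels$states[counts_state == 0], collapse = ", "),
         " have no cells")
  if (sum(counts_state >= 2) < 2)
    stop("need at least 2 states with at least 2 cells each")

  xx <- expression_matrix(x$counts[cells, , drop = FALSE])
  if (ncol(xx$counts) > cfg$n_hvg) xx <- select_hvgs(xx, cfg$n_hvg)
  genes <- xx$gene_ids
  emb <- resolve_embeddings(embeddings, genes)
  bank <- rbf_bank(cfg$rbf_centers, cfg$rbf_width)
  arch <- mpnn_config(node_dim = emb$dim, n_states = K,
                      n_kernels = length(bank$centers),
                      hidden = cfg$hidden, mlp_hidden = cfg$mlp_hidden,
                      dropout = cfg$dropout, head = cfg$head)
  model_params <- mpnn_params(arch, seed = cfg$seed)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  n <- length(cells)
  val_idx <- integer(0)
  if (cfg$val_fraction > 0 && cfg$max_epochs > 0) {
    for (s in seq_len(K)) {
      cs <- which(y == s)
      if (length(cs) >= 2)
        val_idx <- c(val_idx, sample(cs, max(1, floor(cfg$val_fraction *
                                                       length(cs)))))
    }
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) > cfg$max_train_cells) {
    keep <- unlist(lapply(seq_len(K), function(s) {
      cs <- train_idx[y[train_idx] == s]
      target <- max(2L, round(cfg$max_train_cells * length(cs) /
                                length(train_idx)))
      if (length(cs) > target) sample(cs, target) else cs
    }))
    train_idx <- sort(keep)
  }
  NF <- emb$vectors[genes, , drop = FALSE]

  # validation graphs are fixed (one noise draw) for a stable stopping
  # signal
  NFrep <- NF[rep(seq_along(genes), cfg$batch_size + 63), , drop = FALSE]
  val_set <- if (length(val_idx))
    epoch_graph_set(xx$counts, val_idx, bank, cfg)

  params <- model_params$params
  opt <- adam_state(params)
  log_rows <- list()
  best <- list(loss = Inf, params = params)
  patience_left <- cfg$early_stopping_patience

  if (cfg$max_epochs > 0) for (epoch in seq_len(cfg$max_epochs)) {
    tr_set <- epoch_graph_set(xx$counts, train_idx, bank, cfg)
    ord_y <- y[train_idx]
    perm <- if (cfg$balance_alpha > 0) {
      w <- 1 / tabulate(ord_y, K)[ord_y]^cfg$balance_alpha
      sample.int(length(train_idx), replace = TRUE, prob = w)
    } else sample.int(length(train_idx))
    ep_loss <- 0; ep_ord <- 0; ep_rec <- 0; nb <- 0
    for (start in seq(1, length(perm), by = cfg$batch_size)) {
      bi <- perm[start:min(start + cfg$batch_size - 1, length(perm))]
      step <- train_step(batch_from_set(tr_set, bi, NFrep), ord_y[bi],
                         params, arch, cfg)
      grads <- step$grads
      if (is.finite(cfg$clip_norm)) {
        gn <- sqrt(sum(vapply(grads, function(g)
          if (is.null(g)) 0 else sum(g^2), 0)))
        if (gn > cfg$clip_norm)
          grads <- lapply(grads, function(g)
            if (is.null(g)) NULL else g * (cfg$clip_norm / gn))
      }
      lr_now <- cfg$learning_rate * cfg$lr_decay^(epoch - 1)
      if (cfg$warmup_epochs > 0 && epoch <= cfg$warmup_epochs)
        lr_now <- lr_now * (0.1 + 0.9 * epoch / cfg$warmup_epochs)
      params <- adam_step(params, grads, opt, lr = lr_now)
      if (!is.finite(step$loss))
        stop("NaN/Inf loss at epoch ", epoch,
             "; try a lower learning_rate or larger noise_sd")
      ep_loss <- ep_loss + step$loss; ep_ord <- ep_ord + step$ord
      ep_rec <- ep_rec + step$rec; nb <- nb + 1
    }
    vl <- NA_real_; va <- NA_real_
    if (length(val_idx)) {
      iv <- infer_forward_set(val_set, params, arch, NFrep)
      vl <- if (arch$head == "ordinal")
        ordinal_loss(iv$logits, y[val_idx])
      else op_softmax_ce(NULL, iv$logits, y[val_idx])
      va <- mean(logits_to_state(iv$logits, arch, cfg$threshold) ==
                   y[val_idx])
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    train_loss = ep_loss / nb,
                                    train_ord = ep_ord / nb,
                                    train_rec = ep_rec / nb,
                                    val_loss = vl, val_accuracy = va)
    signal <- if (!length(val_idx)) ep_loss / nb
              else if (cfg$monitor == "accuracy") -va else vl
    if (signal < best$loss - 1e-6) {
      best <- list(loss = signal, params = params)
      patience_left <- cfg$early_stopping_patience
    } else {
      patience_left <- patience_left - 1
      if (patience_left <= 0) break
    }
  }
  if (cfg$max_epochs == 0) best$params <- params

  model_params$params <- best$params
  model <- structure(list(params = model_params, arch = arch, cfg = cfg,
                          gene_ids = genes, states = labels$states,
                          embeddings = emb, bank = bank,
                          log = do.call(rbind, log_rows)),
                     class = "scstate_model")
  if (cfg$calibrate_threshold && arch$head == "ordinal" &&
      cfg$max_epochs > 0) {
    cal_idx <- if (n > 500) sort(sample.int(n, 500)) else seq_len(n)
    gs <- epoch_graph_set(xx$counts, cal_idx, bank, cfg)
    fw <- infer_forward_set(gs, model$params$params, arch, NFrep)
    cum <- stats::plogis(fw$logits)
    if (K > 2) cum <- t(apply(cum, 1, cumprod))
    grid <- seq(0.30, 0.70, by = 0.025)
    accs <- vapply(grid, function(t)
      mean((1L + rowSums(cum > t)) == y[cal_idx]), 0)
    # ties break toward the conventional 0.5
    model$cfg$threshold <- grid[order(-accs, abs(grid - 0.5))][1]
  }
  model
}

#' @export
print.scstate_model <- function(x, ...) {
  cat(sprintf("scstate_model: %d genes, %d states (%s), %s head\n",
              length(x$gene_ids), length(x$states),
              paste(x$states, collapse = " < "), x$arch$head))
  if (!is.null(x$log))
    cat(sprintf("  trained %d epochs; final val accuracy %.3f\n",
                nrow(x$log), utils::tail(x$log$val_accuracy, 1)))
  invisible(x)
}

#' Predict cell states for a query matrix
#'
#' Maps the query onto the model's training gene list (genes absent from
#' the query are imputed as zero counts with a warning; below 50% overlap
#' is an error, signalling a reference mismatch), rebuilds cell graphs with
#' a fixed inference noise seed, and runs the network deterministically
#' (dropout off).
#'
#' @param object a trained [train_scstate()] model.
#' @param x an [expression_matrix()] of query cells.
#' @param seed inference noise seed (default 0); the same input and seed
#'   always give identical output.
#' @param n_draws number of count-noise draws to average the predicted
#'   logits over (default 1; a few draws smooth out the stochastic edge
#'   topology at a proportional cost).
#' @param threshold override of the ordinal decision threshold.
#' @param ... unused.
#' @return a data.frame with one row per cell: `cell_id`,
#'   `predicted_state` (name), `q` (decoded index), the cumulative
#'   probabilities `p_gt_<state>` and the per-state masses `p_<state>`.
#'   The cell embeddings are attached as `attr(, "embedding")`.
#' @export
predict.scstate_model <- function(object, x, seed = 0, n_draws = 1,
                                  threshold = object$cfg$threshold, ...) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  hit <- match(object$gene_ids, x$gene_ids)
  overlap <- mean(!is.na(hit))
  if (overlap < 0.5)
    stop(sprintf(paste0("only %.0f%% of the model's genes are present in ",
                        "the query; the reference does not match"),
                 100 * overlap))
  if (anyNA(hit))
    warning(sum(is.na(hit)), " model gene(s) missing from the query; ",
            "imputed as zero counts")
  n <- nrow(x$counts)
  counts <- matrix(0, n, length(object$gene_ids))
  counts[, !is.na(hit)] <- x$counts[, hit[!is.na(hit)], drop = FALSE]

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(object$cfg$seed + seed)
  NF <- object$embeddings$vectors[object$gene_ids, , drop = FALSE]
  NFrep <- NF[rep(seq_len(nrow(NF)), 64), , drop = FALSE]
  out <- NULL
  for (d in seq_len(n_draws)) {
    gs <- epoch_graph_set(counts, seq_len(n), object$bank, object$cfg)
    o <- infer_forward_set(gs, object$params$params, object$arch, NFrep)
    out <- if (is.null(out)) o
           else list(logits = out$logits + o$logits,
                     emb = out$emb + o$emb)
  }
  out$logits <- out$logits / n_draws
  out$emb <- out$emb / n_draws
  q <- logits_to_state(out$logits, object$arch, threshold)
  res <- data.frame(cell_id = x$cell_ids,
                    predicted_state = object$states[q], q = q,
                    stringsAsFactors = FALSE)
  if (object$arch$head == "ordinal") {
    K <- length(object$states)
    cum <- stats::plogis(out$logits)
    if (K > 2) cum <- t(apply(cum, 1, cumprod))  # chain rule
    colnames(cum) <- paste0("p_gt_", object$states[-K])
    masses <- t(apply(out$logits, 1, function(z)
      cumulative_probabilities(z)$state_probs))
    colnames(masses) <- paste0("p_", object$states)
    res <- cbind(res, cum, masses)
  } else {
    p <- exp(out$logits - apply(out$logits, 1, max))
    p <- p / rowSums(p)
    colnames(p) <- paste0("p_", object$states)
    res <- cbind(res, p)
  }
  attr(res, "embedding") <- out$emb
  res
}

#' Stratified repeated cross-validation
#'
#' Splits the labelled cells into `folds` state-stratified folds, `repeats`
#' times; each fold is held out once per repeat while the rest trains a
#' fresh model. Every cell appears in exactly one test fold per repeat.
#'
#' @inheritParams train_scstate
#' @param folds,repeats cross-validation geometry (defaults 5 and 5).
#' @param n_draws inference noise draws averaged per prediction (see
#'   [predict.scstate_model()]).
#' @return data.frame with one row per (repeat, fold): `accuracy` and
#'   `n_test`. Attributes: `confusion` (summed true x predicted matrix),
#'   `per_state` (precision/recall per state from the pooled confusion),
#'   `summary` (mean and sd of fold accuracies).
#' @export
cross_validate <- function(x, labels, embeddings = "one_hot",
                           cfg = training_config(), folds = 5,
                           repeats = 5, n_draws = 1) {
  cells <- intersect(x$cell_ids, names(labels$label_of_cell))
  y <- labels$label_of_cell[cells]
  K <- length(labels$states)
  confusion <- matrix(0, K, K,
                      dimnames = list(truth = labels$states,
                                      predicted = labels$states))
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    old <- get_rng_state()
    set.seed(cfg$seed + 7919 * rep_i)
    fold_of <- integer(length(cells))
    for (s in seq_len(K)) {
      cs <- sample(which(y == s))
      if (length(cs) < folds)
        warning("state ", labels$states[s], " has fewer cells (",
                length(cs), ") than folds; some folds miss it")
      fold_of[cs] <- rep_len(seq_len(folds), length(cs))
    }
    restore_rng_state(old)
    for (f in seq_len(folds)) {
      test <- cells[fold_of == f]
      train <- cells[fold_of != f]
      cfg_f <- cfg
      cfg_f$seed <- cfg$seed + 7919 * rep_i + 31 * f
      fit <- train_scstate(
        expression_matrix(x$counts[train, , drop = FALSE]),
        labels, embeddings, cfg_f)
      pred <- predict(fit,
                      expression_matrix(x$counts[test, , drop = FALSE]),
                      n_draws = n_draws)
      truth <- y[test]
      acc <- mean(pred$q == truth)
      confusion <- confusion + table(factor(truth, seq_len(K)),
                                     factor(pred$q, seq_len(K)))
      rows[[length(rows) + 1]] <- data.frame(rep = rep_i, fold = f,
                                             accuracy = acc,
                                             n_test = length(test))
    }
  }
  res <- do.call(rbind, rows)
  prec <- diag(confusion) / pmax(colSums(confusion), 1)
  rec <- diag(confusion) / pmax(rowSums(confusion), 1)
  attr(res, "confusion") <- confusion
  attr(res, "per_state") <- data.frame(state = labels$states,
                                       precision = as.numeric(prec),
                                       recall = as.numeric(rec))
  attr(res, "summary") <- c(mean = mean(res$accuracy),
                            sd = stats::sd(res$accuracy))
  res
}
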