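# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape records operation nodes in creation order (a valid topological
# order of the computation DAG); ad_backward() walks it in reverse and
# accumulates gradients into the leaf nodes. Every op also works with
# `tape = NULL`, in which case plain matrices flow through — the same
# forward code serves both training and deterministic inference.
#
# Internal: not exported. Gradient correctness is pinned by
# finite-difference tests.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

is_adnode <- function(x) inherits(x, "adnode")

vof <- function(x) if (is_adnode(x)) x$val else x

ad_record <- function(tape, val, parents, bw) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  class(nd) <- "adnode"
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_leaf <- function(tape, val) ad_record(tape, val, list(), NULL)

ad_accum <- function(node, g) {
  if (!is_adnode(node)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node. Leaf gradients are then read off
# the leaves' $grad fields (NULL means the leaf did not influence the loss).
ad_backward <- function(tape, loss) {
  stopifnot(is_adnode(loss))
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    for (k in seq_along(nd$parents)) ad_accum(nd$parents[[k]], gs[[k]])
  }
  invisible(NULL)
}

# ---- ops -------------------------------------------------------------

# y = x %*% W + b (b broadcast over rows; b may be NULL)
op_lin <- function(tape, x, W, b = NULL) {
  xv <- vof(x); Wv <- vof(W)
  val <- xv %*% Wv
  # rep(b, each = n) lays the row-broadcast out column-major, no aperm
  if (!is.null(b)) val <- val + rep(vof(b), each = nrow(val))
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(x, W, b),
            function(g) list(g %*% t(Wv), crossprod(xv, g),
                             if (is.null(b)) NULL else colSums(g)))
}

op_relu <- function(tape, x) {
  xv <- vof(x)
  val <- xv * (xv > 0)
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(x), function(g) list(g * (xv > 0)))
}

op_add <- function(tape, a, b) {
  val <- vof(a) + vof(b)
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(a, b), function(g) list(g, g))
}

op_cbind3 <- function(tape, a, b, c) {
  av <- vof(a); bv <- vof(b); cv <- vof(c)
  val <- cbind(av, bv, cv)
  if (is.null(tape)) return(val)
  na <- ncol(av); nb <- ncol(bv); nc <- ncol(cv)
  ad_record(tape, val, list(a, b, c), function(g)
    list(g[, seq_len(na), drop = FALSE],
         g[, na + seq_len(nb), drop = FALSE],
         g[, na + nb + seq_len(nc), drop = FALSE]))
}

op_gather <- function(tape, x, idx) {
  xv <- vof(x)
  val <- xv[idx, , drop = FALSE]
  if (is.null(tape)) return(val)
  n <- nrow(xv)
  ad_record(tape, val, list(x), function(g) list(scatter_add_rows(g, idx, n)))
}

# rows of x summed into n output rows at positions idx
op_scatter <- function(tape, x, idx, n) {
  xv <- vof(x)
  val <- scatter_add_rows(xv, idx, n)
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(x), function(g) list(g[idx, , drop = FALSE]))
}

scatter_add_rows <- function(x, idx, n) .scatter_rows(x, idx, n)

# Fused edge-message perceptron: msg = MLP3(concat(h[src], h[tgt], e)).
# Forward and backward run in compiled code (the training hot path); the
# composition op_gather + op_cbind3 + mlp3_fwd is the equivalent reference
# implementation used to pin this op down in tests. Each perceptron
# instance owns a C++ cache slot; the backward for a slot must run before
# that slot's next forward (the tape guarantees this ordering).
mlp_slot_names <- c("enc1.msg", "enc1.edge", "enc2.msg", "enc2.edge",
                    "enc3.msg", "enc3.edge", "dec.msg")

op_edge_mlp <- function(tape, h, e, edges, P, name,
                        slot = match(name, mlp_slot_names,
                                     nomatch = 16L) - 1L) {
  W1 <- P[[paste0(name, ".l1.W")]]; b1 <- P[[paste0(name, ".l1.b")]]
  W2 <- P[[paste0(name, ".l2.W")]]; b2 <- P[[paste0(name, ".l2.b")]]
  W3 <- P[[paste0(name, ".l3.W")]]; b3 <- P[[paste0(name, ".l3.b")]]
  hv <- vof(h)
  out <- .edge_mlp_fwd(slot, hv, vof(e), edges[, 1], edges[, 2], vof(W1),
                       vof(b1), vof(W2), vof(b2), vof(W3), vof(b3))
  if (is.null(tape)) return(out)
  n_nodes <- nrow(hv); hd <- ncol(hv)
  ad_record(tape, out, list(h, e, W1, b1, W2, b2, W3, b3),
            function(g) {
    bw <- .edge_mlp_bwd(slot, g, edges[, 1], edges[, 2],
                        vof(W1), vof(W2), vof(W3), n_nodes, hd)
    list(bw$dh, bw$de, bw$dW1, as.numeric(bw$db1), bw$dW2,
         as.numeric(bw$db2), bw$dW3, as.numeric(bw$db3))
  })
}

# row-wise layer normalization with learned gain/offset vectors
op_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- vof(x); gv <- as.numeric(vof(gamma)); bv <- as.numeric(vof(beta))
  n <- nrow(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  val <- xhat * rep(gv, each = n) + rep(bv, each = n)
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- g * rep(gv, each = n)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
    list(dx, dgamma, dbeta)
  })
}

# inverted dropout; identity when rate <= 0 (inference)
op_dropout <- function(tape, x, rate) {
  if (rate <= 0) return(x)
  xv <- vof(x)
  keep <- matrix(stats::runif(length(xv)) >= rate, nrow(xv)) / (1 - rate)
  val <- xv * keep
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(x), function(g) list(g * keep))
}

# mean over rows within each group (graph-level pooling)
op_group_mean <- function(tape, x, groups, n_groups) {
  xv <- vof(x)
  cnt <- tabulate(groups, n_groups)
  val <- scatter_add_rows(xv, groups, n_groups) / cnt
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(x),
            function(g) list((g / cnt)[groups, , drop = FALSE]))
}

# ---- loss nodes (scalar outputs, analytic gradients) -----------------

# Ordinal loss (conditional-subset masked BCE); z: B x (K-1) logits.
op_ordinal_loss <- function(tape, z, labels) {
  zv <- vof(z)
  K1 <- ncol(zv)
  jj <- seq_len(K1)
  mask <- outer(labels, jj, function(y, j) y > j - 1L)
  target <- outer(labels, jj, ">")
  total <- sum(mask)
  sig <- stats::plogis(zv)
  ll <- ifelse(target, -softplus(-zv), -softplus(zv))
  val <- if (total == 0) 0 else -sum(ll[mask]) / total
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(z), function(g) {
    if (total == 0) return(list(zv * 0))
    list(g * (-(target - sig) * mask) / total)
  })
}

# Plain softmax cross-entropy (multiclass ablation head); z: B x K.
op_softmax_ce <- function(tape, z, labels) {
  zv <- vof(z)
  zs <- zv - apply(zv, 1, max)
  ez <- exp(zs)
  p <- ez / rowSums(ez)
  B <- nrow(zv)
  picked <- cbind(seq_len(B), labels)
  val <- -mean(log(pmax(p[picked], 1e-12)))
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(z), function(g) {
    d <- p
    d[picked] <- d[picked] - 1
    list(g * d / B)
  })
}

# Entropic-OT reconstruction loss between masked original rows P and the
# corresponding reconstructed rows of Q, averaged over graphs. The
# transport plan is treated as fixed for the gradient (envelope theorem).
# `groups` assigns each masked row to its graph.
op_recon_loss <- function(tape, Q, P, groups, n_groups, epsilon = 0.05,
                          max_iter = 150, tol = 1e-6) {
  Qv <- vof(Q)
  losses <- numeric(n_groups)
  grads <- if (!is.null(tape)) matrix(0, nrow(Qv), ncol(Qv))
  for (b in seq_len(n_groups)) {
    rows <- which(groups == b)
    if (!length(rows)) next
    Pb <- P[rows, , drop = FALSE]
    Qb <- Qv[rows, , drop = FALSE]
    C <- euclidean_cost(Pb, Qb)
    plan <- sinkhorn_plan(C, epsilon = epsilon, max_iter = max_iter,
                          tol = tol)
    losses[b] <- sum(plan * C)
    if (!is.null(tape)) {
      Cs <- pmax(C, 1e-9)
      # d||P_i - Q_j|| / dQ_j = (Q_j - P_i) / ||P_i - Q_j||
      w <- plan / Cs
      grads[rows, ] <- grads[rows, , drop = FALSE] +
        colSums(w) * Qb - t(w) %*% Pb
    }
  }
  val <- mean(losses)
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(Q),
            function(g) list(g * grads / n_groups))
}

# weighted sum of two scalar loss nodes
op_axpby <- function(tape, a, wa, b, wb) {
  val <- wa * vof(a) + wb * vof(b)
  if (is.null(tape)) return(val)
  ad_record(tape, val, list(a, b), function(g) list(g * wa, g * wb))
}

# ---- Adam ------------------------------------------------------------

adam_state <- function(params) {
  s <- new.env(parent = emptyenv())
  s$m <- lapply(params, function(p) p * 0)
  s$v <- lapply(params, function(p) p * 0)
  s$t <- 0L
  s
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}
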