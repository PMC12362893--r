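#' Architecture configuration of the message passing network
#'
#' The encoder performs three message-passing rounds (fixed — a deliberate
#' architectural constant): per edge, the two incident node states and the
#' edge state are concatenated and pushed through a three-layer perceptron
#' to form the edge message; incoming messages are summed per node,
#' reweighted by a linear neighborhood perceptron (an attention-like layer),
#' and added residually with layer normalization and 10% dropout; a second
#' perceptron of the same shape then updates the edge states residually.
#' The decoder is one further message round that updates nodes only,
#' followed by a linear projection back to the gene-embedding dimension.
#'
#' @param node_dim dimension of the input node (gene-embedding) vectors.
#' @param n_states number of ordered cell states (>= 2).
#' @param n_kernels number of RBF kernels on the edges (default 8).
#' @param hidden shared hidden width all inputs are aligned to
#'   (default 128).
#' @param mlp_hidden the two interior widths of every message perceptron;
#'   default `c(384, 128)`, i.e. perceptron layers (3*hidden -> 384 -> 128
#'   -> hidden).
#' @param dropout dropout rate inside the residual node updates
#'   (default 0.10, applied only in training mode).
#' @param head `"ordinal"` (n_states - 1 cumulative logits) or `"softmax"`
#'   (plain multiclass, kept as an ablation).
#' @return an `mpnn_config` list.
#' @export
mpnn_config <- function(node_dim, n_states, n_kernels = 8, hidden = 128,
                        mlp_hidden = c(384, 128), dropout = 0.1,
                        head = c("ordinal", "softmax")) {
  head <- match.arg(head)
  stopifnot(node_dim >= 1, n_states >= 2, length(mlp_hidden) == 2)
  structure(list(node_dim = as.integer(node_dim),
                 n_states = as.integer(n_states),
                 n_kernels = as.integer(n_kernels),
                 hidden = as.integer(hidden),
                 mlp_hidden = as.integer(mlp_hidden),
                 dropout = dropout, rounds = 3L, head = head),
            class = "mpnn_config")
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

add_linear <- function(p, name, nin, nout, bias = TRUE) {
  p[[paste0(name, ".W")]] <- glorot(nin, nout)
  if (bias) p[[paste0(name, ".b")]] <- numeric(nout)
  p
}

add_mlp <- function(p, name, din, h1, h2, dout) {
  p <- add_linear(p, paste0(name, ".l1"), din, h1)
  p <- add_linear(p, paste0(name, ".l2"), h1, h2)
  add_linear(p, paste0(name, ".l3"), h2, dout)
}

add_block <- function(p, name, cfg) {
  h <- cfg$hidden
  p <- add_mlp(p, paste0(name, ".msg"), 3 * h, cfg$mlp_hidden[1],
               cfg$mlp_hidden[2], h)
  p[[paste0(name, ".nb.W")]] <- glorot(h, h)
  p[[paste0(name, ".ln.gamma")]] <- rep(1, h)
  p[[paste0(name, ".ln.beta")]] <- numeric(h)
  p
}

#' Initialize all model parameters
#'
#' Glorot-uniform initialization of the input aligners, the three encoder
#' message-passing blocks (each with independent edge-message and
#' edge-update perceptrons), the decoder block with its node reconstructor,
#' and the classification head.
#'
#' @param config an [mpnn_config()].
#' @param seed integer seed for reproducible initialization.
#' @return a `ModelParams` object (named list of parameter arrays plus the
#'   config).
#' @export
mpnn_params <- function(config, seed = 1) {
  stopifnot(inherits(config, "mpnn_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  h <- config$hidden
  p <- list()
  p <- add_linear(p, "node_align", config$node_dim, h)
  p <- add_linear(p, "edge_align", config$n_kernels, h)
  for (r in seq_len(config$rounds)) {
    p <- add_block(p, paste0("enc", r), config)           # node update
    p <- add_mlp(p, paste0("enc", r, ".edge"), 3 * h,
                 config$mlp_hidden[1], config$mlp_hidden[2], h)
  }
  p <- add_block(p, "dec", config)
  p <- add_linear(p, "dec.rec", h, config$node_dim)
  n_out <- if (config$head == "ordinal") config$n_states - 1L
           else config$n_states
  p <- add_linear(p, "head", h, n_out)
  structure(list(params = p, config = config), class = "ModelParams")
}

#' @export
print.ModelParams <- function(x, ...) {
  n <- sum(vapply(x$params, length, 1L))
  cat(sprintf("ModelParams: %d tensors, %d parameters (hidden %d, %s head, %d states)\n",
              length(x$params), n, x$config$hidden, x$config$head,
              x$config$n_states))
  invisible(x)
}

# ---- internal batched forward ---------------------------------------

mlp3_fwd <- function(tape, x, P, name) {
  x <- op_lin(tape, x, P[[paste0(name, ".l1.W")]], P[[paste0(name, ".l1.b")]])
  x <- op_relu(tape, x)
  x <- op_lin(tape, x, P[[paste0(name, ".l2.W")]], P[[paste0(name, ".l2.b")]])
  x <- op_relu(tape, x)
  op_lin(tape, x, P[[paste0(name, ".l3.W")]], P[[paste0(name, ".l3.b")]])
}

# one encoder round on (h, e); returns list(h, e)
round_fwd <- function(tape, h, e, batch, P, name, cfg, train) {
  msg <- op_edge_mlp(tape, h, e, batch$edges, P, paste0(name, ".msg"))
  agg <- op_scatter(tape, msg, batch$edges[, 2], batch$n_nodes)
  nb <- op_lin(tape, agg, P[[paste0(name, ".nb.W")]])
  if (train) nb <- op_dropout(tape, nb, cfg$dropout)
  h <- op_layernorm(tape, op_add(tape, h, nb),
                    P[[paste0(name, ".ln.gamma")]],
                    P[[paste0(name, ".ln.beta")]])
  msg2 <- op_edge_mlp(tape, h, e, batch$edges, P, paste0(name, ".edge"))
  list(h = h, e = op_add(tape, e, msg2))
}

# decoder round: updates nodes only, then projects to embedding dim
decoder_fwd <- function(tape, h, e, batch, P, cfg, train = FALSE) {
  msg <- op_edge_mlp(tape, h, e, batch$edges, P, "dec.msg")
  agg <- op_scatter(tape, msg, batch$edges[, 2], batch$n_nodes)
  nb <- op_lin(tape, agg, P[["dec.nb.W"]])
  if (train) nb <- op_dropout(tape, nb, cfg$dropout)
  hd <- op_layernorm(tape, op_add(tape, h, nb), P[["dec.ln.gamma"]],
                     P[["dec.ln.beta"]])
  op_lin(tape, hd, P[["dec.rec.W"]], P[["dec.rec.b"]])
}

# full batched forward over a disjoint union of cell graphs
mpnn_forward <- function(batch, params, cfg, tape = NULL, train = FALSE) {
  P <- if (is.null(tape)) params
       else lapply(params, function(v) ad_leaf(tape, v))
  h <- op_lin(tape, batch$node_feat, P[["node_align.W"]],
              P[["node_align.b"]])
  e <- op_lin(tape, batch$edge_feat, P[["edge_align.W"]],
              P[["edge_align.b"]])
  if (nrow(batch$edges) > 0) {
    for (r in seq_len(cfg$rounds)) {
      st <- round_fwd(tape, h, e, batch, P, paste0("enc", r), cfg, train)
      h <- st$h; e <- st$e
    }
  }
  emb <- op_group_mean(tape, h, batch$node_graph, batch$n_graphs)
  logits <- op_lin(tape, emb, P[["head.W"]], P[["head.b"]])
  recon <- if (nrow(batch$edges) > 0)
    decoder_fwd(tape, h, e, batch, P, cfg, train)
  else op_lin(tape, h, P[["dec.rec.W"]], P[["dec.rec.b"]])
  list(h = h, e = e, emb = emb, logits = logits, recon = recon,
       leaves = if (is.null(tape)) NULL else P)
}

# pack one or more CellGraphs (same gene set) into a disjoint union
assemble_batch <- function(graphs) {
  m <- length(graphs[[1]]$gene_ids)
  B <- length(graphs)
  node_feat <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  edges <- do.call(rbind, lapply(seq_len(B), function(i) {
    e <- graphs[[i]]$edges
    e + (i - 1L) * m
  }))
  edge_feat <- do.call(rbind, lapply(graphs, function(g) g$edge_features))
  list(node_feat = node_feat, edges = edges, edge_feat = edge_feat,
       node_graph = rep(seq_len(B), each = m), n_nodes = B * m,
       n_graphs = B)
}

# ---- public single-graph surface ------------------------------------

#' Align a cell graph's raw features to the model's hidden width
#'
#' Linearly projects node (gene-embedding) and edge (RBF) features to the
#' shared hidden width, producing the initial encoder state.
#'
#' @param g a [build_cell_graph()] result.
#' @param p a [mpnn_params()] object.
#' @return an `EncodedCell`: list with `node_states` (genes x hidden),
#'   `edge_states` (edges x hidden), `cell_embedding` (mean-pooled node
#'   states).
#' @export
align_inputs <- function(g, p) {
  stopifnot(inherits(p, "ModelParams"))
  if (ncol(g$node_features) != p$config$node_dim)
    stop("node feature dimension ", ncol(g$node_features),
         " does not match model node_dim ", p$config$node_dim)
  P <- p$params
  h <- op_lin(NULL, g$node_features, P[["node_align.W"]],
              P[["node_align.b"]])
  e <- op_lin(NULL, g$edge_features, P[["edge_align.W"]],
              P[["edge_align.b"]])
  structure(list(node_states = h, edge_states = e,
                 cell_embedding = colMeans(h)), class = "EncodedCell")
}

#' One encoder message-passing round
#'
#' @param state an `EncodedCell` (from [align_inputs()] or a previous
#'   round).
#' @param g the cell graph the state was computed on.
#' @param p a [mpnn_params()] object.
#' @param train_mode apply dropout inside the residual update (stochastic);
#'   off by default, giving a deterministic function of (state, graph,
#'   params).
#' @param round which encoder block's parameters to use (1..3).
#' @return updated `EncodedCell`.
#' @export
encoder_round <- function(state, g, p, train_mode = FALSE, round = 1) {
  stopifnot(inherits(state, "EncodedCell"), inherits(p, "ModelParams"))
  batch <- assemble_batch(list(g))
  if (nrow(batch$edges) == 0) {
    h <- op_layernorm(NULL, state$node_states,
                      p$params[[paste0("enc", round, ".ln.gamma")]],
                      p$params[[paste0("enc", round, ".ln.beta")]])
    return(structure(list(node_states = h, edge_states = state$edge_states,
                          cell_embedding = colMeans(h)),
                     class = "EncodedCell"))
  }
  st <- round_fwd(NULL, state$node_states, state$edge_states, batch,
                  p$params, paste0("enc", round), p$config, train_mode)
  structure(list(node_states = st$h, edge_states = st$e,
                 cell_embedding = colMeans(st$h)), class = "EncodedCell")
}

#' Encode a cell graph
#'
#' Applies [align_inputs()] followed by exactly three encoder rounds and
#' mean-pools the node states into the cell embedding.
#'
#' @inheritParams encoder_round
#' @param g a [build_cell_graph()] result.
#' @return an `EncodedCell`.
#' @export
encode <- function(g, p, train_mode = FALSE) {
  state <- align_inputs(g, p)
  for (r in seq_len(p$config$rounds))
    state <- encoder_round(state, g, p, train_mode, round = r)
  state
}

#' Decode reconstructed gene representations
#'
#' One message round over the encoded graph updating nodes only (edge
#' states are left frozen), then a linear projection of each node back to
#' the gene-embedding dimension — the reconstruction Q compared against the
#' original embeddings by [reconstruction_loss()].
#'
#' @param enc an `EncodedCell` produced by [encode()] on `g`.
#' @param g the same cell graph.
#' @param p a [mpnn_params()] object.
#' @return numeric matrix (genes x embedding dimension).
#' @export
decode <- function(enc, g, p) {
  stopifnot(inherits(enc, "EncodedCell"), inherits(p, "ModelParams"))
  batch <- assemble_batch(list(g))
  if (nrow(batch$edges) == 0)
    return(op_lin(NULL, enc$node_states, p$params[["dec.rec.W"]],
                  p$params[["dec.rec.b"]]))
  decoder_fwd(NULL, enc$node_states, enc$edge_states, batch, p$params,
              p$config)
}

#' @export
print.EncodedCell <- function(x, ...) {
  cat(sprintf("EncodedCell: %d node states x %d hidden, %d edge states\n",
              nrow(x$node_states), ncol(x$node_states),
              nrow(x$edge_states)))
  invisible(x)
}
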