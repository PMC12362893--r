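# scstate

Sequential cell-state classification from single-cell RNA-seq counts, for
researchers studying ordered biological progressions — developmental
timepoints, differentiation series, dose or perturbation responses — where
adjacent transcriptional states overlap too much for clustering or plain
multiclass classifiers.

## The method

Each cell is turned into a **gene graph**: nodes are the highly variable
genes (carrying prior gene-embedding vectors — zeros, one-hot, or
distributed co-expression embeddings such as Gene2vec; the latter is the
"dual-layer" mode), and directed edges carry the pairwise log-ratios
`log X_j − log X_k` of that cell's counts — depth-invariant, cross-platform
stable features. A small Gaussian perturbation with mean 0.5 keeps counts
positive; each node keeps its 8 largest and 8 smallest ratios (16 outgoing
edges), and each scalar ratio is expanded through 8 Gaussian radial basis
kernels,

```
RBF(x, c) = exp(−(x − c)² / r²),   centers unevenly spaced in [−6, 6].
```

A **message passing neural network** encoder (three rounds; per-edge
messages from a 3-layer perceptron over the concatenated node/edge states;
residual node updates with layer normalization and 10% dropout; residual
edge updates from a second perceptron) produces a mean-pooled cell
embedding; a one-round decoder reconstructs masked gene embeddings (15%
mask rate), scored by an entropic optimal-transport approximation of the
1-Wasserstein distance.

Classification is **ordinal regression with conditional training
subsets**: for n ordered states, n − 1 binary subtasks "is the cell beyond
stage j?", the j-th trained only on cells beyond stage j − 1, with loss

```
Loss_ord = −(1/Σ|S_j|) Σ_j Σ_{i∈S_j} [ log σ(z_j) · I(y > stage_j)
                                      + log(1 − σ(z_j)) · I(y ≤ stage_j) ]
Loss     = λ1·Loss_ord + λ2·Loss_rec
```

Unconditional cumulative probabilities follow by the chain rule
(`P̂(y > stage_j) = Π_{l≤j} σ(z_l)`), and the state is decoded as
`q = 1 + Σ_j I(P̂(y > stage_j) > threshold)`.

A negative-binomial simulator of ordered states (monotone per-gene drift,
library-size variation, mean-dependent dropout, a rare state) makes the
whole pipeline testable offline.

## Worked example

```r
library(scstate)

sim <- simulate_states(synthetic_spec(seed = 1))   # 6 states, ~1200 cells, 300 genes
# synthetic stand-in for a co-expression embedding table: co-regulated
# up- and down-drifting genes share a correlated direction
info <- sim$truth$informative
emb <- make_fixture_embeddings(sim$expression$gene_ids, dim = 50,
         informative_block_corr = 0.6,
         blocks = list(info[sim$truth$beta1[info] > 0],
                       info[sim$truth$beta1[info] < 0]), seed = 2)
cfg <- training_config(n_hvg = 48, hidden = 12, mlp_hidden = c(36, 12),
                       max_epochs = 16, val_fraction = 0,
                       learning_rate = 5e-3, warmup_epochs = 3,
                       lr_decay = 0.93, max_train_cells = 400,
                       calibrate_threshold = TRUE, seed = 1)
fit <- train_scstate(sim$expression, sim$states, emb, cfg)
pred <- predict(fit, sim$expression, n_draws = 3)
print(head(pred[, 1:6]), digits = 3)
mean(pred$q == sim$states$label_of_cell[pred$cell_id])
```

```
    cell_id predicted_state q p_gt_S1 p_gt_S2 p_gt_S3
1 cell00001              S1 1  0.1203  0.0321 0.00254
2 cell00002              S1 1  0.0629  0.0225 0.00319
3 cell00003              S1 1  0.0788  0.0463 0.01585
4 cell00004              S1 1  0.0695  0.0364 0.00963
5 cell00005              S1 1  0.0702  0.0261 0.00388
6 cell00006              S1 1  0.0532  0.0232 0.00423
[1] 0.9191921
```

Each row gives the decoded state (`q`, and its name), the cumulative
probabilities `P̂(y > stage_j)` and the per-state masses. These first
cells sit in the first state: every cumulative probability is far below
the decision threshold, so `q = 1`. Whole-matrix accuracy against the
simulation's ground truth is 0.919 here (the model saw ~400 of these
cells during training; `cross_validate()` gives honest held-out numbers,
~0.92–0.93 mean on this simulation at the configuration above).

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/scstate.R simulate --out data/ --seed 1
Rscript inst/cli/scstate.R train --counts data/matrix.mtx --labels data/labels.tsv \
    --state-order data/state_order.txt --out model.rds
Rscript inst/cli/scstate.R predict --counts data/matrix.mtx --model model.rds --out pred.tsv
```

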