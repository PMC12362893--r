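#' Conditional training subsets for ordinal regression
#'
#' An ordered classification over n states decomposes into n - 1 binary
#' subtasks "is the cell beyond stage j?". Subtask j is trained only on the
#' cells that got past stage j - 1, giving nested subsets
#' S_1 (all cells) >= S_2 >= ... >= S_{n-1}, where S_j holds the cells with
#' state index > j - 1.
#'
#' @param labels integer vector of 1-based state indices per cell.
#' @param n_states total number of ordered states (>= 2); default
#'   `max(labels)`.
#' @return a `ConditionalSubsets`: list of n_states - 1 integer vectors of
#'   cell indices. A state with no cells yields a degenerate (possibly
#'   empty) subset and a warning.
#' @export
build_subsets <- function(labels, n_states = max(labels)) {
  labels <- as.integer(labels)
  stopifnot(n_states >= 2, all(labels >= 1), all(labels <= n_states))
  subsets <- lapply(seq_len(n_states - 1),
                    function(j) which(labels > j - 1))
  names(subsets) <- paste0("S", seq_len(n_states - 1))
  present <- tabulate(labels, n_states)
  if (any(present == 0))
    warning("state(s) with zero cells: ",
            paste(which(present == 0), collapse = ", "),
            "; the corresponding binary subtask is degenerate")
  structure(subsets, class = "ConditionalSubsets")
}

#' Ordinal regression loss over conditional subsets
#'
#' The loss sums, over subtasks j = 1..n-1 and over the cells in subset
#' S_j, the binary cross-entropy of the event "state > stage j" under the
#' predicted logit z_j, and normalizes by the total number of (cell,
#' subtask) terms:
#' \deqn{-\frac{1}{\sum_j |S_j|} \sum_j \sum_{i \in S_j}
#'   [\log\sigma(z_j^{(i)})\,I(y^{(i)} > j) +
#'    (\log\sigma(z_j^{(i)}) - z_j^{(i)})\,I(y^{(i)} \le j)]}
#' The second weight equals log(1 - sigma(z)) analytically; both terms are
#' evaluated in the numerically stable log-sigmoid form
#' log sigma(z) = -softplus(-z).
#'
#' @param logits numeric matrix, one row per cell, n_states - 1 columns of
#'   logits z_j for P(state > stage_j).
#' @param labels integer vector of 1-based state indices per cell.
#' @param subsets optional [build_subsets()] result; recomputed from
#'   `labels` when missing.
#' @return nonnegative scalar; 0 with a warning if every subset is empty.
#' @export
ordinal_loss <- function(logits, labels, subsets = NULL) {
  logits <- as.matrix(logits)
  labels <- as.integer(labels)
  K <- ncol(logits) + 1L
  stopifnot(nrow(logits) == length(labels), all(labels >= 1),
            all(labels <= K))
  if (is.null(subsets)) subsets <- build_subsets(labels, K)
  mask <- outer(labels, seq_len(K - 1L), function(y, j) y > j - 1L)
  total <- sum(mask)
  if (total == 0) {
    warning("all conditional subsets empty; loss defined as 0")
    return(0)
  }
  target <- outer(labels, seq_len(K - 1L), ">")
  # log sigma(z) = -softplus(-z); log(1 - sigma(z)) = -softplus(z)
  ll <- ifelse(target, -softplus(-logits), -softplus(logits))
  -sum(ll[mask]) / total
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Decode the predicted state index from ordinal logits
#'
#' Counts how many unconditional cumulative events "state > stage j"
#' exceed the decision threshold:
#' \eqn{q = 1 + \sum_j I(\hat P(y > stage_j) > threshold)}.
#'
#' Because subtask j is trained only on the cells that passed stage j - 1,
#' sigma(z_j) estimates the *conditional* probability
#' P(y > stage_j | y > stage_{j-1}); the unconditional cumulative
#' probability follows by the chain rule as the running product
#' \eqn{\hat P(y > stage_j) = \prod_{l \le j} \sigma(z_l)} (the default,
#' `conditional = TRUE`), which is non-increasing in j, making the
#' indicator count robust to logits for stages a cell never reached. With
#' `conditional = FALSE` the sigmas are thresholded directly as if they
#' were already unconditional; the indicator sum needs no monotonicity.
#'
#' @param logits numeric vector of n_states - 1 logits, or a matrix with
#'   one row per cell.
#' @param threshold decision probability, default 0.5.
#' @param conditional interpret the logits as chain-rule conditionals
#'   (default) or as unconditional cumulative probabilities.
#' @return integer state index (vector when `logits` is a matrix), in
#'   1..n_states.
#' @export
decode_state <- function(logits, threshold = 0.5, conditional = TRUE) {
  stopifnot(threshold > 0, threshold < 1)
  vec <- !is.matrix(logits)
  z <- if (vec) matrix(logits, 1) else logits
  p <- stats::plogis(z)
  if (conditional) p <- t(apply(p, 1, cumprod))
  if (ncol(z) == 1) p <- matrix(p, ncol = 1)  # apply() drops to vector
  q <- 1L + rowSums(p > threshold)
  if (vec) q[1] else q
}

#' Cumulative and per-state probabilities from ordinal logits
#'
#' Returns the unconditional cumulative probabilities P(state > stage_j)
#' and the per-state masses obtained by telescoping differences with
#' boundary terms 1 and 0. Under the default chain-rule interpretation
#' (`conditional = TRUE`, see [decode_state()]) the cumulative sequence is
#' a running product of sigmoids, hence monotone, and the masses are
#' nonnegative by construction. With `conditional = FALSE` the sigmoids
#' are used directly; a non-monotone sequence can then produce negative
#' raw differences, which are clipped at 0 and renormalized for reporting.
#'
#' @param logits numeric vector of n_states - 1 logits.
#' @param conditional see [decode_state()].
#' @return list with `cumulative` (length n_states - 1) and `state_probs`
#'   (length n_states, sums to 1).
#' @export
cumulative_probabilities <- function(logits, conditional = TRUE) {
  s <- stats::plogis(as.numeric(logits))
  if (conditional) s <- cumprod(s)
  raw <- c(1, s) - c(s, 0)
  p <- pmax(raw, 0)
  if (sum(p) == 0) p <- rep(1 / length(p), length(p)) else p <- p / sum(p)
  list(cumulative = s, state_probs = p)
}
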