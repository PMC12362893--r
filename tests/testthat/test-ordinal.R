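test_that("conditional subsets are nested and sized by direct enumeration", {
  ss <- build_subsets(c(1, 1, 2, 3), n_states = 3)
  expect_equal(ss$S1, 1:4)
  expect_equal(ss$S2, 3:4)
  expect_warning(build_subsets(c(1, 1, 1), n_states = 3), "zero cells")
  ss2 <- build_subsets(c(1, 2, 2), n_states = 2)
  expect_length(ss2, 1)
  expect_equal(ss2$S1, 1:3)
  # nesting over random label vectors
  set.seed(3)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    labs <- sample(seq_len(K), sample(1:40, 1), replace = TRUE)
    ss <- suppressWarnings(build_subsets(labs, K))
    for (j in seq_len(length(ss) - 1))
      expect_true(all(ss[[j + 1]] %in% ss[[j]]))
  }
})

test_that("ordinal loss reproduces closed forms and its limits", {
  expect_equal(suppressWarnings(ordinal_loss(matrix(0, 1, 1), 2)), log(2))
  expect_lt(suppressWarnings(ordinal_loss(matrix(30, 1, 1), 2)), 1e-10)
  empty_subsets <- structure(list(S1 = integer(0), S2 = integer(0)),
                             class = "ConditionalSubsets")
  expect_warning(
    v <- ordinal_loss(matrix(0, 1, 2)[0, , drop = FALSE], integer(0),
                      subsets = empty_subsets), "empty")
  expect_equal(v, 0)
})

test_that("ordinal loss equals the brute-force masked-BCE oracle", {
  set.seed(14)
  for (rep in 1:50) {
    K <- sample(2:6, 1)
    B <- sample(1:50, 1)
    labs <- sample(seq_len(K), B, replace = TRUE)
    z <- matrix(rnorm(B * (K - 1), sd = 3), B)
    expect_equal(suppressWarnings(ordinal_loss(z, labs)),
                 naive_ordinal_loss(z, labs), tolerance = 1e-10)
  }
})

test_that("state decoding counts above-threshold cumulative events", {
  # all sigmas below / above the threshold hit the boundary states
  expect_equal(decode_state(qlogis(c(0.2, 0.1)), 0.5), 1)
  expect_equal(decode_state(qlogis(c(0.9, 0.8, 0.7)), 0.5,
                            conditional = FALSE), 4)
  # direct evaluation of the indicator sum at sigma = (0.9, 0.6, 0.2)
  z <- qlogis(c(0.9, 0.6, 0.2))
  expect_equal(decode_state(z, 0.5, conditional = FALSE),
               1 + sum(c(0.9, 0.6, 0.2) > 0.5))
  expect_equal(decode_state(z, 0.5), 3)   # chain rule: 0.9, 0.54, 0.108
})

test_that("decoding agrees with a brute-force indicator oracle", {
  set.seed(6)
  for (rep in 1:100) {
    K <- sample(2:6, 1)
    z <- rnorm(K - 1, sd = 2)
    thr <- runif(1, 0.05, 0.95)
    for (cond in c(TRUE, FALSE)) {
      p <- plogis(z)
      if (cond) p <- cumprod(p)
      expect_equal(decode_state(z, thr, conditional = cond),
                   1 + sum(vapply(p, function(pi) pi > thr, TRUE)))
    }
  }
})

test_that("decoding is monotone in every cumulative probability", {
  set.seed(12)
  for (rep in 1:30) {
    K <- sample(3:6, 1)
    z <- rnorm(K - 1)
    q0 <- decode_state(z)
    j <- sample(K - 1, 1)
    z2 <- z; z2[j] <- z2[j] + runif(1, 0, 3)
    expect_gte(decode_state(z2), q0)
  }
})

test_that("state probabilities telescope from the cumulative sequence", {
  # direct reading of the sigmas as cumulative probabilities
  cp <- cumulative_probabilities(qlogis(c(0.8, 0.3)), conditional = FALSE)
  expect_equal(cp$state_probs, c(0.2, 0.5, 0.3))
  expect_equal(sum(cp$state_probs), 1)
  cp2 <- cumulative_probabilities(qlogis(0.7), conditional = FALSE)
  expect_equal(cp2$state_probs, c(0.3, 0.7))
  # chain rule: running product is monotone, masses nonnegative
  cp3 <- cumulative_probabilities(c(2, -1, 1.5))
  expect_true(all(diff(cp3$cumulative) <= 0))
  expect_true(all(cp3$state_probs >= 0))
  expect_equal(sum(cp3$state_probs), 1)
})

test_that("gradient descent separates a toy three-state ordinal problem", {
  set.seed(5)
  n <- 60
  x <- c(rnorm(n, -6), rnorm(n, 0), rnorm(n, 6))  # separable 1-d inputs
  y <- rep(1:3, each = n)
  w <- c(0, 0); b <- c(0, 0)                      # linear logits z_j = w_j x + b_j
  for (step in 1:500) {
    z <- cbind(w[1] * x + b[1], w[2] * x + b[2])
    sig <- plogis(z)
    mask <- cbind(TRUE, y > 1)
    tgt <- cbind(y > 1, y > 2)
    gz <- -(tgt - sig) * mask / sum(mask)
    w <- w - 2 * colSums(gz * x)
    b <- b - 2 * colSums(gz)
  }
  z <- cbind(w[1] * x + b[1], w[2] * x + b[2])
  expect_lt(ordinal_loss(z, y), 0.05)
})
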