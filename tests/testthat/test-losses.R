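# Oracles live in helper-fixtures.R so the acceptance suite shares them.

# Brute-force reference implementations, written independently of the
# package internals, serve as oracles for the loss functions.

test_that("focal loss matches a brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(1:40, 1)
    p <- runif(n)
    y <- rbinom(n, 1, 0.5)
    alpha <- runif(1)
    gamma <- runif(1, 0, 4)
    expect_equal(focal_loss(p, y, focal_params(alpha, gamma)),
                 focal_oracle(p, y, alpha, gamma), tolerance = 1e-8)
  }
})

test_that("focal loss hits hand-computed values and the cross-entropy reduction", {
  # perfect prediction gives zero loss
  expect_equal(focal_loss(c(1, 0), c(1, 0)), 0, tolerance = 1e-5)
  # y = 1, p = 0.5, alpha = 0.25, gamma = 2: 0.25 * 0.25 * (-log 0.5)
  expect_equal(focal_loss(0.5, 1, focal_params(0.25, 2)),
               0.25 * 0.25 * (-log(0.5)), tolerance = 1e-10)
  # gamma = 0, alpha = 0.5 halves the binary cross-entropy
  set.seed(11)
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(focal_loss(p, y, focal_params(0.5, 0)), 0.5 * bce,
               tolerance = 1e-7)
})

test_that("focal loss is non-negative and decreasing in p_t", {
  pts <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(pts, function(p) focal_loss(p, 1, focal_params(0.25, 2)),
                 numeric(1))
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) < 0))
  expect_error(focal_loss(c(0.2, 0.3), 1), "length")
})

test_that("contrastive loss matches the double-loop oracle on random instances", {
  set.seed(202)
  for (rep in 1:100) {
    n_pairs <- sample(2:6, 1)
    d <- sample(2:8, 1)
    f <- matrix(rnorm(2 * n_pairs * d), 2 * n_pairs, d)
    tau <- runif(1, 0.1, 1)
    expect_equal(contrastive_loss(f, contrastive_params(tau)),
                 ntxent_oracle(f, tau), tolerance = 1e-8)
  }
})

test_that("contrastive loss on orthogonal unit-vector pairs matches the oracle", {
  f <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(contrastive_loss(f, contrastive_params(0.5)),
               ntxent_oracle(f, 0.5), tolerance = 1e-10)
})

test_that("contrastive loss is invariant to per-vector scaling and global rotation", {
  set.seed(303)
  f <- matrix(rnorm(8 * 5), 8, 5)
  base <- contrastive_loss(f)
  f_scaled <- f
  f_scaled[3, ] <- 3 * f_scaled[3, ]
  expect_equal(contrastive_loss(f_scaled), base, tolerance = 1e-10)
  rot <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(contrastive_loss(f %*% rot), base, tolerance = 1e-8)
  # cosine similarity of a vector with itself is 1
  x <- rnorm(5)
  expect_equal(sum(x * x) / (sqrt(sum(x^2)) * sqrt(sum(x^2))), 1,
               tolerance = 1e-12)
})

test_that("contrastive loss rejects odd batches and degenerate dimensions", {
  expect_error(contrastive_loss(matrix(rnorm(15), 5, 3)), "even")
  expect_error(contrastive_loss(matrix(rnorm(2), 2, 1)), "two positive pairs")
})

test_that("the training-step losses agree with the reference R implementations", {
  cfg <- model_config(base_width = 2, depth = 2, fc_sizes = c(8L, 6L))
  m <- tiny_model()
  set.seed(77)
  imgs <- lapply(1:4, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  labs <- list(matrix(rbinom(256, 1, 0.3), 16, 16), NULL,
               matrix(rbinom(256, 1, 0.4), 16, 16), NULL)
  step <- bundleseg:::.nn_train_step_cpp(
    imgs, labs, m$params, bundleseg:::cfg_for_cpp(m$cfg), as.integer(0:3),
    0.25, 2, 0.5, 1, 0.5, "embedding")
  # focal: mean over labelled samples of the R loss on the sample's forward
  probs <- lapply(c(1, 3), function(i) nn_forward(m, imgs[[i]])$seg_prob)
  f_ref <- mean(c(focal_loss(probs[[1]], labs[[1]]),
                  focal_loss(probs[[2]], labs[[3]])))
  expect_equal(step$focal_loss, f_ref, tolerance = 1e-10)
  # contrastive: R NT-Xent on the embeddings the forward pass reports
  emb <- t(vapply(1:4, function(i) nn_forward(m, imgs[[i]])$cls_embedding,
                  numeric(m$cfg$fc2)))
  expect_equal(step$con_loss, contrastive_loss(emb), tolerance = 1e-10)
})
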