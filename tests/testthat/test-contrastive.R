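test_that("projection head computes W2 ReLU(W1 r) and matches a loop oracle", {
  set.seed(1)
  p <- init_projection_head(5, 4, 3, bias = FALSE, seed = 1)
  r <- matrix(rnorm(6 * 5), 6, 5)
  z <- project(r, p)
  expect_identical(dim(z), c(6L, 3L))
  oracle <- matrix(0, 6, 3)
  for (i in 1:6) {
    hid <- pmax(as.numeric(r[i, ] %*% p$W1), 0)
    for (j in 1:3) oracle[i, j] <- sum(hid * p$W2[, j])
  }
  expect_equal(z, oracle, tolerance = 1e-6)
  # identity-like weights pass non-negative input through
  pid <- p; pid$W1 <- diag(1, 5, 4); pid$W2 <- diag(1, 4, 3)
  rpos <- abs(r)
  expect_equal(project(rpos, pid), rpos[, 1:3], tolerance = 1e-12,
               ignore_attr = TRUE)
  # all-negative hidden pre-activations collapse to zero
  pneg <- p; pneg$W1 <- -abs(p$W1)
  expect_true(all(project(abs(r), pneg) == 0))
})

test_that("projection head honours the reference widths", {
  p <- init_projection_head()
  expect_identical(nrow(p$W1), 128L)
  expect_identical(ncol(p$W2), 64L)
})

test_that("pairwise cosine similarity has the contract properties", {
  # orthogonal unit vectors -> identity matrix
  expect_equal(pairwise_similarity(diag(4)), diag(4))
  # opposite vectors -> -1
  z <- rbind(c(1, 2, 3), -c(1, 2, 3))
  expect_equal(pairwise_similarity(z)[1, 2], -1)
  # random case against a loop oracle
  set.seed(2)
  z <- matrix(rnorm(6 * 4), 6, 4)
  S <- pairwise_similarity(z)
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 6))
  expect_true(all(S >= -1 & S <= 1))
  for (i in 1:6) for (j in 1:6) {
    expect_equal(S[i, j], sum(z[i, ] * z[j, ]) /
                   (sqrt(sum(z[i, ]^2)) * sqrt(sum(z[j, ]^2))),
                 tolerance = 1e-6)
  }
  expect_error(pairwise_similarity(rbind(c(1, 1), c(0, 0))), "zero-norm")
})

test_that("single-pair NT-Xent loss is exactly zero", {
  for (s in 1:5) {
    z <- withr::with_seed(s, matrix(rnorm(2 * 7), 2, 7))
    expect_equal(nt_xent(z, tau = 0.1), 0)
  }
})

test_that("NT-Xent matches the double-loop oracle over batch sizes and temperatures", {
  for (N in c(1, 2, 4, 8)) {
    for (tau in c(0.1, 1, 10)) {
      z <- withr::with_seed(N * 100 + tau * 10,
                            matrix(rnorm(2 * N * 5), 2 * N, 5))
      expect_equal(nt_xent(z, tau), oracle_nt_xent(z, tau), tolerance = 1e-6)
      expect_equal(nt_xent(z, tau, reduce = FALSE),
                   oracle_per_anchor_nt_xent(z, tau), tolerance = 1e-6)
    }
  }
})

test_that("hand-fixed two-pair batch reproduces an unrolled scalar computation", {
  z <- rbind(c(1, 0), c(0.8, 0.6), c(0, 1), c(-0.6, 0.8))
  tau <- 0.1
  # unrolled: all 16 cosine terms computed one by one in the oracle
  expect_equal(nt_xent(z, tau), oracle_nt_xent(z, tau), tolerance = 1e-9)
  expect_gt(nt_xent(z, tau), 0)
})

test_that("high-temperature limit approaches log(2N - 1) per anchor", {
  for (N in c(2, 4)) {
    z <- withr::with_seed(N, matrix(rnorm(2 * N * 6), 2 * N, 6))
    l <- nt_xent(z, tau = 1e6, reduce = FALSE)
    expect_equal(l, rep(log(2 * N - 1), 2 * N), tolerance = 1e-3)
  }
})

test_that("NT-Xent is non-negative and invariant to pair relabelings", {
  set.seed(4)
  N <- 5
  z <- matrix(rnorm(2 * N * 8), 2 * N, 8)
  base <- nt_xent(z, 0.2)
  expect_gte(base, 0)
  # swapping the two views of every pair
  swap <- as.numeric(t(matrix(seq_len(2 * N), 2))[, 2:1])
  swap <- as.numeric(rbind(seq(2, 2 * N, 2), seq(1, 2 * N - 1, 2)))
  expect_equal(nt_xent(z[swap, ], 0.2), base, tolerance = 1e-12)
  # common permutation of the pair order
  pairs <- sample(N)
  idx <- as.numeric(rbind(2 * pairs - 1, 2 * pairs))
  expect_equal(nt_xent(z[idx, ], 0.2), base, tolerance = 1e-12)
  expect_error(nt_xent(z, tau = 0), "positive")
})

test_that("analytic NT-Xent gradient matches finite differences", {
  for (s in 1:3) {
    z <- withr::with_seed(s, matrix(rnorm(4 * 6), 4, 6))
    g <- nt_xent_grad(z, 0.5)
    ng <- numeric_gradient(function(v) nt_xent(v, 0.5), z)
    expect_equal(g, ng, tolerance = 1e-4)
  }
})

test_that("pretraining with zero epochs returns the encoder unchanged", {
  enc <- tiny_encoder(seed = 11)
  imgs <- tiny_images(6, seed = 11)
  fit <- contrastive_pretrain(imgs, enc,
                              cfg = contrastive_config(batch_size = 4,
                                                       epochs = 0, seed = 1))
  expect_equal(fit$encoder$embedding, enc$embedding)
  expect_equal(fit$encoder$blocks, enc$blocks)
  expect_identical(nrow(fit$history), 0L)
})

test_that("pretraining is reproducible under a fixed seed", {
  enc <- tiny_encoder(seed = 12)
  imgs <- tiny_images(8, seed = 12)
  cfg <- contrastive_config(batch_size = 4, epochs = 2, seed = 99)
  f1 <- contrastive_pretrain(imgs, enc, cfg = cfg)
  f2 <- contrastive_pretrain(imgs, enc, cfg = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$encoder$embedding$e, f2$encoder$embedding$e)
})

test_that("contrastive training reduces the loss on small synthetic data", {
  # two texture classes, small encoder; final epoch mean loss must drop
  # below the first epoch's on every seed
  spec <- synthetic_spec(n_classes = 2, images_per_class = 15, H = 32, W = 32,
                         seed = 21)
  dat <- generate_synthetic(spec)
  drops <- vapply(1:3, function(s) {
    enc <- init_encoder(H = 32, W = 32, C = 3, P = 8, D = 16, k = 2,
                        D_mlp = 32, L = 1, seed = s)
    fit <- contrastive_pretrain(dat$images, enc,
                                cfg = contrastive_config(batch_size = 30,
                                                         epochs = 20,
                                                         seed = s))
    h <- fit$history$mean_loss
    h[length(h)] - h[1]
  }, numeric(1))
  expect_true(all(drops < 0))
})

test_that("degenerate configurations are rejected", {
  enc <- tiny_encoder()
  expect_error(contrastive_pretrain(array(0, c(8, 8, 3, 0)), enc), "empty")
  expect_error(contrastive_config(batch_size = 1))
  expect_error(contrastive_config(temperature = 0))
})
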