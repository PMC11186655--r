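# Independent reference implementations used as oracles. These are written
# as literal double loops from the mathematical definitions and must stay
# independent of the package's vectorized code paths.

# NT-Xent via explicit loops: cosine similarities s[n, m], per-anchor loss
# with the 2N-1 non-self denominator terms, symmetric average over pairs.
oracle_nt_xent <- function(z, tau) {
  n2 <- nrow(z)
  s <- matrix(0, n2, n2)
  for (n in seq_len(n2)) {
    for (m in seq_len(n2)) {
      s[n, m] <- sum(z[n, ] * z[m, ]) /
        (sqrt(sum(z[n, ]^2)) * sqrt(sum(z[m, ]^2)))
    }
  }
  l <- function(i, j) {
    den <- 0
    for (kk in seq_len(n2)) if (kk != i) den <- den + exp(s[i, kk] / tau)
    -log(exp(s[i, j] / tau) / den)
  }
  total <- 0
  for (k in seq_len(n2 / 2)) {
    total <- total + l(2 * k - 1, 2 * k) + l(2 * k, 2 * k - 1)
  }
  total / n2
}

oracle_per_anchor_nt_xent <- function(z, tau) {
  n2 <- nrow(z)
  out <- numeric(n2)
  for (i in seq_len(n2)) {
    j <- if (i %% 2 == 1) i + 1 else i - 1
    num <- exp(sum(z[i, ] * z[j, ]) /
                 (sqrt(sum(z[i, ]^2)) * sqrt(sum(z[j, ]^2))) / tau)
    den <- 0
    for (kk in seq_len(n2)) {
      if (kk != i) {
        den <- den + exp(sum(z[i, ] * z[kk, ]) /
                           (sqrt(sum(z[i, ]^2)) * sqrt(sum(z[kk, ]^2))) / tau)
      }
    }
    out[i] <- -log(num / den)
  }
  out
}

# Central finite-difference gradient of f at x (a numeric vector/matrix).
numeric_gradient <- function(f, x, h = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Per-pair counting oracle for multi-class precision/recall/F1/accuracy.
oracle_metrics <- function(pred, truth, C) {
  prec <- rec <- f1 <- numeric(C)
  for (cl in 0:(C - 1)) {
    tp <- fp <- fn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      if (pred[i] == cl && truth[i] != cl) fp <- fp + 1
      if (pred[i] != cl && truth[i] == cl) fn <- fn + 1
    }
    prec[cl + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[cl + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[cl + 1] <- if (prec[cl + 1] + rec[cl + 1] > 0) {
      2 * prec[cl + 1] * rec[cl + 1] / (prec[cl + 1] + rec[cl + 1])
    } else 0
  }
  list(precision = prec, recall = rec, f1 = f1,
       accuracy = mean(pred == truth))
}

# Small encoder configuration used across tests.
tiny_encoder <- function(seed = 1, L = 1L) {
  init_encoder(H = 8L, W = 8L, C = 3L, P = 4L, D = 8L, k = 2L,
               D_mlp = 16L, L = L, seed = seed)
}

tiny_images <- function(n = 4, H = 8, W = 8, C = 3, seed = 1) {
  withr::with_seed(seed, array(stats::runif(H * W * C * n, 0, 255),
                               c(H, W, C, n)))
}
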