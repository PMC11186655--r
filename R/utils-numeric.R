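# Internal numerical primitives shared by the encoder, projection head and
# classifier: initializers, activations with their derivatives, row-wise
# layer normalization with an analytic backward pass, and an Adam optimizer
# that walks arbitrarily nested parameter lists.

#' @keywords internal
#' @noRd
trunc_normal <- function(n, sd = 0.02, cutoff = 2) {
  # rejection sampling; cutoff in units of sd
  out <- stats::rnorm(n, sd = sd)
  bad <- which(abs(out) > cutoff * sd)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), sd = sd)
    bad <- bad[abs(out[bad]) > cutoff * sd]
  }
  out
}

trunc_normal_mat <- function(nrow, ncol, sd = 0.02) {
  matrix(trunc_normal(nrow * ncol, sd = sd), nrow, ncol)
}

# He (Kaiming) normal init for deep ReLU stacks; fan_in is the input width.
he_normal_mat <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / nrow)), nrow, ncol)
}

# Gaussian-CDF form of GELU and its derivative.
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Row-wise softmax with max-shift stabilization.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# --- layer normalization over the feature (column) axis, per row -----------

layernorm_forward <- function(x, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv_sd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv_sd
  y <- sweep(xhat, 2L, gamma, `*`)
  y <- sweep(y, 2L, beta, `+`)
  list(y = y, xhat = xhat, inv_sd = inv_sd)
}

# dy: upstream gradient; cache: from layernorm_forward.
# Returns dx plus parameter gradients.
layernorm_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dx = dx,
       dgamma = colSums(dy * xhat),
       dbeta  = colSums(dy))
}

# --- Adam over nested parameter lists --------------------------------------

#' @keywords internal
#' @noRd
adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else array(0, dim = dim(p) %||% length(p))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam step. `grads` mirrors the structure of `params`; entries of
# `params` that are not numeric (e.g. integer metadata) must not appear in
# `grads`. `lr_scale` optionally mirrors the structure with per-branch
# multipliers (used for the reduced encoder step size in joint fine-tuning).
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      lr_scale = NULL) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v, scale) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(g)) {
      out_p <- p; out_m <- m; out_v <- v
      keys <- names(g) %||% seq_along(g)  # positional for unnamed lists
      for (nm in keys) {
        sc <- if (is.list(scale)) scale[[nm]] else scale
        res <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], sc)
        out_p[[nm]] <- res$p; out_m[[nm]] <- res$m; out_v[[nm]] <- res$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    sc <- if (is.numeric(scale)) scale else 1
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * sc * mhat / (sqrt(vhat) + eps)
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v, lr_scale)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

# Flatten / unflatten nested numeric parameter lists (finite-difference
# checks and the checkpoint manifest both use this).
flatten_params <- function(params) {
  if (!is.list(params)) return(as.numeric(params))
  unlist(lapply(params, flatten_params), use.names = FALSE)
}

assign_flat <- function(params, values) {
  i <- 0L
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    n <- length(p)
    out <- values[(i + 1L):(i + n)]
    i <<- i + n
    if (!is.null(dim(p))) dim(out) <- dim(p)
    out
  }
  walk(params)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}
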