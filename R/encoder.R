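#' Patch specification for the vision-transformer encoder
#'
#' Describes how an `H x W x C` image is cut into non-overlapping `P x P`
#' tiles and projected to `D`-dimensional tokens. `H` and `W` must be
#' divisible by `P`; the number of patches is `H * W / P^2` and each
#' flattened patch has length `P^2 * C`.
#'
#' @param H,W,C Image height, width and channel count.
#' @param P Patch side in pixels.
#' @param D Token (embedding) width.
#' @return A `patch_spec` list with fields `H, W, C, P, N_patch, D,
#'   patch_len`.
#' @export
#' @examples
#' patch_spec(96, 96, 3, P = 6)$N_patch  # 256
patch_spec <- function(H, W, C = 3L, P = 6L, D = 128L) {
  if (H %% P != 0L || W %% P != 0L) {
    stop("image side not divisible by patch size", call. = FALSE)
  }
  structure(list(H = as.integer(H), W = as.integer(W), C = as.integer(C),
                 P = as.integer(P), N_patch = as.integer(H * W / P^2),
                 D = as.integer(D), patch_len = as.integer(P^2 * C)),
            class = "patch_spec")
}

# Batched patch extraction: (H,W,C,B) array -> (B*N_patch) x (P^2*C) matrix.
# Within a patch the flattening is row-major over pixels with channels
# interleaved fastest; patches are ordered row-major over the tile grid;
# batch index slowest.
# Transposed layout (patches in columns); callers use crossprod().
patchify_t <- function(images, spec, scale = 1, offset = 0) {
  d <- dim(images)
  stopifnot(d[1] == spec$H, d[2] == spec$W, d[3] == spec$C)
  patchify_t_cpp(images, spec$H, spec$W, spec$C, d[4], spec$P, scale, offset)
}

patchify_batch <- function(images, spec) t(patchify_t(images, spec))

unpatchify_batch <- function(patches, spec, B) {
  P <- spec$P; nh <- spec$H %/% P; nw <- spec$W %/% P
  x <- t(patches)
  dim(x) <- c(spec$C, P, P, nw, nh, B)
  x <- aperm(x, c(3L, 5L, 2L, 4L, 1L, 6L))  # (row, gh, col, gw, C, B)
  dim(x) <- c(spec$H, spec$W, spec$C, B)
  x
}

#' Cut an image into flattened patches (and back)
#'
#' `image_to_patches()` returns the `N_patch x (P^2*C)` matrix whose row `j`
#' is the row-major flattening (channels interleaved) of the `j`-th
#' non-overlapping tile, tiles ordered row-major over the grid. The
#' operation is exactly invertible by `patches_to_image()`.
#'
#' @param image `H x W x C` array matching `spec`.
#' @param patches Matrix as produced by `image_to_patches()`.
#' @param spec A [patch_spec()].
#' @return A patch matrix, or the reconstructed image.
#' @export
image_to_patches <- function(image, spec) {
  stopifnot(length(dim(image)) == 3L)
  patchify_batch(array(image, c(dim(image), 1L)), spec)
}

#' @rdname image_to_patches
#' @export
patches_to_image <- function(patches, spec) {
  stopifnot(nrow(patches) == spec$N_patch)
  array(unpatchify_batch(patches, spec, 1L), c(spec$H, spec$W, spec$C))
}

#' Initialize encoder parameters
#'
#' Builds the full parameter set of the light vision-transformer encoder:
#' patch projection, class token, learnable 1-d position embeddings, and `L`
#' pre-norm transformer blocks (multi-head self-attention and a two-layer
#' GELU MLP, each wrapped in a residual connection). The representation `r`
#' is read out by average pooling over all tokens (class token included) or,
#' optionally, by the class token alone.
#'
#' Projections are initialized with a truncated normal (sd 0.02), layer-norm
#' scales with ones and shifts with zeros.
#'
#' @param H,W,C,P,D Passed to [patch_spec()].
#' @param k Number of attention heads; must divide `D`. Per-head width is
#'   `D_h = D / k`.
#' @param D_mlp Hidden width of each block MLP (default `2 * D`).
#' @param L Number of transformer blocks (>= 1).
#' @param pooling `"mean"` (default) or `"cls"` readout.
#' @param seed Optional seed for reproducible initialization.
#' @return An `encoder_params` list; the representation width equals `D`.
#' @export
init_encoder <- function(H = 96L, W = 96L, C = 3L, P = 6L, D = 128L,
                         k = 4L, D_mlp = 2L * D, L = 1L,
                         pooling = c("mean", "cls"), seed = NULL) {
  pooling <- match.arg(pooling)
  stopifnot(L >= 1L, D %% k == 0L)
  spec <- patch_spec(H, W, C, P, D)
  D_h <- D %/% k
  build <- function() {
    blocks <- lapply(seq_len(L), function(l) {
      # attention and MLP projections use Xavier-scaled normals so the
      # nonlinear paths contribute at initialization even with L = 1
      U_qkv <- array(stats::rnorm(D * 3L * D_h * k, sd = sqrt(1 / D)),
                     c(D, 3L * D_h, k))
      list(attention = list(U_qkv = U_qkv,
                            U_out = matrix(stats::rnorm(k * D_h * D,
                                                        sd = sqrt(1 / (k * D_h))),
                                           k * D_h, D)),
           mlp = list(W1 = matrix(stats::rnorm(D * D_mlp, sd = sqrt(2 / D)),
                                  D, D_mlp),
                      b1 = numeric(D_mlp),
                      W2 = matrix(stats::rnorm(D_mlp * D, sd = sqrt(1 / D_mlp)),
                                  D_mlp, D),
                      b2 = numeric(D)),
           norm1 = list(gamma = rep(1, D), beta = numeric(D)),
           norm2 = list(gamma = rep(1, D), beta = numeric(D)))
    })
    list(patch_spec = spec,
         embedding = list(e = trunc_normal_mat(spec$patch_len, D),
                          i_class = trunc_normal(D),
                          e_position = trunc_normal_mat(spec$N_patch + 1L, D)),
         final_norm = list(gamma = rep(1, D), beta = numeric(D)),
         blocks = blocks,
         k = as.integer(k), D_h = as.integer(D_h), D_mlp = as.integer(D_mlp),
         L = as.integer(L), pooling = pooling, output_dim = as.integer(D))
  }
  p <- if (!is.null(seed)) withr::with_seed(seed, build()) else build()
  structure(p, class = "encoder_params")
}

#' Token embedding of a patch sequence
#'
#' Projects flattened patches with the patch-projection matrix, prepends the
#' class token, and adds the learnable position embeddings: token 0 is
#' `i_class + e_position[0]`, token `j >= 1` is `patch_j e + e_position[j]`.
#'
#' @param patches `N_patch x (P^2*C)` matrix.
#' @param embedding The `embedding` component of [init_encoder()] output
#'   (fields `e`, `i_class`, `e_position`).
#' @return `(N_patch + 1) x D` token matrix.
#' @export
embed_patches <- function(patches, embedding) {
  stopifnot(ncol(patches) == nrow(embedding$e))
  rbind(embedding$i_class, patches %*% embedding$e) + embedding$e_position
}

#' Scaled dot-product self-attention for one head
#'
#' Computes `Attention %*% V` where `Attention` is the row-wise softmax of
#' `Q K' / sqrt(D_h)` and `[Q, K, V]` are the joint projection of the tokens
#' by the head's `U_qkv` slice. Every attention row is a probability vector.
#'
#' @param x `N x D` token matrix.
#' @param params Attention parameters (fields `U_qkv` of shape
#'   `D x 3 D_h x k`, `U_out` of shape `(k D_h) x D`).
#' @param head Head index in `1..k`.
#' @return `N x D_h` matrix, with the `N x N` attention matrix attached as
#'   attribute `"attention"`.
#' @export
self_attention <- function(x, params, head = 1L) {
  U <- params$U_qkv[, , head]
  D_h <- ncol(U) %/% 3L
  QKV <- x %*% U
  Q <- QKV[, 1:D_h, drop = FALSE]
  K <- QKV[, D_h + (1:D_h), drop = FALSE]
  V <- QKV[, 2L * D_h + (1:D_h), drop = FALSE]
  A <- softmax_rows(Q %*% t(K) / sqrt(D_h))
  structure(A %*% V, attention = A)
}

#' Multi-head self-attention
#'
#' Runs `k` parallel self-attention heads, concatenates their outputs and
#' projects with `U_out`.
#'
#' @inheritParams self_attention
#' @return `N x D` matrix.
#' @export
multi_head_attention <- function(x, params) {
  k <- dim(params$U_qkv)[3]
  heads <- do.call(cbind, lapply(seq_len(k), function(h) {
    out <- self_attention(x, params, h)
    attr(out, "attention") <- NULL
    out
  }))
  heads %*% params$U_out
}

#' One pre-norm transformer block
#'
#' `x' = MSA(Norm(x)) + x`, then `out = MLP(Norm(x')) + x'`, with layer
#' normalization over the token width and a two-layer GELU MLP.
#'
#' @param x `N x D` token matrix.
#' @param params One element of the `blocks` list of [init_encoder()] output.
#' @return `N x D` token matrix.
#' @export
transformer_block <- function(x, params) {
  h1 <- layernorm_forward(x, params$norm1$gamma, params$norm1$beta)$y
  x1 <- multi_head_attention(h1, params$attention) + x
  h2 <- layernorm_forward(x1, params$norm2$gamma, params$norm2$beta)$y
  f <- gelu(sweep(h2 %*% params$mlp$W1, 2L, params$mlp$b1, `+`))
  sweep(f %*% params$mlp$W2, 2L, params$mlp$b2, `+`) + x1
}

# ---------------------------------------------------------------------------
# Batched forward/backward. Token matrices are stored as (B*T) x D with the
# rows of sample b occupying ((b-1)*T+1):(b*T); T = N_patch + 1.

block_forward_batched <- function(X, bp, B, T, k, D_h, keep_cache = FALSE) {
  res <- block_forward_cpp(X, bp$attention$U_qkv, bp$attention$U_out,
                           bp$norm1$gamma, bp$norm1$beta,
                           bp$norm2$gamma, bp$norm2$beta,
                           bp$mlp$W1, bp$mlp$b1, bp$mlp$W2, bp$mlp$b2,
                           B, T, keep_cache)
  list(X = res$X, cache = if (keep_cache) res)
}

block_backward_batched <- function(dX2, bp, cache, B, T, k, D_h) {
  g <- block_backward_cpp(dX2, bp$attention$U_qkv, bp$attention$U_out,
                          bp$norm1$gamma, bp$norm2$gamma,
                          bp$mlp$W1, bp$mlp$W2, cache$cache, B, T)
  list(dX = g$dX,
       grads = list(attention = list(U_qkv = g$dUqkv, U_out = g$dUout),
                    mlp = list(W1 = g$dW1, b1 = as.numeric(g$db1),
                               W2 = g$dW2, b2 = as.numeric(g$db2)),
                    norm1 = list(gamma = as.numeric(g$dg1),
                                 beta = as.numeric(g$dbe1)),
                    norm2 = list(gamma = as.numeric(g$dg2),
                                 beta = as.numeric(g$dbe2))))
}

# Full encoder forward on a (H,W,C,B) pixel array on the [0,255] scale.
# Pixels are mapped to [0,1] before patching.
encoder_forward <- function(images, params, keep_cache = FALSE) {
  images <- as_image_batch(images)
  spec <- params$patch_spec
  B <- dim(images)[4]
  T <- spec$N_patch + 1L
  Pt <- patchify_t(images, spec, scale = 1 / 255, offset = -0.5)
  tokE <- crossprod(Pt, params$embedding$e)
  X <- matrix(0, B * T, spec$D)
  idx_cls <- seq(1L, B * T, by = T)
  X[idx_cls, ] <- matrix(params$embedding$i_class, B, spec$D, byrow = TRUE)
  X[-idx_cls, ] <- tokE
  X <- X + params$embedding$e_position[rep(seq_len(T), B), , drop = FALSE]
  caches <- if (keep_cache) vector("list", params$L)
  for (l in seq_len(params$L)) {
    res <- block_forward_batched(X, params$blocks[[l]], B, T,
                                 params$k, params$D_h, keep_cache)
    X <- res$X
    if (keep_cache) caches[[l]] <- res$cache
  }
  fln <- layernorm_forward(X, params$final_norm$gamma, params$final_norm$beta)
  X <- fln$y
  r <- if (params$pooling == "mean") {
    unname(rowsum(X, rep(seq_len(B), each = T))) / T
  } else {
    X[idx_cls, , drop = FALSE]
  }
  cache <- if (keep_cache) {
    list(Pt = Pt, caches = caches, fln = fln, B = B, T = T,
         idx_cls = idx_cls)
  }
  list(r = r, cache = cache)
}

# Backward from dR (B x D) to gradients of every encoder parameter.
encoder_backward <- function(dR, params, cache) {
  B <- cache$B; T <- cache$T
  dX <- if (params$pooling == "mean") {
    dR[rep(seq_len(B), each = T), , drop = FALSE] / T
  } else {
    dXf <- matrix(0, B * T, ncol(dR))
    dXf[cache$idx_cls, ] <- dR
    dXf
  }
  flnb <- layernorm_backward(dX, cache$fln, params$final_norm$gamma)
  dX <- flnb$dx
  block_grads <- vector("list", params$L)
  for (l in rev(seq_len(params$L))) {
    res <- block_backward_batched(dX, params$blocks[[l]], cache$caches[[l]],
                                  B, T, params$k, params$D_h)
    dX <- res$dX
    block_grads[[l]] <- res$grads
  }
  depos <- rowsum(dX, rep(seq_len(T), B))
  dcls <- colSums(dX[cache$idx_cls, , drop = FALSE])
  dtokE <- dX[-cache$idx_cls, , drop = FALSE]
  de <- cache$Pt %*% dtokE
  list(embedding = list(e = de, i_class = dcls, e_position = depos),
       final_norm = list(gamma = flnb$dgamma, beta = flnb$dbeta),
       blocks = block_grads)
}

#' Encode images to representations
#'
#' Full encoder pipeline: patches, token embedding with class token and
#' position embeddings, `L` transformer blocks, then pooling over the token
#' axis. A pure deterministic function of `(images, params)`. Input pixels
#' are expected on the `[0, 255]` scale and are mapped to `[0, 1]`
#' internally before patching.
#'
#' @param images `H x W x C` image or `H x W x C x B` batch.
#' @param params An [init_encoder()] parameter set.
#' @return `B x D` matrix of representations.
#' @export
encode <- function(images, params) {
  encoder_forward(images, params, keep_cache = FALSE)$r
}

#' Audit encoder parameter shapes
#'
#' Enumerates every weight tensor against the patch specification and
#' returns a tibble with the observed and expected dimensions.
#'
#' @param params An [init_encoder()] parameter set.
#' @return Tibble with columns `component`, `dims`, `expected`, `ok`.
#' @export
encoder_shape_audit <- function(params) {
  s <- params$patch_spec
  fmt <- function(d) paste(d, collapse = "x")
  rows <- list(
    c("patch_projection", fmt(dim(params$embedding$e)),
      fmt(c(s$patch_len, s$D))),
    c("class_token", fmt(length(params$embedding$i_class)), fmt(s$D)),
    c("position_embedding", fmt(dim(params$embedding$e_position)),
      fmt(c(s$N_patch + 1L, s$D))),
    c("final_norm", fmt(length(params$final_norm$gamma)), fmt(s$D))
  )
  for (l in seq_len(params$L)) {
    bp <- params$blocks[[l]]
    rows <- c(rows, list(
      c(sprintf("block%d_U_qkv", l), fmt(dim(bp$attention$U_qkv)),
        fmt(c(s$D, 3L * params$D_h, params$k))),
      c(sprintf("block%d_U_out", l), fmt(dim(bp$attention$U_out)),
        fmt(c(params$k * params$D_h, s$D))),
      c(sprintf("block%d_mlp_W1", l), fmt(dim(bp$mlp$W1)),
        fmt(c(s$D, params$D_mlp))),
      c(sprintf("block%d_mlp_W2", l), fmt(dim(bp$mlp$W2)),
        fmt(c(params$D_mlp, s$D))),
      c(sprintf("block%d_norm1", l), fmt(length(bp$norm1$gamma)), fmt(s$D)),
      c(sprintf("block%d_norm2", l), fmt(length(bp$norm2$gamma)), fmt(s$D))
    ))
  }
  out <- tibble::tibble(
    component = vapply(rows, `[`, "", 1L),
    dims = vapply(rows, `[`, "", 2L),
    expected = vapply(rows, `[`, "", 3L)
  )
  out$ok <- out$dims == out$expected
  out
}
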