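#' Initialize the projection head
#'
#' The small non-linear MLP `z = W2 ReLU(W1 r)` that maps the encoder
#' representation `r` into the space where the contrastive loss is computed.
#' The head is discarded after pretraining. Defaults follow the reference
#' configuration: input width 128, projection dimension 64, one hidden layer
#' equal to the input width. Bias vectors are included by default and can be
#' disabled to recover the pure matrix-product form.
#'
#' @param input_dim Width of `r`.
#' @param hidden_dim Hidden-layer width.
#' @param output_dim Width of the embedding `z`.
#' @param bias Include bias vectors?
#' @param seed Optional seed for reproducible initialization.
#' @return A `projection_params` list.
#' @export
init_projection_head <- function(input_dim = 128L, hidden_dim = input_dim,
                                 output_dim = 64L, bias = TRUE, seed = NULL) {
  build <- function() {
    # He-scaled init: keeps embedding norms well away from zero so the
    # cosine similarity is well conditioned from the first step
    list(W1 = he_normal_mat(input_dim, hidden_dim),
         b1 = if (bias) numeric(hidden_dim),
         W2 = he_normal_mat(hidden_dim, output_dim),
         b2 = if (bias) numeric(output_dim))
  }
  p <- if (!is.null(seed)) withr::with_seed(seed, build()) else build()
  structure(c(p, list(bias = bias,
                      input_dim = as.integer(input_dim),
                      output_dim = as.integer(output_dim))),
            class = "projection_params")
}

projection_forward <- function(r, params, keep_cache = FALSE) {
  A1 <- r %*% params$W1
  if (params$bias) A1 <- sweep(A1, 2L, params$b1, `+`)
  Hn <- pmax(A1, 0)
  z <- Hn %*% params$W2
  if (params$bias) z <- sweep(z, 2L, params$b2, `+`)
  list(z = z, cache = if (keep_cache) list(r = r, A1 = A1, Hn = Hn))
}

projection_backward <- function(dz, params, cache) {
  dHn <- tcrossprod(dz, params$W2)
  dA1 <- dHn * (cache$A1 > 0)
  g <- list(W1 = crossprod(cache$r, dA1), W2 = crossprod(cache$Hn, dz))
  if (params$bias) {
    g$b1 <- colSums(dA1)
    g$b2 <- colSums(dz)
  }
  list(grads = g, dr = tcrossprod(dA1, params$W1))
}

#' Project representations to contrastive embeddings
#'
#' Applies `z = W2 ReLU(W1 r)` (plus biases if configured) row-wise.
#'
#' @param r `B x input_dim` matrix of representations.
#' @param params An [init_projection_head()] parameter set.
#' @return `B x output_dim` embedding matrix.
#' @export
project <- function(r, params) {
  stopifnot(ncol(r) == nrow(params$W1))
  projection_forward(r, params)$z
}

#' Pairwise cosine similarity
#'
#' `s[n, m] = z_n . z_m / (|z_n| |z_m|)`. The matrix is symmetric with unit
#' diagonal and entries in `[-1, 1]`.
#'
#' @param z Embedding matrix, one row per sample; no row may have zero norm.
#' @return Square similarity matrix.
#' @export
pairwise_similarity <- function(z) {
  nrm <- sqrt(rowSums(z * z))
  if (any(nrm == 0)) stop("zero-norm embedding", call. = FALSE)
  zh <- z / nrm
  S <- tcrossprod(zh)
  pmin(pmax(S, -1), 1)
}

# Positive-partner index under the interleaved (2k-1, 2k) batch layout.
partner_index <- function(n2) {
  ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)
}

#' Normalized temperature-scaled cross-entropy (NT-Xent) loss
#'
#' For a batch of `2N` embeddings laid out as interleaved view pairs
#' `(2k-1, 2k)`, each anchor's loss is the negative log-softmax (over the
#' `2N - 1` non-self candidates) of its positive partner's cosine
#' similarity, divided by the temperature. The total is the average over all
#' `2N` anchors, i.e. the symmetric sum over both orderings of each pair.
#' The loss is always non-negative; with a single pair (`N = 1`) the
#' denominator reduces to the positive term and the loss is exactly zero.
#'
#' @param z `2N x d` embedding matrix, interleaved view pairs.
#' @param tau Positive temperature.
#' @param reduce If `FALSE`, return the per-anchor loss vector (length `2N`)
#'   instead of the mean.
#' @return Scalar loss, or per-anchor vector.
#' @export
nt_xent <- function(z, tau = 0.1, reduce = TRUE) {
  if (tau <= 0) stop("temperature must be positive", call. = FALSE)
  n2 <- nrow(z)
  stopifnot(n2 >= 2L, n2 %% 2L == 0L)
  # norms are floored so a transiently all-zero embedding row during
  # training yields a defined (zero-similarity) column instead of an abort
  nrm <- pmax(sqrt(rowSums(z * z)), 1e-12)
  zh <- z / nrm
  logits <- pmin(pmax(tcrossprod(zh), -1), 1) / tau
  diag(logits) <- -Inf
  pos <- logits[cbind(seq_len(n2), partner_index(n2))]
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  l <- lse - pos
  if (reduce) mean(l) else l
}

#' Gradient of the NT-Xent loss with respect to the embeddings
#'
#' Analytic gradient of `nt_xent(z, tau)` (the mean over anchors) through
#' the softmax, the cosine similarity and the row normalization.
#'
#' @inheritParams nt_xent
#' @return Matrix with the shape of `z`.
#' @export
nt_xent_grad <- function(z, tau = 0.1) {
  if (tau <= 0) stop("temperature must be positive", call. = FALSE)
  n2 <- nrow(z)
  stopifnot(n2 >= 2L, n2 %% 2L == 0L)
  nrm <- pmax(sqrt(rowSums(z * z)), 1e-12)
  zh <- z / nrm
  S <- tcrossprod(zh)
  logits <- S / tau
  diag(logits) <- -Inf
  P <- softmax_rows(logits)
  G <- P
  G[cbind(seq_len(n2), partner_index(n2))] <-
    G[cbind(seq_len(n2), partner_index(n2))] - 1
  G <- G / (tau * n2)
  diag(G) <- 0
  dzh <- (G + t(G)) %*% zh
  (dzh - zh * rowSums(dzh * zh)) / nrm
}

#' Contrastive pretraining configuration
#'
#' Defaults mirror the reference experiment settings: batch size 500,
#' temperature 0.1, 200 epochs; the optimizer (Adam, step size 1e-3) is a
#' package default. The batch size is clamped to the pool size and the last
#' incomplete minibatch of each epoch is dropped.
#'
#' @param batch_size Images per minibatch (>= 2); each contributes two views.
#' @param temperature Positive temperature of the NT-Xent loss.
#' @param epochs Number of passes over the unlabeled pool.
#' @param lr Adam step size.
#' @param seed Seed controlling shuffling, augmentation draws and
#'   initialization of the optimizer stream.
#' @return A `contrastive_config` list.
#' @export
contrastive_config <- function(batch_size = 500L, temperature = 0.1,
                               epochs = 200L, lr = 1e-3, seed = NULL) {
  stopifnot(batch_size >= 2L, temperature > 0, epochs >= 0L, lr > 0)
  structure(list(batch_size = as.integer(batch_size),
                 temperature = temperature,
                 epochs = as.integer(epochs), lr = lr, seed = seed),
            class = "contrastive_config")
}

#' Contrastive pretraining of the encoder
#'
#' SimCLR-style pretraining on an unlabeled image pool: every minibatch
#' image is augmented into two views, both are encoded and projected, the
#' NT-Xent loss over the `2N` embeddings is minimized by one joint Adam step
#' on the encoder and the projection head. After the final epoch the
#' projection head is discarded and the trained encoder returned.
#'
#' @param images Unlabeled image batch (`H x W x C x N`, pixels on
#'   `[0, 255]`). Labels must not accompany this object.
#' @param encoder An [init_encoder()] parameter set.
#' @param projection An [init_projection_head()] parameter set, or `NULL` to
#'   create one matching the encoder width.
#' @param cfg A [contrastive_config()].
#' @param aug An [augment_config()] for view sampling.
#' @return A `contrastive_fit` list: `encoder` (trained parameters) and
#'   `history`, a tibble with columns `epoch` and `mean_loss`.
#' @export
contrastive_pretrain <- function(images, encoder, projection = NULL,
                                 cfg = contrastive_config(),
                                 aug = augment_config()) {
  images <- as_image_batch(images)
  n <- dim(images)[4]
  if (n == 0L) stop("empty unlabeled pool", call. = FALSE)
  bs <- min(cfg$batch_size, n)
  if (bs < 2L) stop("need at least 2 images per contrastive batch", call. = FALSE)
  run <- function() {
    if (is.null(projection)) {
      projection <- init_projection_head(input_dim = encoder$output_dim)
    }
    opt_e <- adam_init(list(embedding = encoder$embedding,
                            final_norm = encoder$final_norm,
                            blocks = encoder$blocks))
    opt_p <- adam_init(projection[c("W1", "b1", "W2", "b2")])
    history <- data.frame(epoch = integer(0), mean_loss = numeric(0))
    d <- dim(images)[1:3]
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      losses <- numeric(0)
      for (bi in seq_len(n %/% bs)) {
        idx <- perm[((bi - 1L) * bs + 1L):(bi * bs)]
        # two augmentation draws per image, views interleaved (2k-1, 2k)
        pars <- matrix(0, 2L * bs, 5L + 2L * d[3])
        for (j in seq_len(2L * bs)) {
          p <- draw_view_params(aug, d)
          pars[j, ] <- c("horizontal" %in% p$flips, "vertical" %in% p$flips,
                         p$dx, p$dy, p$zoom, p$gains, p$offsets)
        }
        views <- augment_views_cpp(images, d[1], d[2], d[3],
                                   rep(idx - 1L, each = 2L), pars,
                                   aug$rescale_mode == "minmax",
                                   aug$rescale_range[1], aug$rescale_range[2])
        dim(views) <- c(d, 2L * bs)
        ef <- encoder_forward(views, encoder, keep_cache = TRUE)
        pf <- projection_forward(ef$r, projection, keep_cache = TRUE)
        loss <- nt_xent(pf$z, cfg$temperature)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite contrastive loss at epoch %d batch %d",
                       epoch, bi), call. = FALSE)
        }
        losses <- c(losses, loss)
        dz <- nt_xent_grad(pf$z, cfg$temperature)
        pb <- projection_backward(dz, projection, pf$cache)
        eg <- encoder_backward(pb$dr, encoder, ef$cache)
        res_e <- adam_step(list(embedding = encoder$embedding,
                                final_norm = encoder$final_norm,
                                blocks = encoder$blocks),
                           eg, opt_e, lr = cfg$lr)
        encoder$embedding <- res_e$params$embedding
        encoder$final_norm <- res_e$params$final_norm
        encoder$blocks <- res_e$params$blocks
        opt_e <- res_e$state
        res_p <- adam_step(projection[c("W1", "b1", "W2", "b2")],
                           pb$grads, opt_p, lr = cfg$lr)
        projection[names(res_p$params)] <- res_p$params
        opt_p <- res_p$state
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, mean_loss = mean(losses)))
    }
    list(encoder = encoder, history = tibble::as_tibble(history))
  }
  out <- if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, run()) else run()
  structure(out, class = "contrastive_fit")
}
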