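#' Rectified linear unit
#'
#' Elementwise `max(0, x)`.
#'
#' @param x Numeric scalar or array.
#' @return Same shape as `x`.
#' @export
relu <- function(x) {
  stopifnot_finite(x, "relu input")
  pmax(x, 0)
}

#' Hidden-layer widths of the deep MLP classifier
#'
#' The fixed 12-hidden-layer architecture: three layers of 256, two of 512,
#' two of 1024, two of 512, and three of 256 neurons, each followed by ReLU.
#'
#' @return Integer vector of length 12.
#' @export
deep_mlp_widths <- function() {
  c(256L, 256L, 256L, 512L, 512L, 1024L, 1024L, 512L, 512L, 256L, 256L, 256L)
}

#' Initialize the deep MLP classifier
#'
#' Builds the classifier head applied to encoder representations: 12 hidden
#' affine+ReLU layers with the widths of [deep_mlp_widths()], then an affine
#' output layer of width `n_classes` read out through softmax. Weights use
#' He-normal initialization (suited to deep ReLU stacks), biases start at
#' zero.
#'
#' @param input_dim Width of the representation fed to the first layer.
#' @param n_classes Number of output classes `C`.
#' @param hidden Hidden widths; defaults to the fixed 12-layer sequence.
#' @param seed Optional seed for reproducible initialization.
#' @return A `deep_mlp_params` list with a `layers` list of `(W, b)` pairs.
#' @export
init_deep_mlp <- function(input_dim, n_classes, hidden = deep_mlp_widths(),
                          seed = NULL) {
  stopifnot(input_dim >= 1L, n_classes >= 2L)
  build <- function() {
    dims <- c(input_dim, hidden, n_classes)
    layers <- lapply(seq_len(length(dims) - 1L), function(i) {
      list(W = he_normal_mat(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L]))
    })
    list(layers = layers)
  }
  p <- if (!is.null(seed)) withr::with_seed(seed, build()) else build()
  structure(c(p, list(hidden_widths = as.integer(hidden),
                      input_dim = as.integer(input_dim),
                      n_classes = as.integer(n_classes))),
            class = "deep_mlp_params")
}

mlp_forward_cached <- function(r, params, keep_cache = FALSE) {
  nl <- length(params$layers)
  acts <- if (keep_cache) vector("list", nl)  # post-activation inputs per layer
  x <- r
  for (i in seq_len(nl - 1L)) {
    if (keep_cache) acts[[i]] <- x
    x <- pmax(sweep(x %*% params$layers[[i]]$W, 2L, params$layers[[i]]$b, `+`), 0)
  }
  if (keep_cache) acts[[nl]] <- x
  logits <- sweep(x %*% params$layers[[nl]]$W, 2L, params$layers[[nl]]$b, `+`)
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, acts = acts)
}

# dlogits -> parameter grads and gradient wrt the input representation.
mlp_backward <- function(dlogits, params, cache) {
  nl <- length(params$layers)
  grads <- vector("list", nl)
  dx <- dlogits
  for (i in rev(seq_len(nl))) {
    grads[[i]] <- list(W = crossprod(cache$acts[[i]], dx), b = colSums(dx))
    dx <- tcrossprod(dx, params$layers[[i]]$W)
    if (i > 1L) dx <- dx * (cache$acts[[i]] > 0)
  }
  list(grads = list(layers = grads), dr = dx)
}

#' Forward pass of the deep MLP classifier
#'
#' Applies the 12 hidden affine+ReLU layers and the softmax output layer.
#' Every output row is a probability vector over the `C` classes.
#'
#' @param r `B x input_dim` representation matrix.
#' @param params An [init_deep_mlp()] parameter set.
#' @return `B x C` matrix of class probabilities.
#' @export
mlp_forward <- function(r, params) {
  stopifnot(ncol(r) == nrow(params$layers[[1]]$W))
  mlp_forward_cached(r, params)$probs
}

#' Multi-class cross-entropy loss
#'
#' Mean over the batch of the negative natural log of the predicted
#' probability of the true class. Probabilities are floored at `1e-12`
#' inside the log for numeric safety.
#'
#' @param probs `B x C` matrix of predicted class probabilities.
#' @param y True classes: either a `B x C` one-hot matrix or an integer
#'   vector of 0-based class indices.
#' @return Non-negative scalar; zero iff every row puts probability 1 on
#'   its true class.
#' @export
cross_entropy <- function(probs, y) {
  if (is.matrix(y)) {
    stopifnot(all(dim(y) == dim(probs)))
    idx <- max.col(y, ties.method = "first")
  } else {
    stopifnot(length(y) == nrow(probs))
    idx <- as.integer(y) + 1L
  }
  p_true <- probs[cbind(seq_len(nrow(probs)), idx)]
  mean(-log(pmax(p_true, 1e-12)))
}

#' Fine-tuning configuration
#'
#' @param epochs Training passes over the labeled set.
#' @param batch_size Minibatch size.
#' @param lr Adam step size for the classifier head.
#' @param lr_schedule `"cosine"` (default) decays the step size to zero
#'   over the configured epochs (half-cosine), which stabilizes the deep
#'   head's convergence on small labeled sets; `"constant"` keeps it fixed.
#' @param freeze_encoder If `TRUE` the encoder is left untouched and its
#'   representations are computed once; otherwise encoder and head are
#'   updated jointly, the encoder at `encoder_lr_scale` times the step size.
#' @param encoder_lr_scale Relative encoder step size for joint updates.
#' @param seed Seed for shuffling and initialization streams.
#' @return A `finetune_config` list.
#' @export
finetune_config <- function(epochs = 100L, batch_size = 128L, lr = 1e-4,
                            lr_schedule = c("cosine", "constant"),
                            freeze_encoder = FALSE, encoder_lr_scale = 0.1,
                            seed = NULL) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(epochs >= 0L, batch_size >= 1L, lr > 0, encoder_lr_scale > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_schedule = lr_schedule,
                 freeze_encoder = freeze_encoder,
                 encoder_lr_scale = encoder_lr_scale, seed = seed),
            class = "finetune_config")
}

#' Fine-tune the classifier on labeled images
#'
#' Minimizes the multi-class cross-entropy of the deep MLP head applied to
#' encoder representations, by minibatch Adam. With
#' `cfg$freeze_encoder = TRUE` only the head is trained on frozen
#' representations; otherwise gradients are propagated through the encoder,
#' which is updated at a reduced step size.
#'
#' @param images Labeled image batch (`H x W x C x N`, pixels on `[0, 255]`).
#' @param labels Integer vector of 0-based class indices, length `N`.
#' @param encoder An [init_encoder()] parameter set (pretrained or random).
#' @param head An [init_deep_mlp()] parameter set, or `NULL` to create one
#'   matching the encoder width and the number of classes present.
#' @param n_classes Number of classes `C`; defaults to `max(labels) + 1`.
#' @param cfg A [finetune_config()].
#' @return A `finetune_fit` list: `encoder`, `head`, and `history` (tibble
#'   with `epoch`, `mean_loss`, `train_accuracy`).
#' @export
finetune <- function(images, labels, encoder, head = NULL,
                     n_classes = max(labels) + 1L, cfg = finetune_config()) {
  images <- as_image_batch(images)
  n <- dim(images)[4]
  if (n == 0L) stop("empty labeled set", call. = FALSE)
  stopifnot(length(labels) == n, all(labels >= 0L), all(labels < n_classes))
  labels <- as.integer(labels)
  if (is.null(head)) {
    head <- init_deep_mlp(encoder$output_dim, n_classes)
  }
  run <- function() {
    opt_h <- adam_init(list(layers = head$layers))
    opt_e <- if (!cfg$freeze_encoder) {
      adam_init(list(embedding = encoder$embedding,
                 final_norm = encoder$final_norm, blocks = encoder$blocks))
    }
    # feature-wise standardization of the representations fed to the head,
    # with constants fixed from the initial encoder over the training set
    r_init <- encode(images, encoder)
    rep_center <- colMeans(r_init)
    rep_scale <- pmax(apply(r_init, 2L, stats::sd), 1e-8)
    frozen_r <- if (cfg$freeze_encoder) {
      sweep(sweep(r_init, 2L, rep_center), 2L, rep_scale, `/`)
    }
    history <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                          train_accuracy = numeric(0))
    bs <- min(cfg$batch_size, n)
    for (epoch in seq_len(cfg$epochs)) {
      lr_now <- if (cfg$lr_schedule == "cosine") {
        cfg$lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(cfg$epochs, 1L)))
      } else cfg$lr
      perm <- sample.int(n)
      losses <- numeric(0); correct <- 0L; seen <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, n)]
        y <- labels[idx]
        if (cfg$freeze_encoder) {
          r <- frozen_r[idx, , drop = FALSE]
          ec <- NULL
        } else {
          ef <- encoder_forward(images[, , , idx, drop = FALSE], encoder,
                                keep_cache = TRUE)
          r <- sweep(sweep(ef$r, 2L, rep_center), 2L, rep_scale, `/`)
          ec <- ef$cache
        }
        fw <- mlp_forward_cached(r, head, keep_cache = TRUE)
        loss <- cross_entropy(fw$probs, y)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite fine-tuning loss at epoch %d", epoch),
               call. = FALSE)
        }
        losses <- c(losses, loss)
        pred <- max.col(fw$probs, ties.method = "first") - 1L
        correct <- correct + sum(pred == y); seen <- seen + length(y)
        Y <- matrix(0, length(y), head$n_classes)
        Y[cbind(seq_along(y), y + 1L)] <- 1
        dlogits <- (fw$probs - Y) / length(y)
        mb <- mlp_backward(dlogits, head, fw)
        res_h <- adam_step(list(layers = head$layers), mb$grads, opt_h,
                           lr = lr_now)
        head$layers <- res_h$params$layers
        opt_h <- res_h$state
        if (!cfg$freeze_encoder) {
          eg <- encoder_backward(sweep(mb$dr, 2L, rep_scale, `/`), encoder, ec)
          res_e <- adam_step(list(embedding = encoder$embedding,
                                  final_norm = encoder$final_norm,
                                  blocks = encoder$blocks),
                             eg, opt_e, lr = lr_now * cfg$encoder_lr_scale)
          encoder$embedding <- res_e$params$embedding
          encoder$final_norm <- res_e$params$final_norm
          encoder$blocks <- res_e$params$blocks
          opt_e <- res_e$state
        }
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           mean_loss = mean(losses),
                                           train_accuracy = correct / seen))
    }
    list(encoder = encoder, head = head,
         rep_center = rep_center, rep_scale = rep_scale,
         history = tibble::as_tibble(history))
  }
  out <- if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, run()) else run()
  structure(out, class = "finetune_fit")
}

#' Predict classes for new images
#'
#' @param object A `finetune_fit`.
#' @param images Image batch on the `[0, 255]` pixel scale.
#' @param ... Unused.
#' @return Tibble with columns `class` (0-based predicted index) and one
#'   probability column per class (`p0`, `p1`, ...).
#' @export
predict.finetune_fit <- function(object, images, ...) {
  r <- encode(images, object$encoder)
  r <- sweep(sweep(r, 2L, object$rep_center), 2L, object$rep_scale, `/`)
  probs <- mlp_forward(r, object$head)
  out <- tibble::tibble(class = max.col(probs, ties.method = "first") - 1L)
  colnames(probs) <- paste0("p", seq_len(ncol(probs)) - 1L)
  dplyr::bind_cols(out, tibble::as_tibble(probs))
}
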