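#' Classification metrics report
#'
#' Per-class precision, recall and F1 from the confusion matrix, their macro
#' averages (equal class weight), and overall accuracy. A class that is
#' never predicted receives precision 0 (not `NaN`) so that aggregates stay
#' defined; likewise recall for a class absent from the truth.
#'
#' @param predictions Integer vector of predicted 0-based class indices.
#' @param truth Integer vector of true 0-based class indices, same length.
#' @param n_classes Number of classes `C`.
#' @param labeled_ratio,variant Optional experiment tags carried through to
#'   the report.
#' @return A `metrics_report`: list with `per_class` (tibble), macro
#'   `precision`, `recall`, `f1`, `accuracy`, the `C x C` `confusion`
#'   matrix (rows = truth, columns = prediction), and `n`.
#' @export
#' @examples
#' m <- compute_metrics(c(0, 1, 1, 0), c(0, 1, 0, 0), n_classes = 2)
#' m$accuracy
compute_metrics <- function(predictions, truth, n_classes,
                            labeled_ratio = NA_real_,
                            variant = NA_character_) {
  stopifnot(length(predictions) == length(truth))
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  stopifnot(all(predictions >= 0L), all(predictions < n_classes),
            all(truth >= 0L), all(truth < n_classes))
  lv <- 0:(n_classes - 1L)
  confusion <- table(truth = factor(truth, levels = lv),
                     prediction = factor(predictions, levels = lv))
  confusion <- unclass(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  per_class <- tibble::tibble(class = lv, precision = as.numeric(precision),
                              recall = as.numeric(recall), f1 = as.numeric(f1),
                              support = as.numeric(rowSums(confusion)))
  structure(list(per_class = per_class,
                 precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1), accuracy = sum(tp) / length(truth),
                 confusion = confusion, n = length(truth),
                 labeled_ratio = labeled_ratio, variant = variant),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics report (%d samples%s%s)\n", x$n,
              if (!is.na(x$variant)) paste0(", variant ", x$variant) else "",
              if (!is.na(x$labeled_ratio))
                sprintf(", labeled ratio %g", x$labeled_ratio) else ""))
  cat(sprintf("  accuracy %.4f | macro precision %.4f recall %.4f F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Train a linear probe on frozen representations
#'
#' The minimal readout used in the encoder-only ablation row: a single
#' affine layer with softmax, i.e. multinomial logistic regression, fitted
#' on frozen encoder representations via [nnet::multinom()].
#'
#' @param r Training representation matrix.
#' @param y 0-based integer class labels.
#' @return A `linear_probe` model object.
#' @export
linear_probe <- function(r, y) {
  center <- colMeans(r)
  scl <- pmax(apply(r, 2L, stats::sd), 1e-8)
  rs <- sweep(sweep(r, 2L, center), 2L, scl, `/`)
  df <- as.data.frame(rs)
  df$.y <- factor(y, levels = sort(unique(y)))
  # multinom draws its initial weights from the RNG; fix a local seed so
  # the probe is a pure function of its inputs
  fit <- withr::with_seed(1L,
    nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300,
                   MaxNWts = 1e5))
  structure(list(fit = fit, levels = levels(df$.y),
                 center = center, scale = scl), class = "linear_probe")
}

#' @export
predict.linear_probe <- function(object, r, ...) {
  rs <- sweep(sweep(r, 2L, object$center), 2L, object$scale, `/`)
  df <- as.data.frame(rs)
  as.integer(as.character(predict(object$fit, newdata = df)))
}

#' Linear-probe evaluation of an encoder
#'
#' Encodes the full dataset with a (frozen) encoder, trains a linear probe
#' on the labeled-training representations, and evaluates on the held-out
#' test set of the split plan.
#'
#' @param images Full image batch.
#' @param labels 0-based integer labels.
#' @param plan A [make_split()] plan.
#' @param encoder An [init_encoder()] parameter set.
#' @param n_classes Number of classes.
#' @param variant Tag stored in the report.
#' @return A `metrics_report`.
#' @export
probe_evaluate <- function(images, labels, plan, encoder,
                           n_classes = max(labels) + 1L,
                           variant = "medclr_only") {
  r <- encode(images, encoder)
  lab <- split_indices(plan, "labeled_train")
  tst <- split_indices(plan, "test")
  probe <- linear_probe(r[lab, , drop = FALSE], labels[lab])
  pred <- predict(probe, r[tst, , drop = FALSE])
  compute_metrics(pred, labels[tst], n_classes,
                  labeled_ratio = plan$labeled_ratio, variant = variant)
}

experiment_defaults <- function(n = NULL) {
  list(encoder_opts = list(P = 16L, D = 64L, k = 4L, D_mlp = 128L, L = 1L),
       pretrain_cfg = contrastive_config(batch_size = 8L, epochs = 20L,
                                         temperature = 0.1, lr = 1e-3),
       finetune_cfg = finetune_config(epochs = 40L, batch_size = 64L,
                                      lr = 1e-3, freeze_encoder = TRUE),
       aug = augment_config())
}

report_row <- function(report, seed, variant) {
  tibble::tibble(seed = seed, variant = variant,
                 labeled_ratio = report$labeled_ratio,
                 accuracy = report$accuracy, precision = report$precision,
                 recall = report$recall, f1 = report$f1,
                 report = list(report))
}

#' Run the semi-supervised experiment grid
#'
#' For each seed and labeled ratio: build the stratified split, pretrain the
#' encoder contrastively on the unlabeled pool (labels hidden), then
#' evaluate the requested variants on the shared held-out test set --
#' `"probe"` (frozen pretrained encoder + linear probe on the labeled
#' subset), `"full"` (pretraining + deep-MLP fine-tuning) and
#' `"random_probe"` (the same probe on a randomly initialized encoder, the
#' no-pretraining baseline). Identical splits and initializations are used
#' across variants within a (seed, ratio) cell.
#'
#' @param images,labels Dataset (0-based integer labels).
#' @param ratios Labeled ratios to evaluate (each in (0, 1]).
#' @param seeds Integer seeds; results are averaged downstream.
#' @param variants Subset of `c("probe", "full", "random_probe")`.
#' @param encoder_opts Arguments to [init_encoder()] besides the image
#'   dimensions.
#' @param pretrain_cfg A [contrastive_config()].
#' @param finetune_cfg A [finetune_config()].
#' @param aug An [augment_config()].
#' @return Tibble with one row per (seed, ratio, variant): metric columns
#'   and the full `metrics_report` in a list-column `report`.
#' @export
run_experiment <- function(images, labels, ratios = 0.5, seeds = 1L,
                           variants = c("probe", "full"),
                           encoder_opts = NULL, pretrain_cfg = NULL,
                           finetune_cfg = NULL, aug = NULL) {
  defaults <- experiment_defaults()
  encoder_opts <- encoder_opts %||% defaults$encoder_opts
  pretrain_cfg <- pretrain_cfg %||% defaults$pretrain_cfg
  finetune_cfg <- finetune_cfg %||% defaults$finetune_cfg
  aug <- aug %||% defaults$aug
  stopifnot(all(variants %in% c("probe", "full", "random_probe")))
  images <- as_image_batch(images)
  d <- dim(images)
  n_classes <- max(labels) + 1L
  rows <- list()
  for (seed in seeds) {
    for (ratio in ratios) {
      stopifnot(ratio > 0, ratio <= 1)
      plan <- make_split(labels, labeled_ratio = ratio, seed = seed)
      enc0 <- do.call(init_encoder,
                      c(list(H = d[1], W = d[2], C = d[3], seed = seed),
                        encoder_opts))
      if (ratio < 1 && length(split_indices(plan, "unlabeled_train")) >= 2L) {
        pcfg <- pretrain_cfg; pcfg$seed <- seed
        fit <- contrastive_pretrain(unlabeled_pool(images, plan), enc0,
                                    cfg = pcfg, aug = aug)
        enc <- fit$encoder
      } else {
        enc <- enc0  # degenerate ratio 1: no unlabeled pool to pretrain on
      }
      for (variant in variants) {
        report <- switch(
          variant,
          probe = probe_evaluate(images, labels, plan, enc, n_classes,
                                 variant = "medclr_only"),
          random_probe = probe_evaluate(images, labels, plan, enc0, n_classes,
                                        variant = "random_probe"),
          full = {
            lab <- split_indices(plan, "labeled_train")
            fcfg <- finetune_cfg; fcfg$seed <- seed
            head <- init_deep_mlp(enc$output_dim, n_classes, seed = seed)
            ft <- finetune(images[, , , lab, drop = FALSE], labels[lab],
                           enc, head, n_classes = n_classes, cfg = fcfg)
            tst <- split_indices(plan, "test")
            pred <- predict(ft, images[, , , tst, drop = FALSE])$class
            rep <- compute_metrics(pred, labels[tst], n_classes,
                                   labeled_ratio = ratio, variant = "full")
            rep
          })
        rows[[length(rows) + 1L]] <- report_row(report, seed, variant)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(seed = integer(0), variant = character(0),
                          labeled_ratio = numeric(0), accuracy = numeric(0),
                          precision = numeric(0), recall = numeric(0),
                          f1 = numeric(0), report = list()))
  }
  dplyr::bind_rows(rows)
}

#' Ablation: linear probe versus full pipeline
#'
#' Produces the two ablation rows at one labeled ratio -- the frozen
#' pretrained encoder with a linear probe (`medclr_only`) and the full
#' pipeline with the deep MLP head (`full`) -- under identical splits,
#' seeds and pretraining.
#'
#' @inheritParams run_experiment
#' @param labeled_ratio Single labeled ratio in (0, 1].
#' @return Tibble with one row per (seed, variant); see [run_experiment()].
#' @export
ablation_run <- function(images, labels, labeled_ratio = 0.5, seeds = 1L,
                         ...) {
  run_experiment(images, labels, ratios = labeled_ratio, seeds = seeds,
                 variants = c("probe", "full"), ...)
}

#' Labeled-ratio sweep of the full pipeline
#'
#' One full-pipeline evaluation per labeled ratio on the shared held-out
#' test set.
#'
#' @inheritParams run_experiment
#' @return Tibble with one row per (seed, ratio); empty `ratios` gives an
#'   empty table.
#' @export
ratio_sweep <- function(images, labels, ratios = c(0.1, 0.25, 0.5),
                        seeds = 1L, ...) {
  run_experiment(images, labels, ratios = ratios, seeds = seeds,
                 variants = "full", ...)
}
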