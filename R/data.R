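#' Synthetic image dataset specification
#'
#' Describes a procedurally generated stand-in for directory-per-class
#' medical image datasets (synthetic; no real images involved). Each class
#' is defined by one fixed base pattern: an isotropic band-limited texture
#' with a class-specific dominant spatial frequency (geometric sequence
#' `1.5 * 2^(c-1)` cycles per image) and a mild class hue tint. Each
#' generated image applies nuisance variation on top of the base pattern:
#' an optional random flip / small translation / small zoom, a random
#' per-channel color gain and offset, and i.i.d. Gaussian pixel noise. All
#' nuisances lie inside the augmentation family of [augment_config()], so
#' the class signal survives contrastive-view augmentation while raw-pixel
#' shortcuts (mean color, exact pixel values) are unreliable.
#'
#' @param n_classes Number of classes.
#' @param images_per_class Images generated per class.
#' @param H,W,C Image dimensions (pixels on the 0-255 scale).
#' @param noise_sd Standard deviation of additive pixel noise (0-255 scale).
#' @param pattern_jitter Fraction (in `[0, 1]`) of the texture power drawn
#'   freshly per image from the class frequency band; the remainder is the
#'   fixed class base texture. Keeps same-class images distinguishable (so
#'   the contrastive task is well posed) while class statistics and partial
#'   base correlation carry the class signal.
#' @param color_variation Per-image color nuisance strength `v`: channel
#'   gains uniform in `[1 - v, 1 + v]`, offsets uniform in `[-75 v, 75 v]`.
#' @param spatial_jitter Apply random flip, translation (<= 8% of the side)
#'   and zoom (within 12%) per image?
#' @param tint_strength Magnitude of the class hue tint.
#' @param seed Seed making the dataset deterministic.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 4L, images_per_class = 250L,
                           H = 96L, W = 96L, C = 3L,
                           noise_sd = 10, color_variation = 0.2,
                           spatial_jitter = TRUE, tint_strength = 0.08,
                           pattern_jitter = 0.5, seed = 1L) {
  stopifnot(n_classes >= 2L, images_per_class >= 1L, noise_sd >= 0,
            color_variation >= 0, C == 3L,
            pattern_jitter >= 0, pattern_jitter <= 1)
  structure(list(n_classes = as.integer(n_classes),
                 images_per_class = as.integer(images_per_class),
                 H = as.integer(H), W = as.integer(W), C = as.integer(C),
                 noise_sd = noise_sd, color_variation = color_variation,
                 spatial_jitter = spatial_jitter,
                 tint_strength = tint_strength,
                 pattern_jitter = pattern_jitter, seed = seed),
            class = "synthetic_spec")
}

# Zero-mean unit-sd isotropic texture with power restricted to the annulus
# [f/band, f*band] in cycles per image, via an FFT of masked white noise.
bandlimited_field <- function(H, W, f, band = 1.3) {
  kv <- function(n) {
    k <- 0:(n - 1L)
    k[k > n / 2] <- k[k > n / 2] - n
    k
  }
  rad <- sqrt(outer(kv(H)^2, kv(W)^2, `+`))
  mask <- rad >= f / band & rad <= f * band
  if (!any(mask)) mask[which.min(abs(rad - f))] <- TRUE
  spec <- matrix(complex(real = stats::rnorm(H * W),
                         imaginary = stats::rnorm(H * W)), H, W) * mask
  x <- Re(stats::fft(spec, inverse = TRUE))
  (x - mean(x)) / stats::sd(x)
}

# Fixed per-class hue tint directions (multiplicative, unit-mean-ish).
class_tints <- function(n_classes, strength) {
  dirs <- rbind(c(1, -0.5, -0.5), c(-0.5, 1, -0.5), c(-0.5, -0.5, 1),
                c(0.8, 0.8, -1), c(-1, 0.8, 0.8), c(0.8, -1, 0.8))
  dirs <- dirs[rep_len(seq_len(nrow(dirs)), n_classes), , drop = FALSE]
  1 + strength * dirs
}

#' Class base patterns of the synthetic generator
#'
#' The noise-free `H x W x C` pattern of each class (texture times tint),
#' deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of `n_classes` arrays on the `[0, 255]` scale.
#' @export
synthetic_patterns <- function(spec) {
  withr::with_seed(spec$seed, {
    tints <- class_tints(spec$n_classes, spec$tint_strength)
    lapply(seq_len(spec$n_classes), function(cl) {
      f <- 1.5 * 2^(cl - 1L)
      tex <- bandlimited_field(spec$H, spec$W, f)
      img <- array(0, c(spec$H, spec$W, spec$C))
      for (ch in seq_len(spec$C)) {
        img[, , ch] <- (120 + 45 * tex) * tints[cl, ch]
      }
      img[img < 0] <- 0; img[img > 255] <- 255
      img
    })
  })
}

#' Generate a synthetic labeled image dataset
#'
#' Draws `images_per_class` nuisance-perturbed copies of each class base
#' pattern (see [synthetic_spec()]). Deterministic given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `images` (`H x W x C x N` array, pixels in `[0, 255]`)
#'   and `labels` (integer vector of 0-based class indices, grouped by
#'   class).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  patterns <- synthetic_patterns(spec)
  n <- spec$n_classes * spec$images_per_class
  images <- array(0, c(spec$H, spec$W, spec$C, n))
  labels <- rep(seq_len(spec$n_classes) - 1L, each = spec$images_per_class)
  withr::with_seed(spec$seed + 1L, {
    i <- 0L
    tints <- class_tints(spec$n_classes, spec$tint_strength)
    for (cl in seq_len(spec$n_classes)) {
      base <- patterns[[cl]]
      for (j in seq_len(spec$images_per_class)) {
        i <- i + 1L
        img <- base
        if (spec$pattern_jitter > 0) {
          # fresh texture in the same class band, blended at constant power
          fresh <- bandlimited_field(spec$H, spec$W, 1.5 * 2^(cl - 1L))
          w_base <- sqrt(1 - spec$pattern_jitter)
          w_new <- sqrt(spec$pattern_jitter)
          for (ch in seq_len(spec$C)) {
            tex_mix <- w_base * (base[, , ch] / tints[cl, ch] - 120) / 45 +
              w_new * fresh
            img[, , ch] <- (120 + 45 * tex_mix) * tints[cl, ch]
          }
          img[img < 0] <- 0; img[img > 255] <- 255
        }
        if (spec$spatial_jitter) {
          if (stats::runif(1) < 0.5) img <- flip_image(img, "horizontal")
          dx <- stats::runif(1, -0.08, 0.08) * spec$W
          dy <- stats::runif(1, -0.08, 0.08) * spec$H
          zf <- stats::runif(1, 0.88, 1.12)
          img <- bilinear_warp(img, scale = zf, dx = dx, dy = dy)
        }
        if (spec$color_variation > 0) {
          v <- spec$color_variation
          gains <- stats::runif(spec$C, 1 - v, 1 + v)
          offs <- stats::runif(spec$C, -75 * v, 75 * v)
          for (ch in seq_len(spec$C)) {
            img[, , ch] <- img[, , ch] * gains[ch] + offs[ch]
          }
        }
        if (spec$noise_sd > 0) {
          img <- img + array(stats::rnorm(length(img), sd = spec$noise_sd),
                             dim(img))
        }
        img[img < 0] <- 0; img[img > 255] <- 255
        images[, , , i] <- img
      }
    }
  })
  list(images = images, labels = labels)
}

#' Deterministic stratified train/test and labeled-ratio split
#'
#' Two-stage protocol: first a stratified holdout of `test_fraction` of the
#' images as the test set; then the remaining training images are split,
#' again per class, into a labeled subset of `labeled_ratio` and an
#' unlabeled remainder whose labels are hidden from all training code.
#' Labeled subsets are nested across increasing ratios under the same seed
#' (the per-class permutation does not depend on the ratio).
#'
#' @param labels Integer vector of 0-based class indices, one per image.
#' @param test_fraction Fraction held out for testing, in (0, 1).
#' @param labeled_ratio Fraction of the training split whose labels are
#'   used, in (0, 1].
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return A `split_plan`: list with `assignment` (character vector over
#'   `"test"`, `"labeled_train"`, `"unlabeled_train"`), plus the settings.
#' @export
#' @examples
#' plan <- make_split(rep(0:1, each = 50), 0.2, 0.5, seed = 1)
#' table(plan$assignment)
make_split <- function(labels, test_fraction = 0.2, labeled_ratio = 0.5,
                       seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            labeled_ratio > 0, labeled_ratio <= 1)
  labels <- as.integer(labels)
  n <- length(labels)
  classes <- sort(unique(labels))
  if (n < length(classes)) stop("fewer images than classes", call. = FALSE)
  assignment <- character(n)
  withr::with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      n_c <- length(idx)
      n_test <- round(test_fraction * n_c)
      n_train <- n_c - n_test
      n_lab <- round(labeled_ratio * n_train)
      if (n_test < 1L || n_lab < 1L) {
        stop(sprintf("class %d too small for stratified split", cl),
             call. = FALSE)
      }
      perm <- idx[sample.int(n_c)]
      assignment[perm[seq_len(n_test)]] <- "test"
      assignment[perm[n_test + seq_len(n_lab)]] <- "labeled_train"
      if (n_train > n_lab) {
        assignment[perm[(n_test + n_lab + 1L):n_c]] <- "unlabeled_train"
      }
    }
  })
  structure(list(assignment = assignment, test_fraction = test_fraction,
                 labeled_ratio = labeled_ratio, seed = seed, n = n),
            class = "split_plan")
}

#' Indices of a split component
#'
#' @param plan A [make_split()] plan.
#' @param which One of `"test"`, `"labeled_train"`, `"unlabeled_train"`,
#'   `"train"` (labeled and unlabeled together).
#' @return Integer indices into the image batch.
#' @export
split_indices <- function(plan, which = c("test", "labeled_train",
                                          "unlabeled_train", "train")) {
  which <- match.arg(which)
  if (which == "train") {
    return(base::which(plan$assignment != "test"))
  }
  base::which(plan$assignment == which)
}

#' Label-free view of the unlabeled training pool
#'
#' Extracts the unlabeled-training images as a bare pixel array carrying no
#' label information, the only object the pretraining path is given.
#'
#' @param images Full image batch.
#' @param plan A [make_split()] plan.
#' @return `H x W x C x M` array with no attributes besides `dim`.
#' @export
unlabeled_pool <- function(images, plan) {
  images <- as_image_batch(images)
  out <- images[, , , split_indices(plan, "unlabeled_train"), drop = FALSE]
  attributes(out) <- list(dim = dim(out))
  out
}

#' Load a directory-per-class image dataset
#'
#' Reads a tree with one subdirectory per class containing PNG/JPEG files,
#' decodes each image, resizes it to `H x W` (bilinear, aspect ratio not
#' preserved) and returns pixels on the `[0, 255]` scale. Ordering is
#' deterministic (classes and file paths sorted). Unreadable files are
#' skipped with a warning; an empty class is an error.
#'
#' @param root Directory containing one subdirectory per class.
#' @param H,W Target image size.
#' @return List with `images` (`H x W x 3 x N`), `labels` (0-based integer
#'   indices in sorted class-name order) and `class_names`.
#' @export
load_image_folder <- function(root, H = 96L, W = 96L) {
  dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(dirs) == 0L) stop("no class subdirectories in ", root, call. = FALSE)
  imgs <- list(); labels <- integer(0)
  for (ci in seq_along(dirs)) {
    files <- sort(list.files(dirs[ci], pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    loaded <- 0L
    for (f in files) {
      arr <- tryCatch({
        e <- EBImage::readImage(f)
        e <- EBImage::resize(e, w = W, h = H)
        a <- as.array(e)
        if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
        if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
        aperm(a, c(2L, 1L, 3L)) * 255
      }, error = function(err) {
        warning("skipping unreadable file: ", f, call. = FALSE)
        NULL
      })
      if (!is.null(arr)) {
        imgs[[length(imgs) + 1L]] <- arr
        labels <- c(labels, ci - 1L)
        loaded <- loaded + 1L
      }
    }
    if (loaded == 0L) {
      stop("class directory has no readable images: ", dirs[ci], call. = FALSE)
    }
  }
  images <- array(0, c(H, W, 3L, length(imgs)))
  for (i in seq_along(imgs)) images[, , , i] <- imgs[[i]]
  list(images = images, labels = labels, class_names = basename(dirs))
}
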