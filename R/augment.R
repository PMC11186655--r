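#' Augmentation configuration
#'
#' Settings for the stochastic augmentation module that turns one image into
#' two correlated views (a positive pair) for contrastive pretraining. The
#' chain applies five named stages in order: per-image rescaling to a pixel
#' range, random mirror flips, random translation, random zoom, and a random
#' per-channel color affine map. All magnitudes are fractions of the image
#' side or of the pixel range; a zero-strength configuration is the identity
#' (after rescaling).
#'
#' @param rescale_range Length-2 numeric, lower < upper pixel bound after
#'   rescaling. Default `c(0, 255)`.
#' @param rescale_mode `"minmax"` maps each image's min/max onto the range;
#'   `"none"` leaves pixel values untouched (for data already on the range).
#' @param flip_axes Character vector, subset of
#'   `c("horizontal", "vertical")`, or `"none"`. Default horizontal only.
#' @param flip_prob Probability that each enabled flip is applied.
#' @param translation_fraction Maximum shift, as a fraction of the image
#'   side, drawn uniformly per axis. Must lie in `[0, 1)`.
#' @param zoom_fraction Maximum relative scale change `z`; the zoom factor is
#'   drawn uniformly from `[1 - z, 1 + z]`. Must lie in `[0, 1)`.
#' @param color_affine_strength Magnitude `s` of the per-channel color map:
#'   gains uniform in `[1 - s, 1 + s]`, offsets uniform in
#'   `[-s, s] * diff(rescale_range)`. Output is clipped back to the range.
#' @param seed Optional integer seed making [make_view_pair()] and
#'   [sample_view()] pure functions of `(image, cfg)`.
#'
#' @return An object of class `augment_config` (a list of the settings).
#' @seealso [sample_view()], [make_view_pair()], [augmentation_stages()]
#' @export
#' @examples
#' cfg <- augment_config(seed = 1)
#' img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
#' pair <- make_view_pair(img, cfg)
#' str(pair$view1)
augment_config <- function(rescale_range = c(0, 255),
                           rescale_mode = c("minmax", "none"),
                           flip_axes = "horizontal",
                           flip_prob = 0.5,
                           translation_fraction = 0.1,
                           zoom_fraction = 0.15,
                           color_affine_strength = 0.2,
                           seed = NULL) {
  rescale_mode <- match.arg(rescale_mode)
  stopifnot(length(rescale_range) == 2L, rescale_range[1] < rescale_range[2])
  if (identical(flip_axes, "none")) flip_axes <- character(0)
  stopifnot(all(flip_axes %in% c("horizontal", "vertical")))
  stopifnot(translation_fraction >= 0, translation_fraction < 1)
  stopifnot(zoom_fraction >= 0, zoom_fraction < 1)
  stopifnot(color_affine_strength >= 0)
  structure(list(rescale_range = as.numeric(rescale_range),
                 rescale_mode = rescale_mode,
                 flip_axes = flip_axes,
                 flip_prob = flip_prob,
                 translation_fraction = translation_fraction,
                 zoom_fraction = zoom_fraction,
                 color_affine_strength = color_affine_strength,
                 seed = seed),
            class = "augment_config")
}

#' Named stages of the augmentation chain
#'
#' The augmentation module is a fixed pipeline of five named transform
#' stages; [sample_view()] draws random parameters for each stage and applies
#' them in this order.
#'
#' @return Character vector of the five stage names, in application order.
#' @export
augmentation_stages <- function() {
  c("rescale", "flip", "translate", "zoom", "color_affine")
}

#' Coerce to an image batch
#'
#' Images are numeric arrays `H x W x C`; a batch stacks them along a fourth
#' axis, `H x W x C x N`.
#'
#' @param x A 3-d array (single image) or 4-d array (batch).
#' @return A 4-d `H x W x C x N` array.
#' @export
as_image_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

#' Per-image min-max rescaling to a pixel range
#'
#' Maps each image's minimum to the lower bound and maximum to the upper
#' bound of `cfg$rescale_range`. A constant image (zero range) maps to the
#' lower bound everywhere, keeping the operation deterministic.
#'
#' @param batch An image batch (`H x W x C x N`, or a single `H x W x C`
#'   image, returned in kind).
#' @param cfg An [augment_config()].
#' @return Batch of the same shape with pixels in the configured range.
#' @export
rescale_pixels <- function(batch, cfg = augment_config()) {
  single <- length(dim(batch)) == 3L
  b <- as_image_batch(batch)
  if (length(b) == 0L || dim(b)[4] == 0L) stop("empty image batch", call. = FALSE)
  stopifnot_finite(b, "image batch")
  if (cfg$rescale_mode == "none") {
    return(if (single) array(b, dim(b)[1:3]) else b)
  }
  lo <- cfg$rescale_range[1]; hi <- cfg$rescale_range[2]
  for (n in seq_len(dim(b)[4])) {
    img <- b[, , , n, drop = FALSE]
    rng <- range(img)
    b[, , , n] <- if (rng[2] > rng[1]) {
      (img - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
    } else lo
  }
  if (single) array(b, dim(b)[1:3]) else b
}

#' Deterministic mirror flip
#'
#' @param image `H x W x C` array.
#' @param axis `"horizontal"` (mirror columns) or `"vertical"` (mirror rows).
#' @return Flipped image; applying the same flip twice is the identity.
#' @export
flip_image <- function(image, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  else image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
}

# Fold real-valued coordinates into [1, n] by reflection at the borders.
reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  t <- (x - 1) %% (2 * (n - 1))
  n - abs(t - (n - 1))
}

# Bilinear resampling of the affine map
# src = center + (dest - center)/scale - shift, with reflection padding.
# scale > 1 zooms in; (dx, dy) shift content right/down, in pixels.
bilinear_warp <- function(image, scale = 1, dx = 0, dy = 0) {
  out <- warp_bilinear_cpp(image, scale, dx, dy)
  dim(out) <- dim(image)
  out
}

# Draw all stage parameters for one view from the current RNG stream.
# The draw order and count are fixed so the stream stays aligned.
draw_view_params <- function(cfg, dims) {
  H <- dims[1]; W <- dims[2]; C <- dims[3]
  flips <- character(0)
  for (ax in c("horizontal", "vertical")) {
    if (ax %in% cfg$flip_axes && stats::runif(1) < cfg$flip_prob) flips <- c(flips, ax)
  }
  tf <- cfg$translation_fraction
  dx <- stats::runif(1, -tf, tf) * W
  dy <- stats::runif(1, -tf, tf) * H
  zoom <- stats::runif(1, 1 - cfg$zoom_fraction, 1 + cfg$zoom_fraction)
  s <- cfg$color_affine_strength
  span <- diff(cfg$rescale_range)
  gains <- stats::runif(C, 1 - s, 1 + s)
  offsets <- stats::runif(C, -s, s) * span
  list(flips = flips, dx = dx, dy = dy, zoom = zoom,
       gains = gains, offsets = offsets)
}

# The whole stage chain (rescale -> flips -> translation -> zoom -> color
# affine -> clip) runs as one fused gather pass; the two spatial stages
# share a single bilinear resampling to avoid double interpolation blur.
apply_view_params <- function(image, p, cfg) {
  stopifnot_finite(image, "image")
  out <- view_chain_cpp(image, cfg$rescale_mode == "minmax",
                        cfg$rescale_range[1], cfg$rescale_range[2],
                        "horizontal" %in% p$flips, "vertical" %in% p$flips,
                        p$dx, p$dy, p$zoom, p$gains, p$offsets)
  dim(out) <- dim(image)
  out
}

#' Sample one augmented view of an image
#'
#' Draws random parameters for the five augmentation stages (see
#' [augmentation_stages()]) from the current RNG stream (or from `seed`) and
#' applies them. Shape is preserved and output pixels stay within
#' `cfg$rescale_range`.
#'
#' @param image `H x W x C` numeric array.
#' @param cfg An [augment_config()].
#' @param seed Optional seed overriding `cfg$seed`; with a seed the result is
#'   a pure function of `(image, cfg, seed)`.
#' @return Augmented image of the same shape.
#' @export
sample_view <- function(image, cfg = augment_config(), seed = cfg$seed) {
  stopifnot(length(dim(image)) == 3L)
  run <- function() {
    p <- draw_view_params(cfg, dim(image))
    apply_view_params(image, p, cfg)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Generate a positive pair of augmented views
#'
#' Two independent draws of the augmentation chain applied to the same
#' image -- the positive pair of the contrastive objective.
#'
#' @inheritParams sample_view
#' @return List with elements `view1` and `view2`.
#' @export
make_view_pair <- function(image, cfg = augment_config(), seed = cfg$seed) {
  stopifnot(length(dim(image)) == 3L)
  run <- function() {
    p1 <- draw_view_params(cfg, dim(image))
    p2 <- draw_view_params(cfg, dim(image))
    list(view1 = apply_view_params(image, p1, cfg),
         view2 = apply_view_params(image, p2, cfg))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
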