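test_that("stratified split honours the stated fractions", {
  labels <- rep(0:1, each = 50)
  plan <- make_split(labels, test_fraction = 0.2, labeled_ratio = 0.5,
                     seed = 1)
  tab <- table(plan$assignment)
  expect_identical(as.integer(tab[["test"]]), 20L)
  expect_identical(as.integer(tab[["labeled_train"]]), 40L)
  expect_identical(as.integer(tab[["unlabeled_train"]]), 40L)
  # stratification: balanced within each class
  for (cl in 0:1) {
    expect_identical(sum(plan$assignment == "test" & labels == cl), 10L)
    expect_identical(sum(plan$assignment == "labeled_train" & labels == cl),
                     20L)
  }
  # disjointness and coverage
  expect_identical(sort(c(split_indices(plan, "test"),
                          split_indices(plan, "train"))), seq_along(labels))
})

test_that("labeled ratio 1 leaves no unlabeled pool", {
  plan <- make_split(rep(0:3, each = 25), labeled_ratio = 1, seed = 2)
  expect_length(split_indices(plan, "unlabeled_train"), 0L)
  expect_length(split_indices(plan, "labeled_train"), 80L)
})

test_that("splits are deterministic and nested across increasing ratios", {
  labels <- rep(0:3, each = 40)
  p1 <- make_split(labels, labeled_ratio = 0.25, seed = 7)
  p2 <- make_split(labels, labeled_ratio = 0.25, seed = 7)
  expect_identical(p1$assignment, p2$assignment)
  # nested labeled subsets under one seed
  l10 <- split_indices(make_split(labels, labeled_ratio = 0.1, seed = 7),
                       "labeled_train")
  l25 <- split_indices(p1, "labeled_train")
  l50 <- split_indices(make_split(labels, labeled_ratio = 0.5, seed = 7),
                       "labeled_train")
  expect_true(all(l10 %in% l25))
  expect_true(all(l25 %in% l50))
  # test sets identical across ratios
  expect_identical(split_indices(make_split(labels, labeled_ratio = 0.1,
                                            seed = 7), "test"),
                   split_indices(p1, "test"))
})

test_that("degenerate splits are rejected", {
  expect_error(make_split(c(0L, 1L), labeled_ratio = 0.5), "too small")
  expect_error(make_split(rep(0:1, 50), test_fraction = 0))
  expect_error(make_split(rep(0:1, 50), labeled_ratio = 0))
})

test_that("the unlabeled pool carries no label information", {
  labels <- rep(0:1, each = 20)
  imgs <- tiny_images(40, seed = 5)
  plan <- make_split(labels, labeled_ratio = 0.5, seed = 3)
  pool <- unlabeled_pool(imgs, plan)
  expect_identical(names(attributes(pool)), "dim")
  expect_identical(dim(pool)[4], length(split_indices(plan, "unlabeled_train")))
})

test_that("synthetic generation is deterministic and class-structured", {
  spec <- synthetic_spec(n_classes = 3, images_per_class = 4, H = 24, W = 24,
                         seed = 11)
  d1 <- generate_synthetic(spec)
  d2 <- generate_synthetic(spec)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$labels, rep(0:2, each = 4))
  expect_identical(dim(d1$images), c(24L, 24L, 3L, 12L))
  expect_true(all(d1$images >= 0 & d1$images <= 255))
})

test_that("noise-free, jitter-free generation returns the pure class patterns", {
  spec <- synthetic_spec(n_classes = 2, images_per_class = 1, H = 32, W = 32,
                         noise_sd = 0, color_variation = 0,
                         spatial_jitter = FALSE, pattern_jitter = 0, seed = 4)
  d <- generate_synthetic(spec)
  pats <- synthetic_patterns(spec)
  expect_equal(d$images[, , , 1], pats[[1]])
  expect_equal(d$images[, , , 2], pats[[2]])
})

test_that("a linear classifier separates the noise-free patterns", {
  # sanity oracle: the class signal exists in raw pixels
  spec <- synthetic_spec(n_classes = 3, images_per_class = 6, H = 24, W = 24,
                         noise_sd = 0, color_variation = 0.1, seed = 6)
  d <- generate_synthetic(spec)
  X <- t(apply(d$images, 4, identity))
  X <- matrix(d$images, ncol = dim(d$images)[4])
  # use a handful of pixel summaries per channel to keep the fit small
  feats <- t(apply(X, 2, function(v) {
    img <- array(v, c(24, 24, 3))
    c(apply(img, 3, mean), apply(img, 3, sd),
      apply(img, 3, function(m) mean(abs(diff(m)))))
  }))
  fit <- nnet::multinom(y ~ ., data = data.frame(feats, y = factor(d$labels)),
                        trace = FALSE)
  expect_equal(mean(predict(fit) == factor(d$labels)), 1)
})

test_that("the class signal survives augmentation better than class identity changes", {
  # within-class raw-pixel correlation after a random augmentation must
  # exceed between-class correlation, on average over 50 seeded draws
  spec <- synthetic_spec(n_classes = 4, images_per_class = 4, H = 32, W = 32,
                         seed = 8)
  d <- generate_synthetic(spec)
  cfg <- augment_config()
  set.seed(99)
  within <- c(); between <- c()
  for (i in 1:50) {
    idx <- sample(dim(d$images)[4], 2)
    a1 <- sample_view(d$images[, , , idx[1]], cfg, seed = NULL)
    a2 <- sample_view(d$images[, , , idx[2]], cfg, seed = NULL)
    rho <- cor(as.numeric(a1), as.numeric(a2))
    if (d$labels[idx[1]] == d$labels[idx[2]]) within <- c(within, rho)
    else between <- c(between, rho)
  }
  expect_gt(mean(within), mean(between))
})

test_that("image folders load deterministically with resizing", {
  skip_if_not_installed("png")
  root <- withr::local_tempdir()
  for (cl in c("alpha", "beta")) {
    dir.create(file.path(root, cl))
    for (i in 1:3) {
      img <- withr::with_seed(i + (cl == "beta") * 10,
                              array(runif(10 * 14 * 3), c(10, 14, 3)))
      png::writePNG(img, file.path(root, cl, sprintf("img%d.png", i)))
    }
  }
  d1 <- load_image_folder(root, H = 8, W = 8)
  expect_identical(dim(d1$images), c(8L, 8L, 3L, 6L))
  expect_identical(d1$labels, rep(0:1, each = 3L))
  expect_identical(d1$class_names, c("alpha", "beta"))
  expect_true(all(d1$images >= 0 & d1$images <= 255))
  # identical ordering on a second read
  d2 <- load_image_folder(root, H = 8, W = 8)
  expect_identical(d1$images, d2$images)
  # non-square sources resized exactly to H x W
  d3 <- load_image_folder(root, H = 12, W = 6)
  expect_identical(dim(d3$images)[1:2], c(12L, 6L))
  # empty class directory is an error
  dir.create(file.path(root, "gamma"))
  expect_error(load_image_folder(root, H = 8, W = 8), "no readable images")
})
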