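# Phantom generation, augmentation, splitting and image-folder I/O.

small_cfg <- function(...) phantom_config(n_classes = 3L, per_class = 6L,
                                          size = 64L, seed = 2L, ...)

test_that("phantom generation is deterministic, balanced and in range", {
  d1 <- generate_phantoms(small_cfg())
  d2 <- generate_phantoms(small_cfg())
  expect_identical(d1, d2)
  expect_identical(unname(class_counts(d1)), rep(6L, 3))
  expect_identical(dim(d1$image[[1]]), c(64L, 64L, 3L))
  rng <- range(unlist(lapply(d1$image, range)))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  d5 <- generate_phantoms(phantom_config(n_classes = 5L, per_class = 4L, size = 64L))
  expect_identical(nrow(d5), 20L)
  expect_identical(levels(d5$label), c("CN", "EMCI", "MCI", "LMCI", "AD"))
})

test_that("ventricle area grows monotonically with stage for several seeds", {
  for (s in 1:4) {
    ds <- generate_phantoms(phantom_config(n_classes = 5L, per_class = 6L,
                                           size = 96L, seed = s))
    means <- tapply(ds$ventricle_area, ds$label, mean)
    expect_true(all(diff(means) > 0))
  }
  expect_error(phantom_config(ventricle_scale = c(1, 1, 2)), "strictly increasing")
})

test_that("a least-squares read-out of central intensity separates extreme stages", {
  ds <- generate_phantoms(phantom_config(n_classes = 5L, per_class = 30L,
                                         size = 96L, noise_sd = 0.05, seed = 9))
  keep <- ds$label %in% c("CN", "AD")
  sub <- ds[keep, ]
  ctr <- 33:64   # central window holding the ventricles
  x <- vapply(sub$image, function(im) mean(im[ctr, ctr, 1]), numeric(1))
  y <- as.integer(sub$label == "AD")
  fit <- stats::lm(y ~ x)
  acc <- mean((stats::fitted(fit) > 0.5) == (y == 1))
  expect_gte(acc, 0.9)
})

test_that("flips are involutions and rotation preserves range and shape", {
  ds <- generate_phantoms(small_cfg())
  img <- ds$image[[1]]
  expect_identical(flip_horizontal(flip_horizontal(img)), img)
  expect_identical(flip_vertical(flip_vertical(img)), img)
  rot <- rotate_image(img, 10)
  expect_identical(dim(rot), dim(img))
  expect_gte(min(rot), 0)
  expect_lte(max(rot), 1)
  expect_equal(rotate_image(img, 0), img, tolerance = 1e-12)
})

test_that("augmentation balances every class exactly at the target", {
  ds <- generate_phantoms(phantom_config(n_classes = 3L, per_class = 5L,
                                         size = 64L, seed = 4L))
  ds <- ds[-(1:2), ]   # unbalance: class 1 has 3, others 5
  aug <- augment(ds, target_per_class = 20, seed = 3)
  expect_identical(unname(class_counts(aug)), rep(20L, 3))
  expect_identical(sum(aug$provenance == "synthetic"), nrow(ds))
  expect_identical(sum(aug$provenance == "augmented"), 60L - nrow(ds))
  expect_identical(augment(ds, target_per_class = 5, seed = 1)$image[1:3],
                   ds$image[1:3])  # target == current max keeps originals
  expect_error(augment(ds, target_per_class = 4), "below the largest")
})

test_that("splitting is stratified, seeded, disjoint and exhaustive", {
  ds <- generate_phantoms(phantom_config(n_classes = 3L, per_class = 10L,
                                         size = 64L, seed = 5L))
  sp <- split_dataset(ds, 0.7, seed = 6)
  expect_identical(unname(class_counts(sp$train)), rep(7L, 3))
  expect_identical(unname(class_counts(sp$test)), rep(3L, 3))
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(ds))
  key <- function(d) vapply(d$image, function(im) sum(im[, , 1]), numeric(1))
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  sp2 <- split_dataset(ds, 0.7, seed = 6)
  expect_identical(sp$train$ventricle_area, sp2$train$ventricle_area)
  ds1 <- ds[c(1, 11, 21), ]
  expect_error(split_dataset(ds1, 0.7), "fewer than 2")
})

test_that("image folders round-trip through PNG with resizing and channel replication", {
  skip_if_not_installed("png")
  skip_if_not_installed("EBImage")
  root <- withr::local_tempdir()
  ds <- generate_phantoms(phantom_config(n_classes = 3L, per_class = 2L,
                                         size = 64L, seed = 7L))
  write_image_folder(ds, root)
  back <- load_image_folder(root, size = 227)
  expect_identical(nrow(back), 6L)
  expect_identical(unname(class_counts(back)), rep(2L, 3))
  expect_identical(dim(back$image[[1]]), c(227L, 227L, 3L))
  expect_true(all(back$image[[1]] >= 0 & back$image[[1]] <= 1))
  # grayscale 100x100 input comes back 227x227x3 with equal channels
  dir.create(file.path(root, "gray"))
  png::writePNG(matrix(stats::runif(100 * 100), 100, 100),
                file.path(root, "gray", "g.png"))
  back2 <- load_image_folder(root, size = 227)
  g <- back2$image[[which(back2$label == "gray")[1]]]
  expect_identical(g[, , 1], g[, , 3])

  writeLines("not an image", file.path(root, "gray", "broken.png"))
  expect_error(load_image_folder(root), "broken.png")
  expect_error(load_image_folder(withr::local_tempdir()), "no class subdirectories")
})
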