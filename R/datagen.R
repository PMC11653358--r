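# Image data handling: a synthetic brain-phantom generator whose
# class-dependent morphology (ventricle size as an atrophy proxy, cortical
# ribbon thickness) makes staged classification learnable; flip/rotation
# augmentation with class balancing; class-per-folder image I/O; stratified
# splitting. A dataset is a tibble with list-column `image` (H x W x 3
# arrays in [0, 1]), `label` (factor) and `provenance`.

#' Class counts of an image dataset
#'
#' @param ds Dataset tibble (columns `image`, `label`).
#' @return Named integer vector of per-class counts.
#' @export
class_counts <- function(ds) {
  tab <- table(ds$label)
  stats::setNames(as.integer(tab), names(tab))
}

phantom_class_names <- function(n_classes) {
  switch(as.character(n_classes),
         "5" = c("CN", "EMCI", "MCI", "LMCI", "AD"),
         "4" = c("ND", "VMD", "MD", "MoD"),
         paste0("class", seq_len(n_classes)))
}

#' Configuration for the phantom generator
#'
#' Classes are ordered by increasing atrophy: the ventricle scale factor
#' must be strictly increasing (and the cortical thickness strictly
#' decreasing) across classes, which guarantees a learnable, monotone
#' morphological separation.
#'
#' @param n_classes 4 or 5 diagnostic stages (other counts allowed).
#' @param per_class Images per class.
#' @param ventricle_scale Per-class ventricle size factor; default an
#'   increasing grid from 0.4 to 1.6.
#' @param cortical_thickness Per-class ribbon thickness in pixels; default a
#'   decreasing grid from 14 to 6.
#' @param noise_sd Gaussian intensity noise (default 0.05).
#' @param seed RNG seed.
#' @param size Image side length (default 227).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_classes = 5L, per_class = 40L,
                           ventricle_scale = NULL, cortical_thickness = NULL,
                           noise_sd = 0.05, seed = 1L, size = 227L) {
  n_classes <- as.integer(n_classes)
  ventricle_scale <- ventricle_scale %||% seq(0.4, 1.6, length.out = n_classes)
  cortical_thickness <- cortical_thickness %||% seq(14, 6, length.out = n_classes)
  if (any(diff(ventricle_scale) <= 0)) {
    stop("ventricle_scale must be strictly increasing across classes")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_classes = n_classes, per_class = as.integer(per_class),
                 ventricle_scale = ventricle_scale,
                 cortical_thickness = cortical_thickness,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 size = as.integer(size)),
            class = "phantom_config")
}

# One grayscale phantom slice (size x size matrix). Within-class variability
# is Gaussian sensor noise only: geometric nuisance (position/size jitter) is
# deliberately excluded so the class signal is carried by morphology alone
# and end-to-end assertions isolate pipeline correctness, not robustness to
# anatomical variation (which these phantoms do not model; see the methods
# vignette).
draw_phantom <- function(size, vscale, cthick, noise_sd) {
  s <- size / 227
  cx <- (size + 1) / 2
  cy <- (size + 1) / 2
  x <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  y <- matrix(seq_len(size), size, size) - cy
  a <- 88 * s; b <- 105 * s                       # head ellipse semi-axes
  r2 <- (x / a)^2 + (y / b)^2
  img <- matrix(0, size, size)
  img[r2 <= 1] <- 0.85                            # skull shell, ~6 px thick
  inner <- (x / (a - 6 * s))^2 + (y / (b - 6 * s))^2
  img[inner <= 1] <- 0.45                         # brain parenchyma
  ribbon <- (x / (a - 6 * s - cthick * s))^2 + (y / (b - 6 * s - cthick * s))^2
  img[inner <= 1 & ribbon > 1] <- 0.70            # cortical ribbon
  # paired ventricle lobes, size scaled by the class atrophy factor
  va <- 10 * s * vscale; vb <- 26 * s * vscale
  off <- 13 * s
  v1 <- ((x - off) / va)^2 + (y / vb)^2
  v2 <- ((x + off) / va)^2 + (y / vb)^2
  vmask <- v1 <= 1 | v2 <= 1
  img[vmask] <- 0.08                              # CSF-dark ventricles
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(size^2, 0, noise_sd), size, size)
  list(img = pmin(pmax(img, 0), 1), ventricle_area = sum(vmask))
}

#' Generate a synthetic brain-phantom dataset
#'
#' Each image is a dark background, a bright skull shell, parenchyma with a
#' cortical ribbon whose thickness shrinks with stage, and paired dark
#' ventricles whose area grows with stage (the atrophy proxy), plus
#' Gaussian intensity noise and small per-image position/size jitter.
#' Deterministic per seed.
#'
#' @param cfg A [phantom_config()].
#' @return Dataset tibble with columns `image` (size x size x 3 arrays),
#'   `label`, `provenance = "synthetic"` and `ventricle_area` (pixels).
#' @export
generate_phantoms <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  classes <- phantom_class_names(cfg$n_classes)
  rows <- list()
  for (ci in seq_len(cfg$n_classes)) {
    for (i in seq_len(cfg$per_class)) {
      ph <- draw_phantom(cfg$size, cfg$ventricle_scale[ci],
                         cfg$cortical_thickness[ci], cfg$noise_sd)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image = list(array(ph$img, dim = c(cfg$size, cfg$size, 3L))),
        label = classes[ci], provenance = "synthetic",
        ventricle_area = ph$ventricle_area)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$label <- factor(out$label, levels = classes)
  out
}

#' Elementary augmentation operations
#'
#' Horizontal/vertical mirroring and bilinear rotation about the image
#' centre with zero fill. All operations keep pixel values in `[0, 1]`.
#'
#' @param img H x W x C array (or H x W matrix).
#' @param degrees Rotation angle (counter-clockwise).
#' @return Transformed array of the same shape.
#' @export
flip_horizontal <- function(img) {
  if (length(dim(img)) == 2L) img[, rev(seq_len(ncol(img)))]
  else img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
}

#' @rdname flip_horizontal
#' @export
flip_vertical <- function(img) {
  if (length(dim(img)) == 2L) img[rev(seq_len(nrow(img))), ]
  else img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
}

#' @rdname flip_horizontal
#' @export
rotate_image <- function(img, degrees) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  th <- degrees * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  X <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  Y <- matrix(seq_len(h), h, w) - cy
  # inverse map (sample source location for each target pixel)
  sx <- cos(th) * X + sin(th) * Y + cx
  sy <- -sin(th) * X + cos(th) * Y + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  sample_plane <- function(P) {
    val <- function(yy, xx) {
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
      out <- numeric(length(yy))
      out[ok] <- P[cbind(yy[ok], xx[ok])]
      out
    }
    v <- (1 - fx) * (1 - fy) * val(y0, x0) + fx * (1 - fy) * val(y0, x0 + 1) +
      (1 - fx) * fy * val(y0 + 1, x0) + fx * fy * val(y0 + 1, x0 + 1)
    matrix(v, h, w)
  }
  if (length(d) == 2L) return(sample_plane(img))
  out <- array(0, d)
  for (c in seq_len(d[3])) out[, , c] <- sample_plane(img[, , c])
  out
}

AUGMENT_OPS <- list(
  fliph = function(img) flip_horizontal(img),
  flipv = function(img) flip_vertical(img),
  rot_p5 = function(img) rotate_image(img, 5),
  rot_m5 = function(img) rotate_image(img, -5),
  rot_p10 = function(img) rotate_image(img, 10),
  rot_m10 = function(img) rotate_image(img, -10),
  rot_p15 = function(img) rotate_image(img, 15),
  rot_m15 = function(img) rotate_image(img, -15)
)

#' Balance classes by flip/rotation augmentation
#'
#' Keeps every original and adds transformed copies — a uniformly sampled
#' operation (horizontal/vertical flip, rotation by +/-5, 10 or 15 degrees)
#' applied to a uniformly sampled original of the class — until every class
#' holds exactly `target_per_class` samples. Seeded.
#'
#' @param ds Dataset tibble.
#' @param target_per_class Target count; must be at least the current
#'   maximum class count.
#' @param seed RNG seed.
#' @return The balanced dataset (originals plus `provenance = "augmented"`
#'   rows).
#' @export
augment <- function(ds, target_per_class, seed = 1L) {
  counts <- class_counts(ds)
  if (any(counts == 0L)) stop("cannot augment empty class(es): ",
                              paste(names(counts)[counts == 0L], collapse = ", "))
  if (target_per_class < max(counts)) {
    stop("target_per_class (", target_per_class,
         ") below the largest class count (", max(counts), ")")
  }
  set.seed(seed)
  extra <- list()
  for (cl in names(counts)) {
    need <- target_per_class - counts[[cl]]
    if (need == 0L) next
    pool <- which(ds$label == cl)
    src <- sample(pool, need, replace = TRUE)
    ops <- sample(length(AUGMENT_OPS), need, replace = TRUE)
    for (i in seq_len(need)) {
      img <- AUGMENT_OPS[[ops[i]]](ds$image[[src[i]]])
      extra[[length(extra) + 1L]] <- tibble::tibble(
        image = list(img), label = factor(cl, levels = levels(ds$label)),
        provenance = "augmented")
    }
  }
  out <- dplyr::bind_rows(c(list(ds), extra))
  out
}

#' Stratified train/test split
#'
#' Per-class seeded split, disjoint and exhaustive; every class must have
#' at least two samples so both partitions are populated.
#'
#' @param ds Dataset tibble.
#' @param train_fraction Fraction assigned to training (0 < f < 1).
#' @param seed RNG seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(ds, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- class_counts(ds)
  if (any(counts < 2L)) {
    stop("class(es) with fewer than 2 samples cannot be split: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  set.seed(seed)
  tr_idx <- integer(0)
  for (cl in names(counts)) {
    ix <- which(ds$label == cl)
    ntr <- min(max(1L, round(train_fraction * length(ix))), length(ix) - 1L)
    tr_idx <- c(tr_idx, sample(ix, ntr))
  }
  list(train = ds[sort(tr_idx), ], test = ds[setdiff(seq_len(nrow(ds)), tr_idx), ])
}

#' Load a class-per-subdirectory image folder
#'
#' Each subdirectory of `path` is a class; PNG/JPEG files are decoded,
#' bilinearly resized to `size x size`, grayscale replicated to three
#' channels and scaled to `[0, 1]`. Decoding failures raise an error naming
#' the offending file.
#'
#' @param path Folder with one subdirectory per class.
#' @param size Output side length (default 227).
#' @return Dataset tibble with `provenance = "real"`.
#' @export
load_image_folder <- function(path, size = 227L) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("load_image_folder requires the EBImage package")
  }
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  classes <- classes[nzchar(classes)]
  if (!length(classes)) stop("no class subdirectories under ", path)
  rows <- list()
  for (cl in classes) {
    files <- sort(list.files(file.path(path, cl), pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("class folder '", cl, "' contains no PNG/JPEG images")
    for (f in files) {
      img <- tryCatch(EBImage::readImage(f),
                      error = function(e) stop("cannot decode image file: ", f,
                                               " (", conditionMessage(e), ")",
                                               call. = FALSE))
      img <- EBImage::resize(img, w = size, h = size)
      dat <- EBImage::imageData(img)              # x, y[, c] orientation
      if (length(dim(dat)) == 2L) {
        plane <- t(dat)
        arr <- array(plane, dim = c(size, size, 3L))
      } else {
        nc <- dim(dat)[3]
        if (nc >= 3L) {
          arr <- array(0, dim = c(size, size, 3L))
          for (c in 1:3) arr[, , c] <- t(dat[, , c])
        } else {
          arr <- array(t(dat[, , 1]), dim = c(size, size, 3L))
        }
      }
      arr <- pmin(pmax(arr, 0), 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image = list(arr), label = cl, provenance = "real")
    }
  }
  out <- dplyr::bind_rows(rows)
  out$label <- factor(out$label, levels = classes)
  out
}

#' Write a dataset to a class-per-subdirectory folder of PNGs
#'
#' The inverse of [load_image_folder()]: synthetic and real data become
#' interchangeable downstream.
#'
#' @param ds Dataset tibble.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_image_folder <- function(ds, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("write_image_folder requires the png package")
  }
  for (cl in levels(ds$label)) dir.create(file.path(path, cl), recursive = TRUE,
                                          showWarnings = FALSE)
  counters <- stats::setNames(rep(0L, nlevels(ds$label)), levels(ds$label))
  for (i in seq_len(nrow(ds))) {
    cl <- as.character(ds$label[i])
    counters[cl] <- counters[cl] + 1L
    png::writePNG(ds$image[[i]],
                  file.path(path, cl, sprintf("img_%04d.png", counters[cl])))
  }
  invisible(path)
}

#' Convert a dataset's images to the network input array
#'
#' @param ds Dataset tibble.
#' @return `H x W x 3 x N` numeric array.
#' @export
dataset_array <- function(ds) {
  simplify2array(ds$image)
}
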