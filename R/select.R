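# Wrapper feature selection: CFO searches the continuous box [0, 1]^d; a
# position binarizes at 0.5 into a feature mask; mask fitness is the
# holdout error of a fixed lightweight classifier on the masked features
# plus a sparsity penalty. An exhaustive enumerator over all masks provides
# the independent optimum for small d.

# deterministic per-mask seed so identical masks always score identically
mask_seed <- function(mask, seed) {
  as.integer((as.numeric(seed) * 10007 + sum(which(mask) * 7919)) %% 2147483647L)
}

#' Fitness function for feature masks
#'
#' Builds the deterministic mask-scoring closure used both by the CFO
#' selector and by the exhaustive oracle: a seeded stratified 80/20 split,
#' a single-hidden-layer classifier (width 25, 30 epochs) trained on the
#' masked training features, and fitness = holdout error rate +
#' `lambda * selected/d`.
#'
#' @param X Feature matrix or data frame (n x d).
#' @param y Class labels (>= 2 classes).
#' @param lambda Sparsity weight.
#' @param seed Seed fixing the split and classifier initialization.
#' @param hidden Hidden width of the scoring classifier.
#' @param epochs Training epochs of the scoring classifier.
#' @return `function(mask)` returning the scalar fitness.
#' @export
selection_fitness <- function(X, y, lambda = 0.05, seed = 1L, hidden = 25L,
                              epochs = 30L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("feature selection needs at least two classes")
  d <- ncol(X)
  set.seed(seed)
  holdout <- unlist(lapply(split(seq_along(y), y), function(ix) {
    sample(ix, max(1L, round(0.2 * length(ix))))
  }), use.names = FALSE)
  tr <- setdiff(seq_along(y), holdout)
  force(lambda)
  function(mask) {
    mask <- as.logical(mask)
    stopifnot(length(mask) == d, any(mask))
    fit <- mlp_fit(X[tr, mask, drop = FALSE], y[tr], hidden = hidden,
                   epochs = epochs, lr = 0.1, momentum = 0.9, batch_size = 32L,
                   seed = mask_seed(mask, seed))
    pred <- mlp_predict(fit, X[holdout, mask, drop = FALSE])
    mean(pred != y[holdout]) + lambda * sum(mask) / d
  }
}

new_selection_mask <- function(mask, fitness, trace = NULL) {
  structure(list(mask = as.logical(mask), fitness = fitness,
                 selected_count = sum(mask), selected = which(mask),
                 trace = trace),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("<selection_mask> %d/%d features, fitness %.6g\n",
              x$selected_count, length(x$mask), x$fitness))
  invisible(x)
}

#' @export
tidy.selection_mask <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$mask), selected = x$mask)
}

#' @export
glance.selection_mask <- function(x, ...) {
  tibble::tibble(selected_count = x$selected_count, d = length(x$mask),
                 fitness = x$fitness)
}

# continuous position -> repaired mask (empty mask: activate the dimension
# with the largest position value)
position_to_mask <- function(pos) {
  mask <- pos > 0.5
  if (!any(mask)) mask[which.max(pos)] <- TRUE
  mask
}

#' Select features with the Catch Fish optimizer
#'
#' Runs CFO over `[0, 1]^d`, binarizing positions at 0.5 (an empty mask is
#' repaired by activating the largest coordinate), with mask fitness from
#' [selection_fitness()]. Mask scores are cached, so repeated visits to a
#' mask cost one classifier fit.
#'
#' @param X Feature matrix / data frame / tibble (n x d); a `label` column
#'   is split off automatically if `y` is missing.
#' @param y Class labels.
#' @param lambda Sparsity weight (default 0.05).
#' @param params A [cfo_params()].
#' @param hidden,epochs Scoring-classifier size (see [selection_fitness()]).
#' @return A `selection_mask` with the best mask, its fitness, and the CFO
#'   best-so-far trace.
#' @export
select_features <- function(X, y = NULL, lambda = 0.05, params = cfo_params(),
                            hidden = 25L, epochs = 30L) {
  if (is.null(y)) {
    if (!"label" %in% colnames(X)) stop("y missing and no 'label' column in X")
    y <- X[["label"]]
    X <- X[, setdiff(colnames(X), "label"), drop = FALSE]
  }
  X <- as.matrix(X)
  d <- ncol(X)
  fitf <- selection_fitness(X, y, lambda = lambda, seed = params$seed,
                            hidden = hidden, epochs = epochs)
  cache <- new.env(parent = emptyenv())
  best <- list(mask = NULL, fit = Inf)
  fobj <- function(pos) {
    mask <- position_to_mask(pos)
    key <- paste(which(mask), collapse = ",")
    f <- cache[[key]]
    if (is.null(f)) {
      f <- fitf(mask)
      cache[[key]] <- f
    }
    if (f < best$fit) best <<- list(mask = mask, fit = f)
    f
  }
  res <- cfo_optimize(fobj, lb = rep(0, d), ub = rep(1, d), params = params)
  new_selection_mask(best$mask, best$fit, trace = res$trace)
}

#' Exhaustive search over all non-empty feature masks
#'
#' Enumerates all `2^d - 1` masks with the same fitness function as
#' [select_features()]; the reference optimum for small `d`.
#'
#' @inheritParams select_features
#' @param seed Seed passed to [selection_fitness()].
#' @return A `selection_mask` for the best mask found.
#' @export
exhaustive_selection <- function(X, y, lambda = 0.05, seed = 1L, hidden = 25L,
                                 epochs = 30L) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (d > 16L) stop("exhaustive search is limited to d <= 16 (", 2^d - 1, " masks)")
  fitf <- selection_fitness(X, y, lambda = lambda, seed = seed,
                            hidden = hidden, epochs = epochs)
  best <- NULL; bestf <- Inf
  for (code in seq_len(2^d - 1L)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(d) - 1L)) > 0)
    f <- fitf(mask)
    if (f < bestf) { bestf <- f; best <- mask }
  }
  new_selection_mask(best, bestf)
}
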