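# Shallow feed-forward classifier variants used on the extracted deep
# features, and the confusion-matrix metric suite. Hidden layouts follow
# the narrow/medium/wide/bi-/tri-layered naming convention:
# NNN [10], MNN [25], SWNN [100], BNN [10, 10], TNN [10, 10, 10].

VARIANT_LAYOUTS <- list(
  NNN = 10L, MNN = 25L, SWNN = 100L, BNN = c(10L, 10L), TNN = c(10L, 10L, 10L)
)

#' Specify a shallow classifier variant
#'
#' @param variant One of `"NNN"`, `"MNN"`, `"SWNN"`, `"BNN"`, `"TNN"`
#'   (narrow / medium / shallow-wide / bi-layered / tri-layered).
#' @param input_dim Number of input features.
#' @param n_classes Number of classes.
#' @param seed Weight-initialization seed.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(variant, input_dim, n_classes, seed = 1L) {
  if (!variant %in% names(VARIANT_LAYOUTS)) {
    stop("unknown classifier variant '", variant, "'; choose one of ",
         paste(names(VARIANT_LAYOUTS), collapse = ", "))
  }
  stopifnot(input_dim >= 1L, n_classes >= 2L)
  structure(list(variant = variant, hidden_layout = VARIANT_LAYOUTS[[variant]],
                 input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Build an (untrained) shallow classifier from a spec
#'
#' Feed-forward network with the variant's hidden layout, ReLU activations
#' and a softmax output, seeded He-uniform initialization.
#'
#' @param spec A [classifier_spec()].
#' @return An `nf_classifier` handle (untrained).
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  structure(list(spec = spec, fit = NULL), class = "nf_classifier")
}

#' Learnable parameter count of a shallow classifier
#'
#' @param x An `nf_classifier` or [classifier_spec()].
#' @return Total weights + biases.
#' @export
n_params <- function(x) {
  spec <- if (inherits(x, "nf_classifier")) x$spec else x
  widths <- c(spec$input_dim, spec$hidden_layout, spec$n_classes)
  sum(widths[-length(widths)] * widths[-1] + widths[-1])
}

#' Train a shallow classifier
#'
#' Cross-entropy loss, SGD with momentum 0.9 at learning rate 1e-3,
#' deterministic per seed (zero epochs returns the seeded initial weights).
#'
#' @param handle An [build_classifier()] result.
#' @param X Feature matrix (n x d).
#' @param y Class labels (length n).
#' @param epochs Training epochs (default 200).
#' @param seed Seed (defaults to the spec's).
#' @return The trained `nf_classifier`.
#' @export
fit_classifier <- function(handle, X, y, epochs = 200L, seed = NULL) {
  stopifnot(inherits(handle, "nf_classifier"))
  seed <- seed %||% handle$spec$seed
  handle$fit <- mlp_fit(X, factor(y), hidden = handle$spec$hidden_layout,
                        epochs = epochs, lr = 1e-3, momentum = 0.9,
                        batch_size = 32L, seed = seed)
  handle
}

#' @export
predict.nf_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  if (is.null(object$fit)) stop("classifier has not been fitted")
  mlp_predict(object$fit, newdata, type = match.arg(type))
}

#' @export
print.nf_classifier <- function(x, ...) {
  cat(sprintf("<nf_classifier> %s [%s], %d -> %d, %s\n", x$spec$variant,
              paste(x$spec$hidden_layout, collapse = ","), x$spec$input_dim,
              x$spec$n_classes, if (is.null(x$fit)) "untrained" else "trained"))
  invisible(x)
}

#' Metric suite for a confusion matrix
#'
#' Rows index the true class, columns the predicted class. Reports accuracy
#' (= 100 * trace / total), macro-averaged sensitivity (recall), precision
#' and F1 over classes with non-zero support, and the false negative rate
#' FNR = 100 - sensitivity. Per-class precision for a class that is never
#' predicted is taken as 0.
#'
#' @param confusion Square count matrix (rows = true class).
#' @param elapsed_s Optional wall time to carry through (informational).
#' @return An object of class `classification_report`.
#' @export
compute_metrics <- function(confusion, elapsed_s = NA_real_) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion matrix entries must be non-negative")
  total <- sum(confusion)
  if (total == 0) stop("confusion matrix is all zero")
  classes <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  tp <- diag(confusion)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  precision <- ifelse(support > 0, ifelse(predicted > 0, tp / predicted, 0), NA_real_)
  f1 <- ifelse(support > 0,
               ifelse(recall + precision > 0, 2 * recall * precision / (recall + precision), 0),
               NA_real_)
  keep <- support > 0
  acc <- 100 * sum(tp) / total
  sens <- 100 * mean(recall[keep])
  prec <- 100 * mean(precision[keep])
  f1m <- 100 * mean(f1[keep])
  structure(list(
    confusion = confusion,
    accuracy = acc, sensitivity = sens, precision = prec, f1 = f1m,
    fnr = 100 - sens,
    per_class = tibble::tibble(class = classes, support = as.integer(support),
                               recall = 100 * recall, precision = 100 * precision,
                               f1 = 100 * f1),
    elapsed_s = elapsed_s
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> accuracy %.2f%%  sensitivity %.2f%%  ",
                     "precision %.2f%%  F1 %.2f%%  FNR %.2f%%\n"),
              x$accuracy, x$sensitivity, x$precision, x$f1, x$fnr))
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 precision = x$precision, f1 = x$f1, fnr = x$fnr,
                 elapsed_s = x$elapsed_s)
}

# stratified fold assignment: every class spread as evenly as possible
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    small <- names(which(table(y) < k))
    stop("class(es) ", paste(small, collapse = ", "), " have fewer than k = ",
         k, " members")
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    ix <- sample(which(y == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Stratified k-fold evaluation of a shallow classifier
#'
#' Seeded stratified folds; each fold's held-out predictions are pooled into
#' one confusion matrix, from which the summary report is computed (per-fold
#' reports are also returned).
#'
#' @param X Feature matrix (n x d).
#' @param y Class labels; every class needs at least `k` members.
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param epochs Training epochs per fold.
#' @return A `kfold_result`: pooled `report`, `fold_reports` list, and the
#'   fold assignment.
#' @export
kfold_evaluate <- function(X, y, spec, k = 10L, seed = 1L, epochs = 200L) {
  stopifnot(k >= 2L)
  X <- as.matrix(X)
  y <- as.factor(y)
  fold <- stratified_folds(y, k, seed)
  classes <- levels(y)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  fold_reports <- vector("list", k)
  t0 <- proc.time()[["elapsed"]]
  for (f in seq_len(k)) {
    tr <- fold != f
    h <- build_classifier(spec)
    h <- fit_classifier(h, X[tr, , drop = FALSE], y[tr], epochs = epochs,
                        seed = spec$seed + f)
    pred <- predict(h, X[!tr, , drop = FALSE])
    cm <- table(factor(y[!tr], levels = classes), factor(pred, levels = classes))
    pooled <- pooled + unclass(cm)
    fold_reports[[f]] <- compute_metrics(unclass(cm))
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(list(report = compute_metrics(pooled, elapsed_s = elapsed),
                 fold_reports = fold_reports, fold = fold, spec = spec, k = k),
            class = "kfold_result")
}

#' @export
print.kfold_result <- function(x, ...) {
  cat(sprintf("<kfold_result> %s, %d folds\n", x$spec$variant, x$k))
  print(x$report)
  invisible(x)
}

#' @export
glance.kfold_result <- function(x, ...) {
  dplyr::mutate(glance(x$report), variant = x$spec$variant, k = x$k,
                .before = 1L)
}
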