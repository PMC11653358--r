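# Thin R wrapper around the compiled feed-forward classifier: seeded
# He-uniform initialization, per-feature standardization learned on the
# training rows, deterministic mini-batch SGD.

mlp_init_weights <- function(din, hidden, nclass, seed) {
  set.seed(seed)
  widths <- c(din, hidden, nclass)
  w <- list()
  for (l in seq_len(length(widths) - 1L)) {
    w[[paste0("W", l)]] <- he_uniform(widths[l + 1L], widths[l], widths[l])
    w[[paste0("b", l)]] <- matrix(0, widths[l + 1L], 1L)
  }
  w
}

# X: n x d numeric; y: factor; returns an nf_mlp fit
mlp_fit <- function(X, y, hidden, epochs = 200L, lr = 1e-3, momentum = 0.9,
                    batch_size = 32L, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X))) stop("features contain NA or non-finite values")
  y <- as.factor(y)
  classes <- levels(y)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- t(scale(X, center = mu, scale = sdv))   # d x n
  set.seed(seed)
  ord <- sample.int(ncol(Xs))
  Xs <- Xs[, ord, drop = FALSE]
  yi <- as.integer(y)[ord] - 1L
  w0 <- mlp_init_weights(nrow(Xs), hidden, length(classes), seed)
  res <- if (epochs > 0L) {
    mlp_train_cpp(Xs, yi, w0, as.integer(epochs), lr, momentum, as.integer(batch_size))
  } else {
    list(weights = w0, epoch_loss = numeric(0))
  }
  structure(list(weights = res$weights, classes = classes, mu = mu, sd = sdv,
                 hidden = hidden, epoch_loss = res$epoch_loss, seed = seed),
            class = "nf_mlp")
}

mlp_predict <- function(fit, X, type = c("class", "prob")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  Xs <- t(scale(X, center = fit$mu, scale = fit$sd))
  P <- t(mlp_predict_cpp(Xs, fit$weights))
  colnames(P) <- fit$classes
  if (type == "prob") return(P)
  factor(fit$classes[max.col(P, ties.method = "first")], levels = fit$classes)
}
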