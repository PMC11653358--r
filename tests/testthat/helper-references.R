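# Independent reference implementations used as oracles. These are written
# against the documented conventions, with direct loops, and stay separate
# from the package's compute paths.

# naive attention pipeline on a token matrix (loops, no stabilization tricks
# beyond what the formulas state)
ref_attention <- function(M, Wq, Wk, Wv) {
  Q <- M %*% Wq; K <- M %*% Wk; V <- M %*% Wv
  dk <- ncol(Q)
  m <- nrow(M)
  S <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
  W <- matrix(0, m, m)
  for (i in seq_len(m)) W[i, ] <- exp(S[i, ]) / sum(exp(S[i, ]))
  out <- matrix(0, m, ncol(V))
  for (i in seq_len(m)) for (c in seq_len(ncol(V))) out[i, c] <- sum(W[i, ] * V[, c])
  out
}

# naive 2-D convolution matching the engine's conventions:
# x: H x W x Cin array; W matrix (fh*fw*cin_g x cout), row index
# r = c + cing*(fy + fh*fx) within a group (channel fastest, 0-based);
# stride-1 "same" padding (left pad (f-1)/2) or stride-s "valid".
ref_conv <- function(x, Wm, b, fh, fw, stride, padding, groups = 1L) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  cout <- length(b)
  if (padding == "same") {
    padT <- (fh - 1) %/% 2; padL <- (fw - 1) %/% 2
    oh <- ceiling(H / stride); ow <- ceiling(W / stride)
  } else {
    padT <- 0L; padL <- 0L
    oh <- floor((H - fh) / stride) + 1; ow <- floor((W - fw) / stride) + 1
  }
  cing <- cin / groups; cg <- cout / groups
  out <- array(0, c(oh, ow, cout))
  for (oc in seq_len(cout)) {
    g <- ceiling(oc / cg)
    for (oy in seq_len(oh)) for (ox in seq_len(ow)) {
      acc <- b[oc]
      for (fy in seq_len(fh)) for (fx in seq_len(fw)) {
        y <- (oy - 1) * stride - padT + fy
        xx <- (ox - 1) * stride - padL + fx
        if (y < 1 || y > H || xx < 1 || xx > W) next
        for (c in seq_len(cing)) {
          r <- (c - 1) + cing * ((fy - 1) + fh * (fx - 1)) + 1
          acc <- acc + x[y, xx, (g - 1) * cing + c] * Wm[r, oc]
        }
      }
      out[oy, ox, oc] <- acc
    }
  }
  out
}

# per-class metric hand computation (independent of compute_metrics)
ref_metrics <- function(cm) {
  tp <- diag(cm); sup <- rowSums(cm); pred <- colSums(cm)
  rec <- tp / sup
  prc <- ifelse(pred > 0, tp / pred, 0)
  f1 <- ifelse(rec + prc > 0, 2 * rec * prc / (rec + prc), 0)
  keep <- sup > 0
  list(accuracy = 100 * sum(tp) / sum(cm),
       sensitivity = 100 * mean(rec[keep]),
       precision = 100 * mean(prc[keep]),
       f1 = 100 * mean(f1[keep]))
}

# two well-separated Gaussian blobs in d dims
make_blobs <- function(n_per = 60L, d = 4L, gap = 6, seed = 1L, classes = 2L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(classes), function(k) {
    matrix(stats::rnorm(n_per * d, mean = gap * k), n_per, d)
  }))
  list(X = X, y = factor(rep(seq_len(classes), each = n_per)))
}

# selection toy problem: 3 informative features (class means shifted), rest noise
make_selection_problem <- function(n = 200L, d = 10L, informative = 3L,
                                   shift = 3, seed = 1L) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), length.out = n))
  X <- matrix(stats::rnorm(n * d), n, d)
  for (j in seq_len(informative)) {
    X[y == "b", j] <- X[y == "b", j] + shift
  }
  list(X = X, y = y, informative = seq_len(informative))
}

tiny_graph <- function(input_shape = c(9, 9, 2), n_classes = 3L) {
  network_graph(list(
    layer_spec("input", "input"),
    layer_spec("c1", "convolution", "input", filter = 3, stride = 2, out_channels = 4),
    layer_spec("bn1", "batch-norm", "c1"),
    layer_spec("r1", "relu", "bn1"),
    layer_spec("c2", "convolution", "r1", filter = 1, stride = 1, out_channels = 4),
    layer_spec("cat1", "depth-concatenation", c("r1", "c2")),
    layer_spec("gc", "grouped-convolution", "cat1", filter = 3, stride = 1,
               out_channels = 8, groups = 2),
    layer_spec("p1", "max-pool", "gc", filter = 2, stride = 2),
    layer_spec("flat", "flatten", "p1"),
    layer_spec("att", "self-attention", "flat", heads = 2),
    layer_spec("fc", "fully-connected", "att", out_channels = n_classes),
    layer_spec("sm", "softmax", "fc")), input_shape = input_shape)
}
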