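# The instantiated network engine: forward semantics, taps, loss math,
# determinism, and agreement with independent references.

# reshape a flattened map tap (channel-fastest per spatial position, spatial
# index s = y + H*x) back to an H x W x C array
unflatten_tap <- function(row, H, W, C) {
  arr <- array(0, c(H, W, C))
  for (x in seq_len(W)) for (y in seq_len(H)) for (c in seq_len(C)) {
    arr[y, x, c] <- row[c + C * ((y - 1) + H * (x - 1))]
  }
  arr
}

test_that("convolution forward agrees with a direct-loop reference", {
  cases <- list(
    list(filter = c(3L, 3L), stride = 1L, groups = 1L, cout = 3L),
    list(filter = c(1L, 3L), stride = 1L, groups = 1L, cout = 2L),
    list(filter = c(2L, 2L), stride = 2L, groups = 1L, cout = 4L),
    list(filter = c(3L, 3L), stride = 1L, groups = 2L, cout = 4L)
  )
  set.seed(5)
  for (cs in cases) {
    kind <- if (cs$groups > 1L) "grouped-convolution" else "convolution"
    g <- network_graph(list(
      layer_spec("input", "input"),
      layer_spec("c", kind, "input", filter = cs$filter, stride = cs$stride,
                 out_channels = cs$cout, groups = cs$groups)),
      input_shape = c(7, 6, 4))
    net <- instantiate_network(g, seed = 2)
    x <- array(stats::runif(7 * 6 * 4), c(7, 6, 4))
    out <- forward(net, array(x, c(7, 6, 4, 1)), tap = "c")
    sh <- infer_shapes(g)$c
    got <- unflatten_tap(out[1, ], sh$h, sh$w, sh$c)
    want <- ref_conv(x, net$params[[2]]$W, as.numeric(net$params[[2]]$b),
                     cs$filter[1], cs$filter[2], cs$stride,
                     if (cs$stride == 1L) "same" else "valid", cs$groups)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("max pooling and global average pooling match direct computation", {
  g <- network_graph(list(
    layer_spec("input", "input"),
    layer_spec("p", "max-pool", "input", filter = 2, stride = 2),
    layer_spec("gap", "global-average-pool", "p")), input_shape = c(6, 6, 2))
  net <- instantiate_network(g, seed = 1)
  set.seed(8)
  x <- array(stats::runif(6 * 6 * 2), c(6, 6, 2))
  ptap <- unflatten_tap(forward(net, array(x, c(6, 6, 2, 1)), tap = "p")[1, ], 3, 3, 2)
  for (c in 1:2) for (i in 1:3) for (j in 1:3) {
    expect_equal(ptap[i, j, c], max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]))
  }
  gtap <- forward(net, array(x, c(6, 6, 2, 1)), tap = "gap")
  expect_equal(as.numeric(gtap), c(mean(ptap[, , 1]), mean(ptap[, , 2])))
})

test_that("forward yields probability rows; zero head gives uniform; taps have stated width", {
  g <- tiny_graph()
  net <- instantiate_network(g, seed = 4)
  set.seed(3)
  X <- array(stats::runif(9 * 9 * 2 * 5), c(9, 9, 2, 5))
  p <- forward(net, X)
  expect_identical(dim(p), c(5L, 3L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  expect_true(all(p >= 0))
  # all-zero final FC weights/biases -> uniform probabilities 1/C
  net0 <- net
  fc_idx <- which(names(g$layers) == "fc")
  net0$params[[fc_idx]]$W[] <- 0
  net0$params[[fc_idx]]$b[] <- 0
  expect_equal(forward(net0, X), matrix(1 / 3, 5, 3), ignore_attr = TRUE)
  expect_error(forward(net, X, tap = "nope"), "unknown tap")
})

test_that("fusion-concat tap yields the fused feature width for any batch size", {
  g <- build_fused_network(num_classes = 5, width_scale = 0.125)
  net <- instantiate_network(g, seed = 1)
  for (n in c(1L, 3L)) {
    X <- array(stats::runif(227 * 227 * 3 * n), c(227, 227, 3, n))
    f <- forward(net, X, tap = "fusion_cat")
    expect_identical(dim(f), c(n, fused_feature_dim(g)))
  }
})

test_that("instantiation and forward are deterministic per seed", {
  g <- tiny_graph()
  n1 <- instantiate_network(g, seed = 9)
  n2 <- instantiate_network(g, seed = 9)
  expect_identical(n1$params, n2$params)
  set.seed(1)
  X <- array(stats::runif(9 * 9 * 2 * 2), c(9, 9, 2, 2))
  expect_identical(forward(n1, X), forward(n2, X))
  n3 <- instantiate_network(g, seed = 10)
  expect_false(identical(n1$params, n3$params))
})

test_that("analytic gradients match central finite differences through every node kind", {
  g <- tiny_graph()
  net <- instantiate_network(g, seed = 3)
  set.seed(9)
  N <- 3
  X <- array(stats::runif(9 * 9 * 2 * N), c(9, 9, 2, N))
  y <- c(0L, 1L, 2L)
  comp <- net$compiled
  lossf <- function(params) {
    neurofuse:::nf_loss_cpp(comp$spec, params, as.numeric(X), dim(X), y,
                            comp$logit_node, N)
  }
  ord <- matrix(0:(N - 1), 1)
  lr <- 1e-3
  res <- neurofuse:::nf_train_cpp(comp$spec, net$params, as.numeric(X), dim(X), y,
                                  comp$logit_node, ord, lr, 0.0, N, 0.1)
  checked <- 0L
  for (i in seq_along(net$params)) {
    pl <- net$params[[i]]
    if (is.null(pl)) next
    for (key in setdiff(names(pl), c("rmean", "rvar"))) {
      ga <- (pl[[key]] - res$params[[i]][[key]]) / lr
      for (ii in sample(length(ga), min(2, length(ga)))) {
        eps <- 1e-6
        p2 <- net$params
        p2[[i]][[key]][ii] <- p2[[i]][[key]][ii] + eps
        lp <- lossf(p2)
        p2[[i]][[key]][ii] <- p2[[i]][[key]][ii] - 2 * eps
        lm <- lossf(p2)
        gn <- (lp - lm) / (2 * eps)
        if (max(abs(gn), abs(ga[ii])) > 1e-6) {
          expect_equal(ga[ii], gn, tolerance = 1e-3)
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gt(checked, 10L)
})

test_that("training reduces the loss on learnable signal and is seed-reproducible", {
  g <- tiny_graph(n_classes = 2L)
  net <- instantiate_network(g, seed = 5)
  set.seed(7)
  n <- 12
  y <- rep(1:2, each = n / 2)
  X <- array(stats::runif(9 * 9 * 2 * n) * 0.2, c(9, 9, 2, n))
  X[3:6, 3:6, , y == 2] <- X[3:6, 3:6, , y == 2] + 0.7  # bright square for class 2
  t1 <- train_network(net, X, y, epochs = 30, lr = 0.05, batch_size = 6, seed = 1)
  expect_lt(utils::tail(t1$history$loss, 1), t1$loss0)
  t2 <- train_network(net, X, y, epochs = 30, lr = 0.05, batch_size = 6, seed = 1)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)
})

test_that("softmax cross-entropy matches its closed forms and a naive evaluation", {
  expect_equal(softmax_cross_entropy(rep(1, 5), 2L), log(5), tolerance = 1e-12)
  expect_equal(softmax_cross_entropy(c(2, 0, 0), 1L), -2 + log(exp(2) + 2),
               tolerance = 1e-12)
  expect_equal(softmax_cross_entropy(c(1e4, 0, 0), 1L), 0, tolerance = 1e-6)
  expect_false(is.finite(softmax_cross_entropy(c(1e4, 0, 0), 2L)) &&
                 softmax_cross_entropy(c(1e4, 0, 0), 2L) < 1e3)
  set.seed(2)
  for (i in 1:200) {
    logits <- stats::runif(4, -10, 10)
    k <- sample(4, 1)
    naive <- -log(exp(logits[k]) / sum(exp(logits)))
    expect_equal(softmax_cross_entropy(logits, k), naive, tolerance = 1e-9)
  }
})
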