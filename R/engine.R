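# Instantiation and execution of a network graph: compile the DAG for the
# tensor engine, draw seeded initial weights, run forward passes (optionally
# tapping an intermediate layer) and train with SGD + momentum.

KIND_CODE <- c(
  "input" = 0L, "convolution" = 1L, "grouped-convolution" = 1L,
  "batch-norm" = 2L, "relu" = 3L, "max-pool" = 4L, "global-average-pool" = 5L,
  "depth-concatenation" = 6L, "flatten" = 7L, "self-attention" = 8L,
  "fully-connected" = 9L, "softmax" = 10L, "classification" = 11L
)

# lower the graph to the flat node table the C++ engine consumes
compile_graph <- function(g) {
  sh <- infer_shapes(g)
  ids <- names(g$layers)
  idx <- stats::setNames(seq_along(ids) - 1L, ids)
  storage <- function(s) {
    switch(s$type,
           map = c(rows = s$c, P = s$h * s$w, h = s$h, w = s$w),
           tokens = c(rows = s$emb, P = s$m, h = s$m, w = 1L),
           vec = c(rows = s$d, P = 1L, h = 1L, w = 1L))
  }
  spec <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    l <- g$layers[[i]]
    so <- storage(sh[[l$id]])
    si <- if (length(l$inputs)) storage(sh[[l$inputs[1]]]) else c(rows = 0L, P = 0L, h = 0L, w = 0L)
    ish <- if (length(l$inputs)) sh[[l$inputs[1]]] else NULL
    pad <- c(0L, 0L)
    outHW <- c(1L, 1L)
    if (l$kind %in% c("convolution", "grouped-convolution", "max-pool")) {
      oh <- sh[[l$id]]$h; ow <- sh[[l$id]]$w
      outHW <- c(oh, ow)
      if (identical(l$padding, "same")) {
        pad <- c((l$filter[1] - 1L) %/% 2L, (l$filter[2] - 1L) %/% 2L)
      }
    }
    spec[[i]] <- list(
      kind = KIND_CODE[[l$kind]],
      ins = unname(idx[l$inputs]),
      rows = unname(so[["rows"]]), P = unname(so[["P"]]),
      inH = if (!is.null(ish) && ish$type == "map") ish$h else unname(si[["h"]]),
      inW = if (!is.null(ish) && ish$type == "map") ish$w else unname(si[["w"]]),
      inC = unname(si[["rows"]]),
      outH = outHW[1], outW = outHW[2],
      fh = if (is.null(l$filter)) 0L else l$filter[1],
      fw = if (is.null(l$filter)) 0L else l$filter[2],
      stride = l$stride, padT = pad[1], padL = pad[2],
      groups = l$groups, heads = l$heads,
      din = if (l$kind == "fully-connected") unname(si[["rows"]]) else 0L
    )
  }
  list(spec = spec, ids = ids, shapes = sh,
       logit_node = logit_node_index(g), softmax_node = softmax_node_index(g))
}

logit_node_index <- function(g) {
  ids <- names(g$layers)
  fc <- which(vapply(g$layers, function(l) l$kind == "fully-connected", logical(1)))
  if (!length(fc)) return(NA_integer_)
  max(fc) - 1L  # 0-based, last FC = classification logits
}

softmax_node_index <- function(g) {
  sm <- which(vapply(g$layers, function(l) l$kind == "softmax", logical(1)))
  if (!length(sm)) return(NA_integer_)
  max(sm) - 1L
}

he_uniform <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Instantiate a network: draw seeded initial weights for a graph
#'
#' Convolution and fully-connected weights are He-uniform in the fan-in;
#' batch-norm scale/shift start at 1/0 with running statistics at 0/1;
#' attention projections are He-uniform square maps. The draw order is the
#' graph's topological layer order, so a seed pins down every weight.
#'
#' @param g An [network_graph()].
#' @param seed Integer seed.
#' @return An object of class `nf_network`: the graph, its compiled form and
#'   the parameter list.
#' @export
instantiate_network <- function(g, seed = 1L) {
  comp <- compile_graph(g)
  sh <- comp$shapes
  set.seed(seed)
  params <- vector("list", length(g$layers))
  for (i in seq_along(g$layers)) {
    l <- g$layers[[i]]
    a <- if (length(l$inputs)) sh[[l$inputs[1]]] else NULL
    params[i] <- list(switch(
      l$kind,
      "convolution" = ,
      "grouped-convolution" = {
        k <- prod(l$filter) * a$c / l$groups
        list(W = he_uniform(k, l$out_channels, k), b = matrix(0, l$out_channels, 1L))
      },
      "batch-norm" = {
        cc <- if (a$type == "map") a$c else if (a$type == "vec") a$d else a$emb
        list(gamma = matrix(1, cc, 1L), beta = matrix(0, cc, 1L),
             rmean = matrix(0, cc, 1L), rvar = matrix(1, cc, 1L))
      },
      "self-attention" = {
        n <- a$emb
        p <- list(Wq = he_uniform(n, n, n), Wk = he_uniform(n, n, n), Wv = he_uniform(n, n, n))
        if (l$heads > 1L) p$Wo <- he_uniform(n, n, n)
        p
      },
      "fully-connected" = list(W = he_uniform(l$out_channels, a$d, a$d),
                               b = matrix(0, l$out_channels, 1L)),
      NULL
    ))
  }
  structure(list(graph = g, compiled = comp, params = params, seed = seed,
                 trained = FALSE),
            class = "nf_network")
}

#' @export
print.nf_network <- function(x, ...) {
  cat(sprintf("<nf_network> %s (%strained, seed %d)\n", x$graph$name,
              if (x$trained) "" else "un", x$seed))
  print(x$graph)
  invisible(x)
}

as_input_array <- function(batch, shape) {
  if (is.list(batch)) batch <- simplify2array(batch)
  d <- dim(batch)
  if (length(d) == 3L) dim(batch) <- c(d, 1L)
  d <- dim(batch)
  if (!identical(as.integer(d[1:3]), as.integer(shape))) {
    stop("batch shape ", paste(d[1:3], collapse = "x"),
         " does not match network input ", paste(shape, collapse = "x"))
  }
  if (min(batch) < -1e-8 || max(batch) > 1 + 1e-8) {
    stop("input values must lie in [0, 1]")
  }
  storage.mode(batch) <- "double"
  batch
}

#' Run a forward pass
#'
#' Returns the class probabilities (rows summing to 1) or, with `tap`, the
#' activation at the named layer — tapping the fusion depth-concatenation
#' node yields the fused deep-feature matrix (one 512-wide row per sample at
#' full width).
#'
#' @param net An [instantiate_network()] result.
#' @param batch Numeric array `H x W x C x N` (or a list of `H x W x C`
#'   arrays), values in `[0, 1]`.
#' @param tap Layer id to tap, or `NULL` for the final softmax output.
#' @return Numeric matrix, one row per sample.
#' @export
forward <- function(net, batch, tap = NULL) {
  comp <- net$compiled
  X <- as_input_array(batch, net$graph$input_shape)
  tap_idx <- if (is.null(tap)) {
    if (is.na(comp$softmax_node)) length(comp$ids) - 1L else comp$softmax_node
  } else {
    if (!tap %in% comp$ids) {
      stop("unknown tap layer '", tap, "'; graph layers are: ",
           paste(utils::head(comp$ids, 5), collapse = ", "), ", ...")
    }
    match(tap, comp$ids) - 1L
  }
  res <- nf_forward_cpp(comp$spec, net$params, X, dim(X), tap_idx, FALSE, 32L)
  out <- res$act
  id <- comp$ids[tap_idx + 1L]
  sh <- comp$shapes[[id]]
  colnames(out) <- switch(sh$type,
                          vec = paste0(id, "_", seq_len(sh$d)),
                          NULL)
  out
}

#' Train a network with SGD + momentum
#'
#' Mini-batch stochastic gradient descent on the softmax cross-entropy loss,
#' with batch-norm batch statistics during training and running statistics
#' kept for inference. Shuffling is seeded, so a (network seed, train seed)
#' pair reproduces the run exactly.
#'
#' @param net An [instantiate_network()] result.
#' @param batch Input array as in [forward()].
#' @param labels Integer or factor class labels (length N).
#' @param epochs Training epochs.
#' @param lr Initial learning rate (default 1.4e-4, the tuned value).
#' @param momentum SGD momentum (default 0.7002, the tuned value).
#' @param batch_size Mini-batch size (default 64).
#' @param seed Shuffle seed.
#' @return The trained `nf_network`, with a `history` tibble (epoch, loss)
#'   and `loss0` (full-set loss before any update) attached.
#' @export
train_network <- function(net, batch, labels, epochs = 10L, lr = 1.4e-4,
                          momentum = 0.7002, batch_size = 64L, seed = 1L) {
  comp <- net$compiled
  if (is.na(comp$logit_node)) stop("graph has no fully-connected head to train")
  X <- as_input_array(batch, net$graph$input_shape)
  y <- as.integer(as.factor(labels)) - 1L
  n <- dim(X)[4]
  if (length(y) != n) stop("labels length ", length(y), " != batch size ", n)
  if (anyNA(X)) stop("batch contains NA values")
  nclass <- comp$spec[[comp$logit_node + 1L]]$rows
  if (max(y) + 1L > nclass) stop("more classes than network outputs")
  set.seed(seed)
  order_mat <- t(vapply(seq_len(epochs), function(e) sample.int(n) - 1L, integer(n)))
  if (epochs == 1L) order_mat <- matrix(order_mat, nrow = 1L)
  loss0 <- nf_loss_cpp(comp$spec, net$params, X, dim(X), y,
                       comp$logit_node, as.integer(batch_size))
  res <- nf_train_cpp(comp$spec, net$params, X, dim(X), y,
                      comp$logit_node, order_mat, lr, momentum,
                      as.integer(batch_size), 0.1)
  net$params <- res$params
  net$trained <- TRUE
  net$loss0 <- loss0
  net$history <- tibble::tibble(epoch = seq_len(epochs), loss = res$epoch_loss)
  net$batch_loss <- res$batch_loss
  net
}

#' Stabilized softmax cross-entropy loss
#'
#' `loss = -t_y + log(sum_j exp(t_j))`, evaluated with the log-sum-exp trick
#' so large logits do not overflow.
#'
#' @param logits Numeric vector of raw class scores.
#' @param true_class Index (1-based) of the true class.
#' @return The loss value.
#' @export
softmax_cross_entropy <- function(logits, true_class) {
  stopifnot(all(is.finite(logits)),
            true_class >= 1L, true_class <= length(logits))
  m <- max(logits)
  -logits[true_class] + m + log(sum(exp(logits - m)))
}
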