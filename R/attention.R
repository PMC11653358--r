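# Scaled dot-product self-attention: the exact math used by the attention
# nodes of the network, exposed standalone so it can be verified directly.
#
# Given a token matrix M (m tokens x n embedding) and projection matrices
# Wq, Wk, Wv (n x dk): Q = M Wq, K = M Wk, V = M Wv; scores = Q K' / sqrt(dk);
# weights = row-softmax(scores); output = weights V. Each output row is a
# convex combination of the value rows.

#' Project a token matrix to queries, keys and values
#'
#' @param M Numeric matrix, m tokens x n embedding dimensions.
#' @param Wq,Wk,Wv Projection matrices, each n x dk.
#' @return List with matrices `Aq`, `Ak`, `Av` (each m x dk).
#' @export
project_qkv <- function(M, Wq, Wk, Wv) {
  M <- as.matrix(M)
  for (W in list(Wq, Wk, Wv)) {
    if (nrow(W) != ncol(M)) {
      stop("projection matrix has ", nrow(W), " rows but embedding dimension is ", ncol(M))
    }
  }
  if (!all(is.finite(M))) stop("token matrix contains non-finite values")
  list(Aq = M %*% Wq, Ak = M %*% Wk, Av = M %*% Wv)
}

#' Scaled dot-product attention scores
#'
#' `scores = Aq %*% t(Ak) / sqrt(dk)`. The `1/sqrt(dk)` scaling keeps the
#' dot products from growing with the projection width.
#'
#' @param Aq,Ak Query and key matrices (m x dk).
#' @param dk Projection width used for scaling (defaults to `ncol(Aq)`).
#' @return m x m score matrix.
#' @export
attention_scores <- function(Aq, Ak, dk = ncol(Aq)) {
  if (!is.numeric(dk) || length(dk) != 1L || dk <= 0) stop("dk must be a positive scalar")
  if (!identical(dim(Aq), dim(Ak))) stop("Aq and Ak must have identical dimensions")
  (Aq %*% t(Ak)) / sqrt(dk)
}

#' Row-wise softmax of an attention score matrix
#'
#' Applies a numerically stabilized softmax to every row, so each row of
#' the result is non-negative and sums to 1.
#'
#' @param AtS m x m score matrix (finite).
#' @return m x m row-stochastic weight matrix.
#' @export
attention_weights <- function(AtS) {
  AtS <- as.matrix(AtS)
  if (!all(is.finite(AtS))) stop("attention scores contain non-finite values")
  z <- AtS - apply(AtS, 1L, max)   # shift invariance: softmax(x) == softmax(x + c)
  e <- exp(z)
  e / rowSums(e)
}

#' Apply attention weights to the value matrix
#'
#' @param AtW m x m row-stochastic weight matrix.
#' @param Av m x dk value matrix.
#' @return m x dk output; row i is `sum_j AtW[i, j] * Av[j, ]`.
#' @export
attend <- function(AtW, Av) {
  AtW <- as.matrix(AtW); Av <- as.matrix(Av)
  if (ncol(AtW) != nrow(Av)) {
    stop("weight matrix is ", nrow(AtW), "x", ncol(AtW),
         " but value matrix has ", nrow(Av), " rows")
  }
  AtW %*% Av
}

#' Single-head self-attention (full pipeline)
#'
#' @inheritParams project_qkv
#' @return m x dk attended output matrix.
#' @export
self_attention <- function(M, Wq, Wk, Wv) {
  p <- project_qkv(M, Wq, Wk, Wv)
  attend(attention_weights(attention_scores(p$Aq, p$Ak)), p$Av)
}

#' Multi-head self-attention
#'
#' Splits the embedding into `heads` contiguous slices of width `n/heads`,
#' runs the single-head pipeline per head with that slice's projections
#' (scaling by `sqrt(n/heads)`), concatenates the head outputs along the
#' embedding axis and applies one output projection `Wo`.
#'
#' @param M m x n token matrix.
#' @param heads Head count; must divide `n`.
#' @param Wq,Wk,Wv n x n projection matrices (columns `((h-1)*n/heads + 1):(h*n/heads)`
#'   belong to head h).
#' @param Wo n x n output projection (identity if `NULL`).
#' @return m x n output matrix.
#' @export
multi_head_attention <- function(M, heads, Wq, Wk, Wv, Wo = NULL) {
  M <- as.matrix(M)
  n <- ncol(M)
  heads <- as.integer(heads)
  if (heads < 1L || n %% heads != 0L) {
    stop("embedding dimension ", n, " is not divisible by ", heads, " heads")
  }
  dk <- n %/% heads
  out <- matrix(0, nrow(M), 0L)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    p <- project_qkv(M, Wq[, cols, drop = FALSE], Wk[, cols, drop = FALSE],
                     Wv[, cols, drop = FALSE])
    o <- attend(attention_weights(attention_scores(p$Aq, p$Ak, dk = dk)), p$Av)
    out <- cbind(out, o)
  }
  if (!is.null(Wo)) out <- out %*% Wo
  out
}
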