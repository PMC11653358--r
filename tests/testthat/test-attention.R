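test_that("projections are the stated linear maps", {
  M <- matrix(c(1, 2), 1, 2)
  I2 <- diag(2)
  expect_equal(project_qkv(M, I2, I2, I2)$Aq, M)
  expect_equal(project_qkv(matrix(0, 3, 2), I2, I2, I2)$Av, matrix(0, 3, 2))
  expect_equal(project_qkv(M, 2 * I2, I2, I2)$Aq, matrix(c(2, 4), 1, 2))
  expect_error(project_qkv(M, diag(3), I2, I2), "embedding dimension")
})

test_that("attention scores follow the scaled dot product", {
  I2 <- diag(2)
  expect_equal(attention_scores(I2, I2, dk = 4), I2 / 2)
  expect_equal(attention_scores(matrix(0, 3, 2), matrix(1, 3, 2), dk = 2),
               matrix(0, 3, 3))
  expect_equal(attention_scores(matrix(2), matrix(2), dk = 1), matrix(4))
  expect_error(attention_scores(I2, I2, dk = 0), "positive")
})

test_that("softmax weights are row-stochastic, shift-invariant and exact on closed forms", {
  w <- attention_weights(matrix(c(0, log(2)), 1, 2))
  expect_equal(as.numeric(w), c(1 / 3, 2 / 3))
  expect_equal(as.numeric(attention_weights(matrix(5, 1, 4))), rep(1 / 4, 4))
  set.seed(11)
  for (i in 1:1000) {
    S <- matrix(stats::rnorm(12, sd = 10^stats::runif(1, -2, 2)), 3, 4)
    W <- attention_weights(S)
    expect_true(all(W >= 0))
    expect_true(all(abs(rowSums(W) - 1) < 1e-9))
  }
  S <- matrix(stats::rnorm(16), 4, 4)
  expect_equal(attention_weights(S), attention_weights(S + 3.7), tolerance = 1e-12)
  expect_error(attention_weights(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("attend applies the weighted sum with convex outputs", {
  Av <- matrix(stats::rnorm(12), 4, 3)
  expect_equal(attend(diag(4), Av), Av)
  W <- matrix(1 / 4, 4, 4)
  out <- attend(W, Av)
  for (j in 1:3) expect_equal(out[, j], rep(mean(Av[, j]), 4))
  expect_equal(attend(matrix(1), matrix(c(1, 2), 1, 2)), matrix(c(1, 2), 1, 2))
  expect_error(attend(matrix(1, 2, 2), Av), "rows")
  # convexity: every coordinate within the min/max of the value rows
  set.seed(4)
  for (i in 1:50) {
    W <- attention_weights(matrix(stats::rnorm(25), 5, 5))
    V <- matrix(stats::rnorm(15), 5, 3)
    O <- attend(W, V)
    for (j in 1:3) {
      expect_true(all(O[, j] >= min(V[, j]) - 1e-12))
      expect_true(all(O[, j] <= max(V[, j]) + 1e-12))
    }
  }
})

test_that("single-head pipeline agrees with a naive reference on random 5x8 inputs", {
  set.seed(21)
  for (i in 1:20) {
    M <- matrix(stats::rnorm(40), 5, 8)
    Wq <- matrix(stats::rnorm(64), 8, 8)
    Wk <- matrix(stats::rnorm(64), 8, 8)
    Wv <- matrix(stats::rnorm(64), 8, 8)
    expect_equal(self_attention(M, Wq, Wk, Wv), ref_attention(M, Wq, Wk, Wv),
                 tolerance = 1e-12)
  }
})

test_that("multi-head attention reduces, concatenates and projects as specified", {
  set.seed(31)
  M <- matrix(stats::rnorm(24), 4, 6)
  Wq <- matrix(stats::rnorm(36), 6, 6)
  Wk <- matrix(stats::rnorm(36), 6, 6)
  Wv <- matrix(stats::rnorm(36), 6, 6)
  # heads = 1 with identity output projection == single-head pipeline
  expect_equal(multi_head_attention(M, 1L, Wq, Wk, Wv, Wo = diag(6)),
               self_attention(M, Wq, Wk, Wv), tolerance = 1e-12)
  # output shape = input shape
  out <- multi_head_attention(M, 2L, Wq, Wk, Wv, Wo = matrix(stats::rnorm(36), 6, 6))
  expect_identical(dim(out), dim(M))
  # heads = 2: per-head brute force on the projection column blocks
  o2 <- multi_head_attention(M, 2L, Wq, Wk, Wv)
  h1 <- {
    p <- project_qkv(M, Wq[, 1:3], Wk[, 1:3], Wv[, 1:3])
    attend(attention_weights(attention_scores(p$Aq, p$Ak, dk = 3)), p$Av)
  }
  h2 <- {
    p <- project_qkv(M, Wq[, 4:6], Wk[, 4:6], Wv[, 4:6])
    attend(attention_weights(attention_scores(p$Aq, p$Ak, dk = 3)), p$Av)
  }
  expect_equal(o2, cbind(h1, h2), tolerance = 1e-12)
  expect_error(multi_head_attention(M, 4L, Wq, Wk, Wv), "divisible")
})
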