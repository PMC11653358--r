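# Shallow classifier variants, the confusion-matrix metric suite and
# stratified k-fold evaluation.

test_that("variant layouts and parameter counts match the naming convention", {
  expect_identical(classifier_spec("NNN", 8, 2)$hidden_layout, 10L)
  expect_identical(classifier_spec("MNN", 8, 2)$hidden_layout, 25L)
  expect_identical(classifier_spec("SWNN", 8, 2)$hidden_layout, 100L)
  expect_identical(classifier_spec("BNN", 8, 2)$hidden_layout, c(10L, 10L))
  expect_identical(classifier_spec("TNN", 8, 2)$hidden_layout, c(10L, 10L, 10L))
  expect_error(classifier_spec("XXL", 8, 2), "unknown classifier variant")
  expect_equal(n_params(classifier_spec("SWNN", 512, 5)),
               512 * 100 + 100 + 100 * 5 + 5)  # 51,805
})

test_that("training separates linearly separable blobs completely", {
  b <- make_blobs(n_per = 50, d = 4, gap = 6, seed = 2)
  h <- fit_classifier(build_classifier(classifier_spec("SWNN", 4, 2, seed = 1)),
                      b$X, b$y, epochs = 200)
  expect_identical(mean(predict(h, b$X) == b$y), 1)
})

test_that("zero-epoch and refitted classifiers are reproducible per seed", {
  b <- make_blobs(n_per = 20, d = 3, gap = 2, seed = 3)
  h0a <- fit_classifier(build_classifier(classifier_spec("NNN", 3, 2, seed = 5)),
                        b$X, b$y, epochs = 0)
  h0b <- fit_classifier(build_classifier(classifier_spec("NNN", 3, 2, seed = 5)),
                        b$X, b$y, epochs = 0)
  expect_identical(predict(h0a, b$X, type = "prob"),
                   predict(h0b, b$X, type = "prob"))
  h1a <- fit_classifier(build_classifier(classifier_spec("BNN", 3, 2, seed = 5)),
                        b$X, b$y, epochs = 50)
  h1b <- fit_classifier(build_classifier(classifier_spec("BNN", 3, 2, seed = 5)),
                        b$X, b$y, epochs = 50)
  expect_identical(h1a$fit$weights, h1b$fit$weights)
  expect_error(fit_classifier(build_classifier(classifier_spec("NNN", 3, 2)),
                              matrix(c(1, NA, 2, 3), 2, 2), factor(c("a", "b"))),
               "NA")
})

test_that("metrics match closed forms on canonical matrices", {
  d <- diag(c(5L, 7L, 9L))
  r <- compute_metrics(d)
  expect_equal(r$accuracy, 100)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$precision, 100)
  expect_equal(r$f1, 100)
  expect_equal(r$fnr, 0)

  # frozen hand computation for [[9,1],[2,8]] (rows = true class):
  # accuracy 17/20; recalls .9/.8; precisions 9/11, 8/9
  m <- matrix(c(9, 2, 1, 8), 2, 2)
  r2 <- compute_metrics(m)
  expect_equal(r2$accuracy, 85)
  expect_equal(r2$sensitivity, 85)
  expect_equal(r2$precision, 100 * (9 / 11 + 8 / 9) / 2, tolerance = 1e-12)
  expect_equal(r2$fnr, 15)

  # an empty true class is excluded from macro averages
  m3 <- matrix(c(4, 1, 0, 0, 0, 0, 0, 0, 5), 3, 3, byrow = TRUE)
  r3 <- compute_metrics(m3)
  expect_equal(r3$sensitivity, 100 * (4 / 5 + 1) / 2)

  expect_error(compute_metrics(matrix(0, 2, 2)), "all zero")
  expect_error(compute_metrics(matrix(1, 2, 3)), "square")
})

test_that("metrics agree with an independent hand computation on 50 random matrices", {
  set.seed(17)
  for (i in 1:50) {
    C <- sample(2:5, 1)
    cm <- matrix(stats::rpois(C * C, lambda = 6), C, C)
    if (sum(cm) == 0) cm[1, 1] <- 1
    got <- compute_metrics(cm)
    want <- ref_metrics(cm)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$sensitivity, want$sensitivity, tolerance = 1e-12)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_identical(got$fnr + got$sensitivity, 100)  # exact by construction
    expect_equal(rowSums(got$confusion), rowSums(cm), ignore_attr = TRUE)
  }
})

test_that("stratified k-fold pools a complete partition and is deterministic", {
  b <- make_blobs(n_per = 30, d = 3, gap = 8, seed = 4, classes = 3)
  spec <- classifier_spec("MNN", 3, 3, seed = 2)
  r <- kfold_evaluate(b$X, b$y, spec, k = 2, seed = 5, epochs = 150)
  expect_identical(sum(r$report$confusion), length(b$y))
  expect_equal(r$report$accuracy, 100)
  r2 <- kfold_evaluate(b$X, b$y, spec, k = 2, seed = 5, epochs = 150)
  expect_identical(r$fold, r2$fold)
  expect_identical(r$report$confusion, r2$report$confusion)
  expect_error(kfold_evaluate(b$X[1:5, ], droplevels(b$y[1:5]), spec, k = 10),
               "fewer than k")
})
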