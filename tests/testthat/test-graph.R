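test_that("layer specs validate their geometry", {
  expect_error(layer_spec("a", "convolution", "x"), "filter")
  expect_error(layer_spec("a", "convolution", "x", filter = 0, out_channels = 4),
               "positive")
  expect_error(layer_spec("a", "convolution", "x", filter = 3), "out_channels")
  expect_error(layer_spec("a", "relu", character()), "at least one input")
  expect_error(layer_spec("a", "depth-concatenation", "x"), ">= 2 inputs")
  expect_error(layer_spec("a", "input", inputs = "x"), "cannot have inputs")
  expect_error(layer_spec("a", "grouped-convolution", "x", filter = 3,
                          out_channels = 8, groups = 1), "groups >= 2")
  # default padding convention: same at stride 1, valid at stride 2
  expect_identical(layer_spec("a", "convolution", "x", filter = 3,
                              out_channels = 4)$padding, "same")
  expect_identical(layer_spec("a", "convolution", "x", filter = 3, stride = 2,
                              out_channels = 4)$padding, "valid")
})

test_that("graph validation rejects cycles, duplicates and bad references", {
  mk <- function(...) network_graph(list(...), input_shape = c(8, 8, 1))
  expect_error(mk(layer_spec("input", "input"),
                  layer_spec("r", "relu", "ghost")), "unknown input")
  expect_error(mk(layer_spec("input", "input"),
                  layer_spec("input", "input")), "duplicate|exactly one")
  expect_error(mk(layer_spec("r", "relu", "q"),
                  layer_spec("q", "relu", "r")), "cycle|exactly one")
  expect_error(mk(layer_spec("input", "input"),
                  layer_spec("a", "relu", "b"),
                  layer_spec("b", "relu", "a")), "cycle")
})

test_that("shape inference enforces concatenation alignment and names the layer", {
  layers <- list(
    layer_spec("input", "input"),
    layer_spec("c1", "convolution", "input", filter = 3, stride = 2, out_channels = 2),
    layer_spec("c2", "convolution", "input", filter = 1, stride = 1, out_channels = 2),
    layer_spec("bad", "depth-concatenation", c("c1", "c2")))
  expect_error(network_graph(layers, input_shape = c(16, 16, 1)),
               "'bad'.*spatial size")
})

test_that("concatenation output depth is the sum of input depths everywhere", {
  for (g in list(build_dense_module(), build_inception_module(),
                 build_fused_network())) {
    sh <- infer_shapes(g)
    for (l in g$layers) {
      if (l$kind != "depth-concatenation") next
      s <- sh[[l$id]]
      dims <- vapply(l$inputs, function(i) {
        si <- sh[[i]]
        if (si$type == "map") si$c else si$d
      }, integer(1))
      expect_identical(if (s$type == "map") s$c else s$d, sum(dims))
    }
  }
})

test_that("graph JSON round trip preserves the audit field-for-field", {
  g <- build_fused_network()
  path <- withr::local_tempfile(fileext = ".json")
  graph_to_json(g, path)
  g2 <- graph_from_json(path)
  a1 <- architecture_audit(g)
  a2 <- architecture_audit(g2)
  a2$name <- a1$name
  expect_identical(unclass(a1), unclass(a2))

  apath <- withr::local_tempfile(fileext = ".json")
  audit_to_json(a1, apath)
  a3 <- audit_from_json(apath)
  expect_equal(a3$total_parameters, a1$total_parameters)
  expect_identical(a3$layers_by_kind, a1$layers_by_kind)
})

test_that("width scaling keeps the layer count and scales parameters ~ s^2", {
  g <- build_fused_network()
  p1 <- count_parameters(g)
  for (s in c(0.5, 0.25, 0.125)) {
    gs <- scale_graph(g, s)
    expect_identical(count_layers(gs), count_layers(g))
    ratio <- count_parameters(gs) / p1
    expect_gt(ratio, 0.6 * s^2)
    expect_lt(ratio, 1.8 * s^2)
  }
})
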