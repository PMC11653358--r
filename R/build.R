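# Builders for the fused dense/inception architecture.
#
# Counting convention (frozen, see the methods vignette): the dense module is
# a complete standalone classifier (input + 67-node branch + 3-node head =
# 71 layers); the inception module is a feature extractor ending at its
# multi-head attention node (input + 43-node branch = 44 layers); fusion
# strips the dense head, merges the inputs and adds the 4-node fused head
# (depth-concatenation, fully-connected, softmax, classification):
# 1 + 67 + 43 + 4 = 115.

new_id_chain <- function() {
  env <- new.env(parent = emptyenv())
  env$layers <- list()
  env$last <- NULL
  env$add <- function(l) {
    env$layers[[l$id]] <- l
    env$last <- l$id
    invisible(l$id)
  }
  env
}

# residual block of five layers (conv, BN, ReLU, conv, ReLU) followed by a
# depth-concatenation of the block input with the block output
dense_res_block <- function(ch, prefix, input, d1, d2, f1 = c(1L, 1L), f2 = c(1L, 1L), i) {
  role <- sprintf("residual-block:%s:%d", prefix, i)
  p <- function(s) sprintf("%s_rb%d_%s", prefix, i, s)
  ch$add(layer_spec(p("conv1"), "convolution", input, filter = f1, stride = 1L,
                    out_channels = d1, role = role))
  ch$add(layer_spec(p("bn"), "batch-norm", p("conv1"), role = role))
  ch$add(layer_spec(p("relu1"), "relu", p("bn"), role = role))
  ch$add(layer_spec(p("conv2"), "convolution", p("relu1"), filter = f2, stride = 1L,
                    out_channels = d2, role = role))
  ch$add(layer_spec(p("relu2"), "relu", p("conv2"), role = role))
  ch$add(layer_spec(p("cat"), "depth-concatenation", c(input, p("relu2")), role = role))
  p("cat")
}

#' Build the dense module with self-attention
#'
#' A 71-layer standalone classifier: a 3x3/stride-2/depth-32 stem with batch
#' norm and ReLU, nine five-layer residual blocks (conv, BN, ReLU, conv,
#' ReLU) whose skip connections are realized as depth concatenations of each
#' block's input with its output, three 2x2/stride-2 transition convolutions
#' (depths 128, 256, 256) absorbing the concatenation depth growth, three
#' 3x3/stride-2 max-pools, a flatten, a single-head self-attention node over
#' the final feature map (256-dim embedding), and a fully-connected /
#' softmax / classification head. 22 convolution layers in total.
#'
#' @param num_classes Classes for the standalone head (default 5).
#' @param input_shape Input image shape; default `c(227, 227, 3)`.
#' @return An [network_graph()] with 71 layers.
#' @export
build_dense_module <- function(num_classes = 5L, input_shape = c(227L, 227L, 3L)) {
  ch <- new_id_chain()
  ch$add(layer_spec("input", "input"))
  ch$add(layer_spec("d_stem", "convolution", "input", filter = 3L, stride = 2L, out_channels = 32L))
  ch$add(layer_spec("d_stem_bn", "batch-norm", "d_stem"))
  ch$add(layer_spec("d_stem_relu", "relu", "d_stem_bn"))

  x <- dense_res_block(ch, "d", "d_stem_relu", 64L, 64L, i = 1L)
  x <- dense_res_block(ch, "d", x, 96L, 64L, i = 2L)

  ch$add(layer_spec("d_trans1", "convolution", x, filter = 2L, stride = 2L, out_channels = 128L))
  ch$add(layer_spec("d_trans1_relu", "relu", "d_trans1"))
  ch$add(layer_spec("d_pool1", "max-pool", "d_trans1_relu", filter = 3L, stride = 2L))

  x <- dense_res_block(ch, "d", "d_pool1", 128L, 128L, i = 3L)
  x <- dense_res_block(ch, "d", x, 128L, 64L, i = 4L)
  x <- dense_res_block(ch, "d", x, 128L, 128L, i = 5L)

  ch$add(layer_spec("d_trans2", "convolution", x, filter = 2L, stride = 2L, out_channels = 256L))
  ch$add(layer_spec("d_trans2_relu", "relu", "d_trans2"))
  ch$add(layer_spec("d_pool2", "max-pool", "d_trans2_relu", filter = 3L, stride = 2L))

  x <- dense_res_block(ch, "d", "d_pool2", 256L, 256L, f2 = c(3L, 3L), i = 6L)
  x <- dense_res_block(ch, "d", x, 128L, 128L, i = 7L)
  x <- dense_res_block(ch, "d", x, 256L, 256L, i = 8L)
  x <- dense_res_block(ch, "d", x, 256L, 256L, f2 = c(3L, 3L), i = 9L)

  ch$add(layer_spec("d_trans3", "convolution", x, filter = 2L, stride = 2L, out_channels = 256L))
  ch$add(layer_spec("d_pool3", "max-pool", "d_trans3", filter = 3L, stride = 2L))
  ch$add(layer_spec("d_flatten", "flatten", "d_pool3"))
  ch$add(layer_spec("d_attention", "self-attention", "d_flatten"))

  ch$add(layer_spec("d_fc", "fully-connected", "d_attention", out_channels = as.integer(num_classes)))
  ch$add(layer_spec("d_softmax", "softmax", "d_fc"))
  ch$add(layer_spec("d_class", "classification", "d_softmax"))

  network_graph(ch$layers, name = "dense-attention-module", input_shape = input_shape)
}

# inverted-bottleneck residual block of six layers (conv, ReLU, BN,
# grouped-conv 3x3, conv, BN) + depth-concatenation skip; group width 64
inv_res_block <- function(ch, input, d_mid, d_out, i) {
  role <- sprintf("residual-block:i:%d", i)
  p <- function(s) sprintf("i_ir%d_%s", i, s)
  ch$add(layer_spec(p("conv1"), "convolution", input, filter = 1L, stride = 1L,
                    out_channels = d_mid, role = role))
  ch$add(layer_spec(p("relu"), "relu", p("conv1"), role = role))
  ch$add(layer_spec(p("bn1"), "batch-norm", p("relu"), role = role))
  ch$add(layer_spec(p("gconv"), "grouped-convolution", p("bn1"), filter = 3L, stride = 1L,
                    out_channels = d_mid, groups = max(2L, d_mid %/% 64L), role = role))
  ch$add(layer_spec(p("conv2"), "convolution", p("gconv"), filter = 1L, stride = 1L,
                    out_channels = d_out, role = role))
  ch$add(layer_spec(p("bn2"), "batch-norm", p("conv2"), role = role))
  ch$add(layer_spec(p("cat"), "depth-concatenation", c(input, p("bn2")), role = role))
  p("cat")
}

#' Build the inception module with multiscale self-attention heads
#'
#' A 44-layer feature extractor following the inverted-bottleneck pattern:
#' a 1x1/stride-2/depth-16 stem (BN + ReLU), an inception block with four
#' parallel paths — 1x1; 1x1 followed by parallel 1x3 and 3x1 factorized
#' convolutions; 1x1 depth 32; and a 1x1 + 3x1 pair ahead of a 3x3/stride-1
#' max-pool — joined by depth concatenation and a ReLU; a 3x3/stride-2
#' depth-64 transition; three six-layer inverted residual blocks (conv,
#' ReLU, BN, grouped 3x3 conv, conv, BN; depths 128/256, 128/256, 256/312)
#' with depth-concatenation skips; a 3x3/stride-2 depth-256 transition;
#' max-pool; global average pool; flatten; and a 4-head self-attention node
#' (256-dim embedding).
#'
#' @param heads Attention head count (default 4).
#' @param input_shape Input image shape; default `c(227, 227, 3)`.
#' @return An [network_graph()] with 44 layers.
#' @export
build_inception_module <- function(heads = 4L, input_shape = c(227L, 227L, 3L)) {
  ch <- new_id_chain()
  ch$add(layer_spec("input", "input"))
  ch$add(layer_spec("i_stem", "convolution", "input", filter = 1L, stride = 2L, out_channels = 16L))
  ch$add(layer_spec("i_stem_bn", "batch-norm", "i_stem"))
  ch$add(layer_spec("i_stem_relu", "relu", "i_stem_bn"))

  ch$add(layer_spec("i_incA", "convolution", "i_stem_relu", filter = 1L, out_channels = 16L))
  ch$add(layer_spec("i_incB1", "convolution", "i_stem_relu", filter = 1L, out_channels = 16L))
  ch$add(layer_spec("i_incB_13", "convolution", "i_incB1", filter = c(1L, 3L), out_channels = 16L))
  ch$add(layer_spec("i_incB_31", "convolution", "i_incB1", filter = c(3L, 1L), out_channels = 16L))
  ch$add(layer_spec("i_incC", "convolution", "i_stem_relu", filter = 1L, out_channels = 32L))
  ch$add(layer_spec("i_incD1", "convolution", "i_stem_relu", filter = 1L, out_channels = 32L))
  ch$add(layer_spec("i_incD_31", "convolution", "i_incD1", filter = c(3L, 1L), out_channels = 32L))
  ch$add(layer_spec("i_incD_pool", "max-pool", "i_incD_31", filter = 3L, stride = 1L))
  ch$add(layer_spec("i_inc_cat", "depth-concatenation",
                    c("i_incA", "i_incB_13", "i_incB_31", "i_incC", "i_incD_pool")))
  ch$add(layer_spec("i_inc_relu", "relu", "i_inc_cat"))

  ch$add(layer_spec("i_trans1", "convolution", "i_inc_relu", filter = 3L, stride = 2L, out_channels = 64L))
  ch$add(layer_spec("i_trans1_relu", "relu", "i_trans1"))
  ch$add(layer_spec("i_pool1", "max-pool", "i_trans1_relu", filter = 3L, stride = 1L))

  x <- inv_res_block(ch, "i_pool1", 128L, 256L, 1L)
  x <- inv_res_block(ch, x, 128L, 256L, 2L)
  x <- inv_res_block(ch, x, 256L, 312L, 3L)

  ch$add(layer_spec("i_trans2", "convolution", x, filter = 3L, stride = 2L, out_channels = 256L))
  ch$add(layer_spec("i_trans2_relu", "relu", "i_trans2"))
  ch$add(layer_spec("i_pool2", "max-pool", "i_trans2_relu", filter = 3L, stride = 1L))
  ch$add(layer_spec("i_gap", "global-average-pool", "i_pool2"))
  ch$add(layer_spec("i_flatten", "flatten", "i_gap"))
  ch$add(layer_spec("i_attention", "self-attention", "i_flatten", heads = as.integer(heads)))

  network_graph(ch$layers, name = "inception-attention-module", input_shape = input_shape)
}

# terminal feature node = last node once any trailing FC/softmax/classification
# suffix is stripped; must carry a vector (rank-1) shape
terminal_feature <- function(g, label) {
  keep <- setdiff(names(g$layers), head_suffix_ids(g))
  feat_id <- keep[length(keep)]
  sh <- infer_shapes(g)[[feat_id]]
  if (sh$type != "vec") {
    stop("graph '", g$name, "' (", label, ") does not terminate in a feature vector: ",
         "node '", feat_id, "' has rank-", if (sh$type == "map") 3 else 2, " output")
  }
  list(id = feat_id, dim = sh$d, keep = keep)
}

#' Fuse two feature branches at the network level
#'
#' Strips any trailing fully-connected/softmax/classification head from each
#' argument, merges their input nodes, joins the two terminal feature
#' vectors with a depth-concatenation node (output width `d1 + d2`), and
#' attaches a fully-connected (`num_classes`), softmax and classification
#' head. With the shipped modules the fused feature width is 512 and the
#' fused graph has 115 layers.
#'
#' @param a,b [network_graph()] objects terminating (after head stripping) in
#'   feature vectors. Branch `a`'s layer ids win no special treatment beyond
#'   providing the shared input node.
#' @param num_classes Output classes of the fused head.
#' @param name Name for the fused graph.
#' @return The fused `nf_graph`.
#' @export
fuse_networks <- function(a, b, num_classes = 5L, name = "fused-network") {
  if (!identical(a$input_shape, b$input_shape)) {
    stop("cannot fuse: input shapes differ (",
         paste(a$input_shape, collapse = "x"), " vs ", paste(b$input_shape, collapse = "x"), ")")
  }
  fa <- terminal_feature(a, "first branch")
  fb <- terminal_feature(b, "second branch")

  a_in <- names(a$layers)[vapply(a$layers, function(l) l$kind == "input", logical(1))]
  b_in <- names(b$layers)[vapply(b$layers, function(l) l$kind == "input", logical(1))]

  a_layers <- a$layers[fa$keep]
  b_layers <- b$layers[setdiff(fb$keep, b_in)]
  # rewire b's consumers of its input onto a's input node
  b_layers <- lapply(b_layers, function(l) {
    l$inputs[l$inputs == b_in] <- a_in
    l
  })
  clash <- intersect(names(a_layers), names(b_layers))
  if (length(clash)) {
    stop("cannot fuse: branches share layer ids: ", paste(clash, collapse = ", "))
  }

  layers <- c(a_layers, b_layers)
  layers$fusion_cat <- layer_spec("fusion_cat", "depth-concatenation", c(fa$id, fb$id))
  layers$fused_fc <- layer_spec("fused_fc", "fully-connected", "fusion_cat",
                                out_channels = as.integer(num_classes))
  layers$fused_softmax <- layer_spec("fused_softmax", "softmax", "fused_fc")
  layers$fused_class <- layer_spec("fused_class", "classification", "fused_softmax")
  network_graph(layers, name = name, input_shape = a$input_shape)
}

#' Build the full fused architecture
#'
#' Convenience wrapper: [build_dense_module()] + [build_inception_module()]
#' fused by [fuse_networks()], optionally width-scaled for desk-scale CPU
#' training. At `width_scale = 1` the graph has 115 layers, a 512-wide fused
#' feature node and about 6.9 million parameters.
#'
#' @param num_classes Number of output classes.
#' @param width_scale Channel width multiplier (see [scale_graph()]).
#' @return An `nf_graph`.
#' @export
build_fused_network <- function(num_classes = 5L, width_scale = 1) {
  g <- fuse_networks(build_dense_module(num_classes), build_inception_module(),
                     num_classes = num_classes)
  scale_graph(g, width_scale)
}
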