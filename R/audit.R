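# Architecture audit: structural counts that can be checked against the
# printed description of the network (layer totals, residual blocks,
# convolution layers, parameter total, fused feature width).

#' Audit a network graph
#'
#' Computes the structural summary of a graph: total layers, layers by kind,
#' convolution-layer count (plain + grouped), residual-block count (distinct
#' residual-block roles declared by the builders), total learnable
#' parameters and, where present, the width of the depth-concatenation
#' feature node feeding the final fully-connected head.
#'
#' @param g An [network_graph()].
#' @return An object of class `nf_audit` (named list; see fields above).
#' @export
architecture_audit <- function(g) {
  kinds <- vapply(g$layers, function(l) l$kind, character(1))
  roles <- vapply(g$layers, function(l) l$role %||% "", character(1))
  blocks <- unique(roles[startsWith(roles, "residual-block:")])
  by_kind <- table(factor(kinds, levels = LAYER_KINDS))
  structure(
    list(
      name = g$name,
      total_layers = count_layers(g),
      layers_by_kind = as.list(stats::setNames(as.integer(by_kind), names(by_kind))),
      conv_layer_count = sum(kinds %in% c("convolution", "grouped-convolution")),
      residual_block_count = length(blocks),
      total_parameters = count_parameters(g),
      fused_feature_dim = fused_feature_dim(g)
    ),
    class = "nf_audit"
  )
}

#' Width of the fused feature node
#'
#' Returns the output width of the depth-concatenation node that feeds the
#' final fully-connected head (the layer deep features are extracted from),
#' or `NA` if the graph has no such node.
#'
#' @param g An [network_graph()].
#' @return Integer width or `NA`.
#' @export
fused_feature_dim <- function(g) {
  sh <- infer_shapes(g)
  fc_ids <- names(g$layers)[vapply(g$layers, function(l) l$kind == "fully-connected", logical(1))]
  for (fid in fc_ids) {
    src <- g$layers[[fid]]$inputs[1]
    if (g$layers[[src]]$kind == "depth-concatenation" && sh[[src]]$type == "vec") {
      return(sh[[src]]$d)
    }
  }
  NA_integer_
}

#' @export
print.nf_audit <- function(x, ...) {
  cat(sprintf("<nf_audit> %s\n", x$name))
  cat(sprintf("  layers: %d  convolutions: %d  residual blocks: %d\n",
              x$total_layers, x$conv_layer_count, x$residual_block_count))
  cat(sprintf("  parameters: %s  fused feature width: %s\n",
              format(x$total_parameters, big.mark = ","),
              ifelse(is.na(x$fused_feature_dim), "-", x$fused_feature_dim)))
  invisible(x)
}

#' @export
tidy.nf_audit <- function(x, ...) {
  tibble::tibble(kind = names(x$layers_by_kind),
                 n = unlist(x$layers_by_kind, use.names = FALSE)) |>
    dplyr::filter(.data$n > 0L)
}

#' @export
glance.nf_audit <- function(x, ...) {
  tibble::tibble(
    name = x$name, total_layers = x$total_layers,
    conv_layer_count = x$conv_layer_count,
    residual_block_count = x$residual_block_count,
    total_parameters = x$total_parameters,
    fused_feature_dim = x$fused_feature_dim
  )
}

#' Serialize an audit to JSON / read it back
#'
#' @param a An `nf_audit`.
#' @param path Output path, or `NULL` for a JSON string.
#' @export
audit_to_json <- function(a, path = NULL) {
  js <- jsonlite::toJSON(unclass(a), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' @rdname audit_to_json
#' @param x JSON path or string.
#' @export
audit_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  doc$layers_by_kind <- lapply(doc$layers_by_kind, as.integer)
  doc$total_layers <- as.integer(doc$total_layers)
  doc$conv_layer_count <- as.integer(doc$conv_layer_count)
  doc$residual_block_count <- as.integer(doc$residual_block_count)
  doc$fused_feature_dim <- as.integer(doc$fused_feature_dim)
  structure(doc, class = "nf_audit")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
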