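#' @useDynLib neurofuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

LAYER_KINDS <- c(
  "input", "convolution", "grouped-convolution", "batch-norm", "relu",
  "max-pool", "global-average-pool", "depth-concatenation", "flatten",
  "self-attention", "fully-connected", "softmax", "classification"
)

#' Declare a single layer of a network graph
#'
#' A `layer_spec` is a declarative, backend-independent description of one
#' node in a layer DAG: its kind, its geometry (filter, stride, padding,
#' channel depth, groups) and the ids of its upstream layers. Layer specs
#' carry no weights; they exist so an architecture can be built, counted,
#' audited and serialized independently of any tensor backend.
#'
#' @param id Unique layer id (string).
#' @param kind One of `r paste0('"', LAYER_KINDS, '"', collapse = ", ")`.
#' @param inputs Character vector of upstream layer ids (empty for `input`).
#' @param filter Length-2 integer vector `c(h, w)` for convolution/pooling.
#' @param stride Positive integer stride (convolution/pooling).
#' @param out_channels Output depth (convolution / fully-connected).
#' @param groups Number of filter groups (`grouped-convolution` only).
#' @param padding `"same"` or `"valid"`. Defaults to `"same"` when
#'   `stride == 1` and `"valid"` otherwise (stride-2 reductions use valid
#'   padding with floor division, keeping concatenation branches aligned).
#' @param heads Head count for `self-attention` (1 = single head).
#' @param role Optional free-form structural tag (for instance
#'   `"residual-block:dense:3"`); used by the architecture audit.
#' @return An object of class `nf_layer` (a named list).
#' @export
layer_spec <- function(id, kind, inputs = character(), filter = NULL,
                       stride = 1L, out_channels = NULL, groups = 1L,
                       padding = NULL, heads = 1L, role = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  kind <- match.arg(kind, LAYER_KINDS)
  if (kind == "input") {
    if (length(inputs) > 0L) stop("input layer '", id, "' cannot have inputs")
  } else if (length(inputs) < 1L) {
    stop("layer '", id, "' (", kind, ") must have at least one input")
  }
  if (kind == "depth-concatenation" && length(inputs) < 2L) {
    stop("depth-concatenation '", id, "' needs >= 2 inputs")
  }
  needs_filter <- kind %in% c("convolution", "grouped-convolution", "max-pool")
  if (needs_filter) {
    if (is.null(filter)) stop("layer '", id, "' (", kind, ") needs a filter size")
    filter <- as.integer(filter)
    if (length(filter) == 1L) filter <- c(filter, filter)
    if (any(filter < 1L)) stop("layer '", id, "': filter must be positive")
  } else {
    filter <- NULL
  }
  stride <- as.integer(stride)
  if (stride < 1L) stop("layer '", id, "': stride must be a positive integer")
  if (is.null(padding) && needs_filter) {
    padding <- if (stride == 1L) "same" else "valid"
  }
  if (!is.null(padding)) padding <- match.arg(padding, c("same", "valid"))
  if (kind %in% c("convolution", "grouped-convolution", "fully-connected")) {
    if (is.null(out_channels)) stop("layer '", id, "' (", kind, ") needs out_channels")
    out_channels <- as.integer(out_channels)
    if (out_channels < 1L) stop("layer '", id, "': out_channels must be positive")
  }
  groups <- as.integer(groups)
  if (kind == "grouped-convolution" && groups < 2L) {
    stop("grouped-convolution '", id, "' needs groups >= 2")
  }
  structure(
    list(id = id, kind = kind, inputs = as.character(inputs), filter = filter,
         stride = stride, out_channels = out_channels, groups = groups,
         padding = padding, heads = as.integer(heads), role = role),
    class = "nf_layer"
  )
}

#' Assemble layer specs into a network graph
#'
#' Validates that the layers form a DAG with exactly one input node, that
#' every referenced id exists, and (unless `infer = FALSE`) that shape
#' inference succeeds end to end — in particular that every
#' depth-concatenation joins feature maps of identical spatial size.
#'
#' @param layers List of [layer_spec()] objects in construction order.
#' @param name Graph name.
#' @param input_shape `c(height, width, channels)`; default 227 x 227 x 3.
#' @param infer Run shape inference as part of validation.
#' @return An object of class `nf_graph`.
#' @export
network_graph <- function(layers, name = "network", input_shape = c(227L, 227L, 3L),
                          infer = TRUE) {
  ids <- vapply(layers, function(l) l$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate layer ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  kinds <- vapply(layers, function(l) l$kind, character(1))
  if (sum(kinds == "input") != 1L) stop("graph must have exactly one input node")
  names(layers) <- ids
  for (l in layers) {
    missing <- setdiff(l$inputs, ids)
    if (length(missing)) {
      stop("layer '", l$id, "' references unknown input(s): ",
           paste(missing, collapse = ", "))
    }
  }
  g <- structure(
    list(name = name, input_shape = as.integer(input_shape), layers = layers),
    class = "nf_graph"
  )
  g$layers <- g$layers[topo_order(g)]
  if (infer) infer_shapes(g)  # errors if inconsistent
  g
}

# Kahn topological sort; errors on cycles.
topo_order <- function(g) {
  ids <- names(g$layers)
  indeg <- vapply(g$layers, function(l) length(l$inputs), integer(1))
  consumers <- lapply(ids, function(i) {
    ids[vapply(g$layers, function(l) i %in% l$inputs, logical(1))]
  })
  names(consumers) <- ids
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in consumers[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(ids)) {
    stop("graph '", g$name, "' contains a cycle involving: ",
         paste(setdiff(ids, out), collapse = ", "))
  }
  out
}

shp_map <- function(h, w, c) list(type = "map", h = as.integer(h), w = as.integer(w), c = as.integer(c))
shp_tok <- function(m, emb) list(type = "tokens", m = as.integer(m), emb = as.integer(emb))
shp_vec <- function(d) list(type = "vec", d = as.integer(d))

out_hw <- function(n, f, stride, padding) {
  if (padding == "same") {
    as.integer(ceiling(n / stride))
  } else {
    if (n < f) stop("spatial extent ", n, " smaller than filter ", f)
    as.integer(floor((n - f) / stride) + 1L)
  }
}

#' Infer the activation shape at every node of a graph
#'
#' Walks the DAG in topological order applying the padding convention stored
#' on each layer (same-padding keeps spatial size at stride 1; valid padding
#' uses floor division). Structural inconsistencies — concatenation of maps
#' with different spatial sizes, attention applied to a non-token input,
#' grouped convolution whose input depth is not divisible by its group
#' count — raise an error naming the offending layer.
#'
#' @param g An [network_graph()].
#' @return Named list of shape descriptors (`map`, `tokens` or `vec`).
#' @export
infer_shapes <- function(g) {
  shapes <- list()
  for (l in g$layers) {
    ins <- shapes[l$inputs]
    s <- switch(
      l$kind,
      "input" = shp_map(g$input_shape[1], g$input_shape[2], g$input_shape[3]),
      "convolution" = ,
      "grouped-convolution" = {
        a <- ins[[1]]
        if (a$type != "map") stop("layer '", l$id, "': convolution needs a feature-map input")
        if (l$kind == "grouped-convolution") {
          if (a$c %% l$groups != 0L || l$out_channels %% l$groups != 0L) {
            stop("layer '", l$id, "': channels (", a$c, "->", l$out_channels,
                 ") not divisible by groups (", l$groups, ")")
          }
        }
        shp_map(out_hw(a$h, l$filter[1], l$stride, l$padding),
                out_hw(a$w, l$filter[2], l$stride, l$padding), l$out_channels)
      },
      "batch-norm" = ,
      "relu" = ins[[1]],
      "max-pool" = {
        a <- ins[[1]]
        if (a$type != "map") stop("layer '", l$id, "': max-pool needs a feature-map input")
        shp_map(out_hw(a$h, l$filter[1], l$stride, l$padding),
                out_hw(a$w, l$filter[2], l$stride, l$padding), a$c)
      },
      "global-average-pool" = {
        a <- ins[[1]]
        if (a$type != "map") stop("layer '", l$id, "': global-average-pool needs a feature-map input")
        shp_vec(a$c)
      },
      "depth-concatenation" = {
        types <- vapply(ins, function(x) x$type, character(1))
        if (all(types == "map")) {
          hs <- vapply(ins, function(x) x$h, integer(1))
          ws <- vapply(ins, function(x) x$w, integer(1))
          if (length(unique(hs)) > 1L || length(unique(ws)) > 1L) {
            stop("depth-concatenation '", l$id, "' joins maps of different spatial size: ",
                 paste(sprintf("%s=%dx%d", l$inputs, hs, ws), collapse = ", "))
          }
          shp_map(hs[1], ws[1], sum(vapply(ins, function(x) x$c, integer(1))))
        } else if (all(types == "vec")) {
          shp_vec(sum(vapply(ins, function(x) x$d, integer(1))))
        } else {
          stop("depth-concatenation '", l$id, "' mixes feature-map and vector inputs (rank mismatch)")
        }
      },
      "flatten" = {
        a <- ins[[1]]
        if (a$type == "map") shp_tok(a$h * a$w, a$c)
        else if (a$type == "vec") shp_tok(1L, a$d)
        else stop("layer '", l$id, "': flatten applied twice")
      },
      "self-attention" = {
        a <- ins[[1]]
        if (a$type != "tokens") {
          stop("layer '", l$id, "': self-attention needs a flattened (token) input")
        }
        if (a$emb %% l$heads != 0L) {
          stop("layer '", l$id, "': embedding ", a$emb, " not divisible by ", l$heads, " heads")
        }
        shp_vec(a$emb)
      },
      "fully-connected" = {
        a <- ins[[1]]
        d <- if (a$type == "vec") a$d
        else if (a$type == "tokens") a$m * a$emb
        else stop("layer '", l$id, "': fully-connected needs a vector input")
        shp_vec(l$out_channels)
      },
      "softmax" = ,
      "classification" = {
        a <- ins[[1]]
        if (a$type != "vec") stop("layer '", l$id, "': needs a vector input")
        a
      },
      stop("unknown kind for layer '", l$id, "'")
    )
    shapes[[l$id]] <- s
  }
  shapes
}

#' Scale all channel depths of a graph by a width factor
#'
#' Multiplies every convolutional depth by `s` (rounding, floor 1, grouped
#' depths kept divisible by their group count). The class-count head
#' (fully-connected, softmax, classification) is left untouched. Layer count
#' is invariant under scaling; the parameter count scales approximately as
#' `s^2`, which is what makes desk-scale CPU training of the full topology
#' possible.
#'
#' @param g An [network_graph()].
#' @param s Width multiplier in (0, 1].
#' @return A rescaled `nf_graph`.
#' @export
scale_graph <- function(g, s) {
  stopifnot(is.numeric(s), s > 0, s <= 1)
  if (s == 1) return(g)
  head_ids <- head_suffix_ids(g)
  g$layers <- lapply(g$layers, function(l) {
    if (!is.null(l$out_channels) && l$kind != "fully-connected" && !(l$id %in% head_ids)) {
      k <- max(1L, l$groups)
      l$out_channels <- max(k, as.integer(round(l$out_channels * s / k) * k))
    }
    l
  })
  g$name <- sprintf("%s@x%g", g$name, s)
  infer_shapes(g)
  g
}

# ids of the trailing fully-connected/softmax/classification chain, if any
head_suffix_ids <- function(g) {
  ids <- names(g$layers)
  out <- character(0)
  for (i in rev(seq_along(ids))) {
    k <- g$layers[[i]]$kind
    if (k %in% c("fully-connected", "softmax", "classification")) {
      out <- c(g$layers[[i]]$id, out)
    } else break
  }
  out
}

#' Count the layers of a graph
#'
#' Every declared node counts as one layer: input, convolution, batch-norm,
#' activation, pooling, concatenation, flatten, attention (one node),
#' fully-connected, softmax and classification alike. Under this convention
#' the dense module counts 71 layers, the inception module 44 and the fused
#' network 115.
#'
#' @param g An [network_graph()].
#' @return Integer node count.
#' @export
count_layers <- function(g) length(g$layers)

#' Count the learnable parameters of a graph
#'
#' Convolution: `fh * fw * (Cin / groups) * Cout + Cout`; batch-norm: `2 * C`;
#' fully-connected: `din * dout + dout`; self-attention: three square
#' projection maps of the embedding dimension (plus an output projection for
#' multi-head nodes). Other kinds are parameter-free.
#'
#' @param g An [network_graph()].
#' @return Total learnable parameter count (double, exact integer value).
#' @export
count_parameters <- function(g) {
  shapes <- infer_shapes(g)
  total <- 0
  for (l in g$layers) {
    a <- if (length(l$inputs)) shapes[[l$inputs[1]]] else NULL
    total <- total + switch(
      l$kind,
      "convolution" = ,
      "grouped-convolution" =
        prod(l$filter) * (a$c / l$groups) * l$out_channels + l$out_channels,
      "batch-norm" = 2 * (if (a$type == "map") a$c else if (a$type == "vec") a$d else a$emb),
      "fully-connected" = a$d * l$out_channels + l$out_channels,
      "self-attention" = {
        n <- a$emb
        if (l$heads > 1L) 4 * n * n else 3 * n * n
      },
      0
    )
  }
  total
}

#' @export
print.nf_graph <- function(x, ...) {
  sh <- infer_shapes(x)
  cat(sprintf("<nf_graph> %s: %d layers, input %s\n", x$name, count_layers(x),
              paste(x$input_shape, collapse = "x")))
  last <- sh[[length(sh)]]
  d <- switch(last$type, vec = last$d, tokens = last$emb, map = last$c)
  cat(sprintf("  parameters: %s; terminal width: %d\n",
              format(count_parameters(x), big.mark = ","), d))
  invisible(x)
}

#' Tabulate a graph's layers as a tibble
#'
#' One row per node with its kind, geometry and inferred output shape;
#' convenient for inspection and for joining against parameter budgets.
#'
#' @param x An [network_graph()].
#' @param ... Unused.
#' @return A tibble with one row per layer.
#' @importFrom tibble as_tibble
#' @export as_tibble.nf_graph
#' @export
as_tibble.nf_graph <- function(x, ...) {
  sh <- infer_shapes(x)
  tibble::tibble(
    id = names(x$layers),
    kind = vapply(x$layers, function(l) l$kind, character(1)),
    filter = vapply(x$layers, function(l)
      if (is.null(l$filter)) NA_character_ else paste(l$filter, collapse = "x"), character(1)),
    stride = vapply(x$layers, function(l) l$stride, integer(1)),
    out_channels = vapply(x$layers, function(l)
      if (is.null(l$out_channels)) NA_integer_ else l$out_channels, integer(1)),
    groups = vapply(x$layers, function(l) l$groups, integer(1)),
    inputs = vapply(x$layers, function(l) paste(l$inputs, collapse = ","), character(1)),
    out_shape = vapply(names(x$layers), function(i) {
      s <- sh[[i]]
      switch(s$type,
             map = sprintf("%dx%dx%d", s$h, s$w, s$c),
             tokens = sprintf("%d tokens x %d", s$m, s$emb),
             vec = sprintf("%d", s$d))
    }, character(1)),
    role = vapply(x$layers, function(l) l$role %||% NA_character_, character(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a graph to JSON (and read it back)
#'
#' The JSON manifest lists every layer spec field plus the graph name and
#' input shape; `graph_from_json()` reconstructs a validated graph whose
#' audit is field-for-field identical to the original's.
#'
#' @param g An [network_graph()].
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `graph_to_json()`: the path (or JSON string) invisibly;
#'   `graph_from_json()`: an `nf_graph`.
#' @export
graph_to_json <- function(g, path = NULL) {
  doc <- list(
    name = g$name,
    input_shape = g$input_shape,
    layers = lapply(unname(g$layers), function(l) l[!vapply(l, is.null, logical(1))])
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' @rdname graph_to_json
#' @param x Path to a JSON manifest, or a JSON string.
#' @export
graph_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(doc$layers, function(l) {
    layer_spec(
      id = l$id, kind = l$kind, inputs = unlist(l$inputs) %||% character(),
      filter = l$filter, stride = l$stride %||% 1L,
      out_channels = l$out_channels, groups = l$groups %||% 1L,
      padding = l$padding, heads = l$heads %||% 1L, role = l$role
    )
  })
  network_graph(layers, name = doc$name, input_shape = doc$input_shape)
}
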