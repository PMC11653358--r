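# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the optimizer's best-so-far trace
#'
#' @param object A `cfo_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cfo_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$eval, y = .data$fitness)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::labs(x = "objective evaluations", y = "best fitness",
                  title = "Catch Fish Optimization trace") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heat map
#'
#' @param object A `classification_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classification_report <- function(object, ...) {
  cm <- as.data.frame(as.table(object$confusion))
  names(cm) <- c("true", "predicted", "n")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "grey20") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("accuracy %.1f%%", object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot the training-loss history of a trained network
#'
#' @param object An `nf_network` after [train_network()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nf_network <- function(object, ...) {
  if (is.null(object$history)) stop("network has no training history")
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$loss0, linetype = "dashed") +
    ggplot2::labs(y = "training loss (dashed: before training)") +
    ggplot2::theme_minimal()
}

#' Display sample images of a dataset
#'
#' @param ds Dataset tibble.
#' @param n Images to show (one per class first).
#' @return A ggplot (raster grid).
#' @export
plot_images <- function(ds, n = 8L) {
  pick <- unlist(lapply(split(seq_len(nrow(ds)), ds$label), utils::head, 1L))
  pick <- utils::head(unique(c(pick, seq_len(nrow(ds)))), n)
  df <- purrr::map_dfr(pick, function(i) {
    img <- ds$image[[i]][, , 1]
    tibble::tibble(
      i = sprintf("%d: %s", i, ds$label[i]),
      x = rep(seq_len(ncol(img)), each = nrow(img)),
      y = rep(rev(seq_len(nrow(img))), times = ncol(img)),
      v = as.vector(img))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::facet_wrap(~i) +
    ggplot2::coord_fixed() + ggplot2::theme_void()
}
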