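#' Reachability plot
#'
#' Bar plot of reachability distance in OPTICS visit order; valleys are
#' clusters.  Infinite reachability is drawn capped at 1.05 times the largest
#' finite value.
#'
#' @param object a [optics_order()] result.
#' @param clusters optional [extract_xi()] result used to colour members.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.reachability <- function(object, clusters = NULL, ...) {
  df <- tidy(object)
  fin <- is.finite(df$reachability)
  cap <- if (any(fin)) 1.05 * max(df$reachability[fin]) else 1
  df$shown <- ifelse(fin, df$reachability, cap)
  df$cluster <- "noise"
  if (!is.null(clusters)) {
    for (k in seq_along(clusters$intervals)) {
      iv <- clusters$intervals[[k]]
      df$cluster[iv$start:iv$end] <- sprintf("c%02d", k)
    }
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$shown,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_hue(h.start = 90) +
    ggplot2::labs(x = "OPTICS order", y = "reachability distance",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.reachability
#' @param r a [optics_order()] result.
#' @export
plot_reachability <- function(r, clusters = NULL) {
  autoplot.reachability(r, clusters)
}

#' Dot plot heat map
#'
#' Upper triangle of the base-pair probability matrix as a tile plot.
#'
#' @param object a [dot_plot()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dot_plot <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(limits = c(object$length, 1)) +
    ggplot2::scale_x_continuous(limits = c(1, object$length)) +
    ggplot2::scale_fill_gradient(low = "grey90", high = "black",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "p(i,j)") +
    ggplot2::theme_minimal()
}
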