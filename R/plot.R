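#' Plot a gray image
#'
#' Renders the raster with row 1 at the top, as on the detector.
#'
#' @param object A [gray_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gray_image <- function(object, ...) {
  df <- as_tibble.gray_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "gray") +
    ggplot2::theme_minimal()
}

#' Plot a pixel classification map
#'
#' @param classes Integer matrix of pixel class codes (see [pixel-classes]).
#' @return A ggplot object.
#' @export
plot_class_map <- function(classes) {
  stopifnot(is.matrix(classes))
  df <- tibble::tibble(
    row = rep(seq_len(nrow(classes)), times = ncol(classes)),
    col = rep(seq_len(ncol(classes)), each = nrow(classes)),
    class = factor(pixel_class_label(as.vector(classes)),
      levels = c("background", "diffraction", "main_spot")
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      background = "black", diffraction = "orange", main_spot = "white"
    )) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "pixel class") +
    ggplot2::theme_minimal()
}

ring_outline <- function(ring, n = 181) {
  if (is.na(ring$orientation)) {
    th <- seq(0, 2 * pi, length.out = n)
    rad <- ring$ring_width / 2
    return(tibble::tibble(
      row = ring$center_row + rad * sin(th),
      col = ring$center_col + rad * cos(th)
    ))
  }
  th <- seq(-pi / 2, pi / 2, length.out = n)
  s <- if (ring$orientation == "left") -1 else 1
  inner <- tibble::tibble(
    row = ring$center_row + ring$inner_radius * sin(th),
    col = ring$center_col + s * ring$inner_radius * cos(th)
  )
  outer <- tibble::tibble(
    row = ring$center_row + outer_radius(ring) * sin(rev(th)),
    col = ring$center_col + s * outer_radius(ring) * cos(rev(th))
  )
  dplyr::bind_rows(inner, outer, inner[1, ])
}

#' Plot a pipeline result
#'
#' The refined frame with the fitted ring annuli overlaid.
#'
#' @param object An `autofocus_result` from [run_pipeline()].
#' @param which Which raster to show: `"refined"`, `"cleaned"` or `"input"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.autofocus_result <- function(object, which = c("refined", "cleaned", "input"), ...) {
  which <- match.arg(which)
  p <- autoplot.gray_image(object[[which]])
  if (!is.null(object$stack)) {
    outlines <- purrr::imap(object$stack$rings, function(r, i) {
      df <- ring_outline(r)
      df$ring_id <- factor(i)
      df
    })
    p <- p + ggplot2::geom_path(
      data = dplyr::bind_rows(outlines),
      ggplot2::aes(x = .data$col, y = .data$row, colour = .data$ring_id),
      inherit.aes = FALSE, linewidth = 0.3
    )
  }
  p
}
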