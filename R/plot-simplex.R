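# Simplex-plot visualisation of classification results.  Each subject's
# final body of evidence is a point in the equilateral triangle spanned by
# the control vertex (left), case vertex (right) and uncertainty apex; the
# vertical median is the decision boundary, and the lines from each base
# vertex to the midpoint of the opposite edge separate dominant from
# non-dominant decisions.

#' Simplex plot of classification results
#'
#' @param x A `dst_loocv` / `dst_resub` object, or a data frame with
#'   columns `x`, `y`, `group` and `region` (as in their `results`).
#' @param title Optional plot title; defaults to the comparison name.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_simplex <- function(x, title = NULL, ...) {
  if (inherits(x, c("dst_loocv", "dst_resub"))) {
    if (is.null(title)) title <- x$spec$name
    results <- x$results
  } else {
    results <- x
  }
  stopifnot(is.data.frame(results),
            all(c("x", "y", "group") %in% names(results)))
  V <- simplex_vertices()
  tri <- data.frame(
    x = c(V$control[1], V$case[1], V$theta[1], V$control[1]),
    y = c(V$control[2], V$case[2], V$theta[2], V$control[2])
  )
  mid_case_theta <- (V$case + V$theta) / 2
  mid_control_theta <- (V$control + V$theta) / 2
  seg <- data.frame(
    x = c(0.5, V$control[1], V$case[1]),
    y = c(0, V$control[2], V$case[2]),
    xend = c(V$theta[1], mid_case_theta[1], mid_control_theta[1]),
    yend = c(V$theta[2], mid_case_theta[2], mid_control_theta[2]),
    boundary = c("decision", "dominance", "dominance")
  )
  lab <- data.frame(
    x = c(V$control[1] - 0.03, V$case[1] + 0.03, V$theta[1]),
    y = c(-0.04, -0.04, V$theta[2] + 0.05),
    text = c("control", "case", "θ")
  )
  ggplot2::ggplot() +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$boundary),
      colour = "grey40") +
    ggplot2::geom_point(
      data = results,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group),
      size = 2, alpha = 0.85) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$text), size = 3.5) +
    ggplot2::scale_linetype_manual(
      values = c(decision = "dashed", dominance = "dotted"), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom") +
    ggplot2::labs(title = title, colour = NULL)
}

# Write a ggplot to SVG, preferring the cairo-backed svg device.
save_simplex_svg <- function(p, path, width = 5, height = 5) {
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
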