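# ggplot2 views of the package's result types.

#' Plot a helical wheel
#'
#' Residues on the helical wheel, coloured by hydrophobicity, with an arrow
#' marking the hydrophobic face (the direction of the per-residue
#' hydrophobic-moment vector). The arrow is omitted when the face is
#' undefined (zero moment).
#'
#' @param object A [pep_wheel()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pep_wheel <- function(object, ...) {
  df <- as_tibble(object)
  rad <- df$azimuth * pi / 180
  df$px <- cos(rad); df$py <- sin(rad)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$H), shape = 21, size = 8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$aa), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "orange", midpoint = 0) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::labs(
      title = attr(object, "id"),
      subtitle = sprintf("face magnitude %.2f", attr(object, "face_magnitude")),
      fill = "H"
    ) +
    ggplot2::theme_void()
  face <- attr(object, "face_azimuth")
  if (!is.na(face)) {
    fr <- face * pi / 180
    p <- p + ggplot2::annotate(
      "segment", x = 0, y = 0, xend = 0.9 * cos(fr), yend = 0.9 * sin(fr),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.25, "cm")),
      linewidth = 0.8
    )
  }
  p
}

#' Plot a trajectory trace
#'
#' Raw per-frame values as a line, with the exponentially smoothed copy
#' overlaid when present.
#'
#' @param object A `"pep_trace"` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pep_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(
      x = "time (ps)",
      y = sprintf("%s (%s)", attr(object, "metric"), attr(object, "units"))
    ) +
    ggplot2::theme_minimal()
  if ("smoothed" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                                linewidth = 0.8, colour = "firebrick")
  }
  p
}

#' Plot all traces of an analysis
#'
#' Helicity, surface distance, and tilt traces of a trajectory analysis in
#' one faceted figure, annotated with the called binding mode.
#'
#' @param object A `"traj_analysis"` from [pipeline_analyze()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.traj_analysis <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "time (ps)", y = NULL,
      title = sprintf("binding mode %s%s", object$call$mode,
                      if (object$call$low_confidence) " (low confidence)" else "")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
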