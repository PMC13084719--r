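# ggplot2 figures for diagrams and traces.

#' Plot a phase diagram
#'
#' Classical c-T representation (temperature against concentration):
#' reliable liquidus points coloured by source window, unreliable points in
#' grey, the total concentration W_H as a dashed vertical line, a detected
#' gel-gel corner as a dotted horizontal line, and overlay points from other
#' techniques as open shapes.
#'
#' @param object A `"phase_diagram"` (or `"liquidus_map"`).
#' @param scale `"semilog"` (log10 concentration axis, default) or
#'   `"linear"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_diagram <- function(object, scale = c("semilog", "linear"), ...) {
  scale <- match.arg(scale)
  pts <- dplyr::filter(object$points, .data$segment == "liquidus")
  if (scale == "semilog") pts <- dplyr::filter(pts, .data$w_wtpct_H > 0)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$w_wtpct_H,
                                         y = .data$temperature_C)) +
    ggplot2::geom_point(data = dplyr::filter(pts, !.data$reliable),
                        colour = "grey70", size = 1.8) +
    ggplot2::geom_point(data = dplyr::filter(pts, .data$reliable),
                        ggplot2::aes(colour = .data$source_window), size = 1.8) +
    ggplot2::geom_vline(xintercept = object$W_H, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::labs(x = "w (wt%, H-solvent basis)", y = "T (°C)",
                  colour = "window") +
    ggplot2::theme_minimal()
  if (!is.null(object$corner) && isTRUE(object$corner$detected)) {
    p <- p + ggplot2::geom_hline(yintercept = object$corner$T_GG_C,
                                 linetype = "dotted", colour = "grey30")
  }
  if (!is.null(object$overlays) && nrow(object$overlays) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$overlays,
      ggplot2::aes(x = .data$W_wt_percent_H, y = .data$T_C,
                   shape = .data$technique),
      colour = "black", fill = NA, size = 2.2
    ) + ggplot2::scale_shape_manual(
      values = c(DSC = 0, rheology = 2, turbidimetry = 5), drop = TRUE)
  }
  if (scale == "semilog") p <- p + ggplot2::scale_x_log10()
  p
}

#' @export
autoplot.liquidus_map <- function(object, ...) autoplot(object$diagram, ...)

#' Plot normalized / corrected integral traces against temperature
#'
#' @param traces A trace tibble (from [normalize_traces()] or
#'   [correct_traces()]`$traces`).
#' @param value Column to plot.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, value = "normalized") {
  if (!value %in% names(traces)) {
    stop(sprintf("Column \"%s\" not present in traces.", value), call. = FALSE)
  }
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$temperature_C,
                                       y = .data[[value]],
                                       colour = .data$window)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "T (°C)", y = value, colour = "window") +
    ggplot2::theme_minimal()
}
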