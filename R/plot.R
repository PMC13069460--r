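#' Plot a time-response curve
#'
#' Adjusted odds ratio against developmental age with a pointwise 95% CI
#' ribbon, a horizontal reference line at AOR = 1, and open markers at
#' non-significant occasions.
#'
#' @param curve A `time_response_curve` tibble.
#' @param path Optional file path; when given the plot is written there
#'   (format from the extension) and the path returned invisibly.
#' @param title Optional plot title.
#' @return The ggplot object (or, with `path`, the path invisibly).
#' @export
plot_time_response <- function(curve, path = NULL, title = NULL) {
  if (!nrow(curve)) stop("empty curve", call. = FALSE)
  p <- ggplot2::autoplot(curve) + ggplot2::ggtitle(title %||% "")
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 7, height = 4.5, dpi = 150)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot time_response_curve
#' @export
autoplot.time_response_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$aor)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant),
                        colour = "steelblue", size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "significant",
                                           `FALSE` = "NS"),
                                name = NULL) +
    ggplot2::labs(x = "Developmental age (years; prenatal negative)",
                  y = sprintf("AOR (EPDS %g vs 0)",
                              attr(object, "contrast") %||% 13)) +
    ggplot2::theme_minimal()
}

#' @method autoplot dlnm_surface
#' @export
autoplot.dlnm_surface <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$age, y = .data$level,
                               fill = .data$log_aor)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "log AOR") +
    ggplot2::labs(x = "Developmental age (years)", y = "EPDS score (vs 0)") +
    ggplot2::theme_minimal()
}
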