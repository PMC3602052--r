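#' Longitudinal trend plot for one index
#'
#' Draws one line per group across ordered periods for the chosen index,
#' with a horizontal reference line at 1.0 — the interpretive anchor: a
#' series above the line outperforms the fixed reference on that index,
#' below underperforms. The y axis is linear and always includes 1.0.
#'
#' @param table A `benchmark_table`, typically from [longitudinal()].
#' @param index One of `"essi"`, `"sci"`, `"swi"`, `"sti"`, `"ope"`,
#'   `"ropi"`.
#' @param path Optional output path; when given, the figure is written
#'   there (format from `format`, sized `width` x `height` inches).
#' @param format `"png"`, `"pdf"` or `"svg"` (used when `path` has no
#'   recognised extension).
#' @param reference_line Draw the horizontal line at 1.0 (default
#'   `TRUE`).
#' @param width,height,dpi Device size and resolution.
#' @return The ggplot object, invisibly when written to `path`.
#' @export
plot_index_trend <- function(table, index = "ropi", path = NULL,
                             format = c("png", "pdf", "svg"),
                             reference_line = TRUE,
                             width = 7, height = 4.5, dpi = 150) {
  stopifnot(inherits(table, "benchmark_table"))
  index <- match.arg(index, c("essi", "sci", "swi", "sti", "ope", "ropi"))
  if (!nrow(table)) stop("empty benchmark table", call. = FALSE)
  lab <- c(essi = "eSSI", sci = "SCI", swi = "SWI", sti = "STI",
           ope = "OPE", ropi = "ROPI")[[index]]

  df <- tibble::as_tibble(table)
  df$period <- factor(df$period, levels = unique(df$period))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data[[index]],
                                        colour = .data$group,
                                        group = .data$group)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::expand_limits(y = 1) +
    ggplot2::labs(
      x = "Period", y = lab, colour = "Group",
      title = sprintf("%s relative to reference %s (%s)", lab,
                      attr(table, "reference_id"),
                      attr(table, "reference_period"))
    ) +
    ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (reference_line) {
    p <- p + ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                                 colour = "grey40")
  }
  if (is.null(path)) return(p)
  format <- match.arg(format)
  if (format == "svg") {
    # grDevices' cairo svg device; svglite is not assumed
    ggplot2::ggsave(path, plot = p, device = grDevices::svg,
                    width = width, height = height)
  } else {
    ggplot2::ggsave(path, plot = p, device = format,
                    width = width, height = height, dpi = dpi)
  }
  invisible(p)
}
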