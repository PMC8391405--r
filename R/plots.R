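#' Per-node bar charts of rates and indexes
#'
#' `plot_rates()` draws a grouped bar chart of each node's rate of passing
#' and reception (bits); `plot_indexes()` draws the corresponding `[0, 1]`
#' indexes with the y axis fixed to `[0, 1]` so charts are comparable across
#' teams and matches. Nodes appear in label order; inactive nodes render
#' zero-height bars.
#'
#' @param report A `metric_report` from [full_report()].
#' @param path Optional output path; when given, the chart is saved there
#'   via [ggplot2::ggsave()] (format from the file extension).
#' @param width,height Device size in inches when saving.
#' @return The ggplot object, invisibly when saved.
#' @export
plot_rates <- function(report, path = NULL, width = 8, height = 4) {
  stopifnot(inherits(report, "metric_report"))
  df <- tidyr::pivot_longer(
    report$per_node[, c("node", "R_out", "R_in")], -"node",
    names_to = "direction", values_to = "rate")
  df$direction <- factor(df$direction, levels = c("R_out", "R_in"),
                         labels = c("passing", "reception"))
  df$node <- factor(df$node, levels = report$per_node$node)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$rate,
                                        fill = .data$direction)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = "node", y = "rate (bits)", fill = NULL,
                  title = "Rate of passing and reception") +
    ggplot2::theme_minimal()
  maybe_save(p, path, width, height)
}

#' @rdname plot_rates
#' @export
plot_indexes <- function(report, path = NULL, width = 8, height = 4) {
  stopifnot(inherits(report, "metric_report"))
  df <- tidyr::pivot_longer(
    report$per_node[, c("node", "IndR_out", "IndR_in")], -"node",
    names_to = "direction", values_to = "index")
  df$direction <- factor(df$direction, levels = c("IndR_out", "IndR_in"),
                         labels = c("passing", "reception"))
  df$node <- factor(df$node, levels = report$per_node$node)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$index,
                                        fill = .data$direction)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "node", y = "index", fill = NULL,
                  title = "Index of rate of passing and reception") +
    ggplot2::theme_minimal()
  maybe_save(p, path, width, height)
}

maybe_save <- function(p, path, width, height) {
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' @param object A `metric_report`.
#' @param what `"rates"` or `"indexes"`.
#' @param ... Unused.
#' @rdname plot_rates
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, what = c("rates", "indexes"), ...) {
  what <- match.arg(what)
  if (what == "rates") plot_rates(object) else plot_indexes(object)
}
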