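#' Box plots of normalized usage per event
#'
#' The figure style of the usage analysis: one panel per row (event or
#' isoform group), disease groups side by side within each experiment,
#' values in junctions per million spliced reads, all points shown.
#'
#' @param usage Long tibble `row_id`, `sample`, `jpm`.
#' @param meta Sample metadata.
#' @param rows Optional subset of row ids to plot.
#' @return A ggplot object.
#' @export
plot_usage <- function(usage, meta, rows = NULL) {
  dat <- usage |>
    dplyr::inner_join(meta, by = c(sample = "sample_id"))
  if (!is.null(rows)) dat <- dplyr::filter(dat, .data$row_id %in% rows)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$disease, y = .data$jpm, fill = .data$disease
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.8) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$row_id),
      cols = ggplot2::vars(.data$experiment),
      scales = "free_y"
    ) +
    ggplot2::labs(x = NULL, y = "junction reads per million spliced reads") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' @method autoplot usage_difftest
#' @export
autoplot.usage_difftest <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::distinct(.data$row_id, .data$wald_q, .data$direction_combined)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$row_id, -log10(.data$wald_q)),
    y = -log10(.data$wald_q),
    fill = .data$direction_combined
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10]~"Wald q"),
                  fill = "direction") +
    ggplot2::theme_bw()
}

#' Relative reporter activity across the repeat-length series
#'
#' Normalized luciferase activity (relative to the reference construct)
#' per repeat length, one panel per promoter, one point per independent
#' experiment with the mean drawn as a column.
#'
#' @param activity Normalized table from [normalize_reporter()].
#' @return A ggplot object.
#' @export
plot_reporter <- function(activity) {
  ggplot2::ggplot(activity, ggplot2::aes(
    x = factor(.data$repeat_length), y = .data$value
  )) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$promoter)) +
    ggplot2::labs(x = "CTG repeats",
                  y = "relative luciferase activity (11-repeat = 1)") +
    ggplot2::theme_bw()
}
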