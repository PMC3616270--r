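# ggplot2 visualisations: trajectory traces, per-wave metric profiles, and
# sweep-grid heatmaps.

#' Plot a simulated trajectory
#'
#' Excitatory activity (and, where present, inhibitory and sensory
#' activity) per segment over time, facetted by segment with the posterior
#' segment on top so a forward wave reads downward across panels. An
#' optional horizontal line marks the contraction threshold.
#'
#' @param object A \code{cpg_trajectory}.
#' @param populations Which population types to draw (subset of
#'   `c("E", "I", "S")`).
#' @param threshold Optional contraction threshold to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpg_trajectory <- function(object, populations = c("E", "I"),
                                    threshold = NULL, ...) {
  long <- tidyr::pivot_longer(object, -"time", names_to = "series",
                              values_to = "activity") |>
    tidyr::extract("series", into = c("side", "population", "segment"),
                   regex = "(?:(left|right)_)?([EIS])(\\d+)",
                   convert = TRUE) |>
    mutate(side = ifelse(is.na(.data$side), "only", .data$side),
           segment = factor(.data$segment,
                            levels = sort(unique(.data$segment),
                                          decreasing = TRUE))) |>
    filter(.data$population %in% populations)
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$time, y = .data$activity,
                                    colour = .data$population,
                                    linetype = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$segment)) +
    ggplot2::scale_colour_manual(values = c(E = "#3366cc", I = "#cc3333",
                                            S = "black")) +
    ggplot2::labs(x = "time (t.u.)", y = "activity",
                  colour = "population", linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "grey40")
  if (length(unique(long$side)) == 1)
    p <- p + ggplot2::guides(linetype = "none")
  p
}

#' Plot per-wave metric profiles
#'
#' Normalized contraction duration per segment and intersegmental phase
#' lag per segment pair for a single quantified wave.
#'
#' @param object A \code{cpg_wave_metrics} object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpg_wave_metrics <- function(object, ...) {
  if (is.null(object$durations))
    abort("no per-segment metrics available (wave incomplete)")
  dat <- bind_rows(
    tibble(x = object$durations$segment, metric = "normalized duration",
           value = object$durations$normalized_duration),
    tibble(x = object$lags$from_segment, metric = "phase lag",
           value = object$lags$lag))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_col(fill = "#3366cc") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "segment", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a sweep grid
#'
#' Generic tile plot for the long-format tibbles returned by the sweep
#' experiments, mirroring the published phase-diagram figures. Cells with
#' `NA` fill (for instance no-wave sentinels converted to `NA`) are drawn
#' grey.
#'
#' @param grid A sweep result tibble.
#' @param x,y,fill Column names (strings) for the axes and fill value.
#' @return A ggplot object.
#' @examples
#' \dontrun{
#' sweep_drive(seq(1, 4, 0.5), c(1, 5, 10)) |>
#'   plot_sweep_grid("strength", "duration", "n_waves")
#' }
#' @export
plot_sweep_grid <- function(grid, x, y, fill) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                     fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey70") +
    ggplot2::theme_minimal()
}
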