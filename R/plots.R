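#' Plot AS-event type composition
#'
#' Bar chart of per-type percentages, optionally faceted over several
#' summaries (e.g. the two species groups).
#'
#' @param ... Named [summarize_types()] tables, e.g.
#'   `plot_type_composition(maize = s1, teosinte = s2)`.
#' @return A ggplot object.
#' @export
plot_type_composition <- function(...) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(!nzchar(names(tabs)))) {
    names(tabs) <- paste0("group", seq_along(tabs))
  }
  df <- dplyr::bind_rows(purrr::imap(tabs, function(t, nm) {
    dplyr::mutate(dplyr::as_tibble(t), group = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$event_type,
                                                      -.data$pct),
                                   y = .data$pct, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "AS event type", y = "% of events", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a depth-saturation curve
#'
#' Mean detected AS genes and events per depth fraction, with a ribbon of
#' +/- one standard deviation over replicates.
#'
#' @param x A `saturation_curve` from [saturation_curve()].
#' @return A ggplot object.
#' @export
plot_saturation <- function(x) {
  means <- tidy(x) |>
    tidyr::pivot_longer(-"depth_fraction",
                        names_to = c(".value", "what"),
                        names_pattern = "(mean|sd)_(.*)")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$depth_fraction,
                                      y = .data$mean,
                                      colour = .data$what,
                                      fill = .data$what)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "depth fraction", y = "detected (mean over replicates)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.saturation_curve <- function(object, ...) plot_saturation(object)

#' Plot the retained-intron length distribution
#'
#' @param catalog Event catalog (merged or per-library).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_retained_intron_lengths <- function(catalog, bins = 30) {
  df <- retained_intron_table(catalog)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(x = "retained intron length (bp)", y = "introns") +
    ggplot2::theme_minimal()
}
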