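#' Scatter plot of normalized enrichment with mean ± SD and stars
#'
#' The assay's standard presentation: one jittered point per QC-passing
#' cell, a horizontal bar at the group arithmetic mean with whiskers at
#' mean ± sample SD, and the significance stars of each comparison against
#' the control above the corresponding group.
#'
#' @param results an `rf3h_results` object, or a normalized measurement
#'   tibble (then `stats` and `control` may be supplied separately).
#' @param stats optional comparison tibble from [compare_to_control()].
#' @param control optional control label (ordering only).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, stats = NULL, control = NULL) {
  if (inherits(results, "rf3h_results")) {
    stats <- results$stats
    control <- results$control
    cells <- results$cells
  } else {
    cells <- results
  }
  cells <- filter(cells, .data$qc_pass, !is.na(.data$normalized_value))
  lvls <- unique(cells$condition)
  if (!is.null(control)) lvls <- c(control, setdiff(lvls, control))
  cells$condition <- factor(cells$condition, levels = lvls)
  summ <- cells %>%
    group_by(.data$condition) %>%
    summarise(mean = mean(.data$normalized_value),
              sd = sd(.data$normalized_value), .groups = "drop")
  p <- ggplot2::ggplot(cells,
                       ggplot2::aes(x = .data$condition,
                                    y = .data$normalized_value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1.2) +
    ggplot2::geom_errorbar(
      data = summ,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0.3, linewidth = 0.4) +
    ggplot2::geom_crossbar(
      data = summ,
      ggplot2::aes(y = .data$mean, ymin = .data$mean, ymax = .data$mean),
      width = 0.45, linewidth = 0.5) +
    ggplot2::labs(x = NULL, y = "normalized relative fluorescence") +
    ggplot2::theme_classic()
  if (!is.null(stats) && nrow(stats)) {
    ymax <- max(cells$normalized_value)
    ann <- stats %>%
      filter(.data$group_a %in% lvls) %>%
      mutate(condition = factor(.data$group_a, levels = lvls),
             y = ymax * 1.08)
    p <- p + ggplot2::geom_text(
      data = ann,
      ggplot2::aes(x = .data$condition, y = .data$y, label = .data$stars),
      size = 4)
  }
  p
}

#' @rdname plot_enrichment
#' @param object an `rf3h_results` object.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.rf3h_results <- function(object, ...) {
  plot_enrichment(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
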