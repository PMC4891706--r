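#' Screen scatter plot with category regions
#'
#' One point per line (median maximum mean distance vs median percent
#' dead), coloured by category, with the quantile boundaries drawn as
#' dashed lines and, optionally, the control population as a cross (thick
#' quartile bars, thin decile bars).
#'
#' @param classified A tibble from [classify_lines()].
#' @param boundaries A [compute_boundaries()] result.
#' @param control A [control_summary()] tibble, optional.
#' @return A ggplot object.
#' @export
plot_screen <- function(classified, boundaries, control = NULL) {
  pal <- c(normal = "forestgreen", overcautious = "tan4",
           very_clumsy = "red3", clumsy = "purple3",
           overeager = "royalblue3", super_climber = "gold2")
  p <- ggplot2::ggplot(classified,
                       ggplot2::aes(x = .data$median_max_mean_distance,
                                    y = .data$median_pct_dead,
                                    colour = .data$category)) +
    ggplot2::geom_vline(xintercept = c(boundaries$x_low, boundaries$x_high),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = boundaries$y_high,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(shape = 18, size = 2.5, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "median max mean distance from centre (rel. units)",
                  y = "median dead flies (%)", colour = "category") +
    ggplot2::theme_minimal()
  if (!is.null(control)) {
    cx <- control[control$axis == "max_mean_distance", ]
    cy <- control[control$axis == "pct_dead", ]
    p <- p +
      ggplot2::annotate("segment", x = cx$q10, xend = cx$q90,
                        y = cy$median, yend = cy$median,
                        colour = "darkgreen", linewidth = 0.4) +
      ggplot2::annotate("segment", x = cx$q25, xend = cx$q75,
                        y = cy$median, yend = cy$median,
                        colour = "darkgreen", linewidth = 1.4) +
      ggplot2::annotate("segment", x = cx$median, xend = cx$median,
                        y = cy$q10, yend = cy$q90,
                        colour = "darkgreen", linewidth = 0.4) +
      ggplot2::annotate("segment", x = cx$median, xend = cx$median,
                        y = cy$q25, yend = cy$q75,
                        colour = "darkgreen", linewidth = 1.4)
  }
  p
}

#' Mean-distance-over-time plot
#'
#' Development of the cohort mean distance from centre (relative units)
#' over the recording, one curve per experiment, with the maximum marked.
#'
#' @param tracks_list A named list of `ring_tracks` tibbles.
#' @return A ggplot object.
#' @export
plot_mean_distance <- function(tracks_list) {
  df <- purrr::imap_dfr(tracks_list, function(tr, nm) {
    dplyr::mutate(mean_distance_series(tr), line = nm)
  })
  peaks <- df %>%
    dplyr::group_by(.data$line) %>%
    dplyr::slice_max(.data$mean_r, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$mean_r,
                                   colour = .data$line)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = peaks, shape = 1, size = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "mean distance from centre (rel. units)",
                  colour = "line") +
    ggplot2::theme_minimal()
}

#' Box plots of per-fly fractions over gap width
#'
#' The single-gap summary: per-fly fractions as boxes (quartiles), whiskers
#' (deciles) and median bars, per line and gap width, optionally annotated
#' with rank-sum significance stars.
#'
#' @param fractions A tibble from [per_fly_fractions()].
#' @param metric Fraction column to plot.
#' @param comparisons Optional [compare_to_control()] tibble for star
#'   annotations of this metric.
#' @return A ggplot object.
#' @export
plot_gap_fractions <- function(fractions, metric = "frac_attempt",
                               comparisons = NULL) {
  p <- ggplot2::ggplot(fractions,
                       ggplot2::aes(x = factor(.data$gap_mm),
                                    y = .data[[metric]],
                                    fill = .data$line_id)) +
    ggplot2::stat_summary(
      fun.data = function(v) {
        q <- stats::quantile(v, c(0.10, 0.25, 0.5, 0.75, 0.90), type = 7)
        data.frame(ymin = q[[1]], lower = q[[2]], middle = q[[3]],
                   upper = q[[4]], ymax = q[[5]])
      },
      geom = "boxplot", position = ggplot2::position_dodge(width = 0.75),
      width = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "gap width (mm)", y = metric, fill = "line") +
    ggplot2::theme_minimal()
  if (!is.null(comparisons)) {
    stars <- comparisons %>%
      dplyr::filter(.data$metric == !!metric, .data$stars != "ns")
    if (nrow(stars) > 0) {
      p <- p + ggplot2::geom_text(
        data = dplyr::mutate(stars, gap_mm = factor(.data$gap_mm)),
        ggplot2::aes(x = .data$gap_mm, y = 1.02, label = .data$stars),
        inherit.aes = FALSE, size = 4)
    }
  }
  p
}

#' @export
autoplot.ring_tracks <- function(object, ...) {
  nm <- attr(object, "line_id")
  plot_mean_distance(stats::setNames(list(object),
                                     if (is.na(nm)) "experiment" else nm))
}

#' @export
autoplot.approach_log <- function(object, ...) {
  plot_gap_fractions(per_fly_fractions(object), ...)
}

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
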