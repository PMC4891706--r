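#' Per-line summary of replicate screen metrics
#'
#' Collapses replicate experiments to one row per line: the median maximum
#' mean distance from centre (the screen's x-axis) and the median percentage
#' of dead flies (the y-axis). Warns about lines with fewer than three
#' replicates.
#'
#' @param metrics A tibble of per-experiment metrics (e.g. rows from
#'   [ring_metrics()]) with `line_id`, `max_mean_distance`, `pct_dead`.
#' @return A tibble with `line_id`, `n_replicates`,
#'   `median_max_mean_distance`, `median_pct_dead`.
#' @examples
#' m <- tibble::tibble(line_id = "a", max_mean_distance = c(.2, .4, .9),
#'                     pct_dead = c(0, 20, 40))
#' summarize_lines(m)
#' @export
summarize_lines <- function(metrics) {
  if (nrow(metrics) == 0L) abort_validation("`metrics` is empty.")
  out <- metrics %>%
    dplyr::group_by(.data$line_id) %>%
    dplyr::summarise(
      n_replicates = dplyr::n(),
      median_max_mean_distance = stats::median(.data$max_mean_distance),
      median_pct_dead = stats::median(.data$pct_dead),
      .groups = "drop")
  if (any(out$n_replicates < 3)) {
    rlang::warn("Some lines have fewer than 3 replicates.")
  }
  out
}

#' Population quantile boundaries of the screen
#'
#' The classification boundaries: the 10th and 90th empirical percentiles
#' (linear interpolation of order statistics) of the per-line median maximum
#' mean distance, and the 90th percentile of the per-line median death
#' percentage. Lines at or below `x_low` are under-performers, at or above
#' `x_high` over-performers, and at or above `y_high` flagged for excess
#' losses.
#'
#' @param summaries A tibble from [summarize_lines()] (at least 10 lines).
#' @return A list of class `screen_boundaries` with `x_low`, `x_high`,
#'   `y_high`, `n_lines`.
#' @examples
#' s <- tibble::tibble(line_id = letters[1:10],
#'                     median_max_mean_distance = seq(0.1, 1, by = 0.1),
#'                     median_pct_dead = seq(0, 45, by = 5))
#' compute_boundaries(s)
#' @export
compute_boundaries <- function(summaries) {
  if (nrow(summaries) < 10L) {
    abort_validation("At least 10 lines are required to set quantile boundaries.")
  }
  x <- summaries$median_max_mean_distance
  y <- summaries$median_pct_dead
  structure(
    list(x_low = unname(stats::quantile(x, 0.10, type = 7)),
         x_high = unname(stats::quantile(x, 0.90, type = 7)),
         y_high = unname(stats::quantile(y, 0.90, type = 7)),
         n_lines = nrow(summaries)),
    class = "screen_boundaries")
}

#' @export
print.screen_boundaries <- function(x, ...) {
  cat("<screen_boundaries> x_low", signif(x$x_low, 4),
      "| x_high", signif(x$x_high, 4),
      "| y_high", signif(x$y_high, 4),
      "| n =", x$n_lines, "lines\n")
  invisible(x)
}

#' The six screen categories
#'
#' Category levels in ladder order. Comparisons against the boundaries are
#' inclusive, so lines tied exactly at a boundary are flagged; on the
#' discrete death statistic (multiples of 100/15) this makes the high-death
#' group at least 10% of lines.
#'
#' @return Character vector of the category names.
#' @export
screen_categories <- function() {
  c("normal", "overcautious", "very_clumsy", "clumsy", "overeager",
    "super_climber")
}

#' Classify screened lines into the six categories
#'
#' Decision ladder on the per-line medians (x = median maximum mean
#' distance, y = median percent dead): under-performing and high-death gives
#' "very_clumsy" (drown already at the small gaps); under-performing alone
#' "overcautious"; over-performing and high-death "overeager" (reach the
#' periphery at the cost of losses); over-performing alone "super_climber";
#' high-death alone "clumsy"; everything else "normal". Each line gets
#' exactly one category.
#'
#' @param summaries A tibble from [summarize_lines()].
#' @param boundaries A [compute_boundaries()] result (computed from the same
#'   population).
#' @return `summaries` with an added factor column `category`.
#' @examples
#' s <- tibble::tibble(line_id = sprintf("l%02d", 1:20),
#'                     median_max_mean_distance = seq(0.05, 1, by = 0.05),
#'                     median_pct_dead = rep(c(0, 40), 10))
#' b <- compute_boundaries(s)
#' classify_lines(s, b)
#' @export
classify_lines <- function(summaries, boundaries) {
  stopifnot(inherits(boundaries, "screen_boundaries"))
  x <- summaries$median_max_mean_distance
  y <- summaries$median_pct_dead
  low <- x <= boundaries$x_low
  high <- x >= boundaries$x_high
  deadly <- y >= boundaries$y_high
  cat <- dplyr::case_when(
    low & deadly ~ "very_clumsy",
    low ~ "overcautious",
    high & deadly ~ "overeager",
    high ~ "super_climber",
    deadly ~ "clumsy",
    TRUE ~ "normal")
  dplyr::mutate(summaries,
                category = factor(cat, levels = screen_categories()))
}

#' Category census of a classified screen
#'
#' Counts and percentages per category (all six levels reported, including
#' empty ones); percentages sum to 100 up to rounding.
#'
#' @param classified A tibble from [classify_lines()].
#' @return A tibble with `category`, `n`, `pct`.
#' @export
category_census <- function(classified) {
  if (nrow(classified) == 0L) abort_validation("No classified lines.")
  classified %>%
    dplyr::count(.data$category, .drop = FALSE) %>%
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
}

#' Quantile summary of control experiments
#'
#' Medians, quartiles and deciles of the control population on both screen
#' axes, using the same linear-interpolation quantile convention as the
#' boundaries. Drawn as the control cross on the screen scatter plot.
#'
#' @param metrics A tibble of per-experiment control metrics
#'   (`max_mean_distance`, `pct_dead`; at least 2 rows).
#' @return A tibble with one row per axis and columns `axis`, `q10`, `q25`,
#'   `median`, `q75`, `q90`, `n`.
#' @export
control_summary <- function(metrics) {
  if (nrow(metrics) < 2L) {
    abort_validation("At least 2 control experiments are required.")
  }
  qs <- function(v) {
    q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7)
    tibble::tibble(q10 = q[[1]], q25 = q[[2]], median = q[[3]],
                   q75 = q[[4]], q90 = q[[5]], n = length(v))
  }
  dplyr::bind_rows(
    dplyr::mutate(qs(metrics$max_mean_distance),
                  axis = "max_mean_distance", .before = 1),
    dplyr::mutate(qs(metrics$pct_dead), axis = "pct_dead", .before = 1))
}

#' @export
tidy.screen_boundaries <- function(x, ...) {
  tibble::tibble(boundary = c("x_low", "x_high", "y_high"),
                 value = c(x$x_low, x$x_high, x$y_high))
}
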