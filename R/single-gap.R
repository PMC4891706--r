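#' Per-fly attempt, fall and crossing fractions
#'
#' Collapses an approach log (ten approaches per fly) into per-fly
#' fractions: attempts, falls and crossings per approach, plus falls per
#' attempt (the video-scoring reading of "percentage of falling"). Every
#' fraction is a multiple of 1/10; a fly with a different number of
#' approaches, or with a fall or crossing outside an attempt, aborts.
#'
#' @param log An `approach_log` tibble (see [simulate_catwalk_session()] or
#'   [read_approach_log()]).
#' @param n_approaches Expected approaches per fly.
#' @return A tibble with one row per fly (and per `line_id`, `gap_mm`,
#'   `visibility` group): `n_approaches`, `frac_attempt`, `frac_fall`,
#'   `frac_cross`, `frac_fall_given_attempt`.
#' @examples
#' log <- simulate_catwalk_session(ringgap_profile("control"),
#'                                 catwalk_setup(2.5), n_flies = 10, seed = 1)
#' per_fly_fractions(log)
#' @export
per_fly_fractions <- function(log, n_approaches = 10L) {
  validate_approach_log(log, n_approaches)
  log %>%
    dplyr::group_by(.data$line_id, .data$gap_mm, .data$visibility,
                    .data$fly_id) %>%
    dplyr::summarise(
      n_approaches = dplyr::n(),
      frac_attempt = mean(.data$attempted),
      frac_fall = mean(.data$fell),
      frac_cross = mean(.data$crossed),
      frac_fall_given_attempt =
        ifelse(sum(.data$attempted) > 0,
               sum(.data$fell) / sum(.data$attempted), 0),
      .groups = "drop")
}

validate_approach_log <- function(log, n_approaches = 10L) {
  need <- c("line_id", "gap_mm", "visibility", "fly_id", "approach",
            "attempted", "fell", "crossed")
  missing <- setdiff(need, names(log))
  if (length(missing) > 0) {
    abort_validation(paste0("Approach log is missing columns: ",
                            paste(missing, collapse = ", "), "."))
  }
  counts <- log %>%
    dplyr::count(.data$line_id, .data$gap_mm, .data$visibility, .data$fly_id)
  bad <- counts$n != n_approaches
  if (any(bad)) {
    abort_validation(paste0(
      "Each fly must contribute exactly ", n_approaches,
      " approaches; found counts ",
      paste(unique(counts$n[bad]), collapse = ", "), "."))
  }
  if (any((log$fell | log$crossed) & !log$attempted)) {
    abort_validation("A fall or crossing was recorded without an attempt.")
  }
  if (any(log$fell & log$crossed)) {
    abort_validation("An approach cannot both fall and cross.")
  }
  invisible(log)
}

#' Box-plot statistics
#'
#' Median, 25/75% quartiles and 10/90% quantiles of a numeric vector
#' (linear interpolation of order statistics), the summary drawn as boxes
#' and whiskers for each line and gap width.
#'
#' @param values Numeric vector, length at least 1.
#' @return A one-row tibble: `q10`, `q25`, `median`, `q75`, `q90`, `n`.
#' @examples
#' box_stats(1:10) # q25 = 3.25, q75 = 7.75
#' @export
box_stats <- function(values) {
  if (length(values) == 0L) abort_validation("`values` is empty.")
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7)
  tibble::tibble(q10 = q[[1]], q25 = q[[2]], median = q[[3]],
                 q75 = q[[4]], q90 = q[[5]], n = length(values))
}

#' Box statistics of per-fly fractions by gap width
#'
#' @param fractions A tibble from [per_fly_fractions()].
#' @param metric Which fraction column to summarise.
#' @return One row of [box_stats()] per `line_id` x `gap_mm` x `visibility`.
#' @export
gap_box_stats <- function(fractions, metric = "frac_attempt") {
  fractions %>%
    dplyr::group_by(.data$line_id, .data$gap_mm, .data$visibility) %>%
    dplyr::reframe(box_stats(.data[[metric]])) %>%
    dplyr::mutate(metric = metric, .after = "visibility")
}

#' Wilcoxon rank-sum test (exact enumeration and normal approximation)
#'
#' Two-sided two-sample rank-sum test using midranks for ties. When the
#' combined sample size is at most `exact_max` the null distribution of the
#' rank-sum statistic is enumerated over all label assignments and the
#' p-value is the probability of a statistic at least as far from its null
#' mean as observed. Otherwise a normal approximation with tie correction
#' and continuity correction is used. Both p-values are always reported;
#' `p_value` selects per the size rule. A pooled sample with all values
#' equal gives p = 1.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param exact_max Largest combined sample size for the enumeration path.
#' @return An object of class `ringgap_ranksum`: a list with `statistic`
#'   (rank sum of `group_a`), `p_value`, `p_exact`, `p_approx`, `method`,
#'   `n_a`, `n_b`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p_value # 1/3
#' rank_sum_test(1:3, 4:6)$p_value # 0.1
#' @export
rank_sum_test <- function(group_a, group_b, exact_max = 20L) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort_validation("Both groups must be non-empty.")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  n <- n_a + n_b
  pooled <- c(group_a, group_b)
  r <- rank(pooled) # midranks
  w <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2

  degenerate <- length(unique(pooled)) == 1L
  p_exact <- NA_real_
  if (degenerate) {
    p_exact <- 1
    p_approx <- 1
  } else {
    if (n <= exact_max) {
      sums <- colSums(matrix(r[utils::combn(n, n_a)], nrow = n_a))
      p_exact <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    }
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    d <- w - mu
    d <- sign(d) * max(0, abs(d) - 0.5) # continuity correction toward the mean
    p_approx <- min(1, 2 * stats::pnorm(-abs(d) / sqrt(sigma2)))
  }
  method <- if (degenerate) "degenerate"
            else if (n <= exact_max) "exact enumeration"
            else "normal approximation"
  structure(
    list(statistic = w,
         p_value = if (!is.na(p_exact)) p_exact else p_approx,
         p_exact = p_exact, p_approx = p_approx,
         method = method, n_a = n_a, n_b = n_b),
    class = "ringgap_ranksum")
}

#' @export
print.ringgap_ranksum <- function(x, ...) {
  cat("Rank-sum test (", x$method, "): W = ", x$statistic,
      ", p = ", signif(x$p_value, 4), " (n = ", x$n_a, " vs ", x$n_b, ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.ringgap_ranksum <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 p_exact = x$p_exact, p_approx = x$p_approx,
                 method = x$method, n_a = x$n_a, n_b = x$n_b)
}

#' Significance stars
#'
#' Star coding with strict thresholds: `***` for p < 0.001, `**` for
#' p < 0.01, `*` for p < 0.05, `ns` otherwise (p = 0.05 is `ns`).
#'
#' @param p P-value(s) in \[0, 1\].
#' @return Character vector of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @examples
#' star_code(c(0.04, 0.0009, 0.05))
#' @export
star_code <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_validation("P-values must lie in [0, 1].")
  }
  dplyr::case_when(p < 0.001 ~ "***",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Compare a line to controls per gap width
#'
#' Rank-sum comparisons of per-fly fractions between a line and its control
#' at every gap width present in both, for the requested metrics (attempt
#' and crossing fractions by default). P-values are uncorrected, matching
#' the per-width star coding of the assay figures; set `adjust = "holm"`
#' for a Holm adjustment across widths within each metric.
#'
#' @param line_fractions,control_fractions Tibbles from
#'   [per_fly_fractions()].
#' @param metrics Fraction columns to compare.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A tibble of class `gap_comparison` with `gap_mm`, `metric`,
#'   `statistic`, `p_value`, `method`, `stars`, `median_line`,
#'   `median_control`, `direction`.
#' @export
compare_to_control <- function(line_fractions, control_fractions,
                               metrics = c("frac_attempt", "frac_cross"),
                               adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  widths_line <- unique(line_fractions$gap_mm)
  widths_ctrl <- unique(control_fractions$gap_mm)
  widths <- intersect(widths_line, widths_ctrl)
  skipped <- setdiff(union(widths_line, widths_ctrl), widths)
  if (length(skipped) > 0) {
    rlang::warn(paste0("No matched data at gap width(s) ",
                       paste(sort(skipped), collapse = ", "),
                       " mm; skipped."))
  }
  if (length(widths) == 0L) {
    abort_validation("No gap width is present in both line and control data.")
  }
  grid <- tidyr::expand_grid(gap_mm = sort(widths), metric = metrics)
  out <- purrr::pmap_dfr(grid, function(gap_mm, metric) {
    a <- line_fractions[[metric]][line_fractions$gap_mm == gap_mm]
    b <- control_fractions[[metric]][control_fractions$gap_mm == gap_mm]
    ts <- rank_sum_test(a, b)
    tibble::tibble(
      gap_mm = gap_mm, metric = metric,
      statistic = ts$statistic, p_value = ts$p_value, method = ts$method,
      median_line = stats::median(a), median_control = stats::median(b),
      direction = sign(stats::median(a) - stats::median(b)))
  })
  if (adjust == "holm") {
    out <- out %>%
      dplyr::group_by(.data$metric) %>%
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value, "holm")) %>%
      dplyr::ungroup()
  }
  out <- dplyr::mutate(out, stars = star_code(.data$p_value),
                       .after = "p_value")
  class(out) <- c("gap_comparison", class(out))
  out
}
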