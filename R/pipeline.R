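#' Simulate a small synthetic screen
#'
#' Runs the agent-based ring-assay simulator for a set of line profiles,
#' several replicates each, and returns per-experiment metrics ready for
#' [summarize_lines()].
#'
#' @param line_profiles Named list of [behavior_profile()]s; names are used
#'   as line ids.
#' @param n_replicates Replicates per line.
#' @param geometry An [arena_geometry()].
#' @param duration Recording duration per experiment (s).
#' @param seed Integer seed; each experiment derives its own stream.
#' @return A tibble of [ring_metrics()] rows (one per experiment).
#' @export
simulate_screen <- function(line_profiles, n_replicates = 3,
                            geometry = arena_geometry(), duration = 600,
                            seed = 1) {
  stopifnot(length(line_profiles) > 0, !is.null(names(line_profiles)))
  grid <- tidyr::expand_grid(line = names(line_profiles),
                             replicate = seq_len(n_replicates))
  purrr::pmap_dfr(grid, function(line, replicate) {
    exp_seed <- as.integer((as.numeric(seed) +
                              7919 * match(line, names(line_profiles)) +
                              104729 * replicate) %% .Machine$integer.max)
    tr <- simulate_ring_experiment(line_profiles[[line]], geometry,
                                   duration = duration, seed = exp_seed,
                                   line_id = line, replicate = replicate)
    ring_metrics(tr)
  })
}

#' Run the full demonstration pipeline
#'
#' Executes simulate -> analyze -> classify/compare end-to-end and writes a
#' report bundle: per-experiment metrics CSV, line classification CSV,
#' boundaries JSON, single-gap comparison CSV, a screen scatter figure, a
#' box-summary figure and a run manifest. Stage failures abort with the
#' stage name.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for every random stage.
#' @param config Optional list overriding `lines` (named list of profiles),
#'   `n_replicates`, `duration`, `gap_widths`, `n_flies_gap`.
#' @return Named character vector of output paths, invisibly.
#' @export
pipeline_run <- function(out_dir, seed = 1, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- config$lines %||% {
    nm <- ringgap_profiles()
    stats::setNames(lapply(nm, ringgap_profile), nm)
  }
  n_replicates <- config$n_replicates %||% 3
  duration <- config$duration %||% 300
  gap_widths <- config$gap_widths %||% c(2.5, 4.0, 5.0)
  n_flies_gap <- config$n_flies_gap %||% 12
  geometry <- config$geometry %||% arena_geometry()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("Pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "ringgap_error_pipeline")
    })
  }

  metrics <- stage("simulate-ring", simulate_screen(
    lines, n_replicates = n_replicates, geometry = geometry,
    duration = duration, seed = seed))
  summaries <- stage("summarize", summarize_lines(metrics))
  classified <- if (nrow(summaries) >= 10) {
    b <- stage("classify", compute_boundaries(summaries))
    list(lines = stage("classify", classify_lines(summaries, b)),
         boundaries = b)
  } else NULL

  gap_logs <- stage("simulate-gap", purrr::map_dfr(gap_widths, function(w) {
    dplyr::bind_rows(
      simulate_catwalk_session(ringgap_profile("control"), catwalk_setup(w),
                               n_flies = n_flies_gap,
                               seed = seed + round(1000 * w)),
      simulate_catwalk_session(ringgap_profile("overeager"), catwalk_setup(w),
                               n_flies = n_flies_gap,
                               seed = seed + round(1000 * w) + 1L))
  }))
  fr <- stage("analyze-gap", per_fly_fractions(gap_logs))
  cmp <- stage("analyze-gap", compare_to_control(
    dplyr::filter(fr, .data$line_id == "overeager"),
    dplyr::filter(fr, .data$line_id == "control")))

  paths <- c(metrics = file.path(out_dir, "ring_metrics.csv"),
             summaries = file.path(out_dir, "line_summaries.csv"),
             comparisons = file.path(out_dir, "gap_comparisons.csv"),
             boundaries = file.path(out_dir, "boundaries.json"),
             screen_plot = file.path(out_dir, "screen_scatter.pdf"),
             box_plot = file.path(out_dir, "gap_boxes.pdf"),
             manifest = file.path(out_dir, "manifest.json"))
  readr::write_csv(dplyr::select(metrics, -"dead_per_groove"),
                   paths[["metrics"]], progress = FALSE)
  if (!is.null(classified)) {
    readr::write_csv(classified$lines, paths[["summaries"]], progress = FALSE)
    jsonlite::write_json(unclass(classified$boundaries),
                         paths[["boundaries"]], auto_unbox = TRUE,
                         digits = NA)
    p1 <- plot_screen(classified$lines, classified$boundaries)
    ggplot2::ggsave(paths[["screen_plot"]], p1, width = 6, height = 5)
  } else {
    readr::write_csv(summaries, paths[["summaries"]], progress = FALSE)
    paths <- paths[!names(paths) %in% c("boundaries", "screen_plot")]
  }
  readr::write_csv(cmp, paths[["comparisons"]], progress = FALSE)
  p2 <- plot_gap_fractions(fr, comparisons = cmp)
  ggplot2::ggsave(paths[["box_plot"]], p2, width = 7, height = 4)
  write_manifest("pipeline_run",
                 config = list(n_replicates = n_replicates,
                               duration = duration,
                               gap_widths = gap_widths,
                               n_flies_gap = n_flies_gap,
                               lines = names(lines)),
                 seed = seed, inputs = character(),
                 outputs = unname(paths), path = paths[["manifest"]])
  invisible(paths)
}
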