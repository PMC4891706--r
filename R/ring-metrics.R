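#' Radial distance series of one fly
#'
#' Distance from the disk centre per sample, in relative units of the disk
#' radius (0 = centre, 1 = outer rim).
#'
#' @param track A data frame with `t_s`, `x_mm`, `y_mm` for one fly.
#' @param geometry An [arena_geometry()].
#' @return A tibble with `t_s` and `r_rel`.
#' @examples
#' tr <- tibble::tibble(t_s = 0:1, x_mm = c(0, 30), y_mm = c(0, 40))
#' radial_distance_series(tr, arena_geometry())$r_rel
#' @export
radial_distance_series <- function(track, geometry) {
  r <- sqrt(track$x_mm^2 + track$y_mm^2)
  if (any(r > geometry$disk_radius + 1e-9)) {
    abort_validation("Track contains positions outside the disk.")
  }
  tibble::tibble(t_s = track$t_s, r_rel = r / geometry$disk_radius)
}

#' Mean distance from centre over time
#'
#' Per-second mean of the relative radial distances of all flies in the
#' record. Dead flies keep contributing with their frozen position in a
#' groove, so the series reflects the whole cohort throughout.
#'
#' @param tracks A `ring_tracks` tibble (or any track table with `t_s`,
#'   `fly_id`, `x_mm`, `y_mm`).
#' @param geometry An [arena_geometry()]; defaults to the one attached to
#'   `tracks`.
#' @return A tibble with `t_s` and `mean_r` (relative units).
#' @examples
#' tr <- simulate_ring_experiment(ringgap_profile("control"), seed = 1,
#'                                duration = 30)
#' mean_distance_series(tr)
#' @export
mean_distance_series <- function(tracks, geometry = attr(tracks, "geometry")) {
  check_track_grid(tracks)
  tracks %>%
    dplyr::mutate(r_rel = sqrt(.data$x_mm^2 + .data$y_mm^2) /
                    geometry$disk_radius) %>%
    dplyr::group_by(.data$t_s) %>%
    dplyr::summarise(mean_r = mean(.data$r_rel), .groups = "drop") %>%
    dplyr::arrange(.data$t_s)
}

check_track_grid <- function(tracks) {
  counts <- dplyr::count(tracks, .data$fly_id)
  if (dplyr::n_distinct(counts$n) != 1L) {
    abort_validation("All flies must share the same timestamp grid (no missing samples).")
  }
  grids <- tracks %>%
    dplyr::group_by(.data$fly_id) %>%
    dplyr::summarise(ok = identical(sort(.data$t_s),
                                    as.numeric(seq_len(dplyr::n()) - 1)) ||
                       identical(sort(.data$t_s), seq_len(dplyr::n()) - 1L),
                     .groups = "drop")
  if (!all(grids$ok)) {
    abort_validation("Timestamps must be the full 1 Hz grid 0, 1, ..., duration - 1.")
  }
  invisible(tracks)
}

#' Maximum of the mean-distance series and its first attainment time
#'
#' The maximum mean distance from centre at any time during the recording is
#' the main screen classification parameter; ties are broken by the first
#' time the maximum is reached.
#'
#' @param series A tibble from [mean_distance_series()] (columns `t_s`,
#'   `mean_r`).
#' @return A list with `max_mean_distance` and `time_to_max` (s).
#' @examples
#' s <- tibble::tibble(t_s = 0:3, mean_r = c(0.1, 0.5, 0.3, 0.5))
#' max_mean_distance_and_time(s) # 0.5 at t = 1
#' @export
max_mean_distance_and_time <- function(series) {
  if (nrow(series) == 0L) abort_validation("Mean-distance series is empty.")
  i <- which.max(series$mean_r)
  list(max_mean_distance = series$mean_r[i], time_to_max = series$t_s[i])
}

#' Detect drowned flies from a track table
#'
#' A fly is scored dead when, from some time to the end of the recording,
#' its radial position lies inside one groove annulus and it moves less
#' than `eps` from its final position. On simulated records this reproduces
#' the simulator's ground-truth status exactly, because live flies are never
#' placed inside a groove.
#'
#' @param track One fly's rows (`t_s`, `x_mm`, `y_mm`, ordered by time).
#' @param geometry An [arena_geometry()].
#' @param eps Immobility tolerance in mm.
#' @return A list with `is_dead`, `death_groove` (index or `NA`) and
#'   `death_time` (first second of the terminal immobile stretch, or `NA`).
#' @export
detect_deaths_from_track <- function(track, geometry, eps = 0.5) {
  n <- nrow(track)
  xf <- track$x_mm[n]
  yf <- track$y_mm[n]
  g <- groove_at_radius(sqrt(xf^2 + yf^2), geometry)
  if (is.na(g)) {
    return(list(is_dead = FALSE, death_groove = NA_integer_,
                death_time = NA_real_))
  }
  disp <- sqrt((track$x_mm - xf)^2 + (track$y_mm - yf)^2)
  inside <- !is.na(vapply(sqrt(track$x_mm^2 + track$y_mm^2),
                          groove_at_radius, integer(1), geometry = geometry))
  still <- disp < eps & inside
  # longest terminal run of immobile-in-groove samples
  if (!still[n]) {
    return(list(is_dead = FALSE, death_groove = NA_integer_,
                death_time = NA_real_))
  }
  t_star <- n
  while (t_star > 1L && still[t_star - 1L]) t_star <- t_star - 1L
  list(is_dead = TRUE, death_groove = g, death_time = track$t_s[t_star])
}

#' Walking activity
#'
#' Mean per-second displacement (mm) over all alive fly-seconds: the summed
#' step lengths of flies that are alive at the end of each 1 s interval,
#' divided by the number of such fly-seconds. Dead flies contribute nothing
#' after death. Defined as 0 when no alive fly-seconds exist.
#'
#' @param tracks A track table with `t_s`, `fly_id`, `x_mm`, `y_mm`, `status`.
#' @return Walking activity in mm/s.
#' @export
walking_activity <- function(tracks) {
  steps <- tracks %>%
    dplyr::arrange(.data$fly_id, .data$t_s) %>%
    dplyr::group_by(.data$fly_id) %>%
    dplyr::mutate(step = sqrt((.data$x_mm - dplyr::lag(.data$x_mm))^2 +
                                (.data$y_mm - dplyr::lag(.data$y_mm))^2)) %>%
    dplyr::ungroup() %>%
    dplyr::filter(!is.na(.data$step), .data$status == "alive")
  if (nrow(steps) == 0L) return(0)
  mean(steps$step)
}

#' Screen kinematic metrics of one ring-gap experiment
#'
#' Computes the primary-screen parameters from a 1 Hz track table: the
#' maximum of the cohort's mean distance from centre (relative units) and
#' the time of its first attainment, the number of drowned flies per groove
#' and their percentage, and the walking activity.
#'
#' @param tracks A `ring_tracks` tibble (e.g. from
#'   [simulate_ring_experiment()] or [read_track_table()]).
#' @param geometry An [arena_geometry()]; defaults to the attached one.
#' @param eps Immobility tolerance (mm) for death detection.
#' @return A one-row tibble with `line_id`, `replicate`, `n_flies`,
#'   `max_mean_distance`, `time_to_max`, `pct_dead`, `n_dead`,
#'   `walking_activity` and a list-column `dead_per_groove`.
#' @examples
#' tr <- simulate_ring_experiment(ringgap_profile("control"), seed = 1,
#'                                duration = 120)
#' ring_metrics(tr)
#' @export
ring_metrics <- function(tracks, geometry = attr(tracks, "geometry"),
                         eps = 0.5) {
  if (is.null(geometry)) {
    abort_validation("No geometry attached to `tracks`; pass `geometry` explicitly.")
  }
  check_track_grid(tracks)
  series <- mean_distance_series(tracks, geometry)
  mx <- max_mean_distance_and_time(series)
  flies <- split(tracks[order(tracks$t_s), ], tracks$fly_id[order(tracks$t_s)])
  deaths <- purrr::map(flies, detect_deaths_from_track,
                       geometry = geometry, eps = eps)
  n_grooves <- length(geometry$groove_widths)
  groove_idx <- purrr::map_int(deaths, "death_groove")
  dead_per_groove <- tabulate(groove_idx[!is.na(groove_idx)], nbins = n_grooves)
  n <- length(flies)
  n_dead <- sum(purrr::map_lgl(deaths, "is_dead"))
  tibble::tibble(
    line_id = attr(tracks, "line_id") %||% NA_character_,
    replicate = attr(tracks, "replicate") %||% NA_integer_,
    n_flies = n,
    max_mean_distance = mx$max_mean_distance,
    time_to_max = mx$time_to_max,
    n_dead = n_dead,
    pct_dead = 100 * n_dead / n,
    walking_activity = walking_activity(tracks),
    dead_per_groove = list(dead_per_groove)
  )
}

#' @importFrom rlang %||% .data
#' @importFrom dplyr %>%
NULL

#' @export
glance.ring_tracks <- function(x, ...) ring_metrics(x)
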