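#' Write and read ring-assay track tables
#'
#' The track CSV dialect: comma-separated, UTF-8, `.` decimal, mandatory
#' header `t_s,fly_id,x_mm,y_mm,status` with `status` in `alive`/`dead`.
#' A metadata sidecar JSON (`<stem>_meta.json`) stores line id, replicate,
#' seed and the geometry. Writing then reading then writing again is
#' byte-identical.
#'
#' @param tracks A `ring_tracks` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  df <- tracks %>%
    dplyr::select("t_s", "fly_id", "x_mm", "y_mm", "status") %>%
    dplyr::arrange(.data$fly_id, .data$t_s) %>%
    # micron precision keeps the dialect stable across write/read cycles
    dplyr::mutate(x_mm = round(.data$x_mm, 3), y_mm = round(.data$y_mm, 3))
  readr::write_csv(df, path, progress = FALSE)
  geom <- attr(tracks, "geometry")
  meta <- list(
    line_id = attr(tracks, "line_id"),
    replicate = attr(tracks, "replicate"),
    seed = attr(tracks, "seed"),
    geometry = if (!is.null(geom)) unclass(geom),
    profile = attr(tracks, "profile")$name
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), "_meta.json")
}

#' @rdname write_track_table
#' @param n_flies Expected number of flies (`NULL` to accept any count).
#' @return For `read_track_table()`, a validated `ring_tracks` tibble with
#'   geometry and labels restored from the sidecar when present.
#' @export
read_track_table <- function(path, n_flies = 15) {
  if (!file.exists(path)) abort_validation(paste0("No such file: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    t_s = readr::col_double(), fly_id = readr::col_integer(),
    x_mm = readr::col_double(), y_mm = readr::col_double(),
    status = readr::col_character()), progress = FALSE)
  if (!identical(names(df), c("t_s", "fly_id", "x_mm", "y_mm", "status"))) {
    abort_validation("Malformed header: expected t_s,fly_id,x_mm,y_mm,status.")
  }
  if (any(!df$status %in% c("alive", "dead"))) {
    abort_validation("`status` must be 'alive' or 'dead'.")
  }
  if (any(df$t_s %% 1 != 0)) {
    abort_validation("Timestamps must be whole seconds on a 1 Hz grid.")
  }
  flies <- unique(df$fly_id)
  if (!is.null(n_flies) && length(flies) != n_flies) {
    abort_validation(paste0("Expected ", n_flies, " flies but found ",
                            length(flies), "."))
  }
  check_track_grid(df)
  flips <- df %>%
    dplyr::arrange(.data$fly_id, .data$t_s) %>%
    dplyr::group_by(.data$fly_id) %>%
    dplyr::summarise(flip = any(.data$status == "alive" &
                                  dplyr::lag(.data$status, default = "alive") ==
                                  "dead"),
                     .groups = "drop")
  if (any(flips$flip)) {
    abort_validation("Status flips dead -> alive; dead flies must stay dead.")
  }
  frozen <- df %>%
    dplyr::filter(.data$status == "dead") %>%
    dplyr::group_by(.data$fly_id) %>%
    dplyr::summarise(moves = dplyr::n_distinct(paste(.data$x_mm, .data$y_mm)),
                     .groups = "drop")
  if (any(frozen$moves > 1)) {
    abort_validation("Dead flies must keep a constant position.")
  }
  meta_path <- sidecar_path(path)
  geom <- NULL
  line_id <- NA_character_
  replicate <- NA_integer_
  seed <- NA_integer_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$geometry)) {
      geom <- arena_geometry(
        disk_radius = meta$geometry$disk_radius,
        disk_height = meta$geometry$disk_height,
        recess_radius = meta$geometry$recess_radius,
        groove_widths = meta$geometry$groove_widths,
        groove_inner_radii = meta$geometry$groove_inner_radii,
        ceiling_gap = meta$geometry$ceiling_gap)
    }
    line_id <- meta$line_id %||% NA_character_
    replicate <- meta$replicate %||% NA_integer_
    seed <- meta$seed %||% NA_integer_
  }
  new_ring_tracks(df, geometry = geom, line_id = line_id,
                  replicate = replicate, seed = seed)
}

#' Write and read approach logs
#'
#' CSV dialect `line_id,gap_mm,visibility,fly_id,approach,attempted,fell,
#' crossed` with 0/1 flags. Validation on read enforces ten approaches per
#' fly and the event invariants (a fall or crossing implies an attempt; an
#' approach cannot both fall and cross).
#'
#' @param log An `approach_log` tibble.
#' @param path CSV path.
#' @return `path` invisibly; for `read_approach_log()`, the validated log.
#' @export
write_approach_log <- function(log, path) {
  df <- log %>%
    dplyr::mutate(attempted = as.integer(.data$attempted),
                  fell = as.integer(.data$fell),
                  crossed = as.integer(.data$crossed))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_approach_log
#' @param n_approaches Expected approaches per fly.
#' @export
read_approach_log <- function(path, n_approaches = 10L) {
  if (!file.exists(path)) abort_validation(paste0("No such file: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    line_id = readr::col_character(), gap_mm = readr::col_double(),
    visibility = readr::col_character(), fly_id = readr::col_integer(),
    approach = readr::col_integer(), attempted = readr::col_integer(),
    fell = readr::col_integer(), crossed = readr::col_integer()),
    progress = FALSE)
  if (any(!df$visibility %in% c("dark", "clear", "striped"))) {
    abort_validation("`visibility` must be dark, clear or striped.")
  }
  if (any(!unlist(df[, c("attempted", "fell", "crossed")]) %in% 0:1)) {
    abort_validation("Flags must be 0/1.")
  }
  df <- dplyr::mutate(df, attempted = .data$attempted == 1,
                      fell = .data$fell == 1, crossed = .data$crossed == 1)
  validate_approach_log(df, n_approaches)
  structure(df, class = c("approach_log", class(tibble::tibble())))
}

profile_from_list <- function(spec) {
  allowed <- c("name", "attempt_curve", "success_given_approach",
               "fall_given_attempt", "perception", "speed_mean", "speed_sd",
               "turn_p0", "persistence_tau", "crossing_duration",
               "approach_refractory")
  unknown <- setdiff(names(spec), allowed)
  if (length(unknown) > 0) {
    abort_config(paste0("Unknown profile keys: ",
                        paste(unknown, collapse = ", "), "."))
  }
  if (is.null(spec$attempt_curve)) {
    abort_config("Profile is missing `attempt_curve`.")
  }
  if (is.null(spec$success_given_approach)) {
    abort_config("Profile is missing `success_given_approach`.")
  }
  perc <- spec$perception %||% list()
  args <- list(
    name = spec$name %||% "unnamed",
    attempt_curve = as_curve(spec$attempt_curve, "attempt_curve"),
    success_given_approach = as_curve(spec$success_given_approach,
                                      "success_given_approach"),
    perception = perception_params(gain = perc$gain %||% 1,
                                   c_clear = perc$c_clear %||% 0.2,
                                   c_striped = perc$c_striped %||% 1.5))
  for (k in c("fall_given_attempt", "speed_mean", "speed_sd", "turn_p0",
              "persistence_tau", "crossing_duration",
              "approach_refractory")) {
    if (!is.null(spec[[k]])) args[[k]] <- spec[[k]]
  }
  do.call(behavior_profile, args)
}

#' Read a behaviour profile from JSON or YAML
#'
#' Curves are given as lists of `[width, probability]` pairs (or data
#' frames); all probability invariants are checked and unknown keys are
#' rejected. The packaged profiles are also available as JSON under
#' `system.file("extdata/profiles", package = "ringgap")`.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return A [behavior_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) abort_config(paste0("No such file: ", path))
  spec <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  }
  profile_from_list(spec)
}

#' Write a behaviour profile to JSON
#'
#' @param profile A [behavior_profile()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  spec <- list(
    name = profile$name,
    attempt_curve = as.data.frame(profile$attempt_curve),
    success_given_approach = as.data.frame(profile$success_given_approach),
    fall_given_attempt = profile$fall_given_attempt,
    perception = unclass(profile$perception),
    speed_mean = profile$speed_mean, speed_sd = profile$speed_sd,
    turn_p0 = profile$turn_p0, persistence_tau = profile$persistence_tau,
    crossing_duration = profile$crossing_duration,
    approach_refractory = profile$approach_refractory)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read an arena geometry from JSON
#'
#' @param path A `.json` file with the [arena_geometry()] fields.
#' @return An [arena_geometry()].
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) abort_config(paste0("No such file: ", path))
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  arena_geometry(
    disk_radius = g$disk_radius %||% 69,
    disk_height = g$disk_height %||% 15,
    recess_radius = g$recess_radius %||% 10,
    groove_widths = g$groove_widths %||% c(2, 2.5, 3, 3.5, 4),
    groove_inner_radii = g$groove_inner_radii,
    ceiling_gap = g$ceiling_gap %||% 3)
}

#' Write a run manifest
#'
#' Every pipeline invocation records what ran: the command label, a hash of
#' its configuration, the seed, input/output paths, package version and a
#' timestamp. Reruns with equal configuration and seed reproduce identical
#' outputs for the deterministic stages.
#'
#' @param command Command label.
#' @param config Configuration object (hashed into the manifest).
#' @param seed Integer seed.
#' @param inputs,outputs Character vectors of paths.
#' @param path Manifest JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, config, seed, inputs, outputs, path) {
  manifest <- list(
    command = command,
    config_hash = rlang::hash(config),
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("ringgap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
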