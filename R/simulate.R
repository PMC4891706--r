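#' @keywords internal
#' Seed for fly-level RNG substreams: fixed offsets from the experiment seed
#' so that adding flies never changes earlier flies' trajectories.
fly_seed <- function(seed, fly_id) {
  as.integer((as.numeric(seed) + 1000003 * fly_id) %% .Machine$integer.max)
}

# One second of the correlated random walk. The fly turns (new uniform
# heading) with probability p0 / (1 + t / tau) -- turning gets rarer with
# time, so paths straighten and the swarm disperses outward -- then advances
# at a truncated-normal speed. Reflection at the disk rim and (once a fly has
# left the recess) at the recess wall. Groove encounters are resolved by the
# caller through a crossing decision, never by stepping into the water.
#
# `state` is a list: x, y, heading, t, has_left (logical).
random_walk_step <- function(state, profile, geometry) {
  p_turn <- profile$turn_p0 / (1 + state$t / profile$persistence_tau)
  heading <- state$heading
  if (p_turn > 0 && stats::runif(1) < p_turn) {
    heading <- stats::runif(1, 0, 2 * pi)
  }
  speed <- profile$speed_mean
  if (profile$speed_sd > 0) {
    speed <- max(0, stats::rnorm(1, profile$speed_mean, profile$speed_sd))
  }
  nx <- state$x + speed * cos(heading)
  ny <- state$y + speed * sin(heading)
  r <- sqrt(nx^2 + ny^2)
  edge <- 0.1 # mm standoff from reflecting walls and groove edges
  rim <- geometry$disk_radius - edge
  if (r > rim) {
    nx <- nx * rim / r
    ny <- ny * rim / r
    heading <- atan2(-ny, -nx) # head back toward centre
    r <- rim
  }
  if (state$has_left && r < geometry$recess_radius + edge) {
    s <- (geometry$recess_radius + edge) / max(r, 1e-9)
    nx <- nx * s
    ny <- ny * s
    heading <- atan2(ny, nx) # head outward again
    r <- geometry$recess_radius + edge
  }
  list(x = nx, y = ny, heading = heading, t = state$t + 1,
       has_left = state$has_left || r > geometry$recess_radius + edge)
}

# First groove whose annulus the radial interval [r0, r1] (direction-aware)
# enters; returns list(index, at_inner) or NULL.
first_groove_crossed <- function(r0, r1, geometry) {
  inner <- geometry$groove_inner_radii
  outer <- geometry$groove_outer_radii
  if (r1 > r0) { # outbound: first inner edge passed
    hit <- which(inner > r0 - 1e-9 & inner < r1)
    if (length(hit) == 0L) return(NULL)
    list(index = hit[1L], at_inner = TRUE)
  } else if (r1 < r0) { # inbound: first outer edge passed
    hit <- which(outer < r0 + 1e-9 & outer > r1)
    if (length(hit) == 0L) return(NULL)
    list(index = hit[length(hit)], at_inner = FALSE)
  } else NULL
}

#' Simulate one ring-gap experiment
#'
#' Places `n_flies` flies in the centre recess and lets them explore the
#' climbing disk for `duration` seconds, recorded at 1 Hz. Whenever a fly's
#' path reaches a groove edge it decides whether to attempt a crossing with
#' probability [attempt_probability()] evaluated at the
#' [effective_width()] of that groove; an attempt ends in a fall (the fly
#' drowns and its position freezes at the groove midline at the crossing
#' azimuth), a successful crossing (a timed teleport to the far edge over
#' `crossing_duration` seconds) or a retreat. Declined encounters reverse
#' the heading away from the groove and start the profile's approach
#' refractory, during which groove edges act as reflecting walls; this
#' limits how often a fly re-approaches a gap within the recording.
#' Identical seeds give identical output.
#'
#' @param profile A [behavior_profile()].
#' @param geometry An [arena_geometry()].
#' @param n_flies Number of flies (15 in the screen).
#' @param duration Recording length in seconds (600 in the screen).
#' @param seed Integer seed; every source of randomness derives from it.
#' @param line_id,replicate Labels stored as attributes on the result.
#' @return A tibble of class `ring_tracks` with columns `t_s`, `fly_id`,
#'   `x_mm`, `y_mm`, `status` (`"alive"`/`"dead"`), one row per fly and
#'   second, plus attributes `geometry`, `profile`, `line_id`, `replicate`,
#'   `seed` and `death_groove` (per-fly groove index or `NA`).
#' @examples
#' tr <- simulate_ring_experiment(ringgap_profile("control"), seed = 1,
#'                                duration = 60)
#' dplyr::count(tr, status)
#' @export
simulate_ring_experiment <- function(profile,
                                     geometry = arena_geometry(),
                                     n_flies = 15,
                                     duration = 600,
                                     seed = 1,
                                     line_id = profile$name,
                                     replicate = 1L) {
  stopifnot(inherits(profile, "behavior_profile"),
            inherits(geometry, "arena_geometry"))
  if (n_flies < 1) abort_config("`n_flies` must be at least 1.")
  if (duration < 2) abort_config("`duration` must be at least 2 s.")
  w_eff <- effective_width(geometry$groove_widths, profile$perception, "dark")
  p_att <- attempt_probability(w_eff, profile)
  p_fall <- profile$fall_given_attempt
  q_cross <- cross_given_attempt_nofall(geometry$groove_widths, profile)
  edge <- 0.1

  xs <- matrix(NA_real_, duration, n_flies)
  ys <- matrix(NA_real_, duration, n_flies)
  dead <- matrix(FALSE, duration, n_flies)
  death_groove <- rep(NA_integer_, n_flies)
  n_attempts <- 0L

  for (fly in seq_len(n_flies)) {
    withr::with_seed(fly_seed(seed, fly), {
      r0 <- geometry$recess_radius * sqrt(stats::runif(1))
      th0 <- stats::runif(1, 0, 2 * pi)
      state <- list(x = r0 * cos(th0), y = r0 * sin(th0),
                    heading = stats::runif(1, 0, 2 * pi), t = 0,
                    has_left = FALSE)
      xs[1, fly] <- state$x
      ys[1, fly] <- state$y
      busy_until <- -1   # crossing in progress until this time
      pending <- NULL    # landing position after the crossing
      refract_until <- -1 # no new groove decisions before this time
      is_dead <- FALSE
      for (t in seq_len(duration - 1L)) {
        if (is_dead) {
          xs[t + 1L, fly] <- xs[t, fly]
          ys[t + 1L, fly] <- ys[t, fly]
          dead[t + 1L, fly] <- TRUE
          next
        }
        if (t < busy_until) { # mid-crossing: hold at the proximal edge
          xs[t + 1L, fly] <- xs[t, fly]
          ys[t + 1L, fly] <- ys[t, fly]
          next
        }
        if (t == busy_until && !is.null(pending)) {
          xs[t + 1L, fly] <- pending$x
          ys[t + 1L, fly] <- pending$y
          state$x <- pending$x
          state$y <- pending$y
          state$t <- t
          pending <- NULL
          next
        }
        prev_r <- sqrt(state$x^2 + state$y^2)
        nxt <- random_walk_step(state, profile, geometry)
        new_r <- sqrt(nxt$x^2 + nxt$y^2)
        gc <- first_groove_crossed(prev_r, new_r, geometry)
        if (is.null(gc)) {
          state <- nxt
        } else {
          gi <- gc$index
          near <- if (gc$at_inner) geometry$groove_inner_radii[gi] - edge
                  else geometry$groove_outer_radii[gi] + edge
          far <- if (gc$at_inner) geometry$groove_outer_radii[gi] + edge
                 else geometry$groove_inner_radii[gi] - edge
          # stop at the near edge along the step direction
          az <- segment_azimuth(state$x, state$y, nxt$x, nxt$y,
                                if (gc$at_inner) geometry$groove_inner_radii[gi]
                                else geometry$groove_outer_radii[gi])
          state$x <- near * cos(az)
          state$y <- near * sin(az)
          state$t <- t
          state$has_left <- TRUE
          if (t < refract_until) {                       # groove acts as wall
            state$heading <- az + if (gc$at_inner) pi else 0
          } else if (stats::runif(1) < p_att[gi]) {      # attempt
            n_attempts <- n_attempts + 1L
            if (stats::runif(1) < p_fall) {              # fall -> drown
              mid <- (geometry$groove_inner_radii[gi] +
                        geometry$groove_outer_radii[gi]) / 2
              state$x <- mid * cos(az)
              state$y <- mid * sin(az)
              is_dead <- TRUE
              death_groove[fly] <- gi
            } else if (stats::runif(1) < q_cross[gi]) {  # cross (teleport)
              busy_until <- t + profile$crossing_duration
              pending <- list(x = far * cos(az), y = far * sin(az))
            } else {                                     # retreat
              state$heading <- az + if (gc$at_inner) pi else 0
              refract_until <- t + profile$approach_refractory
            }
          } else {                                       # decline: turn back
            state$heading <- az + if (gc$at_inner) pi else 0
            refract_until <- t + profile$approach_refractory
          }
        }
        xs[t + 1L, fly] <- state$x
        ys[t + 1L, fly] <- state$y
        dead[t + 1L, fly] <- is_dead
      }
    })
  }

  out <- tibble::tibble(
    t_s = rep(0:(duration - 1L), times = n_flies),
    fly_id = rep(seq_len(n_flies), each = duration),
    x_mm = as.vector(xs),
    y_mm = as.vector(ys),
    status = ifelse(as.vector(dead), "dead", "alive")
  )
  res <- new_ring_tracks(out, geometry = geometry, profile = profile,
                         line_id = line_id, replicate = replicate,
                         seed = seed, death_groove = death_groove)
  attr(res, "n_attempts") <- n_attempts
  res
}

new_ring_tracks <- function(df, geometry, profile = NULL, line_id = NA_character_,
                            replicate = NA_integer_, seed = NA_integer_,
                            death_groove = NULL) {
  structure(
    tibble::as_tibble(df),
    geometry = geometry, profile = profile, line_id = line_id,
    replicate = replicate, seed = seed, death_groove = death_groove,
    class = c("ring_tracks", class(tibble::tibble()))
  )
}

# Azimuth of the point where the segment (x0,y0)->(x1,y1) first reaches
# radius r (falls back to the endpoint azimuth if the root is degenerate).
segment_azimuth <- function(x0, y0, x1, y1, r) {
  dx <- x1 - x0
  dy <- y1 - y0
  a <- dx^2 + dy^2
  b <- 2 * (x0 * dx + y0 * dy)
  cc <- x0^2 + y0^2 - r^2
  disc <- b^2 - 4 * a * cc
  if (a < 1e-12 || disc < 0) return(atan2(y1, x1))
  s <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
  s <- s[s >= -1e-9 & s <= 1 + 1e-9]
  if (length(s) == 0L) return(atan2(y1, x1))
  atan2(y0 + s[1] * dy, x0 + s[1] * dx)
}

#' Simulate a single-gap catwalk session
#'
#' Scores `n_flies` flies, ten voluntary approaches each, at one gap width
#' and visibility condition. Each approach is attempted (leg-over-head
#' climbing) with probability [attempt_probability()] at the
#' [effective_width()]; an attempt falls with the profile's per-attempt
#' fall probability, otherwise it crosses with a per-attempt probability
#' calibrated so that at gain 1 the per-approach success equals the
#' profile's success curve at the *true* width.
#'
#' @param profile A [behavior_profile()].
#' @param setup A [catwalk_setup()].
#' @param n_flies Number of flies (at least 10 per line in the assay).
#' @param seed Integer seed.
#' @param line_id Label stored in the log.
#' @param n_approaches Approaches per fly (10 in the assay).
#' @return A tibble of class `approach_log` with columns `line_id`,
#'   `gap_mm`, `visibility`, `fly_id`, `approach`, `attempted`, `fell`,
#'   `crossed` (logical).
#' @examples
#' log <- simulate_catwalk_session(ringgap_profile("control"),
#'                                 catwalk_setup(2.5), n_flies = 10, seed = 1)
#' mean(log$attempted)
#' @export
simulate_catwalk_session <- function(profile, setup, n_flies = 10, seed = 1,
                                     line_id = profile$name,
                                     n_approaches = 10L) {
  stopifnot(inherits(profile, "behavior_profile"),
            inherits(setup, "catwalk_setup"))
  if (n_flies < 1) abort_config("`n_flies` must be at least 1.")
  w_eff <- effective_width(setup$gap_width, profile$perception, setup$visibility)
  p_att <- attempt_probability(w_eff, profile)
  p_fall <- profile$fall_given_attempt
  q_cross <- cross_given_attempt_nofall(setup$gap_width, profile)

  rows <- vector("list", n_flies)
  for (fly in seq_len(n_flies)) {
    withr::with_seed(fly_seed(seed, fly), {
      attempted <- stats::runif(n_approaches) < p_att
      fell <- attempted & (stats::runif(n_approaches) < p_fall)
      crossed <- attempted & !fell & (stats::runif(n_approaches) < q_cross)
      rows[[fly]] <- tibble::tibble(
        fly_id = fly, approach = seq_len(n_approaches),
        attempted = attempted, fell = fell, crossed = crossed)
    })
  }
  out <- dplyr::bind_rows(rows)
  out <- tibble::tibble(
    line_id = line_id,
    gap_mm = setup$gap_width,
    visibility = setup$visibility,
    out
  )
  structure(out, seed = seed,
            class = c("approach_log", class(tibble::tibble())))
}
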