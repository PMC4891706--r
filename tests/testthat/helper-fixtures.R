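# Shared fixtures for the suite; everything is built in code.

small_geometry <- function() arena_geometry()

# Profile with flat attempt/success curves: every approach is attempted with
# p_attempt and crosses with p_success per approach (fall optional). Used to
# drive Bernoulli-style sessions with known per-approach probabilities.
bernoulli_profile <- function(p_attempt = 1, p_success = p_attempt,
                              fall = 0, name = "bernoulli") {
  behavior_profile(
    name,
    attempt_curve = data.frame(width = c(2, 6), prob = c(p_attempt, p_attempt)),
    success_given_approach = data.frame(width = c(2, 6),
                                        prob = c(p_success, p_success)),
    fall_given_attempt = fall)
}

# Two-fly debug track table: each fly fixed at a given relative radius.
fixed_radius_tracks <- function(r_rel, duration = 10,
                                geometry = arena_geometry()) {
  n <- length(r_rel)
  df <- tidyr::expand_grid(fly_id = seq_len(n), t_s = 0:(duration - 1))
  df$x_mm <- r_rel[df$fly_id] * geometry$disk_radius
  df$y_mm <- 0
  df$status <- "alive"
  df <- df[, c("t_s", "fly_id", "x_mm", "y_mm", "status")]
  structure(tibble::as_tibble(df), geometry = geometry,
            class = c("ring_tracks", class(tibble::tibble())))
}

# Hand-built approach log from per-fly outcome counts.
manual_log <- function(n_attempt, n_fall = 0, n_cross = 0, gap = 2.5,
                       line_id = "line", n_approaches = 10) {
  stopifnot(n_fall + n_cross <= n_attempt, n_attempt <= n_approaches)
  attempted <- c(rep(TRUE, n_attempt), rep(FALSE, n_approaches - n_attempt))
  fell <- c(rep(TRUE, n_fall), rep(FALSE, n_approaches - n_fall))
  crossed <- c(rep(FALSE, n_fall), rep(TRUE, n_cross),
               rep(FALSE, n_approaches - n_fall - n_cross))
  tibble::tibble(line_id = line_id, gap_mm = gap, visibility = "dark",
                 fly_id = 1L, approach = seq_len(n_approaches),
                 attempted = attempted, fell = fell, crossed = crossed)
}

# Median of Binomial(n, p) (smallest m with CDF >= 1/2): the independent
# oracle for median per-fly fractions.
binom_median <- function(n, p) {
  m <- 0
  while (stats::pbinom(m, n, p) < 0.5) m <- m + 1
  m
}
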