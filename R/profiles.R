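#' Perception parameters of the gap-width decision model
#'
#' Flies judge gap width from the parallax motion of the distal gap edge
#' during approach. The model summarises manipulations of this percept by a
#' multiplicative gain `g` (1 = control; > 1 = enhanced parallax, as under
#' silencing of the inhibitory C2/C3 feedback neurons; < 1 = attenuated, as
#' under their artificial depolarization) and a per-visibility contrast
#' factor `c` (dark sidewall = 1; clear Perspex < 1; black-and-white stripes
#' > 1). The perceived ("effective") width is `w / (g * c)`.
#'
#' @param gain Perception gain, > 0.
#' @param c_clear Contrast factor for the clear catwalk, > 0 (default 0.2).
#' @param c_striped Contrast factor for the striped sidewall, > 0 (default 1.5).
#' @return An object of class `perception_params`.
#' @examples
#' perception_params(gain = 1.6) # C2/C3-block-like
#' @export
perception_params <- function(gain = 1, c_clear = 0.2, c_striped = 1.5) {
  if (!all(is.finite(c(gain, c_clear, c_striped))) ||
      any(c(gain, c_clear, c_striped) <= 0)) {
    abort_config("Perception gain and contrast factors must be positive.")
  }
  structure(list(gain = gain, c_clear = c_clear, c_striped = c_striped),
            class = "perception_params")
}

contrast_factor <- function(perception, visibility) {
  switch(visibility,
         dark = 1,
         clear = perception$c_clear,
         striped = perception$c_striped,
         abort_config(paste0("Unknown visibility condition: '", visibility, "'.")))
}

#' Effective (perceived) gap width
#'
#' The decision-relevant width: true width divided by perception gain and the
#' visibility contrast factor. Strictly decreasing in both; equals the true
#' width for a control fly (`gain = 1`) at a dark gap (`c = 1`). Enhanced
#' parallax (`gain > 1`) makes the distal side appear closer, so gaps appear
#' narrower and climbing readiness rises.
#'
#' @param w True gap width in mm, > 0.
#' @param perception A [perception_params()] object.
#' @param visibility `"dark"`, `"clear"` or `"striped"`.
#' @return Effective width in mm.
#' @examples
#' effective_width(4, perception_params(gain = 2), "dark") # 2
#' @export
effective_width <- function(w, perception = perception_params(),
                            visibility = "dark") {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0)) {
    abort_config("Gap width `w` must be positive and finite.")
  }
  w / (perception$gain * contrast_factor(perception, visibility))
}

validate_curve <- function(curve, name, non_increasing = TRUE) {
  if (is.null(curve) || nrow(curve) < 1) {
    abort_config(paste0("`", name, "` must contain at least one (width, probability) knot."))
  }
  if (!all(c("width", "prob") %in% names(curve))) {
    abort_config(paste0("`", name, "` must have columns `width` and `prob`."))
  }
  if (any(diff(curve$width) <= 0)) {
    abort_config(paste0("`", name, "` knot widths must be strictly increasing."))
  }
  if (any(curve$prob < 0 | curve$prob > 1)) {
    abort_config(paste0("`", name, "` probabilities must lie in [0, 1]."))
  }
  if (non_increasing && any(diff(curve$prob) > 1e-12)) {
    abort_config(paste0("`", name, "` must be non-increasing in width."))
  }
  curve
}

as_curve <- function(x, name) {
  if (is.data.frame(x)) {
    x <- x[, c("width", "prob")]
  } else if (is.list(x)) {
    x <- data.frame(width = vapply(x, `[[`, numeric(1), 1),
                    prob = vapply(x, `[[`, numeric(1), 2))
  } else if (is.matrix(x)) {
    x <- data.frame(width = x[, 1], prob = x[, 2])
  } else {
    abort_config(paste0("`", name, "` must be a two-column data frame, matrix or list of pairs."))
  }
  tibble::as_tibble(x)
}

#' Per-line behaviour profile for the simulator
#'
#' Bundles the simulation parameters of one genotype: the attempt-probability
#' curve over effective gap width, the per-approach success curve over true
#' gap width, the per-attempt fall probability, the perception parameters,
#' and locomotor parameters of the correlated random walk (speed, initial
#' turn probability, persistence timescale) plus the crossing duration.
#'
#' @param name Profile label.
#' @param attempt_curve Two-column (`width`, `prob`) knots of the control-scale
#'   attempt probability as a function of effective width; non-increasing.
#' @param success_given_approach Knots of the per-approach crossing
#'   probability at gain 1 as a function of true width; non-increasing.
#' @param fall_given_attempt Probability that an attempt ends with a fall.
#' @param perception A [perception_params()] object.
#' @param speed_mean,speed_sd Walking speed distribution, mm/s.
#' @param turn_p0 Initial per-second turn probability of the random walk.
#' @param persistence_tau Timescale (s) over which the turn probability
#'   decays, producing increasingly straight outward paths.
#' @param crossing_duration Time (s) a successful crossing occupies.
#' @param approach_refractory Time (s) after a declined or retreated groove
#'   encounter during which the fly treats groove edges as walls instead of
#'   re-deciding; limits how often a fly re-approaches the same gap.
#' @return An object of class `behavior_profile`.
#' @examples
#' ringgap_profile("control")
#' @export
behavior_profile <- function(name,
                             attempt_curve,
                             success_given_approach,
                             fall_given_attempt = 0.01,
                             perception = perception_params(),
                             speed_mean = 8, speed_sd = 3,
                             turn_p0 = 0.5, persistence_tau = 60,
                             crossing_duration = 3,
                             approach_refractory = 60) {
  attempt_curve <- validate_curve(as_curve(attempt_curve, "attempt_curve"),
                                  "attempt_curve")
  success_given_approach <- validate_curve(
    as_curve(success_given_approach, "success_given_approach"),
    "success_given_approach")
  if (fall_given_attempt < 0 || fall_given_attempt > 1) {
    abort_config("`fall_given_attempt` must lie in [0, 1].")
  }
  if (speed_mean <= 0) abort_config("`speed_mean` must be positive.")
  if (speed_sd < 0) abort_config("`speed_sd` must be non-negative.")
  if (turn_p0 < 0 || turn_p0 > 1) abort_config("`turn_p0` must lie in [0, 1].")
  if (persistence_tau <= 0) abort_config("`persistence_tau` must be positive.")
  if (crossing_duration < 1) abort_config("`crossing_duration` must be at least 1 s.")
  if (approach_refractory < 0) abort_config("`approach_refractory` must be non-negative.")
  stopifnot(inherits(perception, "perception_params"))
  structure(
    list(name = name,
         attempt_curve = attempt_curve,
         success_given_approach = success_given_approach,
         fall_given_attempt = fall_given_attempt,
         perception = perception,
         speed_mean = speed_mean, speed_sd = speed_sd,
         turn_p0 = turn_p0, persistence_tau = persistence_tau,
         crossing_duration = crossing_duration,
         approach_refractory = approach_refractory),
    class = "behavior_profile"
  )
}

#' @export
print.behavior_profile <- function(x, ...) {
  cat("<behavior_profile>", x$name,
      "| gain", x$perception$gain,
      "| fall|attempt", x$fall_given_attempt,
      "| speed", x$speed_mean, "mm/s\n")
  invisible(x)
}

interp_curve <- function(curve, w) {
  if (nrow(curve) == 1L) return(rep(curve$prob, length(w)))
  p <- stats::approx(curve$width, curve$prob, xout = w, rule = 2)$y
  pmin(pmax(p, 0), 1)
}

#' Attempt probability at an effective gap width
#'
#' Piecewise-linear interpolation of the profile's attempt-curve knots,
#' clamped to the knot range and to \[0, 1\]; non-increasing in effective
#' width. The packaged control profile is anchored at 80% attempts at
#' 2.5 mm and falls linearly to 15% at 6.0 mm.
#'
#' @param w_eff Effective gap width in mm (see [effective_width()]).
#' @param profile A [behavior_profile()].
#' @return Attempt probability in \[0, 1\] (vectorised over `w_eff`).
#' @examples
#' attempt_probability(2.5, ringgap_profile("control")) # 0.8
#' @export
attempt_probability <- function(w_eff, profile) {
  if (!is.numeric(w_eff) || any(!is.finite(w_eff)) || any(w_eff <= 0)) {
    abort_config("`w_eff` must be positive and finite.")
  }
  interp_curve(profile$attempt_curve, w_eff)
}

#' Outcome probabilities at a true gap width
#'
#' Returns the per-approach crossing probability (interpolated from the
#' profile's success curve at the *true* width; outcomes depend on physical
#' width, only the decision to attempt depends on the perceived width) and
#' the constant per-attempt fall probability.
#'
#' @param w_true True gap width in mm.
#' @param profile A [behavior_profile()].
#' @return A list with `p_cross_given_approach` and `p_fall_given_attempt`.
#' @examples
#' outcome_probabilities(2.5, ringgap_profile("control"))$p_cross_given_approach # 0.7
#' @export
outcome_probabilities <- function(w_true, profile) {
  if (!is.numeric(w_true) || any(!is.finite(w_true)) || any(w_true <= 0)) {
    abort_config("`w_true` must be positive and finite.")
  }
  list(
    p_cross_given_approach = interp_curve(profile$success_given_approach, w_true),
    p_fall_given_attempt = profile$fall_given_attempt
  )
}

# Per-attempt crossing probability conditional on not falling, calibrated so
# that at gain = contrast = 1 the realized per-approach success equals the
# profile's success curve. Depends only on the true width, which makes the
# per-attempt success fraction independent of perception manipulations.
cross_given_attempt_nofall <- function(w_true, profile) {
  s <- interp_curve(profile$success_given_approach, w_true)
  a <- interp_curve(profile$attempt_curve, w_true)
  f <- profile$fall_given_attempt
  q <- ifelse(a > 0, s / (a * (1 - f)), 0)
  pmin(pmax(q, 0), 1)
}

profile_defaults <- function() {
  ctrl_attempt <- data.frame(width = c(2.5, 6.0), prob = c(0.80, 0.15))
  ctrl_success <- data.frame(width = c(2.5, 4.0), prob = c(0.70, 18 / 440))
  list(
    control = behavior_profile(
      "control", ctrl_attempt, ctrl_success,
      fall_given_attempt = 0.01),
    overcautious = behavior_profile(
      "overcautious",
      data.frame(width = c(2.5, 6.0), prob = c(0.15, 0.02)),
      data.frame(width = c(2.5, 4.0), prob = c(0.13, 0.02)),
      fall_given_attempt = 0, speed_mean = 2, speed_sd = 1),
    clumsy = behavior_profile(
      "clumsy", ctrl_attempt, ctrl_success,
      fall_given_attempt = 0.5),
    tarsi_clumsy = behavior_profile(
      "tarsi_clumsy", ctrl_attempt, ctrl_success,
      fall_given_attempt = 0.13),
    overeager = behavior_profile(
      "overeager", ctrl_attempt, ctrl_success,
      fall_given_attempt = 0.01,
      perception = perception_params(gain = 1.6)),
    c2_activated = behavior_profile(
      "c2_activated", ctrl_attempt, ctrl_success,
      fall_given_attempt = 0.01,
      perception = perception_params(gain = 0.6)),
    c2_activated_27c = behavior_profile(
      "c2_activated_27c", ctrl_attempt, ctrl_success,
      fall_given_attempt = 0.01,
      perception = perception_params(gain = 0.8)),
    super_climber = behavior_profile(
      "super_climber",
      data.frame(width = c(2.5, 6.0), prob = c(0.90, 0.35)),
      data.frame(width = c(2.5, 4.0), prob = c(0.70, 40 / 300)),
      fall_given_attempt = 0.01, speed_mean = 11, speed_sd = 3)
  )
}

#' Packaged behaviour profiles
#'
#' Eight ready-made profiles spanning the screen phenotypes: `control`
#' (80% attempts / 70% success at 2.5 mm, linear decline to 15% attempts at
#' 6 mm), `overcautious` (low attempt rate, low activity, no falls),
#' `clumsy` (half of attempts end in a fall), `tarsi_clumsy` (13% of
#' attempts fall, reduced grip), `overeager` (perception gain 1.6, as under
#' C2/C3 block), `c2_activated` (gain 0.6) and `c2_activated_27c` (gain 0.8,
#' intermediate depolarization), and `super_climber` (elevated attempt curve
#' and activity; per-approach success 40/300 at 4 mm). Values beyond the
#' anchored control statistics are free defaults.
#'
#' @param name Profile name; see Details. Use `ringgap_profiles()` to list all.
#' @return A [behavior_profile()] (or, for `ringgap_profiles()`, a character
#'   vector of available names).
#' @examples
#' ringgap_profiles()
#' ringgap_profile("overeager")$perception$gain
#' @export
ringgap_profile <- function(name) {
  defs <- profile_defaults()
  if (!name %in% names(defs)) {
    abort_config(paste0("Unknown profile '", name, "'. Available: ",
                        paste(names(defs), collapse = ", "), "."))
  }
  defs[[name]]
}

#' @rdname ringgap_profile
#' @export
ringgap_profiles <- function() names(profile_defaults())
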